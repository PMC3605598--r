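---
title: "Flow-space duplicate filtering: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-space duplicate filtering: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The duplicate problem in flow space

454 pyrosequencing reads a DNA template through cyclic nucleotide flows
(T, A, C, G). Each flow reports a continuous flow value `f`, roughly the
number of identical bases incorporated, stored to two decimals in the SFF
container. Emulsion-PCR artifacts create clusters of reads sequenced
independently from copies of one template molecule: all members start at
the same template position, but each receives its own noise and its own
length. `flowdedup` identifies these clusters directly on the flow values.
Working in flow space matters because homopolymer-length uncertainty — the
dominant 454 error mode — is continuous there: a flow value of 2.53 says
"probably 3, possibly 2" while the called sequence says only "3".

## The probability model

Three distributions drive everything: the homopolymer-length prior `P(h)`,
the flow-value likelihood `P(f | h)` (widening towards later flow cycles as
signal quality degrades), and, via Bayes' theorem, the posterior `P(h | f)`.
For two flow values observed at the same flow position of two reads, the
probability that both represent the same homopolymer length is the inner
product of their posteriors over `h = 0..5`, under the assumption that the
two flowgrams are independent. That independence assumption is not strictly
true (carry-forward and incomplete extension correlate neighbouring flows),
but the vendor software partly corrects for those effects and we adopt the
assumption as the working approximation.

Two capping rules guard the poorly resolved high-signal regime: the
agreement probability is fixed to exactly 1 when at least one value exceeds
5.5, or when both exceed 2.5. Long homopolymers therefore never separate
two reads; discrimination is carried by the well-resolved low flow values.
The sum over `h = 0..5` deliberately excludes posterior mass at `h > 5`,
which combines with the caps to down-weight long homopolymers. In the mixed
case — one value in (2.5, 5.5], the other at or below 2.5 — neither cap
fires and the sum applies; this is the literal reading of the two stated
conditions, and it behaves sensibly (a clear 0-mer against a clear 3-mer
scores essentially zero).

One subtlety worth knowing: as a function of the partner value `f_b`, the
agreement probability for a fixed `f_a` peaks where the partner's posterior
is most *concentrated* on `round(f_a)` — near the integer — not exactly at
`f_b = f_a`. The effect is tiny (1e-9 at `f_a = 1.0`) but means "equal flow
values maximize agreement" holds only per homopolymer basin, which is how
the test suite asserts it.

### The parametric default model

The published empirical distributions are not reproducible from first
principles, so the default model is an explicitly labelled parametric
stand-in with the same qualitative structure; empirical tables can be
supplied via `load_lookup_model()` behind the same interface. Parameters:

| parameter          | default | meaning                                                            |
|--------------------|---------|--------------------------------------------------------------------|
| `base_sigma`       | 0.10    | likelihood s.d. offset (flow-value units) at `h = 0`               |
| `sigma_slope`      | 0.02    | extra s.d. per unit homopolymer length                             |
| `degradation_rate` | 0.002   | relative widening per flow cycle (~20 % wider at cycle 100)        |
| `lambda0`          | 23      | exponential rate of the `h = 0` likelihood (mean negative flow 0.04) |
| `prior_ratio`      | 0.4     | geometric decay of `P(h)`; `P(0)` is 0.6                           |
| `h_max`            | 11      | largest explicitly modelled homopolymer length                     |

For `h >= 1` the likelihood is normal, centred at `h`, with standard
deviation `(base_sigma + sigma_slope * h) * (1 + degradation_rate * c)`,
truncated at zero; for `h = 0` it is exponential, concentrating mass well
below the 0.5 calling boundary. The widths were chosen once so that the
posterior argmax boundary between adjacent homopolymer lengths falls within
about 0.05 of the half-integer calling boundaries — i.e. the model base
calls the way a 454 instrument does — and so that noise magnitudes match
the commonly reported ~0.1 s.d. for short homopolymers, growing with `h`
and with cycle. They were not revisited after seeing test results.

## The distance and its exact form

Over the shared informative window (first flow after the key through
`min(400, trim end of a, trim end of b)` flows, flows aligned by absolute
index because duplicates share their start by construction), the distance
is

    d = 1 - (prod p_i)^(1/n)

one minus the geometric mean of the per-flow agreement probabilities. The
per-`n` normalization keeps `d` in [0, 1] and comparable across window
lengths, and makes a stringency threshold interpretable as an average
per-flow mismatch probability — which is what makes 0.05 a sensible
default and 0.01–0.10 the useful sweep range. Any monotone transform of
the product (e.g. an average negative log probability) would order merges
identically; only the threshold scale would change. This choice is the one
place where the package fixes a formula the source material leaves
ambiguous, and it is flagged as such.

Numerics: the product is accumulated as a sum of logarithms (a naive
product underflows to zero near `d = 1`; the test oracle learned this the
hard way), and `d = 0` exactly if and only if every compared pair falls
under a capping rule. Flow values are quantized to hundredths (half-up,
matching the SFF uint16/100 encoding and the half-up base-calling
convention), so per-cycle posterior grids at 0.01 resolution are *exact*
caches, not approximations; the cache is required to agree with direct
evaluation to 1e-6 and in fact agrees bit-for-bit on grid values.

## Preclustering

Full pairwise clustering is quadratic, so reads are first binned by a seed
over their first 8 informative flows, recording only each flow's sign —
positive (`f >= 0.5`, at least one called base) or negative — plus the
called length of the first positive flow, so that all reads in a bin start
with the same homopolymer length. Values exactly at 0.5 are positive,
consistent with base calling. Bins above 2000 reads are split by extending
the seed one flow at a time (the extension step is a package choice; any
small step gives the same fixed points). A bin whose seed is exhausted but
still oversized is passed through whole with a warning rather than
truncated — preclustering must never silently drop comparisons inside a
bin, only between bins. The cost of binning is that duplicates whose noise
flips a seed sign are lost to each other; under the default noise model a
sign flip requires a ~4 sigma excursion, so this is rare.

## Clustering and consensus

Within a bin, clustering is agglomerative with *consensus linkage*: the
distance between clusters is the distance between their consensus
flowgrams, where the consensus is the per-flow median over members
(midpoint for even counts), windowed to the shortest member trim — the
median tracks the cluster's shared signal because true duplicate clusters
stretch to one side of the integer per flow. After each merge the merged
cluster's consensus and its distances to all other clusters are updated;
clustering stops when the minimum pairwise distance exceeds the threshold.
Ties on the minimum break towards the lexicographically smallest pair of
cluster indices, making results deterministic for a given input order. The
implementation keeps a distance matrix and recomputes only the merged row;
its contract is partition-identical agreement with a naive reference that
rebuilds everything from scratch at every step, which the suite checks on
100 random bins.

A consequence worth stating: the threshold only stops the merge sequence,
it does not reorder it. Partitions at increasing thresholds are therefore
nested, so the estimated duplicate rate is non-decreasing in the threshold
on any fixed input — the monotone column structure a stringency sweep
produces.

## Representatives

`longest` keeps the member with the most called bases in its trimmed
region; `best` keeps the member minimizing the squared deviation of flow
values from their nearest integers, normalized by the number of trimmed
*flows* (the score is a per-flow quantity, so flow count rather than called
bases is the right normalizer — base-length normalization would
double-count long homopolymers); `consensus` emits the artificial median
flowgram. Ties break by length, then input order.

## Evaluation

Ground truth from alignments groups reads by (reference, strand-aware
start, 16-base read prefix). Instead of mapping twice against the genome
and its reverse complement and keeping forward matches, reverse-strand SAM
records are canonicalized: the strand-aware start is the alignment end on
the forward axis and the prefix is the reverse complement of the read's
last bases — the same grouping with half the bookkeeping; the equivalence
is asserted on constructed alignments. Records whose CIGAR begins with a
hard clip are discarded (their read start is masked and not comparable);
leading soft clips are kept and counted in a message, since the clipped
bases are still present in the record.

The pair-counting Jaccard index `J = a/(a + b + c)` is computed with
size-based combinatorics (sums of `choose(n, 2)` over the contingency
table), exact in integer-valued doubles, and verified against brute-force
pair enumeration. When neither partition contains any pair, `J` is defined
as 1 — the limit of identical partitions; an all-singleton *prediction*
against a truth with pairs gives `J = 0` (`a = 0`). Classification metrics
(sensitivity/specificity) are deliberately absent: it matters *which* reads
are clustered together, not merely whether a read is flagged as some
duplicate.

The duplicate rate of a partition is `100 * (n_reads - n_clusters) /
n_reads`: the fraction removed when keeping one representative per
cluster.

## The simulator: what it emulates and what it does not

`simulate_run()` draws a uniform-random genome (default 50 kb), places
clusters at distinct template starts, and sequences each member
independently: ideal flows from the template through the TACG cycle, noise
from the *same parametric family* as the default model (normal with
h- and cycle-dependent width for `h >= 1`, exponential for `h = 0`),
quantized to hundredths, with independent per-member length truncation at
flow boundaries and clip points set at the truncation. Defaults: 1000
reads, duplicate rate 0.2 (within the 11–35 % range reported for real
454 data), cluster sizes 2/3/4/5 with probabilities 0.75/0.18/0.05/0.02
(the observed size spectrum: three quarters of duplicate clusters are
pairs), trimmed length 250 ± 50 flows (about 140 bases — at the short end
of Titanium output, chosen to keep desk-scale runs fast while exceeding
the 8-flow seed and the useful distance window), 800 flows per record
(Titanium). The realized duplicate rate equals the target exactly because
cluster sizes are capped during drawing. Template starts whose first base
equals the last key base are skipped so the key's final flow never merges
with template signal; real pipelines face that edge case, this simulator
sidesteps it.

What the simulator does **not** emulate — and what a green test therefore
does not establish: carry-forward/incomplete-extension correlations
between flows (the model's independence assumption is exactly true in
simulation, optimistically so); natural duplicates from deep coverage
(all same-start clusters are artificial by construction); chimeras,
adapter read-through, or any empirical flow-value distribution (noise is
model-matched unless `noise$scale` or the noise parameters are changed,
so parameter-recovery results are upper bounds on real-data performance).
A mismatched-noise robustness check is available simply by clustering
with a different model than was simulated (e.g. a lookup table exported
from other parameters).

## Degenerate inputs and edge policies

Empty read sets produce empty partitions; empty FASTA ids, negative flow
values, heterogeneous flow orders, empty comparison windows, and
mismatched read-id universes raise typed errors naming the offending
reads. Clip points use the quality clips (`clip_qual_*`), not adapter
clips; SFF's `0 = no clipping` convention maps to the full called
sequence. Index blocks in SFF files are skipped on read and never
written. Flows are 1-based everywhere in the API and logs.

## Known limitations

IonTorrent SFF files parse, but the model defaults are pyrosequencing
defaults; no IonTorrent presets are provided or recommended. Thresholds
are tied to the geometric-mean distance form: results from tools using a
different (if monotone-equivalent) form need rescaled thresholds, though
merge order is identical. Preclustering bounds recall: duplicates split by
a seed sign flip are unrecoverable downstream. Runtime is dominated by
within-bin pairwise distances and grows with duplication depth; the
per-cycle posterior cache makes repeated sweeps on one model cheap.
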