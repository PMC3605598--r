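SFF_MAGIC <- as.raw(c(0x2e, 0x73, 0x66, 0x66))  # ".sff"
SFF_VERSION <- as.raw(c(0, 0, 0, 1))

pad8 <- function(n) as.integer((8L - n %% 8L) %% 8L)

r_u16 <- function(r, off) {
  readBin(r[(off + 1L):(off + 2L)], "integer", size = 2L,
          endian = "big", signed = FALSE)
}
r_u32 <- function(r, off) {
  v <- readBin(r[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "big")
  if (v < 0) stop("unsupported field value > 2^31 in SFF header")
  v
}
r_u64 <- function(r, off) {
  hi <- r_u32(r, off); lo <- r_u32(r, off + 4L)
  hi * 2^32 + lo
}

w_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2L, endian = "big")
w_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4L, endian = "big")

#' Read an SFF file
#'
#' Parses the binary standard flowgram format written by 454 instruments
#' (and by [write_sff]): a common header carrying the flow order and key
#' sequence, followed by one record per read with name, clip points, flow
#' values stored as big-endian 16-bit hundredths, per-base flow indices,
#' called bases and qualities. An index block, if present, is skipped.
#'
#' Quality clip points (`clip_qual_left/right`) define the informative
#' region; adapter clips are read but not used. SFF's "0 = no clipping"
#' convention is mapped to the full called sequence.
#'
#' @param path Path to an SFF file.
#' @return List of [flowgram] objects, in file order.
#' @export
read_sff <- function(path) {
  if (!file.exists(path)) stop(sprintf("SFF file '%s' does not exist", path))
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 31L)
    stop(sprintf("'%s' is not SFF: file shorter than the 31-byte common header",
                 path))
  if (!identical(r[1:4], SFF_MAGIC))
    stop(sprintf("'%s' is not SFF: bad magic number at offset 0", path))
  if (!identical(r[5:8], SFF_VERSION))
    stop(sprintf("'%s': unsupported SFF version at offset 4", path))
  index_offset <- r_u64(r, 8L)
  index_length <- r_u32(r, 16L)
  n_reads <- r_u32(r, 20L)
  header_length <- r_u16(r, 24L)
  key_length <- r_u16(r, 26L)
  n_flows <- r_u16(r, 28L)
  fmt <- as.integer(r[31L])
  if (fmt != 1L)
    stop(sprintf("'%s': unknown flowgram format code %d", path, fmt))
  flow_chars <- rawToChar(r[32L:(31L + n_flows)])
  key <- if (key_length > 0)
    rawToChar(r[(32L + n_flows):(31L + n_flows + key_length)]) else ""
  off <- header_length  # already padded to 8 in the stored value

  out <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    if (index_offset > 0 && off == index_offset) off <- off + index_length
    if (off + 16L > length(r))
      stop(sprintf("'%s': truncated at read %d (read header)", path, i))
    name_length <- r_u16(r, off + 2L)
    n_bases <- r_u32(r, off + 4L)
    clip_ql <- r_u16(r, off + 8L)
    clip_qr <- r_u16(r, off + 10L)
    name <- rawToChar(r[(off + 17L):(off + 16L + name_length)])
    off <- off + 16L + name_length
    off <- off + pad8(16L + name_length)
    need <- 2L * n_flows + 3L * n_bases
    if (off + need > length(r))
      stop(sprintf("'%s': truncated at read %d (read data)", path, i))
    fv_raw <- readBin(r[(off + 1L):(off + 2L * n_flows)], "integer",
                      n = n_flows, size = 2L, endian = "big", signed = FALSE)
    off <- off + need
    off <- off + pad8(need)
    if (clip_ql == 0L) clip_ql <- 1L
    out[[i]] <- flowgram(read_id = name, flow_values = fv_raw / 100,
                         flow_order = flow_chars, key_sequence = key,
                         clip_left = clip_ql, clip_right = clip_qr)
  }
  out
}

#' Write flowgrams to an SFF file
#'
#' Produces a standard SFF file that [read_sff] (and other SFF readers) can
#' parse; reading it back reproduces every flowgram field. Called bases are
#' regenerated from the flow values by rounding, qualities are written as a
#' constant placeholder, and no index block is emitted.
#'
#' @param flowgrams List of [flowgram] objects sharing flow order, key
#'   sequence and flow count.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sff <- function(flowgrams, path) {
  if (length(flowgrams) > 0) {
    fo <- vapply(flowgrams, function(f) f$flow_order, "")
    key <- vapply(flowgrams, function(f) f$key_sequence, "")
    nf <- vapply(flowgrams, function(f) f$n_flows, 0L)
    if (length(unique(fo)) != 1L || length(unique(key)) != 1L ||
        length(unique(nf)) != 1L)
      stop("all flowgrams must share flow_order, key_sequence and n_flows")
    flow_chars <- fo[1]; key <- key[1]; n_flows <- nf[1]
  } else {
    flow_chars <- "TACG"; key <- "TCAG"; n_flows <- 4L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(SFF_MAGIC, con)
  writeBin(SFF_VERSION, con)
  w_u32(con, 0L); w_u32(con, 0L)       # index offset (none), as two words
  w_u32(con, 0L)                       # index length
  w_u32(con, length(flowgrams))
  hlen <- 31L + n_flows + nchar(key)
  hlen <- hlen + pad8(hlen)
  w_u16(con, hlen)
  w_u16(con, nchar(key))
  w_u16(con, n_flows)
  writeBin(as.raw(1L), con)            # flowgram format code
  writeBin(charToRaw(flow_chars), con)
  if (nchar(key) > 0) writeBin(charToRaw(key), con)
  writeBin(raw(pad8(31L + n_flows + nchar(key))), con)

  for (fg in flowgrams) {
    hund <- round(fg$flow_values * 100)
    if (any(abs(fg$flow_values * 100 - hund) > 1e-9)) {
      message(sprintf("read '%s': flow values quantized to hundredths on write",
                      fg$read_id))
    }
    bases <- flow_to_bases(fg)
    n_bases <- nchar(bases)
    bfi <- base_flow_index(fg)
    name_length <- nchar(fg$read_id)
    rh <- 16L + name_length
    w_u16(con, rh + pad8(rh))
    w_u16(con, name_length)
    w_u32(con, n_bases)
    w_u16(con, fg$clip_left)
    w_u16(con, fg$clip_right)
    w_u16(con, 0L); w_u16(con, 0L)     # adapter clips: none
    writeBin(charToRaw(fg$read_id), con)
    writeBin(raw(pad8(rh)), con)
    w_u16(con, hund)
    writeBin(as.raw(diff(c(0L, bfi))), con)  # flow index per base, deltas
    if (n_bases > 0) writeBin(charToRaw(bases), con)
    writeBin(as.raw(rep(30L, n_bases)), con)
    writeBin(raw(pad8(2L * fg$n_flows + 3L * n_bases)), con)
  }
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector (names are record ids) or a list of
#'   `(id, sequence)` pairs.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.list(records)) {
    ids <- vapply(records, `[[`, "", 1L)
    seqs <- vapply(records, `[[`, "", 2L)
  } else {
    ids <- names(records)
    seqs <- unname(records)
  }
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every FASTA record needs a non-empty id")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
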