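#' Sequencing reads with per-base qualities
#'
#' Minimal container for a read and its Phred-scale quality values (QV),
#' as used by the averaged-QV trimming rule.
#'
#' @param read_id identifier.
#' @param sequence nucleotide string.
#' @param qualities integer vector of Phred QVs, one per base, all `>= 0`.
#' @param mate_id optional identifier of the paired mate.
#' @return An object of class `quality_read`.
#' @export
quality_read <- function(read_id, sequence, qualities, mate_id = NA_character_) {
  sequence <- as.character(sequence)
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities))
    stop("sequence length and number of quality values differ")
  if (any(qualities < 0))
    stop("quality values must be >= 0")
  structure(list(read_id = as.character(read_id), sequence = sequence,
                 qualities = qualities, mate_id = mate_id),
            class = "quality_read")
}

#' @export
print.quality_read <- function(x, ...) {
  cat(sprintf("<quality_read> %s: %d bp (mean QV %.1f)\n", x$read_id,
              length(x$qualities),
              if (length(x$qualities)) mean(x$qualities) else NA_real_))
  invisible(x)
}

#' @export
length.quality_read <- function(x) length(x$qualities)

#' Mark low-quality bases by windowed average QV
#'
#' A base is marked low-quality when the arithmetic mean QV over the base and
#' its adjacent neighbours (a `+/- window_halfwidth` window, clipped at the
#' read ends so terminal bases average over the existing values only) falls
#' below `qv_threshold`.
#'
#' @param read a [quality_read].
#' @param qv_threshold mark when the window mean is `< qv_threshold`.
#' @param window_halfwidth number of neighbours on each side (default 1,
#'   i.e. the base plus one adjacent nucleotide each way).
#' @return Logical vector, one element per base; `TRUE` = marked.
#' @export
mark_low_quality <- function(read, qv_threshold = 20, window_halfwidth = 1L) {
  q <- read$qualities
  n <- length(q)
  if (n == 0L) return(logical(0))
  cs <- cumsum(c(0, q))
  lo <- pmax(seq_len(n) - window_halfwidth, 1L)
  hi <- pmin(seq_len(n) + window_halfwidth, n)
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  means < qv_threshold
}

#' Trim marked terminal bases
#'
#' Marking is computed once on the original read; the maximal contiguous runs
#' of marked positions at the 5' and 3' ends are removed. Interior marked
#' positions are retained (no iterative re-marking).
#'
#' @inheritParams mark_low_quality
#' @return A [quality_read]; zero-length if every base is marked.
#' @export
trim_read <- function(read, qv_threshold = 20, window_halfwidth = 1L) {
  mask <- mark_low_quality(read, qv_threshold, window_halfwidth)
  keep <- which(!mask)
  if (length(keep) == 0L)
    return(quality_read(read$read_id, "", integer(0), read$mate_id))
  from <- keep[1L]; to <- keep[length(keep)]
  quality_read(read$read_id, substr(read$sequence, from, to),
               read$qualities[from:to], read$mate_id)
}

#' Pair-level length selection
#'
#' After trimming, a pair is kept only if both mates retain at least
#' `min_len` nucleotides; failure of either mate drops the whole pair.
#'
#' @param read1,read2 trimmed [quality_read] mates.
#' @param min_len minimum retained length per mate (inclusive).
#' @return `TRUE` (keep) or `FALSE` (drop the pair).
#' @export
keep_pair <- function(read1, read2, min_len = 20L) {
  length(read1) >= min_len && length(read2) >= min_len
}

#' Optional exact adapter clipping
#'
#' Convenience removal of an exact adapter occurring as a prefix or suffix of
#' the read; adapter removal is normally assumed to have happened upstream.
#'
#' @inheritParams mark_low_quality
#' @param adapter adapter sequence (exact match only).
#' @export
clip_adapter <- function(read, adapter) {
  if (is.null(adapter) || !nzchar(adapter)) return(read)
  s <- read$sequence; q <- read$qualities; la <- nchar(adapter)
  if (startsWith(s, adapter)) {
    s <- substr(s, la + 1L, nchar(s)); q <- q[-seq_len(la)]
  }
  if (nchar(s) >= la && endsWith(s, adapter)) {
    s <- substr(s, 1L, nchar(s) - la); q <- q[seq_len(nchar(s))]
  }
  quality_read(read$read_id, s, q, read$mate_id)
}

#' Read a FASTQ file into quality reads
#'
#' Four-line FASTQ records with Phred+33 qualities, parsed via Biostrings.
#'
#' @param path FASTQ file.
#' @return List of [quality_read] objects, in file order.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- S4Vectors::mcols(x)$qualities
  ids <- names(x)
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    qv <- as.integer(as(Biostrings::PhredQuality(quals[[i]]), "IntegerList")[[1L]])
    out[[i]] <- quality_read(ids[i], as.character(x[[i]]), qv)
  }
  out
}

#' Write quality reads as FASTQ
#'
#' @param reads list of [quality_read] objects.
#' @param path output FASTQ file.
#' @export
write_fastq <- function(reads, path) {
  seqs <- vapply(reads, function(r) r$sequence, "")
  # Phred+33 encoding of the integer QVs
  quals <- vapply(reads, function(r) rawToChar(as.raw(r$qualities + 33L)), "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- vapply(reads, function(r) r$read_id, "")
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Trim paired FASTQ files
#'
#' End-to-end read QC over two synchronized FASTQ files: windowed-QV marking,
#' terminal trimming, and pair-level length selection. Read order and pairing
#' are preserved; dropped pairs are removed from both outputs.
#'
#' @param in1,in2 input FASTQ paths (mate 1 / mate 2, same order).
#' @param out1,out2 output FASTQ paths.
#' @param min_qv windowed-mean QV threshold.
#' @param min_len minimum post-trim length per mate.
#' @param adapter optional exact adapter to clip before marking.
#' @return Invisibly, a list with counts `n_in` and `n_kept`.
#' @export
trim_fastq_pairs <- function(in1, in2, out1, out2, min_qv = 20, min_len = 20L,
                             adapter = NULL) {
  r1 <- read_fastq(in1); r2 <- read_fastq(in2)
  if (length(r1) != length(r2))
    stop("paired FASTQ files differ in record count")
  if (!is.null(adapter)) {
    r1 <- lapply(r1, clip_adapter, adapter = adapter)
    r2 <- lapply(r2, clip_adapter, adapter = adapter)
  }
  t1 <- lapply(r1, trim_read, qv_threshold = min_qv)
  t2 <- lapply(r2, trim_read, qv_threshold = min_qv)
  keep <- mapply(keep_pair, t1, t2, MoreArgs = list(min_len = min_len))
  write_fastq(t1[keep], out1)
  write_fastq(t2[keep], out2)
  invisible(list(n_in = length(r1), n_kept = sum(keep)))
}
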