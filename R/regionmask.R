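#' High-confidence region masks
#'
#' A `region_mask` is a set of sorted, non-overlapping, half-open intervals
#' `[start, end)` in 0-based coordinates, one interval set per chromosome.
#' Masks represent callable "target regions": genomic territory that survives
#' the exclusion filters and inside which variant calls are considered
#' high-confidence. Interval algebra is delegated to IRanges; this wrapper
#' pins down the coordinate convention and the mask invariants.
#'
#' @param chrom character vector of chromosome names (recycled against
#'   `start`/`end`).
#' @param start,end integer vectors; 0-based half-open interval bounds with
#'   `start < end`.
#' @param chrom_lengths optional named integer vector of chromosome lengths,
#'   kept as metadata and used for clipping/complement operations.
#' @return An object of class `region_mask`.
#' @examples
#' m <- region_mask("chr1", c(0L, 50L), c(10L, 60L))
#' mask_total_length(m)
#' @export
region_mask <- function(chrom = character(), start = integer(), end = integer(),
                        chrom_lengths = NULL) {
  if (length(start) != length(end))
    stop("start and end must have equal length")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(start))
  if (length(chrom) != length(start))
    stop("chrom must have length 1 or length(start)")
  start <- as.numeric(start); end <- as.numeric(end)
  keep <- end > start            # empty/negative intervals contribute nothing
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  ranges <- lapply(split(seq_along(start), chrom), function(i) {
    IRanges::reduce(IRanges::IRanges(start = start[i] + 1L, end = end[i]))
  })
  new_region_mask(ranges, chrom_lengths)
}

new_region_mask <- function(ranges, chrom_lengths = NULL) {
  ranges <- ranges[order(names(ranges))]
  ranges <- ranges[vapply(ranges, length, 1L) > 0L]
  structure(list(ranges = ranges, chrom_lengths = chrom_lengths),
            class = "region_mask")
}

#' Whole-genome mask
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return A `region_mask` covering every position of every chromosome.
#' @export
genome_mask <- function(chrom_lengths) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  region_mask(names(chrom_lengths), rep(0L, length(chrom_lengths)),
              as.integer(chrom_lengths), chrom_lengths = chrom_lengths)
}

#' Mask from single-position sites with symmetric padding
#'
#' Each site `p` contributes the interval `[p - pad, p + 1 + pad)`; overlapping
#' intervals are merged. This is the shape used by the strand-bias and
#' read-end exclusion filters ("the adjacent 10 bp sites").
#'
#' @param chrom chromosome names (length 1 or `length(pos)`).
#' @param pos 0-based site positions.
#' @param pad non-negative pad in bp on each side.
#' @inheritParams region_mask
#' @export
mask_from_sites <- function(chrom, pos, pad = 0L, chrom_lengths = NULL) {
  stopifnot(pad >= 0)
  m <- region_mask(chrom, pos - pad, pos + 1L + pad, chrom_lengths = chrom_lengths)
  mask_clip(m, chrom_lengths)
}

mask_chroms <- function(x) names(x$ranges)

merge_lengths <- function(a, b) {
  la <- a$chrom_lengths; lb <- b$chrom_lengths
  if (is.null(la)) return(lb)
  if (is.null(lb)) return(la)
  la[setdiff(names(lb), names(la))] <- lb[setdiff(names(lb), names(la))]
  la
}

#' Mask set algebra
#'
#' Union, intersection and difference of region masks, plus total covered
#' length. These satisfy the inclusion-exclusion identity
#' `|A| + |B| == |A union B| + |A intersect B|`.
#'
#' @param a,b `region_mask` objects.
#' @return `mask_union`, `mask_intersect`, `mask_diff`: a `region_mask`;
#'   `mask_total_length`: a number (sum of `end - start` over all intervals).
#' @export
mask_union <- function(a, b) {
  chroms <- union(mask_chroms(a), mask_chroms(b))
  ranges <- lapply(chroms, function(ch) {
    ra <- a$ranges[[ch]]; rb <- b$ranges[[ch]]
    if (is.null(ra)) rb else if (is.null(rb)) ra
    else IRanges::reduce(c(ra, rb))
  })
  names(ranges) <- chroms
  new_region_mask(ranges, merge_lengths(a, b))
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  chroms <- intersect(mask_chroms(a), mask_chroms(b))
  ranges <- lapply(chroms, function(ch)
    IRanges::intersect(a$ranges[[ch]], b$ranges[[ch]]))
  names(ranges) <- chroms
  new_region_mask(ranges, merge_lengths(a, b))
}

#' @rdname mask_union
#' @export
mask_diff <- function(a, b) {
  ranges <- lapply(mask_chroms(a), function(ch) {
    rb <- b$ranges[[ch]]
    if (is.null(rb)) a$ranges[[ch]] else IRanges::setdiff(a$ranges[[ch]], rb)
  })
  names(ranges) <- mask_chroms(a)
  new_region_mask(ranges, merge_lengths(a, b))
}

#' @rdname mask_union
#' @export
mask_total_length <- function(a) {
  sum(vapply(a$ranges, function(r) sum(IRanges::width(r)), numeric(1)))
}

#' Clip a mask to chromosome bounds
#'
#' @param a a `region_mask`.
#' @param chrom_lengths named lengths; defaults to the mask's own metadata.
#'   With neither available the mask is only clipped at zero.
#' @export
mask_clip <- function(a, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- a$chrom_lengths
  ranges <- lapply(mask_chroms(a), function(ch) {
    r <- IRanges::restrict(a$ranges[[ch]], start = 1L,
                           end = if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
                             as.integer(chrom_lengths[[ch]]) else NA_integer_)
    r[IRanges::width(r) > 0L]
  })
  names(ranges) <- mask_chroms(a)
  new_region_mask(ranges, chrom_lengths)
}

#' Point membership in a mask
#'
#' @param a a `region_mask`.
#' @param chrom chromosome names (length 1 or `length(pos)`).
#' @param pos 0-based positions.
#' @return Logical vector: is each position inside the mask?
#' @export
mask_contains <- function(a, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    r <- a$ranges[[ch]]
    if (!is.null(r))
      out[i] <- IRanges::overlapsAny(IRanges::IRanges(pos[i] + 1L, width = 1L), r)
  }
  out
}

#' @export
as.data.frame.region_mask <- function(x, ...) {
  if (length(x$ranges) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  dfs <- lapply(mask_chroms(x), function(ch) {
    r <- x$ranges[[ch]]
    data.frame(chrom = ch, start = IRanges::start(r) - 1, end = IRanges::end(r))
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' @export
print.region_mask <- function(x, ...) {
  n <- sum(vapply(x$ranges, length, 1L))
  cat(sprintf("<region_mask> %d interval(s) on %d chromosome(s), total length %s bp\n",
              n, length(x$ranges), format(mask_total_length(x), big.mark = ",")))
  invisible(x)
}

#' Convert between masks and GRanges
#'
#' @param a a `region_mask`.
#' @return `mask_to_granges`: a `GRanges` (1-based closed, as usual for
#'   GRanges); `granges_to_mask`: a `region_mask`.
#' @export
mask_to_granges <- function(a) {
  df <- as.data.frame(a)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
  if (!is.null(a$chrom_lengths)) {
    sl <- a$chrom_lengths[intersect(names(a$chrom_lengths),
                                    GenomeInfoDb::seqlevels(gr))]
    GenomeInfoDb::seqlengths(gr)[names(sl)] <- sl
  }
  gr
}

#' @param gr a `GRanges`.
#' @rdname mask_to_granges
#' @export
granges_to_mask <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  region_mask(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
              chrom_lengths = if (all(is.na(sl))) NULL else sl[!is.na(sl)])
}

#' Read/write masks as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param path file path.
#' @param a a `region_mask`.
#' @export
read_bed_mask <- function(path) {
  granges_to_mask(rtracklayer::import(path, format = "BED"))
}

#' @rdname read_bed_mask
#' @export
write_bed_mask <- function(a, path) {
  rtracklayer::export(mask_to_granges(a), path, format = "BED")
  invisible(path)
}
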