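#' IUPAC ambiguity code for a two-allele genotype
#'
#' @param a,b single-base alleles (vectorized).
#' @return One-letter IUPAC codes (e.g. A/G -> R).
#' @export
iupac_code <- function(a, b) {
  map <- Biostrings::IUPAC_CODE_MAP
  key <- vapply(seq_along(a), function(i)
    paste(sort(unique(c(a[i], b[i]))), collapse = ""), "")
  names(map) <- vapply(strsplit(names(map), ""), function(x)
    paste(sort(x), collapse = ""), "")
  out <- names(map)[match(key, map)]
  ifelse(is.na(out), "N", out)
}

#' Cut a strain pseudo-sequence from the reference
#'
#' Reconstructs the sequence of a strain over a requested region by applying
#' the strain's variant calls to the reference. In `snp_only` mode the output
#' has exactly the region's length, with each homozygous SNP substituting the
#' reference base and heterozygous SNPs emitting IUPAC ambiguity codes. In
#' `with_indels` mode insertions add bases and deletions remove them, so the
#' output length is the region length plus the net indel length. Under
#' `no_data_policy = "n_fill"`, reference positions outside the strain's
#' callable mask emit `N` (evaluated in reference coordinates, before indel
#' application); the default policy emits the reference base, mirroring a
#' consensus-from-pileup behaviour.
#'
#' @param reference named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param calls the strain's variant-call data frame ([call_variants()]
#'   layout; `pos` 0-based, indels anchored VCF-style).
#' @param chrom chromosome name.
#' @param start,end requested region, 1-based inclusive (the coordinate
#'   idiom of genome-browser position intervals).
#' @param mode `"snp_only"` or `"with_indels"`.
#' @param no_data_policy `"reference"` or `"n_fill"`.
#' @param mask the strain's callable [region_mask()] (required for
#'   `"n_fill"`).
#' @param max_length maximum region length accepted (default 300000).
#' @return Character scalar: the pseudo-sequence. Attributes `chrom`,
#'   `start`, `end`, `mode`, `policy` record the request.
#' @export
cut_sequence <- function(reference, calls, chrom, start, end,
                         mode = c("snp_only", "with_indels"),
                         no_data_policy = c("reference", "n_fill"),
                         mask = NULL, max_length = 300000L) {
  mode <- match.arg(mode)
  no_data_policy <- match.arg(no_data_policy)
  if (methods::is(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  if (!chrom %in% names(reference)) stop("unknown chromosome: ", chrom)
  chrom_len <- nchar(reference[[chrom]])
  if (start < 1 || end > chrom_len) stop("region off chromosome end")
  if (start > end) stop("start must be <= end")
  if (end - start + 1 > max_length)
    stop("region longer than the configured maximum (", max_length, " bp)")
  if (no_data_policy == "n_fill" && is.null(mask))
    stop("n_fill policy requires the strain's callable mask")

  s0 <- start - 1L                       # 0-based region start
  bases <- strsplit(substr(reference[[chrom]], start, end), "")[[1L]]

  if (no_data_policy == "n_fill") {
    pos0 <- s0 + seq_along(bases) - 1L
    bases[!mask_contains(mask, chrom, pos0)] <- "N"
  }

  calls <- calls[calls$chrom == chrom, , drop = FALSE]
  calls <- calls[order(calls$pos), , drop = FALSE]
  snps <- calls[calls$var_type == "SNP", , drop = FALSE]
  snps <- snps[snps$pos >= s0 & snps$pos <= end - 1L, , drop = FALSE]

  if (mode == "snp_only") {
    if (nrow(snps)) {
      i <- snps$pos - s0 + 1L
      bases[i] <- ifelse(snps$zygosity == "homozygous", snps$alt,
                         iupac_code(snps$ref, snps$alt))
    }
    out <- paste(bases, collapse = "")
  } else {
    indels <- calls[calls$var_type %in% c("insertion", "deletion"), , drop = FALSE]
    sp <- if (nrow(indels)) variant_span(indels) else
      data.frame(start = numeric(0), end = numeric(0))
    inside <- sp$start >= s0 & sp$end <= end
    if (any(!inside & sp$end > s0 & sp$start < end))
      stop("indel overlaps the region boundary; enlarge the region")
    indels <- indels[inside, , drop = FALSE]
    sp <- sp[inside, , drop = FALSE]
    # conflicts: any two variants touching the same reference footprint
    foot_start <- c(sp$start, snps$pos)
    foot_end <- c(sp$end, snps$pos + 1L)
    ord <- order(foot_start, foot_end)
    if (any(foot_start[ord][-1L] < foot_end[ord][-length(ord)])) {
      clash <- which(foot_start[ord][-1L] < foot_end[ord][-length(ord)])[1L]
      stop("overlapping variants near position ",
           foot_start[ord][clash + 1L] + 1L, " on ", chrom)
    }
    if (nrow(snps)) {
      i <- snps$pos - s0 + 1L
      bases[i] <- ifelse(snps$zygosity == "homozygous", snps$alt,
                         iupac_code(snps$ref, snps$alt))
    }
    # splice indels right to left so earlier coordinates stay valid
    if (nrow(indels)) {
      for (k in rev(seq_len(nrow(indels)))) {
        v <- indels[k, ]
        rl <- nchar(v$ref); al <- nchar(v$alt)
        i <- v$pos - s0 + 1L             # anchor index in `bases`
        if (rl > al) {                   # deletion: drop ref bases after anchor
          bases <- bases[-(i + seq_len(rl - al))]
        } else {                         # insertion: add alt bases after anchor
          ins <- strsplit(substr(v$alt, rl + 1L, al), "")[[1L]]
          bases <- append(bases, ins, after = i)
        }
      }
    }
    out <- paste(bases, collapse = "")
  }
  structure(out, chrom = chrom, start = start, end = end, mode = mode,
            policy = no_data_policy)
}

#' Write a pseudo-sequence as FASTA
#'
#' The header records strain, region, mode and no-data policy.
#'
#' @param seq output of [cut_sequence()].
#' @param path FASTA path.
#' @param strain strain name for the header.
#' @export
write_pseudo_fasta <- function(seq, path, strain = "strain") {
  x <- Biostrings::DNAStringSet(as.character(seq))
  names(x) <- sprintf("%s|%s:%d-%d|%s|%s", strain, attr(seq, "chrom"),
                      attr(seq, "start"), attr(seq, "end"),
                      attr(seq, "mode"), attr(seq, "policy"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
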