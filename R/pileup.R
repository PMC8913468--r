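#' Per-position pileup tables
#'
#' A `pileup` is a data frame with one row per covered reference position and
#' the per-allele, per-strand read support needed by the variant-site filters:
#'
#' * `chrom`, `pos` (0-based), `ref` (A/C/G/T/N), `depth`
#' * for each base `B` in A, C, G, T: `B_fwd` and `B_rev` read counts and
#'   `B_ed`, the summed distance (bp) from this position to the *nearest end*
#'   of each supporting read (`NA` when end distances are unavailable, e.g.
#'   parsed from mpileup-dialect text, which does not carry them).
#'
#' `depth` must equal the sum of the eight strand counts.
#'
#' @param df data frame in the layout above (missing count columns are
#'   zero-filled; missing `_ed` columns become `NA`).
#' @return The validated data frame with class `pileup` prepended.
#' @export
as_pileup <- function(df) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(df)))
  for (b in BASES) {
    for (suf in c("_fwd", "_rev"))
      if (is.null(df[[paste0(b, suf)]])) df[[paste0(b, suf)]] <- 0
    if (is.null(df[[paste0(b, "_ed")]])) df[[paste0(b, "_ed")]] <- NA_real_
  }
  counts <- rowSums(as.matrix(df[, paste0(rep(BASES, each = 2), c("_fwd", "_rev"))]))
  if (is.null(df$depth)) df$depth <- counts
  if (any(df$depth != counts))
    stop("depth must equal the sum of per-allele strand counts")
  df <- as.data.frame(df)
  class(df) <- c("pileup", "data.frame")
  df
}

BASES <- c("A", "C", "G", "T")

#' Build a single pileup column
#'
#' Convenience constructor for tests and worked examples.
#'
#' @param chrom,pos,ref position fields (`pos` 0-based).
#' @param counts named list: per allele, a length-2 vector
#'   `c(forward, reverse)`.
#' @param end_distances named list: per allele, the distances (bp) to the
#'   nearest read end for each supporting read.
#' @return A one-row [as_pileup()] data frame.
#' @export
pileup_column <- function(chrom, pos, ref, counts, end_distances = NULL) {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref)
  for (b in names(counts)) {
    row[[paste0(b, "_fwd")]] <- counts[[b]][1L]
    row[[paste0(b, "_rev")]] <- counts[[b]][2L]
  }
  for (b in names(end_distances)) {
    if (is.null(counts[[b]]) || sum(counts[[b]]) != length(end_distances[[b]]))
      stop("end_distances for allele ", b, " must match its read count")
    row[[paste0(b, "_ed")]] <- sum(end_distances[[b]])
  }
  as_pileup(row)
}

allele_counts <- function(p) {
  fwd <- as.matrix(p[, paste0(BASES, "_fwd")])
  rev <- as.matrix(p[, paste0(BASES, "_rev")])
  colnames(fwd) <- colnames(rev) <- BASES
  list(fwd = fwd, rev = rev, total = fwd + rev)
}

#' Most frequent non-reference allele per position
#'
#' Multi-allelic columns are reduced to their top alternative allele; the
#' strand-bias and end-distance checks are evaluated on that allele only.
#'
#' @param p a [as_pileup()] data frame.
#' @return Data frame aligned with `p`: `alt` (NA if no non-reference read),
#'   `alt_count`, `alt_fwd`, `alt_rev`, `alt_fraction` (of depth),
#'   `alt_mean_ed` (mean nearest-end distance of alt-supporting reads),
#'   `ref_fwd`, `ref_rev`, `ref_count`, `ref_fraction`.
#' @export
top_alt <- function(p) {
  ac <- allele_counts(p)
  tot <- ac$total
  n <- nrow(p)
  refi <- match(p$ref, BASES)
  tot_alt <- tot
  ok <- !is.na(refi)                      # ref N: every allele is "alternative"
  tot_alt[cbind(which(ok), refi[ok])] <- -1  # never pick the reference allele
  alti <- max.col(tot_alt, ties.method = "first")
  alt_count <- tot[cbind(seq_len(n), alti)]
  alt <- ifelse(alt_count > 0, BASES[alti], NA_character_)
  ed <- as.matrix(p[, paste0(BASES, "_ed")])
  ref_count <- ifelse(is.na(refi), 0, tot[cbind(seq_len(n), refi)])
  data.frame(
    alt = alt, alt_count = alt_count,
    alt_fwd = ac$fwd[cbind(seq_len(n), alti)],
    alt_rev = ac$rev[cbind(seq_len(n), alti)],
    alt_fraction = ifelse(p$depth > 0, alt_count / p$depth, 0),
    alt_mean_ed = ifelse(alt_count > 0,
                         ed[cbind(seq_len(n), alti)] / alt_count, NA_real_),
    ref_fwd = ifelse(is.na(refi), 0, ac$fwd[cbind(seq_len(n), refi)]),
    ref_rev = ifelse(is.na(refi), 0, ac$rev[cbind(seq_len(n), refi)]),
    ref_count = ref_count,
    ref_fraction = ifelse(p$depth > 0, ref_count / p$depth, 0))
}

#' Read/write the native per-allele pileup TSV
#'
#' Plain TSV of the [as_pileup()] columns; positions are written 1-based in
#' the file and converted back on read.
#'
#' @param path file path.
#' @param p a pileup.
#' @export
read_pileup_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  df$pos <- df$pos - 1L
  as_pileup(df)
}

#' @rdname read_pileup_tsv
#' @export
write_pileup_tsv <- function(p, path) {
  out <- as.data.frame(p)
  out$pos <- out$pos + 1L
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Parse samtools-mpileup-dialect text
#'
#' Reads the classic six-column mpileup dialect (chrom, 1-based pos, ref,
#' depth, read bases, base qualities). The read-bases string follows the
#' usual conventions: `.`/`,` reference on forward/reverse strand, upper and
#' lower case letters for alternative alleles by strand, `^X` read starts
#' (mapping-quality character skipped), `$` read ends, `*` deletion
#' placeholders, and `+n`/`-n` followed by n inserted/deleted bases (the
#' indel text is skipped; indel calls enter the pipeline as an explicit call
#' list). End distances are not represented in this dialect, so all `_ed`
#' sums are `NA`.
#'
#' @param path mpileup text file.
#' @return A [as_pileup()] data frame.
#' @export
read_mpileup <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  if (ncol(df) < 5L) stop("not an mpileup file: fewer than 5 columns")
  names(df)[1:5] <- c("chrom", "pos", "ref", "depth", "bases")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    b <- parse_mpileup_bases(df$bases[i], toupper(df$ref[i]))
    row <- data.frame(chrom = df$chrom[i], pos = df$pos[i] - 1L,
                      ref = toupper(df$ref[i]))
    for (base in BASES) {
      row[[paste0(base, "_fwd")]] <- b$fwd[[base]]
      row[[paste0(base, "_rev")]] <- b$rev[[base]]
    }
    row
  })
  as_pileup(do.call(rbind, rows))
}

parse_mpileup_bases <- function(s, ref) {
  fwd <- stats::setNames(numeric(4), BASES)
  rev <- stats::setNames(numeric(4), BASES)
  chars <- strsplit(s, "")[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }                 # read start + mapQ char
    if (ch == "$" || ch == "*" || ch == "#") { i <- i + 1L; next }
    if (ch == "+" || ch == "-") {                        # indel text: skip
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      next
    }
    if (ch == ".") { if (ref %in% BASES) fwd[ref] <- fwd[ref] + 1 }
    else if (ch == ",") { if (ref %in% BASES) rev[ref] <- rev[ref] + 1 }
    else if (ch %in% BASES) fwd[ch] <- fwd[ch] + 1
    else if (ch %in% tolower(BASES)) { b <- toupper(ch); rev[b] <- rev[b] + 1 }
    i <- i + 1L
  }
  list(fwd = as.list(fwd), rev = as.list(rev))
}
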