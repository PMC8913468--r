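#' Alignment identity with indels counted as mismatches
#'
#' Identity of a scored alignment, in percent:
#' `100 * matches / (matches + mismatches + inserted_bases + deleted_bases)`.
#' Every inserted or deleted base counts against identity exactly like a
#' substitution.
#'
#' @param matches,mismatches,inserted_bases,deleted_bases non-negative counts
#'   (vectorized).
#' @return Numeric vector of identities in `[0, 100]`.
#' @export
alignment_identity <- function(matches, mismatches, inserted_bases = 0,
                               deleted_bases = 0) {
  if (any(c(matches, mismatches, inserted_bases, deleted_bases) < 0))
    stop("alignment counts must be non-negative")
  denom <- matches + mismatches + inserted_bases + deleted_bases
  if (any(denom == 0))
    stop("unscored alignment: matches + mismatches + indel bases is zero")
  100 * matches / denom
}

#' Classify one read's alignment candidates
#'
#' A read is `unmapped` when no candidate exceeds `min_identity` percent
#' identity (strictly: identity must be `> min_identity`). Otherwise, with
#' `i1 >= i2` the two highest candidate identities (`i2 = 0` for a single
#' candidate), the read is `multi_hit` when `i1 - i2 <= ambiguity_gap`
#' (a gap of exactly the threshold is still multi-hit), else `unique`.
#' Only uniquely mapped reads propagate downstream.
#'
#' @param identity numeric vector of candidate identities (percent) for one
#'   read; may be empty.
#' @param min_identity minimum identity, percent (exclusive bound).
#' @param ambiguity_gap maximum first-to-second identity gap, percent
#'   (inclusive bound), below which the origin is ambiguous.
#' @return List with `status` (`"unique"`, `"multi_hit"` or `"unmapped"`) and
#'   `best` (index of the best candidate, or `NA`).
#' @export
classify_mapping <- function(identity, min_identity = 95, ambiguity_gap = 2) {
  if (length(identity) == 0L || !any(identity > min_identity))
    return(list(status = "unmapped", best = NA_integer_))
  ord <- order(identity, decreasing = TRUE)
  i1 <- identity[ord[1L]]
  i2 <- if (length(identity) >= 2L) identity[ord[2L]] else 0
  if (i1 - i2 <= ambiguity_gap)
    list(status = "multi_hit", best = NA_integer_)
  else
    list(status = "unique", best = ord[1L])
}

#' Classify a table of alignment candidates
#'
#' @param candidates data frame with columns `read_id`, `matches`,
#'   `mismatches`, `inserted_bases`, `deleted_bases` (and any positional
#'   columns, carried through for the best candidate).
#' @inheritParams classify_mapping
#' @return Data frame with one row per read: `read_id`, `status`,
#'   `best_identity`, plus the best candidate's remaining columns (NA unless
#'   unique).
#' @export
classify_alignments <- function(candidates, min_identity = 95, ambiguity_gap = 2) {
  stopifnot(all(c("read_id", "matches", "mismatches") %in% names(candidates)))
  if (is.null(candidates$inserted_bases)) candidates$inserted_bases <- 0
  if (is.null(candidates$deleted_bases)) candidates$deleted_bases <- 0
  ident <- alignment_identity(candidates$matches, candidates$mismatches,
                              candidates$inserted_bases, candidates$deleted_bases)
  ids <- unique(candidates$read_id)
  rows <- lapply(ids, function(id) {
    i <- which(candidates$read_id == id)
    cl <- classify_mapping(ident[i], min_identity, ambiguity_gap)
    best <- if (is.na(cl$best)) NA_integer_ else i[cl$best]
    data.frame(read_id = id, status = cl$status,
               best_identity = max(ident[i]),
               chrom = if (!is.na(best) && !is.null(candidates$chrom))
                 candidates$chrom[best] else NA_character_,
               start = if (!is.na(best) && !is.null(candidates$start))
                 candidates$start[best] else NA_real_,
               strand = if (!is.na(best) && !is.null(candidates$strand))
                 as.character(candidates$strand[best]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pair-level uniqueness
#'
#' Both mates must classify `unique` for the pair to survive.
#'
#' @param status1,status2 classification status of the two mates.
#' @return `TRUE` if the pair is retained.
#' @export
pair_unique <- function(status1, status2) {
  status1 == "unique" & status2 == "unique"
}

# CIGAR-derived per-base counts. NM = mismatches + inserted + deleted bases,
# so mismatches = NM - I - D and matches = aligned(M/= /X) - mismatches.
cigar_counts <- function(cigar, nm) {
  opt <- GenomicAlignments::cigarOpTable(cigar)
  aligned <- opt[, "M"] + opt[, "="] + opt[, "X"]
  ins <- opt[, "I"]
  del <- opt[, "D"]
  mism <- pmax(nm - ins - del, 0)
  data.frame(matches = aligned - mism, mismatches = mism,
             inserted_bases = ins, deleted_bases = del)
}

#' Read alignment candidates from SAM/BAM
#'
#' Primary and secondary records are all treated as candidates for their read.
#' Per-record counts come from the CIGAR string and the `NM` edit-distance
#' tag. SAM text input is converted through `Rsamtools::asBam()`.
#'
#' @param path SAM or BAM file.
#' @return Candidate data frame suitable for [classify_alignments()]:
#'   `read_id`, `chrom`, `start` (0-based), `strand`, `flag`, `matches`,
#'   `mismatches`, `inserted_bases`, `deleted_bases`.
#' @export
read_sam_candidates <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "flag"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  if (length(rec$qname) == 0L)
    return(data.frame(read_id = character(), chrom = character(),
                      start = numeric(), strand = character(), flag = integer(),
                      matches = numeric(), mismatches = numeric(),
                      inserted_bases = numeric(), deleted_bases = numeric()))
  nm <- rec$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(rec$qname))
  nm[is.na(nm)] <- 0L
  cc <- cigar_counts(rec$cigar, nm)
  # mates share a qname; distinguish them so each classifies independently
  mate <- ifelse(bitwAnd(rec$flag, 128L) > 0L, 2L, 1L)
  data.frame(read_id = paste0(rec$qname, "/", mate), qname = rec$qname,
             mate = mate, chrom = as.character(rec$rname),
             start = rec$pos - 1L, strand = as.character(rec$strand),
             flag = rec$flag, cc, stringsAsFactors = FALSE)
}

#' Filter a SAM file down to uniquely mapped pairs
#'
#' Classifies every read from its candidate set, requires both mates of a
#' pair to be unique, and writes (1) a SAM file retaining only primary
#' records of surviving pairs and (2) an optional per-read classification
#' TSV.
#'
#' @param in_sam input SAM path (text SAM).
#' @param out_sam output SAM path.
#' @param out_tsv optional classification TSV path.
#' @inheritParams classify_mapping
#' @return Invisibly, the classification data frame.
#' @export
filter_sam_unique <- function(in_sam, out_sam, out_tsv = NULL,
                              min_identity = 95, ambiguity_gap = 2) {
  cand <- read_sam_candidates(in_sam)
  cls <- classify_alignments(cand, min_identity, ambiguity_gap)
  # pair-level: every mate of a qname must classify unique
  cls$qname <- sub("/[12]$", "", cls$read_id)
  keep_ids <- names(which(tapply(cls$status == "unique", cls$qname, all)))
  lines <- readLines(in_sam)
  is_header <- startsWith(lines, "@")
  body <- lines[!is_header]
  qname <- vapply(strsplit(body, "\t", fixed = TRUE), `[[`, "", 1L)
  flag <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE), `[[`, "", 2L))
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  writeLines(c(lines[is_header], body[primary & qname %in% keep_ids]), out_sam)
  if (!is.null(out_tsv))
    utils::write.table(cls, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cls)
}
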