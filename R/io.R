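#' Read/write variant calls as the flat TSV dialect
#'
#' Five columns — `chrom`, `pos` (1-based in the file), `ref`, `alt`,
#' `zygosity` — the per-strain SNP-table layout used for downstream
#' comparative analyses. Variant type is inferred from the allele lengths.
#'
#' @param path file path.
#' @param calls variant-call data frame ([call_variants()] layout, `pos`
#'   0-based internally).
#' @export
read_calls_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = c("ref", "alt"))))
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  if (is.null(df$zygosity)) df$zygosity <- "homozygous"
  data.frame(chrom = df$chrom, pos = df$pos - 1L, ref = df$ref, alt = df$alt,
             var_type = infer_var_type(df$ref, df$alt),
             zygosity = df$zygosity,
             alt_fraction = if (is.null(df$alt_fraction)) NA_real_ else df$alt_fraction,
             stringsAsFactors = FALSE)
}

#' @rdname read_calls_tsv
#' @export
write_calls_tsv <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos = calls$pos + 1L,
                    ref = calls$ref, alt = calls$alt,
                    zygosity = calls$zygosity)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

infer_var_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Write variant calls as VCF 4.2
#'
#' Homozygous calls get GT `1/1`, heterozygous `0/1`. When `filtered` rows
#' are supplied (near-miss sites with the criterion that removed them), they
#' are emitted with that criterion in the FILTER column; passing calls carry
#' `PASS`.
#'
#' @param calls variant-call data frame (`pos` 0-based; written 1-based).
#' @param path output path (`.vcf.gz` is produced by vcfR; pass a path
#'   ending in `.vcf.gz`).
#' @param sample sample (strain) name for the genotype column.
#' @param filtered optional data frame like `calls` with an extra `filter`
#'   column naming the removing criterion.
#' @importClassesFrom vcfR vcfR
#' @export
write_vcf_calls <- function(calls, path, sample = "sample", filtered = NULL) {
  all_calls <- calls
  filt <- rep("PASS", nrow(calls))
  if (!is.null(filtered) && nrow(filtered)) {
    all_calls <- rbind(calls, filtered[, names(calls)])
    filt <- c(filt, filtered$filter)
  }
  ord <- order(all_calls$chrom, all_calls$pos)
  all_calls <- all_calls[ord, , drop = FALSE]; filt <- filt[ord]
  fix <- cbind(CHROM = all_calls$chrom, POS = as.character(all_calls$pos + 1L),
               ID = ".", REF = all_calls$ref, ALT = all_calls$alt,
               QUAL = ".", FILTER = filt, INFO = ".")
  gt <- cbind(FORMAT = "GT",
              ifelse(all_calls$zygosity == "homozygous", "1/1", "0/1"))
  colnames(gt) <- c("FORMAT", sample)
  v <- methods::new("vcfR",
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

#' Read variant calls from VCF
#'
#' Zygosity is taken from the first sample's GT when present (`1/1` and
#' other homozygous-alt forms map to `homozygous`); records without GT are
#' treated as homozygous. Multi-allelic ALT fields keep the first allele.
#'
#' @param path VCF path (plain or gz).
#' @return Variant-call data frame (`pos` 0-based).
#' @export
read_vcf_calls <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_calls())
  alt <- vapply(strsplit(fix$ALT, ","), `[[`, "", 1L)
  zyg <- rep("homozygous", nrow(fix))
  if (ncol(v@gt) >= 2L) {
    gt <- sub(":.*", "", v@gt[, 2L])
    a <- strsplit(gt, "[/|]")
    zyg <- vapply(a, function(x)
      if (length(unique(x)) == 1L && x[1L] != "0") "homozygous"
      else "heterozygous", "")
  }
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             ref = fix$REF, alt = alt,
             var_type = infer_var_type(fix$REF, alt),
             zygosity = zyg, alt_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

#' Read an external variant catalog
#'
#' Accepts VCF (alleles possibly comma-separated in ALT) or a TSV with
#' `chrom`, `pos` (1-based), `alt` columns. Returns the flat layout used by
#' [novelty_count()], preserving per-site candidate order.
#'
#' @param path catalog path.
#' @export
read_catalog <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
               alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    stopifnot(all(c("chrom", "pos", "alt") %in% names(df)))
    data.frame(chrom = df$chrom, pos = df$pos - 1L, alt = as.character(df$alt),
               stringsAsFactors = FALSE)
  }
}

#' Read a strain-to-subspecies grouping table
#'
#' Two-column TSV (`strain`, `subspecies`), returned as the named vector
#' expected by [subspecies_specific_sites()].
#'
#' @param path TSV path.
#' @export
read_grouping <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a phenotype trait table
#'
#' CSV or TSV with one row per animal; requires `strain` and `sex` columns.
#'
#' @param path file path.
#' @export
read_trait_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("strain", "sex") %in% names(df)))
  df
}
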