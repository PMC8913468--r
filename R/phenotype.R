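#' Derived phenotype traits
#'
#' Appends the derived traits to a trait table (one row per animal, columns
#' `strain`, `sex` and numeric trait columns):
#'
#' * adiposity index `AI = (SFAT + VFAT + DBAT) / BW * 100` — total fat
#'   tissue weight as a percentage of body weight;
#' * body mass index `BMI = BW / BL^2 * 100` with BW in g and BL
#'   (nose-to-anus length) in mm, which lands mouse BMI on the conventional
#'   g/cm^2 scale (about 0.2-0.4);
#' * each organ-weight column among `HEA`, `LIV`, `SPL`, `KID`, `TES`
#'   re-expressed as a percentage of BW in `<organ>_relBW`.
#'
#' Animals with zero or missing BW (or BL for BMI) get `NA` with a warning.
#'
#' @param tab trait data frame.
#' @return The table with derived columns appended.
#' @export
derive_traits <- function(tab) {
  stopifnot(all(c("strain", "sex") %in% names(tab)))
  need <- c("BW", "BL", "SFAT", "VFAT", "DBAT")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  bw <- tab$BW; bl <- tab$BL
  bad_bw <- !is.na(bw) & bw == 0
  bad_bl <- !is.na(bl) & bl == 0
  if (any(bad_bw)) warning(sum(bad_bw), " animal(s) with zero BW: derived traits set to NA")
  if (any(bad_bl)) warning(sum(bad_bl), " animal(s) with zero BL: BMI set to NA")
  bw[bad_bw] <- NA; bl[bad_bl] <- NA
  tab$AI <- (tab$SFAT + tab$VFAT + tab$DBAT) / bw * 100
  tab$BMI <- bw / bl^2 * 100
  for (org in intersect(c("HEA", "LIV", "SPL", "KID", "TES"), names(tab)))
    tab[[paste0(org, "_relBW")]] <- tab[[org]] / bw * 100
  tab
}

#' Flag values beyond an instrument ceiling
#'
#' Measurements at or above a configured measurable threshold are flagged and
#' set to missing, so the affected strain-sex cells drop out of testing (and
#' become untestable when fewer than 2 values remain).
#'
#' @param tab trait data frame.
#' @param limits named numeric vector: trait -> instrument ceiling. Traits
#'   without a limit are untouched.
#' @return List with `table` (censored values set to `NA`) and `flags`
#'   (logical data frame of the censored cells, one column per limited
#'   trait).
#' @export
censor_values <- function(tab, limits = NULL) {
  flags <- data.frame(row.names = seq_len(nrow(tab)))
  if (!is.null(limits))
    for (trait in names(limits)) {
      if (!trait %in% names(tab)) next
      f <- !is.na(tab[[trait]]) & tab[[trait]] >= limits[[trait]]
      flags[[trait]] <- f
      tab[[trait]][f] <- NA
    }
  list(table = tab, flags = flags)
}

#' Bonferroni-corrected pairwise t-tests for one trait and sex
#'
#' For every unordered pair of strains with at least 2 non-missing animals
#' each, a two-sided Welch (unequal-variance) t-test is run; the corrected
#' p-value is `min(1, p * m)` with `m` the number of pairs tested for this
#' trait and sex (the Bonferroni family is per trait, per sex). Classes:
#' `hisig` (corrected p < 0.001), `sig` (< 0.05), `ns`, and `nd` for
#' untestable pairs (a cell with fewer than 2 animals, or degenerate data).
#'
#' @param tab trait data frame with `strain`, `sex` and the trait column.
#' @param trait trait column name.
#' @param sex sex level to analyse (sexes are always analysed separately).
#' @param alpha,alpha_high significance and high-significance thresholds on
#'   the corrected p-value (defaults 0.05 / 0.001).
#' @param strains strain order for the output matrices (default: order of
#'   appearance).
#' @return Object of class `pairwise_sig`: list with `trait`, `sex`,
#'   `p_raw`, `p_corr` (symmetric matrices), `class` (character matrix with
#'   `ns`/`sig`/`hisig`/`nd`, `""` diagonal), `n` (animals per strain),
#'   `n_tests`.
#' @export
pairwise_tests <- function(tab, trait, sex, alpha = 0.05, alpha_high = 0.001,
                           strains = NULL) {
  stopifnot(trait %in% names(tab))
  sub <- tab[tab$sex == sex, , drop = FALSE]
  if (is.null(strains)) strains <- unique(tab$strain)
  values <- lapply(stats::setNames(strains, strains), function(s) {
    v <- sub[[trait]][sub$strain == s]
    v[!is.na(v)]
  })
  n <- vapply(values, length, 1L)
  k <- length(strains)
  p_raw <- matrix(NA_real_, k, k, dimnames = list(strains, strains))
  for (i in seq_len(max(k - 1L, 0L))) for (j in (i + 1L):k) {
    if (k < 2L) break
    x <- values[[i]]; y <- values[[j]]
    if (length(x) < 2L || length(y) < 2L) next
    p <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)  # degenerate cells
    # both cells constant: no within-group variance for a t statistic;
    # identical constants are trivially non-significant, otherwise untestable
    if (is.na(p) && stats::sd(c(x, y)) == 0) p <- 1
    p_raw[i, j] <- p_raw[j, i] <- p
  }
  m <- sum(!is.na(p_raw[upper.tri(p_raw)]))
  p_corr <- pmin(p_raw * m, 1)
  cls <- matrix("nd", k, k, dimnames = list(strains, strains))
  cls[!is.na(p_corr) & p_corr < alpha] <- "sig"
  cls[!is.na(p_corr) & p_corr < alpha_high] <- "hisig"
  cls[!is.na(p_corr) & p_corr >= alpha] <- "ns"
  diag(cls) <- ""
  structure(list(trait = trait, sex = sex, p_raw = p_raw, p_corr = p_corr,
                 class = cls, n = n, n_tests = m),
            class = "pairwise_sig")
}

#' @export
print.pairwise_sig <- function(x, ...) {
  cat(sprintf("<pairwise_sig> trait %s, sex %s: %d pair(s) tested\n",
              x$trait, x$sex, x$n_tests))
  print(x$class, quote = FALSE)
  invisible(x)
}

#' Trait-by-strain-pair significance matrix
#'
#' Runs [pairwise_tests()] for every trait and sex and assembles the
#' two-level significance grid with its summary rates.
#'
#' @param tab trait data frame.
#' @param traits trait column names.
#' @param sexes sex levels (default the levels present).
#' @inheritParams pairwise_tests
#' @return Object of class `significance_matrix`: list of `pairwise_sig`
#'   slices keyed `<trait>.<sex>`, plus a `summary()` giving per-sex rates of
#'   `sig`/`hisig` pairs over all tested comparisons.
#' @export
significance_matrix <- function(tab, traits, sexes = unique(tab$sex),
                                alpha = 0.05, alpha_high = 0.001,
                                strains = NULL) {
  slices <- list()
  for (trait in traits) for (sex in sexes)
    slices[[paste(trait, sex, sep = ".")]] <-
      pairwise_tests(tab, trait, sex, alpha, alpha_high, strains)
  structure(list(slices = slices, traits = traits, sexes = sexes),
            class = "significance_matrix")
}

#' @export
summary.significance_matrix <- function(object, ...) {
  rows <- lapply(object$sexes, function(sx) {
    cls <- unlist(lapply(object$slices[endsWith(names(object$slices),
                                                paste0(".", sx))],
                         function(s) s$class[upper.tri(s$class)]))
    tested <- sum(cls %in% c("ns", "sig", "hisig"))
    data.frame(sex = sx, comparisons = tested,
               pct_hisig = 100 * sum(cls == "hisig") / max(tested, 1L),
               pct_sig = 100 * sum(cls == "sig") / max(tested, 1L))
  })
  do.call(rbind, rows)
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("<significance_matrix> %d trait(s) x %d sex(es)\n",
              length(x$traits), length(x$sexes)))
  print(summary(x))
  invisible(x)
}

#' Per-strain five-number boxplot summaries
#'
#' Default-convention boxplot statistics (as drawn by `boxplot()` with
#' default settings): median, hinges, whiskers at the most extreme points
#' within 1.5 x IQR of the hinges, remaining points flagged as outliers.
#'
#' @inheritParams pairwise_tests
#' @return Named list per strain: `stats` (lower whisker, lower hinge,
#'   median, upper hinge, upper whisker), `n`, `outliers`.
#' @export
boxplot_summaries <- function(tab, trait, sex) {
  sub <- tab[tab$sex == sex, , drop = FALSE]
  lapply(split(sub[[trait]], sub$strain), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(list(stats = rep(NA_real_, 5L), n = 0L, outliers = numeric(0)))
    b <- grDevices::boxplot.stats(v)
    list(stats = as.numeric(b$stats), n = b$n, outliers = b$out)
  })
}
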