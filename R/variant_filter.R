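#' Filter configuration for high-confidence variant calling
#'
#' Thresholds of the five exclusion criteria that define callable target
#' regions, plus the allele-fraction bands used for genotype classes.
#'
#' @param min_depth minimum read depth at a callable position (default 10).
#' @param depth_sd_limit upper depth cutoff in standard deviations above the
#'   genome-wide mean (default 2.5); the boundary is inclusive.
#' @param indel_pad bp excluded on each side of an indel (default 10); this
#'   exclusion never applies to the indel calls themselves.
#' @param bias_pad bp excluded around a strand-biased site (default 10).
#' @param end_distance_limit sites whose alt-supporting reads lie on average
#'   within this many bp of a read end are excluded, together with the same
#'   pad around them (default 10, inclusive).
#' @param hom_fraction minimum alt-allele fraction for a homozygous call
#'   (default 0.8).
#' @param het_low,het_high alt-fraction band for a heterozygous call
#'   (defaults 0.25 / 0.75). `het_low` also defines which alleles count as
#'   part of the genotype when the strand-balance criterion is evaluated.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L, depth_sd_limit = 2.5,
                          indel_pad = 10L, bias_pad = 10L,
                          end_distance_limit = 10L,
                          hom_fraction = 0.8, het_low = 0.25, het_high = 0.75) {
  stopifnot(indel_pad >= 0, bias_pad >= 0, end_distance_limit >= 0,
            het_low > 0, het_low < het_high, het_high < hom_fraction,
            hom_fraction <= 1)
  structure(list(min_depth = min_depth, depth_sd_limit = depth_sd_limit,
                 indel_pad = indel_pad, bias_pad = bias_pad,
                 end_distance_limit = end_distance_limit,
                 hom_fraction = hom_fraction, het_low = het_low,
                 het_high = het_high),
            class = "filter_config")
}

#' Genome-wide depth statistics
#'
#' Mean and population standard deviation of read depth over covered
#' positions (depth >= 1); uncovered positions do not enter the statistics.
#'
#' @param p a [as_pileup()] data frame.
#' @return List with `mean` and `sd`.
#' @export
depth_stats <- function(p) {
  d <- p$depth[p$depth >= 1]
  if (length(d) == 0L) stop("no covered positions: depth statistics undefined")
  m <- mean(d)
  list(mean = m, sd = sqrt(mean((d - m)^2)))
}

#' Depth filter (criterion 1)
#'
#' A position is callable when
#' `min_depth <= depth <= mean + depth_sd_limit * sd` (upper bound
#' inclusive), screening out both undersampled positions and depth spikes
#' typical of collapsed repeats.
#'
#' @param p a pileup.
#' @param stats output of [depth_stats()].
#' @param cfg a [filter_config()].
#' @return A [region_mask()] of positions passing the depth criterion.
#' @export
depth_mask <- function(p, stats = depth_stats(p), cfg = filter_config()) {
  hi <- stats$mean + cfg$depth_sd_limit * stats$sd
  i <- p$depth >= cfg$min_depth & p$depth <= hi
  mask_from_sites(p$chrom[i], p$pos[i])
}

#' Strand-coverage filter (criterion 2)
#'
#' A position is callable only when it is covered by at least one forward and
#' at least one reverse read (summed over all alleles).
#'
#' @param p a pileup.
#' @return A [region_mask()].
#' @export
balance_mask <- function(p) {
  ac <- allele_counts(p)
  i <- rowSums(ac$fwd) >= 1 & rowSums(ac$rev) >= 1
  mask_from_sites(p$chrom[i], p$pos[i])
}

# 0-based half-open reference footprint of a call (anchored VCF-style
# representation: deletions alter [pos+1, pos+nchar(ref)), insertions sit at
# the junction between pos and pos+1).
variant_span <- function(calls) {
  rl <- nchar(calls$ref); al <- nchar(calls$alt)
  start <- ifelse(rl > al, calls$pos + 1L, calls$pos)
  end <- ifelse(rl > al, calls$pos + rl,
                ifelse(al > rl, calls$pos + 2L, calls$pos + 1L))
  data.frame(chrom = calls$chrom, start = start, end = end)
}

#' Indel-adjacent exclusion (criterion 3)
#'
#' For each indel with reference footprint `[s, e)`, the window
#' `[s - indel_pad, e + indel_pad)` is excluded from the SNP target regions.
#' The indel calls themselves are never removed by this criterion.
#'
#' @param indels variant-call data frame (see [call_variants()] for the
#'   layout) restricted to rows with `var_type` `"insertion"`/`"deletion"`;
#'   SNP rows are ignored.
#' @param cfg a [filter_config()].
#' @return A [region_mask()] of *excluded* intervals.
#' @export
indel_exclusion <- function(indels, cfg = filter_config()) {
  if (is.null(indels) || nrow(indels) == 0L)
    return(region_mask())
  indels <- indels[indels$var_type %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(indels) == 0L) return(region_mask())
  sp <- variant_span(indels)
  region_mask(sp$chrom, sp$start - cfg$indel_pad, sp$end + cfg$indel_pad)
}

#' Per-site strand-balance check (criterion 4)
#'
#' Every allele that is part of the site's genotype (allele fraction at least
#' `het_low` of depth, among the reference and top alternative alleles) must
#' be supported by at least one forward and one reverse read. A site whose
#' reference allele is effectively absent (below the genotype fraction, e.g.
#' a clean homozygous SNP) is judged on the alternative allele's strand
#' support alone. Example: ref A (20 fwd, 12 rev) with alt G (15 fwd, 18 rev)
#' is retained; ref A (18 fwd, 0 rev) with alt G (19 fwd, 22 rev) is biased.
#'
#' @param col a one-row pileup (see [pileup_column()]).
#' @param ref_allele,alt_allele the site's reference and candidate
#'   alternative alleles.
#' @param cfg a [filter_config()].
#' @return `"retained"` or `"biased"`.
#' @export
strand_balance_check <- function(col, ref_allele, alt_allele,
                                 cfg = filter_config()) {
  stopifnot(nrow(col) == 1L)
  af <- col[[paste0(alt_allele, "_fwd")]]; ar <- col[[paste0(alt_allele, "_rev")]]
  if (af + ar == 0)
    stop("alt allele ", alt_allele, " absent from column: not a variant site")
  rf <- col[[paste0(ref_allele, "_fwd")]]; rr <- col[[paste0(ref_allele, "_rev")]]
  if (is.null(rf)) { rf <- 0; rr <- 0 }   # reference N
  strand_balance_counts(rf, rr, af, ar, col$depth, cfg$het_low)
}

# vectorized core: genotype alleles (fraction >= het_low) need both strands
strand_balance_counts <- function(ref_fwd, ref_rev, alt_fwd, alt_rev, depth,
                                  het_low = 0.25) {
  ref_in <- (ref_fwd + ref_rev) / depth >= het_low
  alt_in <- (alt_fwd + alt_rev) / depth >= het_low
  ok <- (!ref_in | (ref_fwd >= 1 & ref_rev >= 1)) &
        (!alt_in | (alt_fwd >= 1 & alt_rev >= 1))
  ifelse(ok, "retained", "biased")
}

#' Strand-bias exclusion windows (criterion 4, regions)
#'
#' Each biased site and its adjacent `bias_pad` bp on both sides are excluded
#' from the target regions.
#'
#' @param chrom,pos biased-site coordinates (0-based).
#' @param cfg a [filter_config()].
#' @return A [region_mask()] of excluded intervals.
#' @export
bias_exclusion <- function(chrom, pos, cfg = filter_config()) {
  if (length(pos) == 0L) return(region_mask())
  mask_from_sites(chrom, pos, pad = cfg$bias_pad)
}

#' Read-end artifact check (criterion 5)
#'
#' A candidate site is an end artifact when the mean distance from the site
#' to the nearest end of its alt-supporting reads is within
#' `end_distance_limit` bp (inclusive) — the signature of alignment artifacts
#' at read termini. When end distances are unavailable (`NA`), the site is
#' retained.
#'
#' @inheritParams strand_balance_check
#' @return `"retained"` or `"end_artifact"`.
#' @export
end_distance_check <- function(col, alt_allele, cfg = filter_config()) {
  stopifnot(nrow(col) == 1L)
  cnt <- col[[paste0(alt_allele, "_fwd")]] + col[[paste0(alt_allele, "_rev")]]
  if (cnt == 0) stop("no reads support alt allele ", alt_allele)
  edsum <- col[[paste0(alt_allele, "_ed")]]
  if (is.null(edsum) || is.na(edsum)) return("retained")
  if (edsum / cnt <= cfg$end_distance_limit) "end_artifact" else "retained"
}

#' Combine masks into high-confidence target regions
#'
#' `target = (depth_mask intersect balance_mask) minus union(exclusions)`,
#' clipped to chromosome bounds when lengths are known.
#'
#' @param depth a depth-criterion [region_mask()].
#' @param balance a strand-coverage [region_mask()].
#' @param exclusions list of exclusion masks (indel-adjacent, strand-bias,
#'   read-end windows).
#' @param chrom_lengths optional named chromosome lengths for clipping.
#' @return A [region_mask()] of target regions.
#' @export
build_target_regions <- function(depth, balance, exclusions = list(),
                                 chrom_lengths = NULL) {
  target <- mask_intersect(depth, balance)
  for (ex in exclusions) target <- mask_diff(target, ex)
  mask_clip(target, chrom_lengths)
}

# candidate variant sites: the top alt allele would enter a genotype
candidate_sites <- function(p, cfg = filter_config()) {
  ta <- top_alt(p)
  i <- which(!is.na(ta$alt) & ta$alt_fraction >= cfg$het_low)
  cbind(p[i, c("chrom", "pos", "ref", "depth")], ta[i, , drop = FALSE])
}

#' Emit filtered variant calls
#'
#' At each candidate position (top alternative-allele fraction at least
#' `het_low`) inside the target regions that passes the strand-balance and
#' read-end criteria, a SNP call is emitted with zygosity `homozygous` when
#' the alt fraction is at least `hom_fraction` and `heterozygous` when it
#' falls inside `[het_low, het_high]`; fractions between `het_high` and
#' `hom_fraction` yield no call. Indel calls pass through from the upstream
#' list, filtered only by membership in target regions computed *without*
#' the indel-adjacent exclusion.
#'
#' @param p a pileup.
#' @param target SNP target regions (all five criteria applied).
#' @param cfg a [filter_config()].
#' @param indels optional upstream indel-call data frame.
#' @param indel_target target regions for indel retention (all criteria
#'   except the indel-adjacent exclusion); defaults to `target`.
#' @return Variant-call data frame: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `var_type` (`SNP`/`insertion`/`deletion`), `zygosity`, `alt_fraction`.
#' @export
call_variants <- function(p, target, cfg = filter_config(), indels = NULL,
                          indel_target = target) {
  cand <- candidate_sites(p, cfg)
  out <- empty_calls()
  if (nrow(cand) > 0L) {
    in_target <- mask_contains(target, cand$chrom, cand$pos)
    balance <- strand_balance_counts(cand$ref_fwd, cand$ref_rev,
                                     cand$alt_fwd, cand$alt_rev,
                                     cand$depth, cfg$het_low) == "retained"
    end_ok <- is.na(cand$alt_mean_ed) |
      cand$alt_mean_ed > cfg$end_distance_limit
    zyg <- ifelse(cand$alt_fraction >= cfg$hom_fraction, "homozygous",
                  ifelse(cand$alt_fraction <= cfg$het_high, "heterozygous", NA))
    keep <- in_target & balance & end_ok & !is.na(zyg)
    if (any(keep))
      out <- data.frame(chrom = cand$chrom[keep], pos = cand$pos[keep],
                        ref = cand$ref[keep], alt = cand$alt[keep],
                        var_type = "SNP", zygosity = zyg[keep],
                        alt_fraction = cand$alt_fraction[keep],
                        stringsAsFactors = FALSE)
  }
  if (!is.null(indels) && nrow(indels) > 0L) {
    ind <- indels[indels$var_type %in% c("insertion", "deletion"), , drop = FALSE]
    keep <- mask_contains(indel_target, ind$chrom, ind$pos)
    ind <- ind[keep, , drop = FALSE]
    if (is.null(ind$alt_fraction)) ind$alt_fraction <- NA_real_
    out <- rbind(out, ind[, names(empty_calls())])
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), var_type = character(), zygosity = character(),
             alt_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Run the full five-criterion filtering pipeline
#'
#' Orchestrates [depth_stats()], the five exclusion criteria, target-region
#' construction and [call_variants()] for one sample.
#'
#' @param p a pileup for one individual.
#' @param indels upstream indel-call data frame (optional).
#' @param cfg a [filter_config()].
#' @param chrom_lengths named chromosome lengths.
#' @return List of class `variant_filter_result`: `stats`, `target`
#'   (SNP target regions), `indel_target` (without the indel-adjacent
#'   exclusion), `calls`, `biased_sites`, `end_artifact_sites`, `cfg`.
#' @export
variant_pipeline <- function(p, indels = NULL, cfg = filter_config(),
                             chrom_lengths = NULL) {
  stats <- depth_stats(p)
  dmask <- depth_mask(p, stats, cfg)
  bmask <- balance_mask(p)
  cand <- candidate_sites(p, cfg)
  biased <- cand[strand_balance_counts(cand$ref_fwd, cand$ref_rev,
                                       cand$alt_fwd, cand$alt_rev,
                                       cand$depth, cfg$het_low) == "biased", ,
                 drop = FALSE]
  endart <- cand[!is.na(cand$alt_mean_ed) &
                   cand$alt_mean_ed <= cfg$end_distance_limit, , drop = FALSE]
  bias_ex <- bias_exclusion(biased$chrom, biased$pos, cfg)
  end_ex <- bias_exclusion(endart$chrom, endart$pos, cfg)  # same +/- pad shape
  indel_ex <- indel_exclusion(indels, cfg)
  target <- build_target_regions(dmask, bmask,
                                 list(indel_ex, bias_ex, end_ex),
                                 chrom_lengths)
  indel_target <- build_target_regions(dmask, bmask, list(bias_ex, end_ex),
                                       chrom_lengths)
  calls <- call_variants(p, target, cfg, indels, indel_target)
  structure(list(stats = stats, target = target, indel_target = indel_target,
                 calls = calls, biased_sites = biased,
                 end_artifact_sites = endart, cfg = cfg),
            class = "variant_filter_result")
}

#' @export
print.variant_filter_result <- function(x, ...) {
  cat("<variant_filter_result>\n")
  cat(sprintf("  depth: mean %.2f, sd %.2f\n", x$stats$mean, x$stats$sd))
  cat(sprintf("  target regions: %s bp\n",
              format(mask_total_length(x$target), big.mark = ",")))
  cat(sprintf("  calls: %d (%d SNP, %d indel); %d biased, %d end-artifact sites excluded\n",
              nrow(x$calls), sum(x$calls$var_type == "SNP"),
              sum(x$calls$var_type != "SNP"),
              nrow(x$biased_sites), nrow(x$end_artifact_sites)))
  invisible(x)
}
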