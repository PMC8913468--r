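simple_pileup <- function(depths, ref = "A", chrom = "chr1") {
  # balanced ref-only columns with the given depths
  df <- data.frame(chrom = chrom, pos = seq_along(depths) - 1L, ref = ref)
  df$A_fwd <- ceiling(depths / 2); df$A_rev <- floor(depths / 2)
  as_pileup(df)
}

test_that("depth statistics use covered positions and population SD", {
  expect_equal(depth_stats(simple_pileup(c(10, 10, 10))), list(mean = 10, sd = 0))
  expect_equal(depth_stats(simple_pileup(c(8, 12))), list(mean = 10, sd = 2))
  # uncovered positions are excluded
  expect_equal(depth_stats(simple_pileup(c(0, 8, 12)))$mean, 10)
  expect_error(depth_stats(simple_pileup(c(0, 0))), "no covered")
  set.seed(21)
  s <- depth_stats(simple_pileup(rpois(10000, 30) + 0L))
  expect_lt(abs(s$mean - 30), 1)
  expect_lt(abs(s$sd - sqrt(30)), 0.5)
})

test_that("depth mask enforces the minimum and the inclusive mean + 2.5 SD cutoff", {
  p <- simple_pileup(c(9, 10, 30, 40, 41))
  stats <- list(mean = 30, sd = 4)   # cutoff 40, inclusive
  m <- depth_mask(p, stats, filter_config())
  expect_identical(mask_positions(m), c(1L, 2L, 3L))
  expect_equal(mask_total_length(depth_mask(simple_pileup(rep(0, 5)), stats)), 0)
})

test_that("strand-coverage mask needs at least one read on each strand", {
  df <- data.frame(chrom = "chr1", pos = 0:3, ref = "A",
                   A_fwd = c(20, 1, 0, 3), A_rev = c(0, 1, 5, 2))
  m <- balance_mask(as_pileup(df))
  expect_identical(mask_positions(m), c(1L, 3L))
})

test_that("indel windows exclude the footprint plus 10 bp on each side", {
  cfg <- filter_config()
  expect_equal(mask_total_length(indel_exclusion(NULL, cfg)), 0)
  # 1-bp deletion of reference base 100 (anchored at 99): exclusion [90, 111)
  del <- data.frame(chrom = "chr1", pos = 99L, ref = "AC", alt = "A",
                    var_type = "deletion", zygosity = "homozygous",
                    alt_fraction = 1)
  expect_equal(as.data.frame(indel_exclusion(del, cfg)),
               data.frame(chrom = "chr1", start = 90, end = 111))
  # overlapping pads merge into one interval
  del2 <- rbind(del, transform(del, pos = 109L))
  expect_equal(nrow(as.data.frame(indel_exclusion(del2, cfg))), 1L)
})

test_that("strand-balance check reproduces the worked retention examples", {
  retained <- pileup_column("chr1", 100, "A",
                            counts = list(A = c(20, 12), G = c(15, 18)))
  biased <- pileup_column("chr1", 100, "A",
                          counts = list(A = c(18, 0), G = c(19, 22)))
  expect_equal(strand_balance_check(retained, "A", "G"), "retained")
  expect_equal(strand_balance_check(biased, "A", "G"), "biased")
  # minimal satisfying case: all four counts 1
  minimal <- pileup_column("chr1", 1, "A", counts = list(A = c(1, 1), G = c(1, 1)))
  expect_equal(strand_balance_check(minimal, "A", "G"), "retained")
  # a clean homozygous site (no reference reads) is judged on alt support only
  hom <- pileup_column("chr1", 5, "A", counts = list(G = c(14, 16)))
  expect_equal(strand_balance_check(hom, "A", "G"), "retained")
  hom_biased <- pileup_column("chr1", 5, "A", counts = list(G = c(30, 0)))
  expect_equal(strand_balance_check(hom_biased, "A", "G"), "biased")
  # alt absent is an error: not a variant site
  expect_error(strand_balance_check(retained, "A", "T"), "absent")
})

test_that("bias exclusion windows pad biased sites by 10 bp and merge", {
  cfg <- filter_config()
  expect_equal(as.data.frame(bias_exclusion("chr1", 50, cfg)),
               data.frame(chrom = "chr1", start = 40, end = 61))
  expect_equal(as.data.frame(bias_exclusion("chr1", c(50, 55), cfg)),
               data.frame(chrom = "chr1", start = 40, end = 66))
  expect_equal(mask_total_length(bias_exclusion("chr1", integer(0), cfg)), 0)
})

test_that("read-end check flags sites whose alt reads average within 10 bp of an end", {
  mk <- function(ed) {
    n <- length(ed)
    pileup_column("chr1", 10, "A",
                  counts = list(A = c(5, 5), G = c(ceiling(n / 2), floor(n / 2))),
                  end_distances = list(G = ed))
  }
  expect_equal(end_distance_check(mk(c(50, 60, 70)), "G"), "retained")
  expect_equal(end_distance_check(mk(c(2, 4, 6)), "G"), "end_artifact")
  # boundary: mean exactly 10 is "within 10 bp"
  expect_equal(end_distance_check(mk(c(10, 10)), "G"), "end_artifact")
  # unavailable distances: retained
  no_ed <- pileup_column("chr1", 10, "A", counts = list(A = c(5, 5), G = c(2, 2)))
  expect_equal(end_distance_check(no_ed, "G"), "retained")
  expect_error(end_distance_check(mk(c(2, 4)), "T"), "no reads")
})

test_that("target building intersects coverage masks and subtracts exclusions", {
  lens <- c(chr1 = 100)
  full <- genome_mask(lens)
  expect_equal(mask_total_length(build_target_regions(full, full, list(), lens)), 100)
  ex <- region_mask("chr1", 40, 60)
  t1 <- build_target_regions(full, full, list(ex), lens)
  expect_false(any(mask_contains(t1, "chr1", 40:59)))
  expect_equal(mask_total_length(t1), 80)
})

test_that("zygosity bands assign hom/het calls and leave the gap uncalled", {
  cfg <- filter_config()
  lens <- c(chr1 = 200)
  mk <- function(altf, altr, reff, refr, ed_per_read = 45) {
    n <- altf + altr
    pileup_column("chr1", 100, "A",
                  counts = list(A = c(reff, refr), G = c(altf, altr)),
                  end_distances = list(G = rep(ed_per_read, n)))
  }
  target <- genome_mask(lens)
  hom <- call_variants(mk(15, 15, 0, 0), target, cfg)
  expect_equal(hom$zygosity, "homozygous")
  expect_equal(hom$alt, "G")
  het <- call_variants(mk(8, 7, 8, 7), target, cfg)
  expect_equal(het$zygosity, "heterozygous")
  # fraction 0.78 sits between het_high and hom_fraction: no call
  gap <- call_variants(mk(39, 39, 11, 11), target, cfg)
  expect_equal(nrow(gap), 0L)
  # fraction 0.1: below het_low, no call
  low <- call_variants(mk(2, 1, 14, 13), target, cfg)
  expect_equal(nrow(low), 0L)
})

test_that("interval pipeline matches the per-position brute-force oracle", {
  set.seed(101)
  cfg <- filter_config()
  for (trial in 1:40) {
    L <- sample(150:400, 1)
    p <- random_pileup(L)
    indels <- random_indels(L, sample(0:3, 1))
    res <- variant_pipeline(p, indels, cfg, c(chr1 = L))
    orc <- oracle_filter(p, indels, cfg, L)
    expect_identical(mask_positions(res$target), orc$target)
    expect_identical(mask_positions(res$indel_target), orc$target_noindel)
    got <- res$calls[order(res$calls$pos, res$calls$alt),
                     c("pos", "ref", "alt", "var_type", "zygosity")]
    rownames(got) <- NULL
    expect_equal(got, orc$calls)
  }
})

test_that("every emitted SNP re-passes all five per-site predicates", {
  cfg <- filter_config()
  sim <- simulate_strain_genomes(strain_sim_config(seed = 55,
                                                   genome_length = 15000))
  rs <- simulate_reads(sim$snp_genomes$mus_a[["chr1"]],
                       read_sim_config(seed = 56, n_strand_bias_sites = 2),
                       chrom = "chr1", reference = sim$reference[["chr1"]],
                       return_reads = FALSE)
  p <- rs$pileup
  res <- variant_pipeline(p, NULL, cfg, c(chr1 = 15000))
  snps <- res$calls[res$calls$var_type == "SNP", ]
  expect_gt(nrow(snps), 0)
  stats <- depth_stats(p)
  for (r in seq_len(nrow(snps))) {
    i <- which(p$pos == snps$pos[r])
    col <- p[i, ]
    expect_true(mask_contains(res$target, "chr1", snps$pos[r]))
    expect_gte(col$depth, cfg$min_depth)
    expect_lte(col$depth, stats$mean + cfg$depth_sd_limit * stats$sd)
    expect_equal(strand_balance_check(col, snps$ref[r], snps$alt[r], cfg),
                 "retained")
    expect_equal(end_distance_check(col, snps$alt[r], cfg), "retained")
  }
})

test_that("adding exclusions never grows the target or the call set", {
  set.seed(77)
  cfg <- filter_config()
  p <- random_pileup(300)
  dm <- depth_mask(p, depth_stats(p), cfg)
  bm <- balance_mask(p)
  ex1 <- region_mask("chr1", 50, 120)
  t0 <- build_target_regions(dm, bm, list(), c(chr1 = 300))
  t1 <- build_target_regions(dm, bm, list(ex1), c(chr1 = 300))
  expect_lte(mask_total_length(t1), mask_total_length(t0))
  c0 <- call_variants(p, t0, cfg)
  c1 <- call_variants(p, t1, cfg)
  expect_lte(nrow(c1), nrow(c0))
  # the smaller call set is nested in the larger one
  expect_true(all(paste(c1$pos, c1$alt) %in% paste(c0$pos, c0$alt)))
})
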