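test_that("generators are pure functions of seed and config", {
  cfg <- strain_sim_config(seed = 99, genome_length = 5000, indel_rate = 2e-4)
  t1 <- simulate_genotype_table(cfg)
  t2 <- simulate_genotype_table(cfg)
  expect_identical(t1$alleles, t2$alleles)
  expect_identical(t1$sites, t2$sites)
  s1 <- simulate_strain_genomes(cfg)
  s2 <- simulate_strain_genomes(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
  r1 <- simulate_reads(s1$genomes$dom_a[["chr1"]], read_sim_config(seed = 4))
  r2 <- simulate_reads(s1$genomes$dom_a[["chr1"]], read_sim_config(seed = 4))
  expect_identical(as.data.frame(r1$pileup), as.data.frame(r2$pileup))
  expect_identical(r1$reads, r2$reads)
  p1 <- simulate_phenotypes(list(X = c(a = 1, b = 2)), seed = 7)
  p2 <- simulate_phenotypes(list(X = c(a = 1, b = 2)), seed = 7)
  expect_identical(p1, p2)
  # simulation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_genotype_table(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero branch probabilities give strains identical to the ancestor", {
  tree <- default_strain_tree()
  tree$edge.length[] <- 0
  cfg <- strain_sim_config(seed = 2, genome_length = 2000, tree = tree)
  tab <- simulate_genotype_table(cfg)
  expect_equal(nrow(tab$sites), 0L)
  sim <- simulate_strain_genomes(cfg)
  for (s in names(sim$genomes))
    expect_identical(sim$genomes[[s]], sim$reference)
})

test_that("realized pairwise divergence is binomial around the path sum", {
  two <- ape::read.tree(text = "(A:0.004,B:0.004);")
  cfg <- strain_sim_config(seed = 11, genome_length = 100000, tree = two,
                           group_map = c(A = "x", B = "y"))
  tab <- simulate_genotype_table(cfg)
  frac <- asd_matrix(tab)["A", "B"] * nrow(tab$sites) / cfg$genome_length
  se <- sqrt(0.008 * 0.992 / cfg$genome_length)
  expect_lt(abs(frac - 0.008), 3 * se)
})

test_that("error-free reads reproduce the genome exactly in the pileup", {
  set.seed(6)
  g <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = "")
  rs <- simulate_reads(g, read_sim_config(seed = 8, base_error_rate = 0,
                                          mean_depth = 20))
  ta <- top_alt(rs$pileup)
  expect_true(all(ta$alt_count == 0))
  gbase <- strsplit(g, "")[[1]]
  expect_identical(rs$pileup$ref, gbase[rs$pileup$pos + 1])
  # depth equals per-allele sums by construction and matches coverage
  expect_equal(sum(rs$pileup$depth), 2 * 100 * ceiling(20 * 4000 / 200))
})

test_that("observed mean depth tracks the requested coverage", {
  set.seed(61)
  g <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE), collapse = "")
  rs <- simulate_reads(g, read_sim_config(seed = 13, mean_depth = 30),
                       return_reads = FALSE)
  interior <- rs$pileup$depth[rs$pileup$pos >= 300 &
                                rs$pileup$pos < 50000 - 300]
  expect_lt(abs(mean(interior) - 30) / 30, 0.05)
})

test_that("injected artifacts are realized exactly as specified", {
  set.seed(66)
  g <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")
  rs <- simulate_reads(g, read_sim_config(seed = 14, n_strand_bias_sites = 3,
                                          n_end_artifact_sites = 3,
                                          n_depth_spikes = 1,
                                          spike_factor = 5, spike_width = 400))
  p <- rs$pileup
  for (r in seq_len(nrow(rs$truth$strand_bias))) {
    site <- rs$truth$strand_bias[r, ]
    col <- p[p$pos == site$pos, ]
    # alt support on one strand only -> fails the strand-balance check
    expect_equal(col[[paste0(site$alt, "_rev")]], 0)
    expect_gt(col[[paste0(site$alt, "_fwd")]], 0)
    expect_equal(strand_balance_check(col, col$ref, site$alt), "biased")
  }
  for (r in seq_len(nrow(rs$truth$end_artifact))) {
    site <- rs$truth$end_artifact[r, ]
    col <- p[p$pos == site$pos, ]
    cnt <- col[[paste0(site$alt, "_fwd")]] + col[[paste0(site$alt, "_rev")]]
    expect_gt(cnt, 0)
    expect_lte(col[[paste0(site$alt, "_ed")]] / cnt, 10)
  }
  spike <- rs$truth$depth_spike[1, ]
  inside <- p$depth[p$pos >= spike$start & p$pos < spike$end]
  outside <- p$depth[p$pos < spike$start - 500 | p$pos >= spike$end + 500]
  expect_gt(mean(inside), 3 * mean(outside))
})

test_that("artifact injection fails loudly when depth cannot realize it", {
  set.seed(91)
  g <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  # depth ~0.5: many positions uncovered, strand-biased sites unrealizable
  expect_error(simulate_reads(g, read_sim_config(seed = 3, mean_depth = 0.2,
                                                 insert_size = 250,
                                                 n_strand_bias_sites = 8)),
               "depth too low|cannot place")
})

test_that("the default tree matches the intended divergence regime", {
  tree <- default_strain_tree()
  d <- ape::cophenetic.phylo(tree) * 100   # percent scale
  gm <- default_group_map()
  # deep lineages: domesticus / castaneus / musculus-molossinus complex
  lineage <- gm
  lineage[lineage %in% c("musculus", "molossinus")] <- "musmol"
  within <- between <- c()
  for (a in rownames(d)) for (b in colnames(d)) {
    if (a >= b) next
    if (lineage[a] == lineage[b]) within <- c(within, d[a, b])
    else between <- c(between, d[a, b])
  }
  expect_true(all(within >= 0.15 & within <= 0.33))
  expect_true(all(between >= 0.71 & between <= 0.88))
})

test_that("phenotype simulation recovers configured effects and warns on tiny cells", {
  tab <- simulate_phenotypes(list(BW = c(a = 20, b = 30)), n_per_cell = 10,
                             noise_sd = 0.5, seed = 21)
  m <- tapply(tab$BW, tab$strain, mean)
  expect_lt(abs(m[["a"]] - 20), 0.5)
  expect_lt(abs(m[["b"]] - 30), 0.5)
  expect_true(all(tab$age_days >= 67 & tab$age_days <= 79))
  expect_warning(simulate_phenotypes(list(X = c(a = 0)), n_per_cell = 1),
                 "untestable")
})
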