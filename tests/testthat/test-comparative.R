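tiny_table <- function(alleles, L = 1000L) {
  # alleles: strains x sites character matrix; sites at positions 0,10,20,...
  sites <- data.frame(chrom = "chr1", pos = seq(0, by = 10,
                                                length.out = ncol(alleles)),
                      ref = rep("A", ncol(alleles)))
  masks <- lapply(stats::setNames(rownames(alleles), rownames(alleles)),
                  function(s) genome_mask(c(chr1 = L)))
  genotype_table(alleles, sites, masks)
}

test_that("snp_percent divides differing sites by effective joint length", {
  al <- rbind(x = c("A", "G", "A", "T"), y = c("A", "C", "A", "T"))
  tab <- tiny_table(al, L = 1000L)
  expect_equal(snp_percent(tab, "x", "x"), 0)
  # 1 differing site over 1000 bp effective length
  expect_equal(snp_percent(tab, "x", "y"), 0.1)
  expect_equal(snp_percent(tab, "y", "x"), 0.1)
  # 2 differing sites over effective length 1000 -> 0.2
  al2 <- rbind(x = c("A", "G", "C", "T"), y = c("A", "C", "A", "T"))
  expect_equal(snp_percent(tiny_table(al2), "x", "y"), 0.2)
  # restricted masks shrink the denominator
  tab$masks$y <- region_mask("chr1", 0, 500)
  expect_equal(snp_percent(tab, "x", "y"), 100 * 1 / 500)
  # disjoint masks: no effective length
  tab$masks$y <- region_mask("chr1", 2000, 2500)
  expect_error(snp_percent(tab, "x", "y"), "effective genome length")
})

test_that("missing and heterozygous alleles drop out pairwise", {
  al <- rbind(x = c("A", "G", "R", "T"), y = c(NA, "C", "A", "T"))
  tab <- tiny_table(al)
  # only sites 2 and 4 are jointly homozygous; one differs
  expect_equal(asd_matrix(tab)["x", "y"], 0.5)
  expect_equal(snp_percent(tab, "x", "y"), 100 * 1 / 1000)
})

test_that("divergence and ASD matrices are symmetric with zero diagonals", {
  set.seed(12)
  tab <- simulate_genotype_table(strain_sim_config(seed = 3, genome_length = 30000))
  d <- divergence_matrix(tab)
  a <- asd_matrix(tab)
  expect_equal(d, t(d))
  expect_equal(a, t(a))
  expect_equal(diag(d), stats::setNames(rep(0, nrow(d)), rownames(d)))
  expect_equal(diag(a), stats::setNames(rep(0, nrow(a)), rownames(a)))
  # permuting strains permutes rows/columns consistently
  perm <- sample(rownames(d))
  tab2 <- tab
  tab2$alleles <- tab$alleles[perm, , drop = FALSE]
  tab2$strains <- perm
  tab2$masks <- tab$masks[perm]
  expect_equal(divergence_matrix(tab2), d[perm, perm])
})

test_that("ASD equals the site-by-site brute-force count on random tables", {
  set.seed(31)
  for (trial in 1:10) {
    n_sites <- 50L
    strains <- c("s1", "s2", "s3")
    al <- matrix(sample(c("A", "C", "G", "T", NA, "R"), 3 * n_sites,
                        replace = TRUE, prob = c(rep(0.2, 4), 0.12, 0.08)),
                 nrow = 3, dimnames = list(strains, NULL))
    al[, 1] <- "A"  # guarantee a joint site for every pair
    tab <- tiny_table(al)
    a <- asd_matrix(tab)
    for (i in 1:2) for (j in (i + 1):3)
      expect_equal(a[i, j], oracle_asd(tab, strains[i], strains[j]))
  }
})

test_that("UPGMA reproduces forced and hand-computed merges", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))
  # ultrametric 3-taxon case: ((A,B),C) with heights 0.1 and 0.4
  d3 <- matrix(c(0, .2, .8, .2, 0, .8, .8, .8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(ape::write.tree(t3), "((A:0.1,B:0.1):0.3,C:0.4);")
  expect_error(upgma(d2[1, 1, drop = FALSE]), "at least 2")
})

test_that("UPGMA is a fixed point on ultrametric matrices and matches average linkage", {
  set.seed(19)
  for (trial in 1:20) {
    n <- sample(3:8, 1)
    d <- random_ultrametric(n)
    tr <- upgma(d)
    coph <- as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]
    expect_equal(coph, d, tolerance = 1e-12)
    # independent cross-check: hclust average linkage gives the same heights
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(stats::cophenetic(hc)), sort(stats::as.dist(d)),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA heights are monotone non-decreasing towards the root", {
  set.seed(23)
  for (trial in 1:10) {
    n <- 6
    m <- matrix(stats::runif(n * n, 0.1, 1), n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(d)
    depths <- ape::node.depth.edgelength(tr)   # root-to-node path lengths
    heights <- max(depths[1:n]) - depths       # ultrametric node heights
    for (e in seq_len(nrow(tr$edge)))
      expect_gte(heights[tr$edge[e, 1]] + 1e-12, heights[tr$edge[e, 2]])
  }
})

test_that("UPGMA ties break towards the earliest label-order pair", {
  lab <- c("A", "B", "C")
  d <- matrix(0.4, 3, 3, dimnames = list(lab, lab)); diag(d) <- 0
  tr <- upgma(d)
  # the first merge must join A and B
  pair <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "B")))$tip.label
  expect_setequal(pair, c("A", "B"))
})

test_that("subspecies-specific sites need full callability and exclusive sharing", {
  al <- rbind(m1 = c("G", "G", "G", "A"),
              m2 = c("G", "G", NA,  "A"),
              d1 = c("A", "G", "A", "A"))
  tab <- tiny_table(al)
  grouping <- c(m1 = "molossinus", m2 = "molossinus", d1 = "domesticus")
  ss <- subspecies_specific_sites(tab, grouping)
  # site 1: both molossinus carry G, domesticus does not -> specific
  expect_equal(ss$molossinus$pos, 0)
  expect_equal(ss$molossinus$allele, "G")
  # site 2 is shared by all strains -> specific to no subspecies
  # site 3 is missing in one in-group strain -> not counted
  # site 4 is reference everywhere
  expect_equal(nrow(ss$domesticus), 0L)
  expect_error(subspecies_specific_sites(tab, c(grouping, zz = "x")),
               "unknown strain")
})

test_that("novelty counting honors the three-candidate limit and conserves totals", {
  calls <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                      ref = "A", alt = c("G", "T", "C", "T"),
                      var_type = "SNP", zygosity = "homozygous",
                      alt_fraction = 1)
  empty <- data.frame(chrom = character(), pos = numeric(), alt = character())
  expect_equal(novelty_count(calls, empty), list(novel = 4L, known = 0L))
  full <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                     alt = c("G", "T", "C", "T"))
  expect_equal(novelty_count(calls, full), list(novel = 0L, known = 4L))
  # 4th-ranked catalog allele does not count as known
  cat4 <- data.frame(chrom = "chr1", pos = 10, alt = "C,A,T,G")
  expect_equal(novelty_count(calls[1, ], cat4), list(novel = 1L, known = 0L))
  cat3 <- data.frame(chrom = "chr1", pos = 10, alt = "C,A,G")
  expect_equal(novelty_count(calls[1, ], cat3), list(novel = 0L, known = 1L))
  # random instances vs brute-force scan
  set.seed(41)
  for (trial in 1:10) {
    calls2 <- data.frame(chrom = "chr1", pos = sample(1:60, 30, replace = TRUE),
                         alt = sample(c("A", "C", "G", "T"), 30, replace = TRUE))
    catalog <- data.frame(chrom = "chr1", pos = sample(1:60, 25, replace = TRUE),
                          alt = replicate(25, paste(sample(c("A", "C", "G", "T"),
                                                           sample(1:4, 1)),
                                                    collapse = ",")))
    got <- novelty_count(calls2, catalog)
    expect_equal(got, oracle_novelty(calls2, catalog))
    expect_equal(got$novel + got$known, nrow(calls2))
  }
})
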