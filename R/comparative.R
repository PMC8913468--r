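#' Strain-by-site genotype tables
#'
#' Container for the comparative analyses: an allele matrix (strains x
#' sites, values A/C/G/T, IUPAC ambiguity codes for heterozygous sites, or
#' `NA` for missing), the site coordinates, and each strain's callable
#' territory as a [region_mask()]. A non-missing allele is only meaningful
#' inside the strain's callable mask.
#'
#' @param alleles character matrix, strains in rows (rownames = strain
#'   names), sites in columns.
#' @param sites data frame with `chrom`, `pos` (0-based) and `ref`, one row
#'   per column of `alleles`.
#' @param masks named list of per-strain [region_mask()] callable regions.
#' @param validate check that every non-missing allele lies inside the
#'   strain's callable mask (O(strains x sites); disable for large tables).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(alleles, sites, masks, validate = FALSE) {
  stopifnot(is.matrix(alleles), nrow(sites) == ncol(alleles),
            all(c("chrom", "pos", "ref") %in% names(sites)),
            !is.null(rownames(alleles)),
            all(rownames(alleles) %in% names(masks)))
  if (validate) {
    for (s in rownames(alleles)) {
      i <- which(!is.na(alleles[s, ]))
      if (length(i) && !all(mask_contains(masks[[s]], sites$chrom[i], sites$pos[i])))
        stop("strain ", s, " has alleles outside its callable mask")
    }
  }
  structure(list(strains = rownames(alleles), sites = sites,
                 alleles = alleles, masks = masks[rownames(alleles)]),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d strain(s) x %d site(s)\n",
              length(x$strains), nrow(x$sites)))
  invisible(x)
}

#' Build a genotype table from per-strain call sets
#'
#' The site set is the union of homozygous SNP positions across strains.
#' A strain's allele at a site is its called alternative allele; the
#' reference base where the site is callable but uncalled; `NA` outside the
#' callable mask. Heterozygous calls are recorded as IUPAC ambiguity codes
#' (and are dropped pairwise by the distance computations).
#'
#' @param calls_by_strain named list of variant-call data frames (layout of
#'   [call_variants()]).
#' @param masks named list of per-strain callable [region_mask()]s.
#' @param het how to record heterozygous SNP calls: `"iupac"` (default) or
#'   `"drop"` (treat as missing).
#' @return A [genotype_table()].
#' @export
genotype_table_from_calls <- function(calls_by_strain, masks, het = "iupac") {
  strains <- names(calls_by_strain)
  stopifnot(!is.null(strains), all(strains %in% names(masks)))
  snps <- lapply(calls_by_strain, function(cc)
    cc[cc$var_type == "SNP", , drop = FALSE])
  sites <- unique(do.call(rbind, lapply(snps, function(cc)
    cc[, c("chrom", "pos", "ref")])))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos)
  alleles <- matrix(NA_character_, nrow = length(strains), ncol = nrow(sites),
                    dimnames = list(strains, NULL))
  for (s in strains) {
    callable <- mask_contains(masks[[s]], sites$chrom, sites$pos)
    alleles[s, callable] <- sites$ref[callable]
    cc <- snps[[s]]
    if (nrow(cc)) {
      j <- match(paste(cc$chrom, cc$pos), key)
      val <- ifelse(cc$zygosity == "homozygous", cc$alt,
                    if (het == "iupac") iupac_code(cc$ref, cc$alt)
                    else NA_character_)
      alleles[s, j] <- val
    }
  }
  genotype_table(alleles, sites, masks)
}

joint_hom <- function(tab, a, b) {
  x <- tab$alleles[a, ]; y <- tab$alleles[b, ]
  !is.na(x) & !is.na(y) & x %in% BASES & y %in% BASES
}

#' Pairwise SNP divergence in percent of effective genome length
#'
#' `100 *` (number of jointly callable, homozygous sites where the two
#' strains carry different alleles) `/` (effective length = total length of
#' the intersection of the two strains' callable masks). Heterozygous and
#' missing sites are dropped pairwise. Symmetric in its arguments.
#'
#' @param tab a [genotype_table()].
#' @param a,b strain names.
#' @return Percent divergence (numeric scalar).
#' @export
snp_percent <- function(tab, a, b) {
  stopifnot(a %in% tab$strains, b %in% tab$strains)
  eff <- mask_total_length(mask_intersect(tab$masks[[a]], tab$masks[[b]]))
  if (eff == 0) stop("effective genome length between ", a, " and ", b, " is zero")
  j <- joint_hom(tab, a, b)
  100 * sum(tab$alleles[a, j] != tab$alleles[b, j]) / eff
}

#' All-pairs divergence matrix
#'
#' @param tab a [genotype_table()].
#' @return Symmetric matrix of [snp_percent()] values with zero diagonal.
#' @export
divergence_matrix <- function(tab) {
  n <- length(tab$strains)
  d <- matrix(0, n, n, dimnames = list(tab$strains, tab$strains))
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- snp_percent(tab, tab$strains[i], tab$strains[j])
  d
}

#' Allele sharing distance matrix
#'
#' For fully homozygous inbred strains the allele sharing distance between
#' two strains collapses to the mismatch proportion over their jointly
#' callable, non-missing homozygous sites (heterozygous/ambiguous sites are
#' dropped pairwise). This is the distance fed to [upgma()].
#'
#' @param tab a [genotype_table()].
#' @return Symmetric distance matrix, zero diagonal.
#' @export
asd_matrix <- function(tab) {
  n <- length(tab$strains)
  d <- matrix(0, n, n, dimnames = list(tab$strains, tab$strains))
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- tab$strains[i]; b <- tab$strains[j]
      jt <- joint_hom(tab, a, b)
      if (!any(jt)) stop("no jointly callable sites between ", a, " and ", b)
      d[i, j] <- d[j, i] <- mean(tab$alleles[a, jt] != tab$alleles[b, jt])
    }
  d
}

#' UPGMA dendrogram
#'
#' Standard unweighted pair group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters; the distance between clusters is the
#' size-weighted arithmetic average over all cross-pairs; the merge node sits
#' at half the merge distance, so leaf-to-root heights are ultrametric. Ties
#' are broken deterministically towards the pair whose members come first in
#' the input label order.
#'
#' @param d symmetric numeric distance matrix with labels as dimnames (or a
#'   `dist` object), at least 2 labels.
#' @return A rooted `phylo` tree (ape) with branch lengths; serialize with
#'   `ape::write.tree()`.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 2L) stop("UPGMA requires at least 2 labels")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("d must be a symmetric non-negative matrix with zero diagonal")
  work <- d
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- labels
  first <- seq_len(n)          # smallest original index in each cluster
  active <- seq_len(n)
  while (length(active) > 1L) {
    # closest active pair; ties -> smallest (first-member, other-member) order
    best <- NULL; bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      a <- active[ii]; b <- active[jj]
      dv <- work[a, b]
      lo <- min(first[a], first[b]); hi <- max(first[a], first[b])
      if (dv < bestd - 1e-15 ||
          (abs(dv - bestd) <= 1e-15 &&
           (lo < best[3L] || (lo == best[3L] && hi < best[4L])))) {
        bestd <- dv; best <- c(a, b, lo, hi)
      }
    }
    a <- best[1L]; b <- best[2L]
    h <- bestd / 2
    newick_a <- sprintf("%s:%.17g", newick[a], h - height[a])
    newick_b <- sprintf("%s:%.17g", newick[b], h - height[b])
    ord <- order(c(first[a], first[b]))
    parts <- c(newick_a, newick_b)[ord]
    merged <- sprintf("(%s,%s)", parts[1L], parts[2L])
    others <- setdiff(active, c(a, b))
    for (k in others) {
      work[a, k] <- work[k, a] <-
        (size[a] * work[a, k] + size[b] * work[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    height[a] <- h
    newick[a] <- merged
    first[a] <- min(first[a], first[b])
    active <- setdiff(active, b)
  }
  ape::read.tree(text = paste0(newick[active], ";"))
}

#' Subspecies-specific sites
#'
#' A site is specific to a subspecies when (1) it is callable (non-missing)
#' in every strain of the table, (2) every strain of the subspecies carries
#' the same non-reference allele there, and (3) no strain outside the
#' subspecies carries that allele.
#'
#' @param tab a [genotype_table()].
#' @param grouping named character vector mapping every strain to its
#'   subspecies.
#' @return Named list (one element per subspecies) of data frames with
#'   `chrom`, `pos`, `ref`, `allele`.
#' @export
subspecies_specific_sites <- function(tab, grouping) {
  if (!all(tab$strains %in% names(grouping)))
    stop("grouping is missing strains: ",
         paste(setdiff(tab$strains, names(grouping)), collapse = ", "))
  if (!all(names(grouping) %in% tab$strains))
    stop("unknown strain in grouping: ",
         paste(setdiff(names(grouping), tab$strains), collapse = ", "))
  al <- tab$alleles
  callable_all <- colSums(is.na(al)) == 0L
  groups <- unique(grouping[tab$strains])
  out <- list()
  for (g in groups) {
    ing <- tab$strains[grouping[tab$strains] == g]
    outg <- setdiff(tab$strains, ing)
    a_in <- al[ing, , drop = FALSE]
    shared <- apply(a_in, 2L, function(col)
      if (anyNA(col) || !all(col == col[1L])) NA_character_ else col[1L])
    is_alt <- !is.na(shared) & shared != tab$sites$ref & shared %in% BASES
    not_outside <- if (length(outg) == 0L) rep(TRUE, ncol(al)) else
      colSums(al[outg, , drop = FALSE] ==
                matrix(shared, nrow = length(outg), ncol = ncol(al),
                       byrow = TRUE), na.rm = TRUE) == 0L
    keep <- which(callable_all & is_alt & not_outside)
    out[[g]] <- data.frame(tab$sites[keep, c("chrom", "pos", "ref")],
                           allele = shared[keep], row.names = NULL)
  }
  out
}

#' Novelty of calls against an external catalog
#'
#' A homozygous call is *known* when its `(chrom, pos, alt)` triple matches
#' the catalog, considering at most the first `max_alts` alternative alleles
#' recorded per catalog site; otherwise it is *novel*. Totals are conserved:
#' `novel + known == nrow(calls)`.
#'
#' @param calls variant-call data frame (homozygous set).
#' @param catalog data frame with `chrom`, `pos` and either an `alt` column
#'   (possibly comma-separated alleles) or multiple rows per site; row order
#'   within a site defines candidate rank.
#' @param max_alts number of catalog alternative alleles considered per site
#'   (default 3).
#' @return List with counts `novel` and `known`.
#' @export
novelty_count <- function(calls, catalog, max_alts = 3L) {
  if (nrow(calls) == 0L) return(list(novel = 0L, known = 0L))
  if (nrow(catalog) == 0L)
    return(list(novel = nrow(calls), known = 0L))
  # explode comma-separated alts, keep per-site candidate rank
  alts <- strsplit(as.character(catalog$alt), ",", fixed = TRUE)
  reps <- lengths(alts)
  flat <- data.frame(chrom = rep(catalog$chrom, reps),
                     pos = rep(catalog$pos, reps),
                     alt = unlist(alts), stringsAsFactors = FALSE)
  sitekey <- paste(flat$chrom, flat$pos)
  rank <- stats::ave(seq_along(sitekey), sitekey, FUN = seq_along)
  flat <- flat[rank <= max_alts, , drop = FALSE]
  known <- paste(calls$chrom, calls$pos, calls$alt) %in%
    paste(flat$chrom, flat$pos, flat$alt)
  list(novel = sum(!known), known = sum(known))
}

#' Write a divergence matrix as lower-triangle TSV
#'
#' Strain names as the header row; each subsequent row holds the strain name
#' and the percentages against the strains preceding it.
#'
#' @param d symmetric divergence matrix.
#' @param path output path.
#' @param digits rounding applied at presentation only (default 2).
#' @export
write_divergence_tsv <- function(d, path, digits = 2) {
  labels <- rownames(d)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("strain", labels), collapse = "\t"), con)
  for (i in seq_along(labels)) {
    vals <- if (i > 1L) format(round(d[i, seq_len(i - 1L)], digits)) else character(0)
    writeLines(paste(c(labels[i], vals), collapse = "\t"), con)
  }
  invisible(path)
}
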