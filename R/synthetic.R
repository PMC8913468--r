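# run expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default strain tree for the simulator
#'
#' A rooted ultrametric 10-strain tree whose branch lengths are per-site
#' substitution probabilities, shaped like a wild-derived inbred panel of
#' three *Mus musculus* subspecies plus their hybrid: two domesticus-like
#' strains, five musculus-like strains, one castaneus-like strain, and two
#' molossinus-like strains nested inside the musculus clade's divergence
#' band. Pairwise path sums land within-subspecies divergence in the
#' 0.15-0.33% range and between-subspecies divergence in the 0.71-0.88%
#' range.
#'
#' @return An ape `phylo` tree with edge lengths as substitution
#'   probabilities.
#' @export
default_strain_tree <- function() {
  ape::read.tree(text = paste0(
    "((dom_a:0.00135,dom_b:0.00135):0.00255,",
    "(((mus_a:0.0009,mus_b:0.0009):0.00075,",
    "(((mus_c:0.00075,mus_d:0.00075):0.0004,mus_e:0.00115):0.00025,",
    "(mol_a:0.00085,mol_b:0.00085):0.00055):0.00025):0.00195,",
    "cas_a:0.0036):0.0003);"))
}

#' @rdname default_strain_tree
#' @export
default_group_map <- function() {
  c(dom_a = "domesticus", dom_b = "domesticus",
    mus_a = "musculus", mus_b = "musculus", mus_c = "musculus",
    mus_d = "musculus", mus_e = "musculus",
    cas_a = "castaneus", mol_a = "molossinus", mol_b = "molossinus")
}

#' Configuration for strain-genome simulation
#'
#' @param seed RNG seed; all outputs are pure functions of seed + config.
#' @param genome_length total genome length in bp (>= 1000).
#' @param n_chromosomes number of equally sized chromosomes.
#' @param tree rooted `phylo` whose edge lengths are per-site substitution
#'   probabilities; tip labels name the strains.
#' @param indel_rate per-site probability of an indel per strain (terminal
#'   branches only; default 0).
#' @param indel_max maximum indel length, bp; lengths are geometric,
#'   truncated to `[1, indel_max]`.
#' @param group_map named strain -> subspecies vector.
#' @return List of class `strain_sim_config`.
#' @export
strain_sim_config <- function(seed = 1L, genome_length = 100000L,
                              n_chromosomes = 1L,
                              tree = default_strain_tree(),
                              indel_rate = 0, indel_max = 10L,
                              group_map = default_group_map()) {
  stopifnot(genome_length >= 1000, n_chromosomes >= 1,
            inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), all(tree$edge.length <= 1),
            indel_rate >= 0, indel_rate <= 1)
  structure(list(seed = seed, genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes), tree = tree,
                 indel_rate = indel_rate, indel_max = as.integer(indel_max),
                 group_map = group_map),
            class = "strain_sim_config")
}

# propagate sparse substitution maps down the tree; returns per-tip named
# character vectors (names = 0-based global positions) plus the ancestral
# base of every touched position
evolve_sparse <- function(tree, L) {
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")   # parents precede children
  maps <- vector("list", n_tip + tree$Nnode)
  maps[[n_tip + 1L]] <- character(0)          # root carries no changes
  anc <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    p <- tree$edge.length[e]
    m <- maps[[parent]]
    nmut <- stats::rbinom(1L, L, p)
    if (nmut > 0L) {
      pos <- sample.int(L, nmut) - 1L
      key <- as.character(pos)
      cur <- m[key]
      miss <- is.na(cur)
      if (any(miss)) {
        # first touch: fix the ancestral base now
        for (k in key[miss])
          if (!exists(k, envir = anc, inherits = FALSE))
            assign(k, sample(BASES, 1L), envir = anc)
        cur[miss] <- vapply(key[miss], function(k)
          get(k, envir = anc, inherits = FALSE), "")
      }
      # substitute to one of the three other bases, uniformly
      nxt <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), "")
      m[key] <- nxt
    }
    maps[[child]] <- m
  }
  list(tips = stats::setNames(maps[seq_len(n_tip)], tree$tip.label), anc = anc)
}

chrom_layout <- function(cfg) {
  per <- cfg$genome_length %/% cfg$n_chromosomes
  lens <- rep(per, cfg$n_chromosomes)
  lens[cfg$n_chromosomes] <- cfg$genome_length - per * (cfg$n_chromosomes - 1L)
  stats::setNames(lens, paste0("chr", seq_len(cfg$n_chromosomes)))
}

global_to_chrom <- function(gpos, lens) {
  offs <- cumsum(c(0, lens[-length(lens)]))
  i <- findInterval(gpos, offs)
  data.frame(chrom = names(lens)[i], pos = as.integer(gpos - offs[i]))
}

#' Simulate a genotype table from the strain tree
#'
#' Sparse simulation of the substitution process only (no sequences, no
#' reads): substitutions are placed per branch as Binomial(L, p) events, so
#' the realized divergence between two strains is binomial around the path
#' sum of their branch probabilities. The returned table holds the variant
#' sites (positions where at least one strain differs from the ancestral
#' reference), with full-genome callable masks.
#'
#' @param cfg a [strain_sim_config()].
#' @return A [genotype_table()]; attribute `tree` carries the generating
#'   tree.
#' @export
simulate_genotype_table <- function(cfg) {
  with_local_seed(cfg$seed, {
    L <- cfg$genome_length
    ev <- evolve_sparse(cfg$tree, L)
    keys <- unique(unlist(lapply(ev$tips, names)))
    gpos <- sort(as.integer(keys))
    keys <- as.character(gpos)
    refb <- vapply(keys, function(k)
      get(k, envir = ev$anc, inherits = FALSE), "")
    lens <- chrom_layout(cfg)
    loc <- global_to_chrom(gpos, lens)
    strains <- names(ev$tips)
    alleles <- matrix(rep(refb, each = length(strains)),
                      nrow = length(strains), dimnames = list(strains, NULL))
    for (s in strains) {
      m <- ev$tips[[s]]
      if (length(m)) alleles[s, match(names(m), keys)] <- unname(m)
    }
    # drop positions where every strain reverted to the ancestral base
    seg <- colSums(alleles != matrix(refb, nrow = length(strains),
                                     ncol = length(refb), byrow = TRUE)) > 0L
    sites <- data.frame(chrom = loc$chrom[seg], pos = loc$pos[seg],
                        ref = refb[seg])
    masks <- lapply(stats::setNames(strains, strains),
                    function(s) genome_mask(lens))
    tab <- genotype_table(alleles[, seg, drop = FALSE], sites, masks)
    attr(tab, "tree") <- cfg$tree
    tab
  })
}

#' Simulate strain genomes with known truth
#'
#' Materializes the ancestral (reference) genome with uniform base
#' composition, applies per-branch substitutions down the strain tree, adds
#' optional short indels on the terminal branches, and records every variant
#' per strain as an anchored truth call set. Substitutions and indels are
#' placed so their reference footprints never overlap within a strain.
#'
#' @param cfg a [strain_sim_config()].
#' @return List of class `strain_sim`: `reference` (named character vector
#'   of chromosome sequences), `genomes` (named list: per strain, named
#'   character vector of chromosome sequences with all variants applied),
#'   `snp_genomes` (SNPs applied only — indel-free coordinates, the input
#'   for read simulation), `truth` (named list of per-strain call data
#'   frames), `table`
#'   (SNP [genotype_table()]), `chrom_lengths`, `config`.
#' @export
simulate_strain_genomes <- function(cfg) {
  tab <- simulate_genotype_table(cfg)
  with_local_seed(cfg$seed + 1L, {
    lens <- chrom_layout(cfg)
    reference <- vapply(lens, function(l)
      paste(sample(BASES, l, replace = TRUE), collapse = ""), "")
    # overwrite ancestral bases at variant sites to match the sparse truth
    ref_split <- lapply(reference, function(s) strsplit(s, "")[[1L]])
    for (i in seq_len(nrow(tab$sites)))
      ref_split[[tab$sites$chrom[i]]][tab$sites$pos[i] + 1L] <- tab$sites$ref[i]
    reference <- vapply(ref_split, paste, "", collapse = "")

    strains <- tab$strains
    truth <- list()
    genomes <- list()
    snp_genomes <- list()
    for (s in strains) {
      snp_i <- which(tab$alleles[s, ] != tab$sites$ref)
      calls <- if (length(snp_i))
        data.frame(chrom = tab$sites$chrom[snp_i],
                   pos = tab$sites$pos[snp_i],
                   ref = tab$sites$ref[snp_i],
                   alt = tab$alleles[s, snp_i],
                   var_type = "SNP", zygosity = "homozygous",
                   alt_fraction = 1, stringsAsFactors = FALSE)
      else empty_calls()
      if (cfg$indel_rate > 0) {
        calls <- rbind(calls, simulate_indels(ref_split, calls, cfg))
      }
      calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      truth[[s]] <- calls
      genomes[[s]] <- apply_calls(reference, calls)
      snp_genomes[[s]] <- apply_calls(reference,
                                      calls[calls$var_type == "SNP", ,
                                            drop = FALSE])
    }
    structure(list(reference = reference, genomes = genomes,
                   snp_genomes = snp_genomes, truth = truth,
                   table = tab, chrom_lengths = lens, config = cfg),
              class = "strain_sim")
  })
}

# sample indels whose padded footprints avoid the strain's SNPs and each other
simulate_indels <- function(ref_split, snp_calls, cfg) {
  out <- empty_calls()
  for (ch in names(ref_split)) {
    L <- length(ref_split[[ch]])
    n <- stats::rbinom(1L, L, cfg$indel_rate)
    if (n == 0L) next
    occupied <- snp_calls$pos[snp_calls$chrom == ch]
    anchors <- integer(0); lens <- integer(0); types <- character(0)
    tries <- 0L
    while (length(anchors) < n && tries < 50L * n) {
      tries <- tries + 1L
      len <- min(1L + stats::rgeom(1L, 0.4), cfg$indel_max)
      a <- sample.int(L - len - 2L, 1L)    # 0-based anchor, off the ends
      lo <- a - 1L; hi <- a + len + 1L
      if (any(occupied >= lo & occupied <= hi)) next
      occupied <- c(occupied, lo:hi)
      anchors <- c(anchors, a); lens <- c(lens, len)
      types <- c(types, sample(c("insertion", "deletion"), 1L))
    }
    if (length(anchors) == 0L) next
    rows <- lapply(seq_along(anchors), function(i) {
      a <- anchors[i]; len <- lens[i]
      anchor_base <- ref_split[[ch]][a + 1L]
      if (types[i] == "deletion") {
        data.frame(chrom = ch, pos = a,
                   ref = paste(ref_split[[ch]][a + 1L + 0:len], collapse = ""),
                   alt = anchor_base, var_type = "deletion",
                   zygosity = "homozygous", alt_fraction = 1,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(chrom = ch, pos = a, ref = anchor_base,
                   alt = paste(c(anchor_base,
                                 sample(BASES, len, replace = TRUE)),
                               collapse = ""),
                   var_type = "insertion", zygosity = "homozygous",
                   alt_fraction = 1, stringsAsFactors = FALSE)
      }
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  out
}

# apply a sorted, non-overlapping call set to the reference -> strain genome
apply_calls <- function(reference, calls) {
  out <- reference
  for (ch in names(reference)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    if (nrow(cc) == 0L) next
    out[[ch]] <- as.character(cut_sequence(
      reference, cc, ch, 1L, nchar(reference[[ch]]),
      mode = "with_indels", max_length = nchar(reference[[ch]])))
  }
  out
}

#' Configuration for read/pileup simulation
#'
#' @param seed RNG seed.
#' @param read_length read length, bp.
#' @param mean_depth target mean coverage.
#' @param base_error_rate per-base substitution error probability (default
#'   0.001, a short-read-like error floor).
#' @param strand_fraction probability that a fragment has standard
#'   orientation (mate 1 forward); per-position strand composition is
#'   binomial around 0.5 for the default.
#' @param insert_size outer fragment length (>= 2 * read_length).
#' @param n_strand_bias_sites,n_end_artifact_sites,n_depth_spikes counts of
#'   injected artifacts.
#' @param spike_factor,spike_width depth-spike multiplier and width, bp.
#' @return List of class `read_sim_config`.
#' @export
read_sim_config <- function(seed = 1L, read_length = 100L, mean_depth = 30,
                            base_error_rate = 0.001, strand_fraction = 0.5,
                            insert_size = 300L, n_strand_bias_sites = 0L,
                            n_end_artifact_sites = 0L, n_depth_spikes = 0L,
                            spike_factor = 5, spike_width = 500L) {
  stopifnot(mean_depth > 0, base_error_rate >= 0, base_error_rate <= 1,
            strand_fraction >= 0, strand_fraction <= 1,
            insert_size >= 2 * read_length)
  structure(list(seed = seed, read_length = as.integer(read_length),
                 mean_depth = mean_depth, base_error_rate = base_error_rate,
                 strand_fraction = strand_fraction,
                 insert_size = as.integer(insert_size),
                 n_strand_bias_sites = as.integer(n_strand_bias_sites),
                 n_end_artifact_sites = as.integer(n_end_artifact_sites),
                 n_depth_spikes = as.integer(n_depth_spikes),
                 spike_factor = spike_factor,
                 spike_width = as.integer(spike_width)),
            class = "read_sim_config")
}

#' Simulate paired reads and their pileup from one chromosome
#'
#' Fragments are placed uniformly; each yields a forward and a reverse read.
#' Per-base substitution errors occur at `base_error_rate`. Injected
#' artifacts are realized exactly: at a strand-biased site every
#' forward-strand observation is flipped to one alternative allele (so the
#' alternative is supported by one strand only); at a read-end artifact site
#' every observation within 10 bp of its read's nearest end is flipped (so
#' the mean alt end distance is at most 10 bp by construction); a depth
#' spike multiplies the pileup depth over a window. Truth records every
#' injection.
#'
#' @param genome chromosome sequence the reads are drawn from (character
#'   scalar or named length-1 vector) — for a strain, its SNP-applied
#'   sequence (indel-free coordinates; indel calls enter the pipeline as an
#'   explicit upstream list).
#' @param cfg a [read_sim_config()].
#' @param chrom chromosome name for the output.
#' @param reference chromosome sequence used for the pileup's `ref` column
#'   (the mapping reference); defaults to `genome` itself, in which case no
#'   variant sites arise.
#' @param return_reads also materialize read sequences (FASTQ-ready);
#'   disable for large simulations where only the pileup is needed.
#' @return List of class `read_sim`: `pileup` (an [as_pileup()] frame with
#'   end-distance sums), `alignments` (read placements), `reads` (or NULL),
#'   `truth` (injected artifact records), `config`.
#' @export
simulate_reads <- function(genome, cfg = read_sim_config(), chrom = NULL,
                           reference = NULL, return_reads = TRUE) {
  if (!is.null(names(genome)) && is.null(chrom)) chrom <- names(genome)[1L]
  if (is.null(chrom)) chrom <- "chr1"
  genome <- as.character(genome[[1L]])
  if (is.null(reference)) reference <- genome
  reference <- as.character(reference[[1L]])
  if (nchar(reference) != nchar(genome))
    stop("reference and genome must have equal length (indel-free coordinates)")
  L <- nchar(genome)
  rl <- cfg$read_length
  if (L < cfg$insert_size) stop("genome shorter than the insert size")
  with_local_seed(cfg$seed, {
    n_frag <- ceiling(cfg$mean_depth * L / (2 * rl))
    fs <- sample.int(L - cfg$insert_size + 1L, n_frag, replace = TRUE) - 1L
    flip <- stats::runif(n_frag) > cfg$strand_fraction
    gbase <- strsplit(genome, "")[[1L]]
    rbase <- strsplit(reference, "")[[1L]]

    # one row per sequenced base observation
    mk <- function(start0, strand, read_id) {
      data.table::data.table(
        read = rep(read_id, each = rl),
        pos = rep(start0, each = rl) + rep(0:(rl - 1L), length(start0)),
        off = rep(0:(rl - 1L), length(start0)),
        strand = rep(strand, each = rl))
    }
    r1_start <- fs
    r2_start <- fs + cfg$insert_size - rl
    s1 <- ifelse(flip, "-", "+"); s2 <- ifelse(flip, "+", "-")
    obs <- data.table::rbindlist(list(
      mk(r1_start, s1, paste0("frag", seq_len(n_frag), "/1")),
      mk(r2_start, s2, paste0("frag", seq_len(n_frag), "/2"))))
    obs[, ed := pmin(off, rl - 1L - off)]
    obs[, allele := gbase[pos + 1L]]

    # sequencing errors
    n_err <- stats::rbinom(1L, nrow(obs), cfg$base_error_rate)
    if (n_err > 0L) {
      idx <- sample.int(nrow(obs), n_err)
      cur <- obs$allele[idx]
      obs$allele[idx] <- vapply(cur, function(b)
        sample(setdiff(BASES, b), 1L), "")
    }

    truth <- list(strand_bias = data.frame(pos = integer(), alt = character()),
                  end_artifact = data.frame(pos = integer(), alt = character()),
                  depth_spike = data.frame(start = integer(), end = integer(),
                                           factor = numeric()))

    pick_sites <- function(n, taken) {
      ok <- setdiff(seq.int(rl, L - rl) - 1L, unlist(lapply(taken, function(p)
        (p - 30L):(p + 30L))))
      if (length(ok) < n) stop("cannot place ", n, " artifact site(s)")
      sort(sample(ok, n))
    }
    taken <- list()
    if (cfg$n_strand_bias_sites > 0L) {
      sites <- pick_sites(cfg$n_strand_bias_sites, taken)
      taken <- c(taken, as.list(sites))
      for (p in sites) {
        i <- which(obs$pos == p & obs$strand == "+")
        if (length(i) == 0L || !any(obs$pos == p & obs$strand == "-"))
          stop("depth too low to realize a strand-biased site at ", p)
        alt <- sample(setdiff(BASES, c(gbase[p + 1L], rbase[p + 1L])), 1L)
        obs$allele[i] <- alt
        truth$strand_bias <- rbind(truth$strand_bias,
                                   data.frame(pos = p, alt = alt))
      }
    }
    if (cfg$n_end_artifact_sites > 0L) {
      sites <- pick_sites(cfg$n_end_artifact_sites, taken)
      taken <- c(taken, as.list(sites))
      for (p in sites) {
        i <- which(obs$pos == p & obs$ed <= 10L)
        if (length(i) == 0L)
          stop("depth too low to realize a read-end artifact at ", p)
        alt <- sample(setdiff(BASES, c(gbase[p + 1L], rbase[p + 1L])), 1L)
        obs$allele[i] <- alt
        truth$end_artifact <- rbind(truth$end_artifact,
                                    data.frame(pos = p, alt = alt))
      }
    }
    if (cfg$n_depth_spikes > 0L) {
      for (k in seq_len(cfg$n_depth_spikes)) {
        s <- sample.int(L - cfg$spike_width, 1L) - 1L
        win <- obs[pos >= s & pos < s + cfg$spike_width]
        extra <- win[rep(seq_len(nrow(win)), cfg$spike_factor - 1L)]
        extra[, read := paste0(read, ".dup")]
        obs <- data.table::rbindlist(list(obs, extra))
        truth$depth_spike <- rbind(truth$depth_spike,
                                   data.frame(start = s,
                                              end = s + cfg$spike_width,
                                              factor = cfg$spike_factor))
      }
    }

    # aggregate to the per-allele, per-strand pileup
    agg <- obs[, .(n = .N, edsum = sum(ed)), by = .(pos, allele, strand)]
    wide <- data.table::dcast(agg, pos ~ allele + strand,
                              value.var = c("n", "edsum"), fill = 0)
    df <- data.frame(chrom = chrom, pos = wide$pos,
                     ref = rbase[wide$pos + 1L])
    for (b in BASES) {
      nf <- wide[[paste0("n_", b, "_+")]]
      nr <- wide[[paste0("n_", b, "_-")]]
      ef <- wide[[paste0("edsum_", b, "_+")]]
      er <- wide[[paste0("edsum_", b, "_-")]]
      df[[paste0(b, "_fwd")]] <- if (is.null(nf)) 0 else nf
      df[[paste0(b, "_rev")]] <- if (is.null(nr)) 0 else nr
      ed <- (if (is.null(ef)) 0 else ef) + (if (is.null(er)) 0 else er)
      cnt <- df[[paste0(b, "_fwd")]] + df[[paste0(b, "_rev")]]
      df[[paste0(b, "_ed")]] <- ifelse(cnt > 0, ed, NA_real_)
    }
    p <- as_pileup(df)

    aln <- data.frame(read_id = c(paste0("frag", seq_len(n_frag), "/1"),
                                  paste0("frag", seq_len(n_frag), "/2")),
                      chrom = chrom, start = c(r1_start, r2_start),
                      end = c(r1_start, r2_start) + rl, strand = c(s1, s2),
                      stringsAsFactors = FALSE)
    reads <- NULL
    if (return_reads) {
      data.table::setorder(obs, read, off)
      rs <- obs[, .(seq = paste(allele, collapse = "")), by = read]
      rev_ids <- aln$read_id[aln$strand == "-"]
      i <- rs$read %in% rev_ids
      rs$seq[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(rs$seq[i])))
      reads <- data.frame(read_id = rs$read, sequence = rs$seq,
                          stringsAsFactors = FALSE)
    }
    structure(list(pileup = p, alignments = aln, reads = reads, truth = truth,
                   config = cfg, chrom = chrom, genome_length = L),
              class = "read_sim")
  })
}

#' Simulate a phenotype trait table
#'
#' Each animal's trait value is its strain-sex mean plus Gaussian noise, so
#' configured strain effects are recoverable by the downstream significance
#' machinery and an all-equal configuration provides a null for family-wise
#' error control.
#'
#' @param strain_means named list: trait -> named numeric vector of
#'   per-strain means (applied to both sexes), or trait -> list with `M` and
#'   `F` components for sex-specific means.
#' @param n_per_cell animals per strain-sex cell (a warning is issued below
#'   2, where downstream tests become untestable).
#' @param noise_sd residual standard deviation (shared).
#' @param seed RNG seed.
#' @param sexes sex labels.
#' @return Trait data frame: `strain`, `sex`, `age_days`, one column per
#'   trait.
#' @export
simulate_phenotypes <- function(strain_means, n_per_cell = 8L, noise_sd = 1,
                                seed = 1L, sexes = c("M", "F")) {
  if (n_per_cell < 2L)
    warning("n_per_cell < 2: strain-sex cells will be untestable downstream")
  strains <- names(if (is.list(strain_means[[1L]]))
    strain_means[[1L]][[1L]] else strain_means[[1L]])
  with_local_seed(seed, {
    grid <- expand.grid(strain = strains, sex = sexes,
                        animal = seq_len(n_per_cell),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(strain = grid$strain, sex = grid$sex,
                      age_days = sample(67:79, nrow(grid), replace = TRUE),
                      stringsAsFactors = FALSE)
    for (trait in names(strain_means)) {
      sm <- strain_means[[trait]]
      mu <- if (is.list(sm))
        mapply(function(s, sx) sm[[sx]][[s]], out$strain, out$sex)
      else sm[out$strain]
      out[[trait]] <- mu + stats::rnorm(nrow(out), 0, noise_sd)
    }
    out
  })
}
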