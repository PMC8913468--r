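# Independent brute-force oracles: position-by-position / element-by-element
# re-implementations of the filtering rules, kept deliberately naive so the
# package's interval-algebra and vectorized paths can be checked against them.

# --- read QC ---------------------------------------------------------------

oracle_mark <- function(q, thr = 20, w = 1) {
  n <- length(q)
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- q[max(1, i - w):min(n, i + w)]
    out[i] <- mean(win) < thr
  }
  out
}

oracle_trim_range <- function(mask) {
  n <- length(mask)
  from <- 1L
  while (from <= n && mask[from]) from <- from + 1L
  to <- n
  while (to >= 1L && mask[to]) to <- to - 1L
  if (from > to) NULL else c(from, to)
}

random_read <- function(id, len) {
  quality_read(id, paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = ""),
               sample(2:41, len, replace = TRUE))
}

# --- pileups ---------------------------------------------------------------

# random single-chromosome pileup with optional end-distance sums; not every
# position is covered
random_pileup <- function(L, p_covered = 0.85, max_count = 12,
                          p_ed = 0.7, chrom = "chr1") {
  pos <- which(stats::runif(L) < p_covered) - 1L
  n <- length(pos)
  df <- data.frame(chrom = chrom, pos = pos,
                   ref = sample(c("A", "C", "G", "T"), n, replace = TRUE))
  for (b in c("A", "C", "G", "T")) {
    df[[paste0(b, "_fwd")]] <- stats::rpois(n, 1.2)
    df[[paste0(b, "_rev")]] <- stats::rpois(n, 1.2)
    cnt <- df[[paste0(b, "_fwd")]] + df[[paste0(b, "_rev")]]
    ed <- ifelse(cnt > 0 & stats::runif(n) < p_ed,
                 round(stats::runif(n, 0, 40) * cnt), NA_real_)
    df[[paste0(b, "_ed")]] <- ed
  }
  as_pileup(df)
}

random_indels <- function(L, n, chrom = "chr1") {
  if (n == 0L) return(NULL)
  pos <- sort(sample.int(max(L - 12L, 1L), n)) - 1L
  type <- sample(c("insertion", "deletion"), n, replace = TRUE)
  rl <- ifelse(type == "deletion", 1L + sample(1:5, n, replace = TRUE), 1L)
  al <- ifelse(type == "insertion", 1L + sample(1:5, n, replace = TRUE), 1L)
  data.frame(chrom = chrom, pos = pos,
             ref = strrep("A", rl), alt = strrep("A", al),
             var_type = type, zygosity = "homozygous", alt_fraction = 1,
             stringsAsFactors = FALSE)
}

# --- the five-criterion filter, evaluated per position ---------------------

# Returns 0-based target positions, indel-target positions and the call set,
# computed with plain loops; `cfg` fields are read directly.
oracle_filter <- function(p, indels, cfg, L) {
  bases <- c("A", "C", "G", "T")
  depth <- setNames(p$depth, p$pos)
  covered <- p$depth[p$depth >= 1]
  m <- mean(covered)
  s <- sqrt(mean((covered - m)^2))
  hi <- m + cfg$depth_sd_limit * s

  rowinfo <- list()
  for (r in seq_len(nrow(p))) {
    row <- p[r, ]
    cnt <- sapply(bases, function(b) row[[paste0(b, "_fwd")]] + row[[paste0(b, "_rev")]])
    fwd <- sapply(bases, function(b) row[[paste0(b, "_fwd")]])
    rev <- sapply(bases, function(b) row[[paste0(b, "_rev")]])
    cnt_alt <- cnt
    if (row$ref %in% bases) cnt_alt[row$ref] <- -1
    alt <- bases[which.max(cnt_alt)]
    info <- list(pos = row$pos, ref = row$ref, depth = row$depth,
                 depth_ok = row$depth >= cfg$min_depth && row$depth <= hi,
                 balance_ok = sum(fwd) >= 1 && sum(rev) >= 1,
                 alt = alt, alt_cnt = cnt[alt], alt_fwd = fwd[alt],
                 alt_rev = rev[alt],
                 ref_cnt = if (row$ref %in% bases) cnt[row$ref] else 0,
                 ref_fwd = if (row$ref %in% bases) fwd[row$ref] else 0,
                 ref_rev = if (row$ref %in% bases) rev[row$ref] else 0)
    edsum <- row[[paste0(alt, "_ed")]]
    info$alt_mean_ed <- if (info$alt_cnt > 0 && !is.na(edsum))
      edsum / info$alt_cnt else NA_real_
    info$candidate <- row$depth > 0 && info$alt_cnt > 0 &&
      info$alt_cnt / row$depth >= cfg$het_low
    if (info$candidate) {
      ref_in <- info$ref_cnt / row$depth >= cfg$het_low
      info$biased <- (ref_in && !(info$ref_fwd >= 1 && info$ref_rev >= 1)) ||
        !(info$alt_fwd >= 1 && info$alt_rev >= 1)
      info$endart <- !is.na(info$alt_mean_ed) &&
        info$alt_mean_ed <= cfg$end_distance_limit
    } else {
      info$biased <- FALSE
      info$endart <- FALSE
    }
    rowinfo[[r]] <- info
  }

  excluded <- rep(FALSE, L)       # index i = position i-1
  excluded_noindel <- rep(FALSE, L)
  pad_out <- function(excl, lo, hi) {
    for (q in max(0, lo):min(L - 1, hi)) excl[q + 1] <- TRUE
    excl
  }
  if (!is.null(indels)) for (r in seq_len(nrow(indels))) {
    v <- indels[r, ]
    if (!v$var_type %in% c("insertion", "deletion")) next
    if (nchar(v$ref) > nchar(v$alt)) { s0 <- v$pos + 1; e0 <- v$pos + nchar(v$ref) }
    else { s0 <- v$pos; e0 <- v$pos + 2 }
    excluded <- pad_out(excluded, s0 - cfg$indel_pad, e0 + cfg$indel_pad - 1)
  }
  for (info in rowinfo) {
    if (info$biased) {
      excluded <- pad_out(excluded, info$pos - cfg$bias_pad,
                          info$pos + cfg$bias_pad)
      excluded_noindel <- pad_out(excluded_noindel, info$pos - cfg$bias_pad,
                                  info$pos + cfg$bias_pad)
    }
    if (info$endart) {
      excluded <- pad_out(excluded, info$pos - cfg$bias_pad,
                          info$pos + cfg$bias_pad)
      excluded_noindel <- pad_out(excluded_noindel, info$pos - cfg$bias_pad,
                                  info$pos + cfg$bias_pad)
    }
  }

  in_base <- rep(FALSE, L)
  for (info in rowinfo)
    if (info$pos < L && info$depth_ok && info$balance_ok)
      in_base[info$pos + 1] <- TRUE
  target <- which(in_base & !excluded) - 1L
  target_noindel <- which(in_base & !excluded_noindel) - 1L

  calls <- list()
  for (info in rowinfo) {
    if (!info$candidate || !(info$pos %in% target)) next
    if (info$biased || info$endart) next
    frac <- info$alt_cnt / info$depth
    zyg <- if (frac >= cfg$hom_fraction) "homozygous"
      else if (frac <= cfg$het_high) "heterozygous" else NA
    if (is.na(zyg)) next
    calls[[length(calls) + 1L]] <-
      data.frame(pos = info$pos, ref = info$ref, alt = info$alt,
                 var_type = "SNP", zygosity = zyg, stringsAsFactors = FALSE)
  }
  if (!is.null(indels)) for (r in seq_len(nrow(indels))) {
    v <- indels[r, ]
    if (v$var_type %in% c("insertion", "deletion") &&
        v$pos %in% target_noindel)
      calls[[length(calls) + 1L]] <-
        data.frame(pos = v$pos, ref = v$ref, alt = v$alt,
                   var_type = v$var_type, zygosity = v$zygosity,
                   stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               var_type = character(), zygosity = character())
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  list(target = target, target_noindel = target_noindel, calls = calls)
}

mask_positions <- function(mask) {
  df <- as.data.frame(mask)
  if (nrow(df) == 0L) return(integer(0))
  sort(unlist(mapply(function(s, e) s:(e - 1), df$start, df$end,
                     SIMPLIFY = FALSE)))
}

# --- comparative -----------------------------------------------------------

oracle_asd <- function(tab, a, b) {
  bases <- c("A", "C", "G", "T")
  x <- tab$alleles[a, ]; y <- tab$alleles[b, ]
  num <- 0L; den <- 0L
  for (i in seq_along(x)) {
    if (is.na(x[i]) || is.na(y[i])) next
    if (!(x[i] %in% bases) || !(y[i] %in% bases)) next
    den <- den + 1L
    if (x[i] != y[i]) num <- num + 1L
  }
  if (den == 0L) stop("no joint sites")
  num / den
}

oracle_novelty <- function(calls, catalog, max_alts = 3) {
  novel <- 0L; known <- 0L
  for (i in seq_len(nrow(calls))) {
    hit <- FALSE
    rows <- which(catalog$chrom == calls$chrom[i] & catalog$pos == calls$pos[i])
    seen <- 0L
    for (r in rows) {
      for (a in strsplit(catalog$alt[r], ",")[[1]]) {
        seen <- seen + 1L
        if (seen > max_alts) break
        if (a == calls$alt[i]) hit <- TRUE
      }
      if (seen > max_alts) break
    }
    if (hit) known <- known + 1L else novel <- novel + 1L
  }
  list(novel = novel, known = known)
}

# random ultrametric distance matrix via a recorded random agglomeration
random_ultrametric <- function(n, labels = paste0("t", seq_len(n))) {
  groups <- as.list(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  h <- 0
  while (length(groups) > 1L) {
    h <- h + stats::runif(1, 0.05, 0.5)
    i <- sample(length(groups), 2L)
    for (a in groups[[i[1]]]) for (b in groups[[i[2]]])
      d[a, b] <- d[b, a] <- h
    groups[[i[1]]] <- c(groups[[i[1]]], groups[[i[2]]])
    groups[[i[2]]] <- NULL
  }
  d
}
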