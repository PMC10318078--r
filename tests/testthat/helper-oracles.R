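# Shared fixtures and independent brute-force oracles.
# The oracles enumerate windows/intervals explicitly and are kept free of
# the package's cumulative-sum and difference-array machinery so they can
# stand as independent references.

# Build a genotype_matrix from a bare calls matrix.
make_gm <- function(calls, chrom = NULL, bp = NULL, iid = NULL) {
  calls <- as.matrix(calls)
  n_ind <- nrow(calls)
  n_loc <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", n_loc)
  if (is.null(bp))
    bp <- stats::ave(seq_len(n_loc), chrom, FUN = seq_along) * 10000
  if (is.null(iid)) iid <- sprintf("I%02d", seq_len(n_ind))
  genotype_matrix(
    calls,
    data.frame(fid = rep("F", n_ind), iid = iid, pat = rep("0", n_ind),
               mat = rep("0", n_ind), sex = rep("1", n_ind),
               phenotype = rep("-9", n_ind), stringsAsFactors = FALSE),
    data.frame(chrom = chrom, snp_id = sprintf("s%04d", seq_len(n_loc)),
               cm = "0", bp = bp, stringsAsFactors = FALSE),
    cbind(a1 = rep("A", n_loc), a2 = rep("B", n_loc)))
}

# Enumerate every window explicitly.
oracle_window_fractions <- function(calls, wp) {
  n <- length(calls)
  w <- wp$window_snp
  if (n < w) return(rep(0, n))
  ok <- vapply(seq_len(n - w + 1), function(s) {
    win <- calls[s:(s + w - 1)]
    sum(win == 1, na.rm = TRUE) <= wp$window_het_allow &&
      sum(is.na(win)) <= wp$window_missing_allow
  }, logical(1))
  vapply(seq_len(n), function(i) {
    ws <- max(1, i - w + 1):min(i, n - w + 1)
    mean(ok[ws])
  }, numeric(1))
}

# Rule-by-rule run assembly for one individual on one chromosome.
oracle_roh_chrom <- function(g, pos, wp, sp) {
  marked <- oracle_window_fractions(g, wp) >= wp$window_threshold
  n <- length(g)
  segs <- list()
  i <- 1
  while (i <= n) {
    if (!marked[i]) { i <- i + 1; next }
    j <- i
    while (j < n && marked[j + 1]) j <- j + 1
    # split the run at large gaps
    starts <- i
    if (j > i) {
      for (q in i:(j - 1)) {
        if (pos[q + 1] - pos[q] > sp$max_gap_kb * 1000)
          starts <- c(starts, q + 1)
      }
    }
    bounds <- c(starts - 1, j)
    for (p in seq_along(starts)) {
      s <- bounds[p] + 1
      e <- bounds[p + 1]
      while (s <= e && (is.na(g[s]) || g[s] == 1)) s <- s + 1
      while (e >= s && (is.na(g[e]) || g[e] == 1)) e <- e - 1
      if (s > e) next
      n_snp <- e - s + 1
      len <- pos[e] - pos[s] + 1
      if (n_snp >= sp$min_snp && len >= sp$min_length_kb * 1000 &&
          (len / 1000) / n_snp <= sp$max_density_kb_per_snp) {
        segs[[length(segs) + 1]] <-
          data.frame(start_bp = pos[s], end_bp = pos[e], n_snp = n_snp)
      }
    }
    i <- j + 1
  }
  if (length(segs)) do.call(rbind, segs) else
    data.frame(start_bp = numeric(), end_bp = numeric(), n_snp = integer())
}

# Point-in-interval incidence count per locus.
oracle_incidence <- function(segments, loci) {
  vapply(seq_len(nrow(loci)), function(l) {
    hit <- segments$chrom == loci$chrom[l] &
      segments$start_bp <= loci$bp[l] & segments$end_bp >= loci$bp[l]
    length(unique(segments$iid[hit]))
  }, integer(1))
}

# Base-level overlap via explicit position sets (small coordinates only).
oracle_overlap_bp <- function(a, b, L = 20000) {
  cover <- function(df) {
    v <- logical(L)
    for (k in seq_len(nrow(df))) v[df$start_bp[k]:df$end_bp[k]] <- TRUE
    v
  }
  sum(cover(a) & cover(b))
}

# A small HWE cohort at given allele-2 frequencies.
random_hwe_gm <- function(n_ind, p2, chrom = NULL, bp = NULL) {
  n_loc <- length(p2)
  calls <- matrix(stats::rbinom(n_ind * n_loc, 2, rep(p2, each = n_ind)),
                  nrow = n_ind)
  make_gm(calls, chrom = chrom, bp = bp)
}

# A quick default-scale pipeline run shared by heavier tests: QC'd
# detection on one simulated cohort.
run_pipeline <- function(sim) {
  gm <- restrict_to_autosomes(sim$genotypes)
  gm <- filter_by_call_rate(gm, qc_params())$genotypes
  L <- compute_min_snp(n_loci(gm), n_individuals(gm),
                       mean_heterozygosity(gm))
  segs <- call_roh(gm, window_params(), segment_params(min_snp = L))
  list(gm = gm, segs = segs, min_snp = L)
}

# Small simulator config for fast tests: 12 dogs on a 4-chromosome
# genome, study-like marker spacing.
small_sim_config <- function(seed, ...) {
  sim_config(n_dogs = 12,
             chromosomes = data.frame(
               chrom = c("1", "2", "3", "4"),
               length_bp = c(8e7, 6e7, 5e7, 4e7),
               stringsAsFactors = FALSE),
             shared_island = list(chrom = "2", start_bp = 1e7,
                                  length_bp = 2e6,
                                  carrier_fraction = 0.5),
             seed = seed, ...)
}
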