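test_that("the minimum-SNP rule matches its closed form and clamps at 1", {
  # frozen arbitrary-precision evaluation of
  # ln(0.05 / (164310 * 39)) / ln(0.75) = 64.8938737...
  expect_equal(compute_min_snp(164310, 39, 0.25, alpha = 0.05), 64L)
  # ln(0.05 / (128536 * 39)) / ln(1 - 0.3559) = 41.8804373...
  expect_equal(compute_min_snp(128536, 39, 0.3559, alpha = 0.05), 41L)
  # near-total heterozygosity drives L below 1; clamped
  expect_equal(compute_min_snp(1, 1, 0.999, alpha = 0.5), 1L)
  expect_error(compute_min_snp(100, 10, 0), "mean_het")
  expect_error(compute_min_snp(100, 10, 0.25, alpha = 1.2), "alpha")
})

test_that("L never decreases when the dataset grows", {
  ns <- 1000
  for (k in 1:12) {
    expect_gte(compute_min_snp(2 * ns, 39, 0.3), compute_min_snp(ns, 39, 0.3))
    ns <- 2 * ns
  }
})

test_that("window hit fractions handle the saturated extremes", {
  wp <- window_params()
  pos <- seq_len(60) * 10000
  expect_equal(window_hit_fractions(rep(0L, 60), pos, wp), rep(1, 60))
  expect_equal(window_hit_fractions(rep(1L, 60), pos, wp), rep(0, 60))
  # chromosome shorter than one window: no window fits
  expect_equal(window_hit_fractions(rep(0L, 10), seq_len(10) * 1e4, wp),
               rep(0, 10))
  expect_error(window_hit_fractions(rep(0L, 10), 1:9, wp), "length")
  expect_error(window_hit_fractions(c(0L, 0L), c(5, 5), window_params(2)),
               "increasing")
})

test_that("window hit fractions equal brute-force window enumeration", {
  set.seed(41)
  for (r in 1:25) {
    n <- sample(30:200, 1)
    wp <- window_params(window_snp = sample(3:15, 1),
                        window_het_allow = sample(0:2, 1),
                        window_missing_allow = sample(0:2, 1))
    calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                    prob = c(0.5, 0.2, 0.2, 0.1))
    pos <- cumsum(sample(1000:20000, n, replace = TRUE))
    expect_equal(window_hit_fractions(calls, pos, wp),
                 oracle_window_fractions(calls, wp))
  }
})

test_that("an ideal homozygous chromosome yields a single full-length run", {
  pos <- seq_len(300) * 10000                    # ~3 Mb, 10 kb spacing
  gm <- make_gm(matrix(0L, 1, 300), bp = pos)
  segs <- call_roh(gm, window_params(), segment_params(min_snp = 50))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snp, 300)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[300])
})

test_that("a large central gap splits a run into two retained segments", {
  pos <- seq_len(300) * 10000
  pos[151:300] <- pos[151:300] + 1.5e6           # 1.5 Mb gap after SNP 150
  gm <- make_gm(matrix(0L, 1, 300), bp = pos)
  segs <- call_roh(gm, window_params(), segment_params(min_snp = 50))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snp, c(150, 150))
  # each half spans 1.49 Mb, above the 1 Mb floor
  expect_true(all(segs$length_bp >= 1e6))
  oracle <- oracle_roh_chrom(rep(0L, 300), pos, window_params(),
                             segment_params(min_snp = 50))
  expect_equal(segs$start_bp, oracle$start_bp)
  expect_equal(segs$end_bp, oracle$end_bp)
})

test_that("full caller equals rule-by-rule enumeration on random instances", {
  set.seed(42)
  for (r in 1:30) {
    n <- sample(100:500, 1)
    wp <- window_params(window_snp = sample(5:20, 1))
    sp <- segment_params(min_snp = sample(10:40, 1),
                         min_length_kb = sample(c(100, 300, 500), 1),
                         max_gap_kb = sample(c(100, 500, 1000), 1),
                         max_density_kb_per_snp = sample(c(30, 50), 1))
    # blocks of homozygosity embedded in noisy background
    calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                    prob = c(0.42, 0.38, 0.15, 0.05))
    s <- sample(n - 50, 1)
    calls[s:(s + 49)] <- sample(c(0L, 2L), 50, replace = TRUE)
    pos <- cumsum(sample(c(1:30 * 1000, 6e5), n, replace = TRUE,
                         prob = c(rep(1, 30), 0.5) / 30.5))
    gm <- make_gm(matrix(calls, 1), bp = pos)
    segs <- call_roh(gm, wp, sp)
    oracle <- oracle_roh_chrom(calls, pos, wp, sp)
    expect_equal(nrow(segs), nrow(oracle))
    expect_equal(segs$start_bp, oracle$start_bp)
    expect_equal(segs$end_bp, oracle$end_bp)
    expect_equal(segs$n_snp, oracle$n_snp)
  }
})

test_that("every emitted segment satisfies the segment-level constraints", {
  sim <- simulate_genotypes(small_sim_config(seed = 43))
  run <- run_pipeline(sim)
  segs <- run$segs
  sp <- attr(segs, "segment_params")
  expect_true(all(segs$n_snp >= sp$min_snp))
  expect_true(all(segs$length_bp >= sp$min_length_kb * 1000))
  expect_true(all(segs$density_kb_per_snp <= sp$max_density_kb_per_snp))
  expect_true(all(segs$length_bp == segs$end_bp - segs$start_bp + 1))
  # per-individual, per-chromosome segments are disjoint and sorted
  by_ic <- split(segs, paste(segs$iid, segs$chrom))
  for (s in by_ic) {
    if (nrow(s) < 2) next
    expect_true(all(diff(s$start_bp) > 0))
    expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
})

test_that("marking is monotone in the window threshold", {
  set.seed(44)
  calls <- sample(c(0L, 1L, 2L, NA), 400, replace = TRUE,
                  prob = c(0.6, 0.15, 0.2, 0.05))
  pos <- cumsum(sample(5000:20000, 400, replace = TRUE))
  fr <- window_hit_fractions(calls, pos, window_params(window_snp = 20))
  marked_prev <- rep(TRUE, 400)
  for (th in c(0.01, 0.05, 0.2, 0.5, 0.9, 1)) {
    marked <- fr >= th
    expect_true(all(marked_prev | !marked))   # marked set only shrinks
    marked_prev <- marked
  }
})

test_that("the segment set does not depend on individual order", {
  sim <- simulate_genotypes(small_sim_config(seed = 45))
  gm <- sim$genotypes
  perm <- sample(n_individuals(gm))
  gm_perm <- genotype_matrix(gm$calls[perm, ], gm$individuals[perm, ],
                             gm$loci, gm$alleles)
  sp <- segment_params(min_snp = 41)
  a <- call_roh(gm, window_params(), sp)
  b <- call_roh(gm_perm, window_params(), sp)
  cols <- c("iid", "chrom", "start_bp", "end_bp", "n_snp")
  expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols])
})
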