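# Helper: a segment table with prescribed counts per length class.
segments_with_counts <- function(counts, lengths_mb, n_dogs = 39) {
  lens <- rep(lengths_mb, counts) * 1e6
  data.frame(iid = rep_len(sprintf("T%02d", seq_len(n_dogs)), length(lens)),
             chrom = "1", start_bp = 1, end_bp = lens,
             length_bp = lens, stringsAsFactors = FALSE)
}

test_that("length classes use left-closed bins and reproduce cohort percentages", {
  segs <- segments_with_counts(c(1143, 306, 136, 67, 47),
                               c(1.5, 2.7, 5.6, 11.0, 25.1))
  cls <- classify_roh(segs, n_individuals = 39)
  expect_equal(cls$n, c(1143, 306, 136, 67, 47))
  expect_equal(round(cls$percent), c(67, 18, 8, 4, 3))
  expect_equal(sum(cls$n), 1699)
  # boundary: a run of exactly 2 Mb belongs to the 2-4 Mb class
  one <- data.frame(iid = "T01", chrom = "1", start_bp = 1, end_bp = 2e6,
                    length_bp = 2e6)
  expect_equal(classify_roh(one, n_individuals = 1)$n, c(0, 1, 0, 0, 0))
  # sub-minimum segments violate the caller contract
  short <- data.frame(iid = "T01", chrom = "1", start_bp = 1, end_bp = 5e5,
                      length_bp = 5e5)
  expect_error(classify_roh(short, n_individuals = 1), "caller contract")
})

test_that("random segment sets bin identically to a per-segment loop", {
  set.seed(51)
  lens <- exp(runif(500, log(1), log(40))) * 1e6
  segs <- data.frame(iid = sample(sprintf("T%02d", 1:10), 500, TRUE),
                     chrom = "1", start_bp = 1, end_bp = lens,
                     length_bp = lens)
  cls <- classify_roh(segs, n_individuals = 10)
  edges <- c(1, 2, 4, 8, 16, Inf) * 1e6
  manual <- sapply(1:5, function(k)
    sum(lens >= edges[k] & lens < edges[k + 1]))
  expect_equal(cls$n, manual)
  # permutation invariance
  cls2 <- classify_roh(segs[sample(500), ], n_individuals = 10)
  expect_equal(cls2$n, cls$n)
})

test_that("class genome coverage follows the count x length / genome formula", {
  expect_equal(round(class_genome_coverage(7.85, 2.68, 2396.86), 2), 0.88)
  expect_equal(round(class_genome_coverage(3.49, 5.63, 2396.86), 2), 0.82)
  expect_equal(class_genome_coverage(0, 3, 2396.86), 0)
  expect_error(class_genome_coverage(1, 1, 0), "positive")
  # per-class coverages pooled match the all-segments computation
  set.seed(52)
  segs <- segments_with_counts(c(40, 30, 20, 5, 2), c(1.4, 2.9, 6, 12, 20),
                               n_dogs = 10)
  cls <- classify_roh(segs, n_individuals = 10, genome_mb = 2396.86)
  pooled <- class_genome_coverage(nrow(segs) / 10,
                                  mean(segs$length_bp) / 1e6, 2396.86)
  expect_equal(sum(cls$coverage_pct), pooled, tolerance = 1e-10)
})

test_that("F_ROH is the summed run length over the denominator", {
  whole <- data.frame(iid = "T01", chrom = "5", start_bp = 1, end_bp = 6e7,
                      length_bp = 6e7)
  expect_equal(froh(whole, 6e7), 1)
  expect_equal(froh(whole[0, ], 6e7), 0)
  over <- data.frame(iid = "T01", chrom = c("5", "5"),
                     start_bp = c(1, 5e6), end_bp = c(1e7, 1.5e7),
                     length_bp = c(1e7, 1e7))
  expect_error(froh(over, 6e7), "overlapping")
  # monotone under segment addition
  set.seed(53)
  lens <- runif(20, 1e6, 5e6)
  segs <- data.frame(iid = "T01", chrom = as.character(1:20),
                     start_bp = 1, end_bp = lens, length_bp = lens)
  f <- sapply(1:20, function(k) froh(segs[1:k, ], dog_genome_mb * 1e6))
  expect_true(all(diff(f) > 0))
})

test_that("F_ROH recovers the planted autozygous fraction per dog", {
  sim <- simulate_genotypes(small_sim_config(seed = 54))
  run <- run_pipeline(sim)
  genome_bp <- sum(sim$config$chromosomes$length_bp)
  tt <- sim$truth$tracts
  ft <- froh_table(run$segs, genome_bp = genome_bp)
  for (id in ft$genome$iid) {
    planted <- sum(tt$end_bp[tt$iid == id] - tt$start_bp[tt$iid == id] + 1)
    expect_lt(abs(ft$genome$froh[ft$genome$iid == id] - planted / genome_bp),
              0.01)
  }
})

test_that("per-chromosome F_ROH supports both denominator conventions", {
  segs <- data.frame(iid = "T01", chrom = "1", start_bp = 2e6, end_bp = 5e6,
                     length_bp = 3e6 + 1)
  loci <- data.frame(chrom = "1", bp = c(1e6, 3e6, 9e6))
  asm <- froh_table(segs, individuals = "T01",
                    chrom_lengths = data.frame(chrom = "1", length_bp = 1e7),
                    genome_bp = 1e7, by_chrom = TRUE)
  span <- froh_table(segs, individuals = "T01", denominator = "snp_span",
                     loci = loci, by_chrom = TRUE)
  expect_equal(unname(asm$by_chrom["T01", "1"]), (3e6 + 1) / 1e7)
  expect_equal(unname(span$by_chrom["T01", "1"]), (3e6 + 1) / 8e6)
})

test_that("per-dog summaries report exact counts and a sample sd", {
  segs <- segments_with_counts(c(1143, 306, 136, 67, 47),
                               c(1.5, 2.7, 5.6, 11.0, 25.1))
  pd <- summarize_per_dog(segs, sprintf("T%02d", 1:39))
  expect_equal(sum(pd$per_dog$n_roh), 1699)
  expect_equal(round(pd$mean_n, 2), 43.56)
  # one dog: sd undefined, reported as 0
  one <- summarize_per_dog(segs[segs$iid == "T01", ], "T01")
  expect_equal(one$sd_n, 0)
  # random allocation: mean is total over cohort size
  set.seed(55)
  alloc <- data.frame(iid = sample(sprintf("T%02d", 1:7), 100, TRUE),
                      length_bp = 1e6)
  expect_equal(summarize_per_dog(alloc, sprintf("T%02d", 1:7))$mean_n,
               100 / 7)
})

test_that("life-history generation length sums estrus and gestation times", {
  expect_equal(generation_length_life_history(9, 9, 2), 1.7)
  expect_equal(generation_length_life_history(12, 0, 0), 1.0)
  expect_equal(generation_length_life_history(9, 9, 2, round_digits = NULL),
               20 / 12)
})
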