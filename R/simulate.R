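#' Configuration for the synthetic genotype simulator
#'
#' Describes a cohort at canine SNP-array scale. The defaults emulate a
#' 39-dog breed panel genotyped on a ~160k-SNP array spread over the 38
#' dog autosomes: exponential inter-marker spacing with a 14 kb mean,
#' minor allele frequencies uniform on (0.05, 0.5), five autozygous
#' tracts planted per dog with lengths log-uniform on 1-40 Mb, one
#' shared 2 Mb region on chromosome 18 carried by half the cohort (an
#' island of homozygosity), a 0.5% heterozygote-error rate inside
#' planted tracts and 2% genome-wide missingness.
#'
#' @param n_dogs Cohort size.
#' @param chromosomes data.frame (`chrom`, `length_bp`); default
#'   [dog_autosomes()].
#' @param snp_spacing_bp Mean inter-SNP distance (exponential draws).
#' @param maf_range Per-locus minor allele frequency, uniform bounds.
#' @param n_tracts_per_dog Autozygous tracts planted per dog.
#' @param tract_length_range_mb Tract lengths, log-uniform bounds (Mb).
#' @param shared_island `NULL` or list(`chrom`, `start_bp`, `length_bp`,
#'   `carrier_fraction`): a region whose full extent is autozygous in
#'   `ceiling(carrier_fraction * n_dogs)` randomly chosen dogs. Each
#'   carrier's tract covers the region and extends beyond both ends by
#'   independent exponential flanks (mean `island_flank_mean_bp`),
#'   mimicking how a selected core sits inside IBD haplotypes of
#'   varying extent; the region itself is the stable intersection.
#' @param island_flank_mean_bp Mean of the exponential flank extension
#'   on each side of a carrier's shared tract (bp).
#' @param het_error_rate Probability a genotype inside a planted tract
#'   is misread as heterozygous.
#' @param missing_rate Genome-wide missing-call probability.
#' @param seed Mandatory RNG seed; one global stream drives every draw,
#'   so a config reproduces its dataset exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_dogs = 39L,
                       chromosomes = dog_autosomes(),
                       snp_spacing_bp = 14000,
                       maf_range = c(0.05, 0.5),
                       n_tracts_per_dog = 5L,
                       tract_length_range_mb = c(1, 40),
                       shared_island = list(chrom = "18", start_bp = 1e6,
                                            length_bp = 2e6,
                                            carrier_fraction = 0.5),
                       island_flank_mean_bp = 1e6,
                       het_error_rate = 0.005,
                       missing_rate = 0.02,
                       seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  for (r in c(het_error_rate, missing_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (!is.null(shared_island)) {
    cl <- chromosomes$length_bp[chromosomes$chrom == shared_island$chrom]
    if (!length(cl)) stop("shared island chromosome not in genome")
    if (shared_island$start_bp + shared_island$length_bp - 1 > cl)
      stop("shared island extends beyond its chromosome")
    if (shared_island$carrier_fraction < 0 ||
        shared_island$carrier_fraction > 1)
      stop("carrier_fraction must lie in [0, 1]")
  }
  if (any(tract_length_range_mb * 1e6 > max(chromosomes$length_bp)))
    stop("tract length range exceeds the longest chromosome")
  structure(list(n_dogs = as.integer(n_dogs), chromosomes = chromosomes,
                 snp_spacing_bp = snp_spacing_bp, maf_range = maf_range,
                 n_tracts_per_dog = as.integer(n_tracts_per_dog),
                 tract_length_range_mb = tract_length_range_mb,
                 shared_island = shared_island,
                 island_flank_mean_bp = island_flank_mean_bp,
                 het_error_rate = het_error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotyped cohort with planted autozygous tracts
#'
#' Background genotypes are drawn under Hardy-Weinberg equilibrium from
#' per-locus allele frequencies. Inside a dog's planted tract the two
#' haplotypes are identical by descent: a single allele is drawn by
#' frequency and doubled, then misread as heterozygous with
#' `het_error_rate`. Missing calls are sprinkled uniformly at
#' `missing_rate`. The record of planted tracts, shared-island carriers
#' and true allele frequencies is returned as ground truth for recovery
#' scoring.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result`: `genotypes` (a
#'   [genotype_matrix()]) and `truth` (list with `tracts` — data.frame
#'   `iid`, `chrom`, `start_bp`, `end_bp`, `shared` —, `carriers`, and
#'   `freq_allele2` per locus).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- config$chromosomes
  loci_list <- lapply(seq_len(nrow(chroms)), function(ci) {
    len <- chroms$length_bp[ci]
    n_exp <- ceiling(len / config$snp_spacing_bp)
    pos <- numeric(0)
    at <- 0
    while (TRUE) {
      gaps <- ceiling(stats::rexp(n_exp + 50, 1 / config$snp_spacing_bp))
      pos <- c(pos, at + cumsum(gaps))
      at <- pos[length(pos)]
      if (at > len) break
    }
    pos <- pos[pos <= len]
    data.frame(chrom = chroms$chrom[ci],
               snp_id = sprintf("snp_%s_%d", chroms$chrom[ci],
                                seq_along(pos)),
               cm = "0", bp = pos, stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci_list)
  ord <- order(chrom_rank(loci$chrom), loci$bp)
  loci <- loci[ord, , drop = FALSE]
  n_loc <- nrow(loci)
  n <- config$n_dogs

  p2 <- stats::runif(n_loc, config$maf_range[1], config$maf_range[2])
  calls <- matrix(stats::rbinom(n * n_loc, 2L, rep(p2, each = n)),
                  nrow = n, ncol = n_loc)

  iids <- sprintf("D%03d", seq_len(n))
  tracts <- list()
  for (d in seq_len(n)) {
    placed <- data.frame(chrom = character(), start_bp = numeric(),
                         end_bp = numeric(), stringsAsFactors = FALSE)
    for (t in seq_len(config$n_tracts_per_dog)) {
      for (try in 1:20) {
        len_bp <- round(1e6 * exp(stats::runif(
          1, log(config$tract_length_range_mb[1]),
          log(config$tract_length_range_mb[2]))))
        okc <- chroms$length_bp >= len_bp
        ci <- sample(which(okc), 1, prob = chroms$length_bp[okc])
        start <- floor(stats::runif(1, 1, chroms$length_bp[ci] - len_bp + 1))
        end <- start + len_bp - 1
        same <- placed$chrom == chroms$chrom[ci]
        if (!any(same & placed$start_bp <= end & placed$end_bp >= start)) {
          placed <- rbind(placed, data.frame(
            chrom = chroms$chrom[ci], start_bp = start, end_bp = end,
            stringsAsFactors = FALSE))
          break
        }
      }
    }
    if (nrow(placed) > 0) {
      placed$iid <- iids[d]
      placed$shared <- FALSE
      tracts[[length(tracts) + 1L]] <- placed
    }
  }
  carriers <- character(0)
  si <- config$shared_island
  if (!is.null(si) && si$carrier_fraction > 0) {
    n_car <- min(n, ceiling(si$carrier_fraction * n))
    carriers <- sort(sample(iids, n_car))
    core_start <- si$start_bp
    core_end <- si$start_bp + si$length_bp - 1
    chr_len <- chroms$length_bp[chroms$chrom == si$chrom]
    for (id in carriers) {
      tr_start <- max(1, round(core_start -
                                 stats::rexp(1, 1 / config$island_flank_mean_bp)))
      tr_end <- min(chr_len, round(core_end +
                                     stats::rexp(1, 1 / config$island_flank_mean_bp)))
      for (k in seq_along(tracts)) {
        tk <- tracts[[k]]
        drop <- tk$iid == id & tk$chrom == si$chrom &
          tk$start_bp <= tr_end & tk$end_bp >= tr_start
        tracts[[k]] <- tk[!drop, , drop = FALSE]
      }
      tracts[[length(tracts) + 1L]] <- data.frame(
        chrom = si$chrom, start_bp = tr_start, end_bp = tr_end,
        iid = id, shared = TRUE, stringsAsFactors = FALSE)
    }
  }
  truth_tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), iid = character(), shared = logical(),
               stringsAsFactors = FALSE)
  truth_tracts <- truth_tracts[order(truth_tracts$iid,
                                     chrom_rank(truth_tracts$chrom),
                                     truth_tracts$start_bp),
                               c("iid", "chrom", "start_bp", "end_bp",
                                 "shared")]
  rownames(truth_tracts) <- NULL

  # overwrite genotypes inside planted tracts with IBD homozygotes
  for (k in seq_len(nrow(truth_tracts))) {
    tr <- truth_tracts[k, ]
    idx <- which(loci$chrom == tr$chrom & loci$bp >= tr$start_bp &
                   loci$bp <= tr$end_bp)
    if (!length(idx)) next
    d <- match(tr$iid, iids)
    hom <- 2L * stats::rbinom(length(idx), 1L, p2[idx])
    err <- stats::runif(length(idx)) < config$het_error_rate
    hom[err] <- 1L
    calls[d, idx] <- hom
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  # canonical allele coding against observed symbols (A = allele 1, B =
  # allele 2); loci where only one symbol was realized are recoded the
  # way a PED reader would see them, keeping file round-trips exact
  obsA <- colSums(calls <= 1L, na.rm = TRUE) > 0
  obsB <- colSums(calls >= 1L, na.rm = TRUE) > 0
  flip <- !obsA & obsB
  if (any(flip)) calls[, flip] <- 2L - calls[, flip]
  a1 <- ifelse(obsA, "A", ifelse(obsB, "B", NA_character_))
  a2 <- ifelse(obsA & obsB, "B", NA_character_)

  individuals <- data.frame(
    fid = "SIM", iid = iids, pat = "0", mat = "0",
    sex = rep_len(c("2", "1"), n), phenotype = "-9",
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, individuals, loci,
                        cbind(a1 = a1, a2 = a2))
  structure(list(genotypes = gm,
                 truth = list(tracts = truth_tracts, carriers = carriers,
                              freq_allele2 = p2),
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: ", n_individuals(x$genotypes), " dogs x ",
      n_loci(x$genotypes), " loci; ", nrow(x$truth$tracts),
      " planted tracts (", length(x$truth$carriers),
      " shared-island carriers)\n", sep = "")
  invisible(x)
}

#' Score recovery of planted tracts
#'
#' Compares called ROH against the simulator's planted tracts, per
#' individual. Base-pair precision is the fraction of called bases that
#' lie inside true tracts; base-pair recall is the fraction of true
#' bases (of tracts at least `min_length_bp` long, the detector's
#' contract) that are called. Segment-level recall counts a true tract
#' as recovered when at least `min_overlap` of its length is covered by
#' calls; segment-level precision counts a called segment as correct
#' when at least `min_overlap` of its length lies inside truth. With no
#' calls at all, recall is 0 and precision is reported as 1 (an empty
#' call set makes no false claim; the zero denominator is resolved in
#' its favour).
#'
#' @param called Called segments (`iid`, `chrom`, `start_bp`, `end_bp`).
#' @param truth Planted tracts in the same layout.
#' @param min_length_bp Only true tracts at least this long count
#'   towards recall (default 1 Mb, the detector's minimum).
#' @param min_overlap Fractional overlap for segment-level scoring.
#' @return A list: `bp_precision`, `bp_recall`, `seg_precision`,
#'   `seg_recall`, plus the raw base totals.
#' @export
score_recovery <- function(called, truth, min_length_bp = 1e6,
                           min_overlap = 0.95) {
  truth <- truth[(truth$end_bp - truth$start_bp + 1) >= min_length_bp, ,
                 drop = FALSE]
  inter_len <- function(s1, e1, s2, e2) {
    # total intersection of two sets of disjoint intervals
    if (!length(s1) || !length(s2)) return(0)
    ov <- pmin(rep(e1, times = length(s2)),
               rep(e2, each = length(s1))) -
      pmax(rep(s1, times = length(s2)), rep(s2, each = length(s1))) + 1
    sum(pmax(0, ov))
  }
  called_bp <- if (nrow(called)) sum(called$end_bp - called$start_bp + 1) else 0
  truth_bp <- if (nrow(truth)) sum(truth$end_bp - truth$start_bp + 1) else 0
  overlap_bp <- 0
  seg_rec <- 0; seg_prec_hits <- 0
  keys <- unique(rbind(called[c("iid", "chrom")], truth[c("iid", "chrom")]))
  for (k in seq_len(nrow(keys))) {
    cc <- called[called$iid == keys$iid[k] & called$chrom == keys$chrom[k], ]
    tt <- truth[truth$iid == keys$iid[k] & truth$chrom == keys$chrom[k], ]
    overlap_bp <- overlap_bp +
      inter_len(cc$start_bp, cc$end_bp, tt$start_bp, tt$end_bp)
    for (r in seq_len(nrow(tt))) {
      cov <- inter_len(cc$start_bp, cc$end_bp, tt$start_bp[r], tt$end_bp[r])
      if (cov / (tt$end_bp[r] - tt$start_bp[r] + 1) >= min_overlap)
        seg_rec <- seg_rec + 1
    }
    for (r in seq_len(nrow(cc))) {
      cov <- inter_len(tt$start_bp, tt$end_bp, cc$start_bp[r], cc$end_bp[r])
      if (cov / (cc$end_bp[r] - cc$start_bp[r] + 1) >= min_overlap)
        seg_prec_hits <- seg_prec_hits + 1
    }
  }
  list(bp_precision = if (called_bp > 0) overlap_bp / called_bp else 1,
       bp_recall = if (truth_bp > 0) overlap_bp / truth_bp else 1,
       seg_precision = if (nrow(called) > 0)
         seg_prec_hits / nrow(called) else 1,
       seg_recall = if (nrow(truth) > 0) seg_rec / nrow(truth) else 1,
       called_bp = called_bp, truth_bp = truth_bp,
       overlap_bp = overlap_bp)
}
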