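#' Quality-control parameters
#'
#' Thresholds for the pre-ROH filtering stage. Defaults follow common
#' SNP-array practice for breed studies: individuals must have a call
#' rate of at least 0.90 (`max_sample_missing = 0.10`, PLINK `--mind`),
#' SNPs a call rate of at least 0.95 (`max_snp_missing = 0.05`, PLINK
#' `--geno`), and pairs with estimated genome-wide IBD proportion
#' PI_HAT above 0.4 are flagged as related (PLINK `--genome`). No minor
#' allele frequency, Hardy-Weinberg or LD pruning is applied: rare and
#' out-of-equilibrium markers are informative for homozygosity runs.
#'
#' @param max_sample_missing Maximum per-individual missing fraction.
#' @param max_snp_missing Maximum per-SNP missing fraction, evaluated
#'   after sample removal.
#' @param pi_hat_threshold PI_HAT above which a pair is flagged.
#' @param apply_sample_filter Set `FALSE` to skip the per-individual
#'   call-rate filter (useful for sparse datasets).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(max_sample_missing = 0.10,
                      max_snp_missing = 0.05,
                      pi_hat_threshold = 0.4,
                      apply_sample_filter = TRUE) {
  for (x in c(max_sample_missing, max_snp_missing, pi_hat_threshold))
    if (!is.numeric(x) || x < 0 || x > 1)
      stop("qc_params fractions must lie in [0, 1]")
  structure(list(max_sample_missing = max_sample_missing,
                 max_snp_missing = max_snp_missing,
                 pi_hat_threshold = pi_hat_threshold,
                 apply_sample_filter = isTRUE(apply_sample_filter)),
            class = "qc_params")
}

#' Keep autosomal loci only
#'
#' Drops loci whose chromosome label is not one of the 38 dog autosomes
#' (removing X, Y, MT and any other label), preserving locus order.
#'
#' @param gm A [genotype_matrix()].
#' @param autosomes Character vector of chromosome labels counted as
#'   autosomal; defaults to [dog_autosome_labels].
#' @return A [genotype_matrix()] restricted to autosomal loci.
#' @export
restrict_to_autosomes <- function(gm, autosomes = dog_autosome_labels) {
  subset_loci(gm, gm$loci$chrom %in% autosomes)
}

#' Filter individuals and SNPs by call rate
#'
#' Two-stage missingness filter: individuals whose missing fraction
#' exceeds `params$max_sample_missing` are removed first (when
#' `params$apply_sample_filter`), then SNPs whose missing fraction among
#' the remaining individuals exceeds `params$max_snp_missing` are
#' removed. The order matters and is fixed: a bad sample can push a SNP
#' over its threshold, so samples are judged on the full marker set and
#' markers on the cleaned sample set.
#'
#' @param gm A [genotype_matrix()].
#' @param params A [qc_params()] object.
#' @return A list with elements `genotypes` (the filtered matrix),
#'   `removed_samples` and `removed_snps` (data.frames of removed ids
#'   with their missing fractions).
#' @export
filter_by_call_rate <- function(gm, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  removed_samples <- data.frame(iid = character(), missing_frac = numeric(),
                                stringsAsFactors = FALSE)
  if (params$apply_sample_filter && n_individuals(gm) > 0 && n_loci(gm) > 0) {
    frac <- rowMeans(is.na(gm$calls))
    drop <- frac > params$max_sample_missing
    if (all(drop))
      stop("all individuals removed by the sample call-rate filter; ",
           "pipeline cannot proceed")
    removed_samples <- data.frame(iid = gm$individuals$iid[drop],
                                  missing_frac = frac[drop],
                                  stringsAsFactors = FALSE)
    gm <- subset_individuals(gm, !drop)
  }
  removed_snps <- data.frame(snp_id = character(), missing_frac = numeric(),
                             stringsAsFactors = FALSE)
  if (n_loci(gm) > 0 && n_individuals(gm) > 0) {
    frac <- colMeans(is.na(gm$calls))
    drop <- frac > params$max_snp_missing
    removed_snps <- data.frame(snp_id = gm$loci$snp_id[drop],
                               missing_frac = frac[drop],
                               stringsAsFactors = FALSE)
    gm <- subset_loci(gm, !drop)
  }
  list(genotypes = gm, removed_samples = removed_samples,
       removed_snps = removed_snps)
}

#' Method-of-moments pairwise relatedness (PI_HAT)
#'
#' Estimates, for every pair of individuals, the probabilities of
#' sharing 0, 1 or 2 alleles identical by descent from identity-by-state
#' (IBS) counts and sample allele frequencies, following the
#' bias-corrected moment estimator of Purcell et al. (2007) as
#' implemented in PLINK `--genome`. The summary statistic is
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`, the expected genome-wide IBD
#' proportion.
#'
#' Monomorphic loci and loci with fewer than two non-missing genotypes
#' contribute nothing (the expectation terms are undefined there); the
#' three moment estimates are clipped to `[0, 1]` and renormalized to
#' sum to one. Allele frequencies are taken from the supplied matrix,
#' which should already be call-rate filtered and autosomal.
#'
#' @param gm A [genotype_matrix()] with at least two individuals.
#' @return A data.frame of class `relatedness_report` with one row per
#'   unordered pair: `iid1`, `iid2`, `n_used` (co-non-missing polymorphic
#'   loci), `ibs0`, `ibs1`, `ibs2`, `z0`, `z1`, `z2` (the IBD state
#'   probabilities) and `pi_hat`, mirroring PLINK `.genome` columns.
#' @references Purcell S et al. (2007) PLINK: a tool set for
#'   whole-genome association and population-based linkage analyses.
#'   Am J Hum Genet 81:559-575.
#' @export
estimate_relatedness <- function(gm) {
  n <- n_individuals(gm)
  if (n < 2) stop("relatedness needs at least two individuals")
  calls <- gm$calls
  obs_cnt <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * obs_cnt)   # freq of allele 2
  # usable: polymorphic with at least 4 sampled alleles (the finite-sample
  # corrections divide by N-1, N-2, N-3)
  usable <- is.finite(p) & p > 0 & p < 1 & obs_cnt >= 2
  if (!any(usable))
    stop("all loci monomorphic: IBS expectations undefined")

  Nall <- 2 * obs_cnt
  q <- 1 - p
  cf3 <- Nall / (Nall - 1) * Nall / (Nall - 2) * Nall / (Nall - 3)
  cf2 <- Nall / (Nall - 1) * Nall / (Nall - 2)
  e00 <- 2 * p^2 * q^2 * ((p * Nall - 1) / (p * Nall)) *
    ((q * Nall - 1) / (q * Nall)) * cf3
  e10 <- 4 * p^3 * q * ((p * Nall - 1) / (p * Nall)) *
    ((p * Nall - 2) / (p * Nall)) * cf3 +
    4 * p * q^3 * ((q * Nall - 1) / (q * Nall)) *
    ((q * Nall - 2) / (q * Nall)) * cf3
  e11 <- 2 * p^2 * q * ((p * Nall - 1) / (p * Nall)) * cf2 +
    2 * p * q^2 * ((q * Nall - 1) / (q * Nall)) * cf2
  ok <- usable & Nall >= 4 & is.finite(e00) & is.finite(e10) & is.finite(e11)
  if (!any(ok))
    stop("no locus with enough sampled alleles for IBS expectations")
  e00[!ok] <- 0; e10[!ok] <- 0; e11[!ok] <- 0

  G0 <- (calls == 0L); G0[is.na(G0)] <- FALSE; mode(G0) <- "numeric"
  G1 <- (calls == 1L); G1[is.na(G1)] <- FALSE; mode(G1) <- "numeric"
  G2 <- (calls == 2L); G2[is.na(G2)] <- FALSE; mode(G2) <- "numeric"
  keep <- as.numeric(ok)
  G0 <- G0 * rep(keep, each = n)
  G1 <- G1 * rep(keep, each = n)
  G2 <- G2 * rep(keep, each = n)
  Obs <- G0 + G1 + G2

  M02 <- tcrossprod(G0, G2)
  N0 <- M02 + t(M02)
  A <- tcrossprod(G0, G1) + tcrossprod(G1, G2)
  N1 <- A + t(A)
  N2 <- tcrossprod(G0) + tcrossprod(G1) + tcrossprod(G2)
  S00 <- tcrossprod(Obs * rep(e00, each = n), Obs)
  S10 <- tcrossprod(Obs * rep(e10, each = n), Obs)
  S11 <- tcrossprod(Obs * rep(e11, each = n), Obs)
  Nco <- tcrossprod(Obs)
  S20 <- Nco - S00 - S10
  S21 <- Nco - S11

  ut <- which(upper.tri(Nco), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  n0 <- N0[ut]; n1 <- N1[ut]; n2 <- N2[ut]; m <- Nco[ut]
  z0 <- ifelse(S00[ut] > 0, n0 / S00[ut], 0)
  z1 <- ifelse(S11[ut] > 0, (n1 - z0 * S10[ut]) / S11[ut], 0)
  z2 <- ifelse(m > 0, (n2 - z0 * S20[ut] - z1 * S21[ut]) / m, 0)
  z0 <- pmin(pmax(z0, 0), 1)
  z1 <- pmin(pmax(z1, 0), 1)
  z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  tot[tot == 0] <- 1
  z0 <- z0 / tot; z1 <- z1 / tot; z2 <- z2 / tot
  pi_hat <- pmin(pmax(z2 + z1 / 2, 0), 1)

  rep_df <- data.frame(
    iid1 = gm$individuals$iid[i], iid2 = gm$individuals$iid[j],
    n_used = m, ibs0 = n0, ibs1 = n1, ibs2 = n2,
    z0 = z0, z1 = z1, z2 = z2, pi_hat = pi_hat,
    stringsAsFactors = FALSE)
  class(rep_df) <- c("relatedness_report", "data.frame")
  rep_df
}

#' @export
print.relatedness_report <- function(x, ...) {
  cat("relatedness_report:", nrow(x), "pairs; PI_HAT range [",
      sprintf("%.3f", min(x$pi_hat)), ",",
      sprintf("%.3f", max(x$pi_hat)), "]\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more pairs\n")
  invisible(x)
}

#' Flag related pairs
#'
#' Returns pairs whose PI_HAT exceeds a threshold, sorted by descending
#' PI_HAT. Flagged individuals are reported, never removed automatically:
#' which member of a related pair to drop (if any) is a study decision.
#'
#' @param report A `relatedness_report` from [estimate_relatedness()].
#' @param threshold Flag pairs with `pi_hat > threshold` (default 0.4).
#' @return The flagged subset of `report`, sorted by descending `pi_hat`.
#' @export
flag_related_pairs <- function(report, threshold = 0.4) {
  out <- report[report$pi_hat > threshold, , drop = FALSE]
  out <- out[order(-out$pi_hat), , drop = FALSE]
  rownames(out) <- NULL
  out
}
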