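#' Construct a genotype matrix
#'
#' In-memory container for biallelic SNP-array genotypes. Calls are coded
#' per (individual, locus) as the number of copies of allele 2: `0` =
#' homozygous allele 1, `1` = heterozygous, `2` = homozygous allele 2,
#' `NA` = missing. Allele 1 is, by convention, the lexicographically
#' smaller of the two allele symbols observed at the locus, so that the
#' coding is deterministic for PED input, which carries no ref/alt
#' orientation.
#'
#' @param calls Integer matrix, individuals in rows, loci in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param individuals data.frame with columns `fid`, `iid`, `pat`, `mat`,
#'   `sex` (PED codes: 1 male, 2 female, other/0 unknown) and `phenotype`;
#'   only `iid` is interpreted, the rest are carried for lossless PED
#'   round-trips.
#' @param loci data.frame with columns `chrom` (character), `snp_id`,
#'   `cm` and `bp` (1-based physical position).
#' @param alleles Character matrix with one row per locus and columns
#'   `a1`, `a2`: the two observed allele symbols (`NA` where fewer than
#'   two alleles were observed).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals, loci, alleles) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(individuals))
    stop("calls has ", nrow(calls), " rows but ", nrow(individuals),
         " individuals")
  if (ncol(calls) != nrow(loci))
    stop("calls has ", ncol(calls), " columns but ", nrow(loci), " loci")
  if (nrow(alleles) != nrow(loci))
    stop("alleles must have one row per locus")
  if (anyDuplicated(individuals$iid))
    stop("duplicate sample ids: ",
         paste(unique(individuals$iid[duplicated(individuals$iid)]),
               collapse = ", "))
  if (anyDuplicated(loci$snp_id))
    stop("duplicate SNP ids: ",
         paste(utils::head(unique(loci$snp_id[duplicated(loci$snp_id)]), 5),
               collapse = ", "))
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  rownames(calls) <- individuals$iid
  colnames(calls) <- loci$snp_id
  gm <- structure(
    list(calls = calls,
         individuals = as.data.frame(individuals, stringsAsFactors = FALSE),
         loci = as.data.frame(loci, stringsAsFactors = FALSE),
         alleles = alleles),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  l <- gm$loci
  if (any(l$bp < 1)) stop("locus positions must be >= 1")
  ord <- order(chrom_rank(l$chrom), l$bp)
  if (!identical(ord, seq_len(nrow(l))))
    stop("loci must be sorted by (chromosome, position)")
  dup <- stats::ave(l$bp, l$chrom, FUN = function(x) duplicated(x))
  if (any(dup > 0))
    stop("positions must be strictly increasing within a chromosome")
  invisible(gm)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of individuals / loci in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(gm) nrow(gm$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$calls))
  cat("genotype_matrix: ", n_individuals(x), " individuals x ",
      n_loci(x), " loci\n", sep = "")
  cat("  chromosomes: ", length(unique(x$loci$chrom)),
      "  missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

# Subset a genotype matrix by logical/integer index on loci or individuals.
subset_loci <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE],
                  gm$individuals,
                  gm$loci[keep, , drop = FALSE],
                  gm$alleles[keep, , drop = FALSE])
}

subset_individuals <- function(gm, keep) {
  genotype_matrix(gm$calls[keep, , drop = FALSE],
                  gm$individuals[keep, , drop = FALSE],
                  gm$loci,
                  gm$alleles)
}

#' Mean observed SNP heterozygosity
#'
#' Mean over loci of the observed heterozygote fraction (heterozygous
#' calls over non-missing calls); the \eqn{\bar h} input to the
#' minimum-SNP rule of [compute_min_snp()].
#'
#' @param gm A `genotype_matrix`.
#' @return A fraction in `[0, 1]`.
#' @export
mean_heterozygosity <- function(gm) {
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  obs <- colSums(!is.na(gm$calls))
  mean(ifelse(obs > 0, het / obs, NA_real_), na.rm = TRUE)
}
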