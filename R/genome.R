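#' Dog autosome labels
#'
#' The domestic dog karyotype has 38 autosomes; sex chromosomes and the
#' mitochondrion are labelled "X", "Y" and "MT" on input and excluded by
#' [restrict_to_autosomes()].
#'
#' @format Character vector of chromosome labels `"1"` .. `"38"`.
#' @export
dog_autosome_labels <- as.character(1:38)

#' Total dog genome size used as the F_ROH and coverage denominator (Mb)
#'
#' Assembly size of the dog reference genome, in megabases, used as the
#' default genome-wide denominator for F_ROH and for length-class genome
#' coverage.
#'
#' @export
dog_genome_mb <- 2396.86

#' Approximate dog autosome lengths
#'
#' Per-chromosome physical lengths for the 38 dog autosomes, in base pairs.
#' These are approximate, rounded values at the scale of the current dog
#' reference assemblies; they drive the synthetic-genotype simulator and
#' serve as a per-chromosome F_ROH denominator when no assembly table is
#' supplied. For exact per-chromosome work against a specific assembly,
#' pass your own table wherever a `chrom_lengths` argument is accepted.
#'
#' @return A data.frame with columns `chrom` (character) and `length_bp`
#'   (integer-valued numeric).
#' @export
dog_autosomes <- function() {
  data.frame(
    chrom = dog_autosome_labels,
    length_bp = 1e6 * c(
      122.7, 85.4, 91.9, 88.3, 88.9, 77.3, 80.9, 74.3, 61.1, 69.3,
      74.4, 72.5, 63.2, 60.9, 64.2, 59.6, 64.3, 55.9, 53.3, 58.1,
      50.8, 61.4, 52.3, 47.7, 51.6, 39.0, 45.9, 41.2, 41.5, 40.2,
      39.2, 38.8, 31.4, 42.1, 26.5, 30.8, 30.9, 23.9),
    stringsAsFactors = FALSE
  )
}

# Rank used to sort chromosome labels: autosomes numerically, then X, Y, MT,
# then anything else alphabetically after those.
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  r <- suppressWarnings(as.numeric(chrom))
  special <- match(chrom, c("X", "Y", "MT"))
  r[is.na(r) & !is.na(special)] <- 1000 + special[is.na(r) & !is.na(special)]
  unknown <- is.na(r)
  if (any(unknown)) {
    r[unknown] <- 2000 + as.integer(factor(chrom[unknown]))
  }
  r
}
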