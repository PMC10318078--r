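#' Classify ROH into length classes
#'
#' Assigns every run to one of the canonical length classes (defaults:
#' 1-2, 2-4, 4-8, 8-16 and >16 Mb; bins are left-closed/right-open, so a
#' run of exactly 2 Mb falls in the 2-4 Mb class) and tabulates per-class
#' count, percentage of all runs, mean length, mean count per animal,
#' genome coverage and the spread of per-individual F_ROH restricted to
#' that class.
#'
#' Genome coverage of a class is computed the conventional way: mean
#' number of runs per animal times mean run length (Mb), divided by the
#' genome size (Mb), times 100 (see [class_genome_coverage()]).
#'
#' @param segments A `roh_set` or data.frame with columns `iid` and
#'   `length_bp`.
#' @param n_individuals Cohort size; taken from the `roh_set` attribute
#'   when omitted. Per-class F_ROH statistics average over all
#'   individuals, counting zero for individuals without runs in a class.
#' @param genome_mb Genome size in Mb used for coverage and F_ROH
#'   (default [dog_genome_mb]).
#' @param breaks_mb Ascending bin edges in Mb; the last bin is open if
#'   the final edge is `Inf`.
#' @return data.frame with one row per class: `class`, `n`, `percent`,
#'   `mean_length_mb`, `mean_count_per_animal`, `coverage_pct`,
#'   `mean_froh`, `min_froh`, `max_froh`.
#' @export
classify_roh <- function(segments, n_individuals = NULL,
                         genome_mb = dog_genome_mb,
                         breaks_mb = c(1, 2, 4, 8, 16, Inf)) {
  if (is.null(n_individuals)) n_individuals <- attr(segments, "n_individuals")
  if (is.null(n_individuals)) stop("n_individuals required")
  len_mb <- segments$length_bp / 1e6
  if (any(len_mb < breaks_mb[1]))
    stop("segment shorter than ", breaks_mb[1],
         " Mb present: caller contract violated")
  nb <- length(breaks_mb) - 1L
  bin <- findInterval(len_mb, breaks_mb, rightmost.closed = FALSE)
  bin[bin > nb] <- nb   # only when the last edge is finite
  lab <- vapply(seq_len(nb), function(k) {
    if (is.infinite(breaks_mb[k + 1])) paste0(">", breaks_mb[k])
    else paste0(breaks_mb[k], "-", breaks_mb[k + 1])
  }, character(1))
  ids <- if (!is.null(attr(segments, "individuals")))
    attr(segments, "individuals") else unique(segments$iid)
  out <- lapply(seq_len(nb), function(k) {
    in_bin <- bin == k
    n <- sum(in_bin)
    mean_len <- if (n > 0) mean(len_mb[in_bin]) else 0
    mean_cnt <- n / n_individuals
    cov <- if (n > 0)
      class_genome_coverage(mean_cnt, mean_len, genome_mb) else 0
    per_ind <- vapply(ids, function(id) {
      sum(segments$length_bp[in_bin & segments$iid == id])
    }, numeric(1)) / (genome_mb * 1e6)
    if (length(per_ind) < n_individuals)
      per_ind <- c(per_ind, rep(0, n_individuals - length(per_ind)))
    data.frame(class = lab[k], n = n,
               percent = if (nrow(segments) > 0) 100 * n / nrow(segments) else 0,
               mean_length_mb = mean_len,
               mean_count_per_animal = mean_cnt,
               coverage_pct = cov,
               mean_froh = mean(per_ind),
               min_froh = min(per_ind),
               max_froh = max(per_ind),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genome coverage of a ROH length class
#'
#' Percentage of the genome covered by a class of runs, computed from
#' summary quantities: average number of runs per animal multiplied by
#' the average run length (Mb), divided by the genome size (Mb), times
#' 100.
#'
#' @param mean_count_per_animal Average number of runs per individual.
#' @param mean_length_mb Average run length in Mb.
#' @param genome_mb Genome size in Mb (default [dog_genome_mb]).
#' @return Coverage percentage.
#' @export
class_genome_coverage <- function(mean_count_per_animal, mean_length_mb,
                                  genome_mb = dog_genome_mb) {
  if (genome_mb <= 0) stop("genome_mb must be positive")
  100 * (mean_count_per_animal * mean_length_mb) / genome_mb
}

#' ROH-based inbreeding coefficient
#'
#' McQuillan-style F_ROH for one individual: the summed length of the
#' individual's runs divided by the length of the genome (or chromosome)
#' they are measured against.
#'
#' @param segments Data.frame of one individual's runs (columns `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`); must be non-overlapping.
#' @param denominator_bp Genome or chromosome length in bp.
#' @return A fraction in `[0, 1]`.
#' @export
froh <- function(segments, denominator_bp) {
  if (denominator_bp <= 0) stop("denominator_bp must be positive")
  if (nrow(segments) == 0) return(0)
  if ("iid" %in% names(segments) && length(unique(segments$iid)) > 1)
    stop("froh expects the segments of a single individual")
  o <- order(chrom_rank(segments$chrom), segments$start_bp)
  s <- segments[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1 && any(same & s$start_bp[-1] <= s$end_bp[-nrow(s)]))
    stop("overlapping segments for one individual")
  f <- sum(s$length_bp) / denominator_bp
  if (f > 1) stop("F_ROH > 1: denominator smaller than summed ROH length")
  f
}

#' Per-individual and per-chromosome F_ROH table
#'
#' Computes genome-wide F_ROH per individual and, optionally, F_ROH per
#' (individual, chromosome). Two denominator conventions are supported
#' and must be chosen explicitly: `"assembly"` divides by assembly
#' lengths (the genome constant, or per-chromosome lengths from
#' `chrom_lengths`), while `"snp_span"` divides by the span actually
#' covered by genotyped SNPs (last minus first SNP position), the
#' convention often used for per-chromosome plots. The genome-wide
#' default is the assembly convention.
#'
#' @param segments A `roh_set` or compatible data.frame.
#' @param individuals Character vector of all sample ids (individuals
#'   without runs get F_ROH 0); defaults to the `roh_set` attribute.
#' @param denominator `"assembly"` or `"snp_span"`.
#' @param genome_bp Genome-wide denominator in bp for
#'   `denominator = "assembly"` (default `dog_genome_mb * 1e6`).
#' @param chrom_lengths data.frame (`chrom`, `length_bp`) for
#'   per-chromosome assembly denominators; default [dog_autosomes()].
#' @param loci Locus table (`chrom`, `bp`) required for
#'   `denominator = "snp_span"`.
#' @param by_chrom Also return the per-(individual, chromosome) matrix.
#' @return A list with `genome` (data.frame `iid`, `froh`) and, when
#'   `by_chrom`, `by_chrom` (matrix individuals x chromosomes).
#' @export
froh_table <- function(segments, individuals = NULL,
                       denominator = c("assembly", "snp_span"),
                       genome_bp = dog_genome_mb * 1e6,
                       chrom_lengths = dog_autosomes(),
                       loci = NULL, by_chrom = FALSE) {
  denominator <- match.arg(denominator)
  if (is.null(individuals)) individuals <- attr(segments, "individuals")
  if (is.null(individuals)) individuals <- unique(segments$iid)
  if (denominator == "snp_span") {
    if (is.null(loci)) stop("snp_span denominator needs the locus table")
    spans <- tapply(loci$bp, loci$chrom, function(x) max(x) - min(x))
    chrom_den <- data.frame(chrom = names(spans),
                            length_bp = as.numeric(spans),
                            stringsAsFactors = FALSE)
    genome_den <- sum(chrom_den$length_bp)
  } else {
    chrom_den <- chrom_lengths
    genome_den <- genome_bp
  }
  gen <- data.frame(
    iid = individuals,
    froh = vapply(individuals, function(id) {
      froh(segments[segments$iid == id, , drop = FALSE], genome_den)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(genome = gen)
  if (by_chrom) {
    chroms <- chrom_den$chrom
    m <- matrix(0, length(individuals), length(chroms),
                dimnames = list(individuals, chroms))
    for (ci in seq_along(chroms)) {
      den <- chrom_den$length_bp[ci]
      sub <- segments[segments$chrom == chroms[ci], , drop = FALSE]
      for (id in unique(sub$iid)) {
        m[id, ci] <- froh(sub[sub$iid == id, , drop = FALSE], den)
      }
    }
    out$by_chrom <- m
  }
  out
}

#' Per-individual ROH counts and totals
#'
#' @param segments A `roh_set` or data.frame with `iid` and `length_bp`.
#' @param individuals All sample ids (zero-run individuals included);
#'   defaults to ids present in `segments`.
#' @return A list: `per_dog` (data.frame `iid`, `n_roh`, `total_mb`),
#'   `mean_n` and `sd_n` (cohort mean and sample sd of counts; sd is
#'   reported as 0 for a single individual, where it is undefined).
#' @export
summarize_per_dog <- function(segments, individuals = NULL) {
  if (is.null(individuals)) individuals <- attr(segments, "individuals")
  if (is.null(individuals)) individuals <- unique(segments$iid)
  cnt <- vapply(individuals, function(id) sum(segments$iid == id),
                numeric(1))
  tot <- vapply(individuals, function(id)
    sum(segments$length_bp[segments$iid == id]) / 1e6, numeric(1))
  per_dog <- data.frame(iid = individuals, n_roh = as.integer(cnt),
                        total_mb = tot, stringsAsFactors = FALSE,
                        row.names = NULL)
  list(per_dog = per_dog,
       mean_n = if (length(cnt)) mean(cnt) else NA_real_,
       sd_n = if (length(cnt) > 1) stats::sd(cnt) else 0)
}

#' Generation length from life-history traits
#'
#' Generation length as the sum of the average age at mating and the
#' gestation time, with age at mating taken as age at first estrus plus
#' one inter-estrus interval. All inputs are in months; the result is in
#' years. For the Tazy sighthound (first estrus at 9 months, 9-month
#' estrus cycle, 2-month gestation) this gives 1.7 years.
#'
#' @param age_first_estrus_months Age at first estrus (months).
#' @param estrus_interval_months Interval between estruses (months).
#' @param gestation_months Gestation time (months).
#' @param round_digits Decimals to round to (default 1); `NULL` returns
#'   the exact value.
#' @return Generation length in years.
#' @export
generation_length_life_history <- function(age_first_estrus_months = 9,
                                           estrus_interval_months = 9,
                                           gestation_months = 2,
                                           round_digits = 1) {
  if (age_first_estrus_months <= 0 || estrus_interval_months < 0 ||
      gestation_months < 0)
    stop("life-history inputs must be positive")
  years <- (age_first_estrus_months + estrus_interval_months +
              gestation_months) / 12
  if (is.null(round_digits)) years else round(years, round_digits)
}
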