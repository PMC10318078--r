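#' Per-SNP ROH incidence across individuals
#'
#' For every locus, counts the individuals whose ROH cover it (a locus
#' is covered by a segment of the same chromosome when
#' `start_bp <= bp <= end_bp`) and the corresponding carrier fraction.
#' This is the track behind Manhattan-style plots of ROH sharing and the
#' input to island calling.
#'
#' @param segments A `roh_set` or data.frame (`iid`, `chrom`,
#'   `start_bp`, `end_bp`); one individual's segments must be disjoint.
#' @param loci Locus table (`chrom`, `snp_id`, `bp`), position-sorted
#'   within chromosome.
#' @param n_individuals Cohort size (the fraction denominator); defaults
#'   to the `roh_set` attribute.
#' @return A data.frame of class `incidence_track`: `chrom`, `snp_id`,
#'   `bp`, `n_in_roh`, `fraction`.
#' @export
snp_incidence <- function(segments, loci, n_individuals = NULL) {
  if (is.null(n_individuals)) n_individuals <- attr(segments, "n_individuals")
  if (is.null(n_individuals)) stop("n_individuals required")
  counts <- integer(nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    bp <- loci$bp[li]
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(segs) == 0) next
    # difference-array accumulation over position-sorted loci
    first <- findInterval(segs$start_bp - 0.5, bp) + 1L
    last <- findInterval(segs$end_bp, bp)
    d <- integer(length(bp) + 1L)
    for (k in seq_len(nrow(segs))) {
      if (first[k] <= last[k]) {
        d[first[k]] <- d[first[k]] + 1L
        d[last[k] + 1L] <- d[last[k] + 1L] - 1L
      }
    }
    counts[li] <- cumsum(d[-length(d)])
  }
  out <- data.frame(chrom = loci$chrom, snp_id = loci$snp_id,
                    bp = loci$bp, n_in_roh = counts,
                    fraction = if (n_individuals > 0)
                      counts / n_individuals else 0,
                    stringsAsFactors = FALSE)
  structure(out, n_individuals = n_individuals,
            class = c("incidence_track", "data.frame"))
}

#' Extract extreme ROH islands
#'
#' Selects loci whose ROH carrier fraction reaches `threshold` and
#' merges consecutive selected loci on a chromosome into islands,
#' splitting wherever adjacent selected loci are more than `max_gap_kb`
#' apart. Island bounds are the first and last selected SNP; the span is
#' `end_bp - start_bp` (the difference of the bounding positions, the
#' convention used in breed eROHi tables).
#'
#' The number of supporting individuals per island depends on the rule:
#' `"cover"` (default) counts individuals with a single ROH spanning the
#' whole island extent; `"overlap"` counts individuals with any ROH
#' overlapping it.
#'
#' @param track An `incidence_track` from [snp_incidence()].
#' @param segments Segment table used to count supporting individuals;
#'   when `NULL`, `n_dogs` is `NA`.
#' @param threshold Minimum carrier fraction (e.g. 0.5 for "at least
#'   half the cohort").
#' @param max_gap_kb Split islands across gaps larger than this (kb).
#' @param n_dog_rule `"cover"` or `"overlap"` (see above).
#' @return A data.frame of class `eroh_islands`: `chrom`, `start_bp`,
#'   `end_bp`, `span_bp`, `n_snp`, `n_dogs`.
#' @export
call_islands <- function(track, segments = NULL, threshold = 0.5,
                         max_gap_kb = 1000,
                         n_dog_rule = c("cover", "overlap")) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  n_dog_rule <- match.arg(n_dog_rule)
  sel <- track$fraction >= threshold
  rows <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(sel & track$chrom == ch)
    if (!length(idx)) next
    bp <- track$bp[idx]
    brk <- which(diff(bp) > max_gap_kb * 1000)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(idx))
    for (k in seq_along(starts)) {
      i1 <- idx[starts[k]]; i2 <- idx[ends[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = track$bp[i1], end_bp = track$bp[i2],
        span_bp = track$bp[i2] - track$bp[i1],
        n_snp = ends[k] - starts[k] + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), span_bp = numeric(), n_snp = integer(),
               stringsAsFactors = FALSE)
  out$n_dogs <- rep(NA_integer_, nrow(out))
  if (!is.null(segments) && nrow(out) > 0) {
    for (k in seq_len(nrow(out))) {
      segs <- segments[segments$chrom == out$chrom[k], , drop = FALSE]
      hit <- if (n_dog_rule == "cover")
        segs$start_bp <= out$start_bp[k] & segs$end_bp >= out$end_bp[k]
      else
        segs$start_bp <= out$end_bp[k] & segs$end_bp >= out$start_bp[k]
      out$n_dogs[k] <- length(unique(segs$iid[hit]))
    }
  }
  out <- out[order(chrom_rank(out$chrom), out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("eroh_islands", "data.frame"))
}

#' Island span in base pairs
#'
#' Difference of the bounding SNP positions, `end_bp - start_bp`. Note
#' this is a position difference, not a count of covered bases, matching
#' how island sizes are conventionally tabulated.
#'
#' @param island A row (or several) of an `eroh_islands` table, or any
#'   data.frame with `start_bp` and `end_bp`.
#' @return Numeric vector of spans.
#' @export
island_span <- function(island) {
  island$end_bp - island$start_bp
}
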