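#' Sliding-window parameters for ROH scanning
#'
#' Parameters of the overlapping sliding-window scan (PLINK `--homozyg`
#' family). Defaults are the standard parameterization for ~170k-SNP
#' canine arrays: 50-SNP windows, at most one heterozygous and one
#' missing call per window, and a SNP is declared "in a homozygous
#' window" when at least 5% of the windows containing it are homozygous.
#'
#' @param window_snp Window length in SNPs (`--homozyg-window-snp`).
#' @param window_het_allow Heterozygous calls allowed per window
#'   (`--homozyg-window-het`).
#' @param window_missing_allow Missing calls allowed per window
#'   (`--homozyg-window-missing`).
#' @param window_threshold Minimum fraction of homozygous windows
#'   containing a SNP for it to be marked (`--homozyg-window-threshold`).
#' @return A list of class `window_params`.
#' @export
window_params <- function(window_snp = 50L, window_het_allow = 1L,
                          window_missing_allow = 1L,
                          window_threshold = 0.05) {
  if (window_snp < 1) stop("window_snp must be >= 1")
  if (window_het_allow < 0 || window_missing_allow < 0)
    stop("window allowances must be >= 0")
  if (window_threshold <= 0 || window_threshold > 1)
    stop("window_threshold must lie in (0, 1]")
  structure(list(window_snp = as.integer(window_snp),
                 window_het_allow = as.integer(window_het_allow),
                 window_missing_allow = as.integer(window_missing_allow),
                 window_threshold = window_threshold),
            class = "window_params")
}

#' Segment-level constraints for ROH calling
#'
#' @param min_snp Minimum SNPs per run (`--homozyg-snp`); usually set
#'   from [compute_min_snp()].
#' @param min_length_kb Minimum run length in kb (`--homozyg-kb`;
#'   default 1000 kb = 1 Mb, excluding short runs likely to reflect
#'   shared allozygous haplotypes rather than autozygosity).
#' @param max_gap_kb Maximum gap between adjacent SNPs inside one run
#'   (`--homozyg-gap`, default 1000 kb); a larger gap splits the run.
#' @param max_density_kb_per_snp Maximum average marker spacing inside a
#'   run (`--homozyg-density`, default 50 kb/SNP); sparser runs are
#'   dropped.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(min_snp, min_length_kb = 1000,
                           max_gap_kb = 1000,
                           max_density_kb_per_snp = 50) {
  if (min_snp < 1 || min_length_kb <= 0 || max_gap_kb <= 0 ||
      max_density_kb_per_snp <= 0)
    stop("segment_params must all be positive")
  structure(list(min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb,
                 max_gap_kb = max_gap_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp),
            class = "segment_params")
}

#' Minimum number of SNPs forming a ROH (Lencz/Purfield rule)
#'
#' Chooses the minimum run length in SNPs so that the expected number of
#' chance runs of that length across the whole dataset stays below a
#' false-positive rate alpha:
#' \deqn{L = \frac{\ln(\alpha / (n_s \, n_i))}{\ln(1 - \bar h)}}
#' where \eqn{n_s} is the number of SNPs, \eqn{n_i} the number of
#' individuals and \eqn{\bar h} the mean SNP heterozygosity. The result
#' is floored to an integer and clamped to at least 1.
#'
#' @param n_snps Number of genotyped SNPs after QC.
#' @param n_individuals Number of individuals.
#' @param mean_het Mean per-SNP observed heterozygosity, in (0, 1); see
#'   [mean_heterozygosity()].
#' @param alpha Tolerated false-positive rate (default 0.05).
#' @return Integer minimum SNP count.
#' @export
compute_min_snp <- function(n_snps, n_individuals, mean_het,
                            alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_snps < 1 || n_individuals < 1) stop("counts must be >= 1")
  if (!is.finite(mean_het) || mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly in (0, 1)")
  L <- log(alpha / (n_snps * n_individuals)) / log(1 - mean_het)
  max(1L, as.integer(floor(L)))
}

#' Per-SNP homozygous-window hit fractions
#'
#' Slides a window of `wp$window_snp` consecutive SNPs along one
#' individual's calls on one chromosome. A window is homozygous when it
#' contains at most `wp$window_het_allow` heterozygous and at most
#' `wp$window_missing_allow` missing calls. Each SNP's hit fraction is
#' the number of homozygous windows containing it divided by the number
#' of windows containing it (SNPs near chromosome ends belong to fewer
#' windows, hence the per-SNP denominator). A chromosome shorter than
#' one window yields all-zero fractions.
#'
#' @param calls Integer vector of calls (0/1/2, `NA` missing) for one
#'   individual on one chromosome, in position order.
#' @param positions Physical positions (bp), strictly increasing,
#'   aligned with `calls`.
#' @param wp A [window_params()] object.
#' @return Numeric vector of per-SNP fractions in `[0, 1]`.
#' @export
window_hit_fractions <- function(calls, positions, wp = window_params()) {
  n <- length(calls)
  if (length(positions) != n)
    stop("calls and positions differ in length")
  if (n > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  w <- wp$window_snp
  if (n < w) return(rep(0, n))
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  csh <- c(0L, cumsum(het))
  csm <- c(0L, cumsum(mis))
  nwin <- n - w + 1L
  ws <- seq_len(nwin)
  ok <- (csh[ws + w] - csh[ws]) <= wp$window_het_allow &
    (csm[ws + w] - csm[ws]) <= wp$window_missing_allow
  cso <- c(0, cumsum(ok))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - w + 1L)
  hi <- pmin(idx, nwin)
  hits <- cso[hi + 1L] - cso[lo]
  denom <- hi - lo + 1L
  hits / denom
}

#' Call runs of homozygosity
#'
#' PLINK-style overlapping-window ROH caller. For each individual and
#' chromosome the scan proceeds in five steps: (1) mark SNPs whose
#' homozygous-window hit fraction ([window_hit_fractions()]) reaches
#' `wp$window_threshold`; (2) take maximal runs of consecutive marked
#' SNPs; (3) split a run wherever adjacent SNPs are more than
#' `sp$max_gap_kb` apart; (4) trim run ends so each run starts and ends
#' on a non-missing homozygous call (interior heterozygous or missing
#' calls survive only through the window allowances); (5) keep runs with
#' at least `sp$min_snp` SNPs, physical length of at least
#' `sp$min_length_kb` kb, and average spacing of at most
#' `sp$max_density_kb_per_snp` kb/SNP. Length is `end - start + 1` bp
#' over the first/last SNP of the run.
#'
#' @param gm A [genotype_matrix()], autosomal and quality-controlled.
#' @param wp A [window_params()] object.
#' @param sp A [segment_params()] object; its `min_snp` is usually
#'   [compute_min_snp()] output.
#' @return An object of class `roh_set`: a data.frame with one row per
#'   run (`iid`, `chrom`, `start_bp`, `end_bp`, `start_snp`, `end_snp`,
#'   `n_snp`, `length_bp`, `n_het`, `n_missing`, `density_kb_per_snp`)
#'   sorted by (individual, chromosome, start), carrying the call
#'   parameters and cohort size as attributes.
#' @export
call_roh <- function(gm, wp = window_params(), sp) {
  stopifnot(inherits(wp, "window_params"), inherits(sp, "segment_params"))
  loci <- gm$loci
  out <- vector("list", 0L)
  chroms <- unique(loci$chrom)
  for (ch in chroms) {
    sel <- which(loci$chrom == ch)
    pos <- loci$bp[sel]
    if (any(diff(pos) <= 0)) stop("positions not sorted on chromosome ", ch)
    ids <- loci$snp_id[sel]
    for (i in seq_len(n_individuals(gm))) {
      g <- gm$calls[i, sel]
      frac <- window_hit_fractions(g, pos, wp)
      marked <- frac >= wp$window_threshold
      segs <- assemble_runs(g, pos, marked, sp)
      if (nrow(segs) > 0) {
        segs$iid <- gm$individuals$iid[i]
        segs$chrom <- ch
        segs$start_snp <- ids[segs$s]
        segs$end_snp <- ids[segs$e]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(s = integer(), e = integer(), start_bp = numeric(),
               end_bp = numeric(), n_snp = integer(), length_bp = numeric(),
               n_het = integer(), n_missing = integer(),
               iid = character(), chrom = character(),
               start_snp = character(), end_snp = character(),
               stringsAsFactors = FALSE)
  res$density_kb_per_snp <- ifelse(res$n_snp > 0,
                                   (res$length_bp / 1000) / res$n_snp,
                                   NA_real_)
  res <- res[order(res$iid, chrom_rank(res$chrom), res$start_bp),
             c("iid", "chrom", "start_bp", "end_bp", "start_snp",
               "end_snp", "n_snp", "length_bp", "n_het", "n_missing",
               "density_kb_per_snp")]
  rownames(res) <- NULL
  structure(res,
            window_params = wp, segment_params = sp,
            individuals = gm$individuals$iid,
            n_individuals = n_individuals(gm),
            class = c("roh_set", "data.frame"))
}

# Steps 2-5 of the caller: runs of marked SNPs -> gap split -> end trim ->
# segment-level filters. Returns a data.frame with local indices s, e.
assemble_runs <- function(g, pos, marked, sp) {
  res <- list()
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hom <- !is.na(g) & g != 1L
  for (k in which(r$values)) {
    pieces <- split_at_gaps(starts[k], ends[k], pos, sp$max_gap_kb * 1000)
    for (pc in pieces) {
      s <- pc[1]; e <- pc[2]
      while (s <= e && !hom[s]) s <- s + 1L
      while (e >= s && !hom[e]) e <- e - 1L
      if (s > e) next
      n_snp <- e - s + 1L
      len <- pos[e] - pos[s] + 1
      if (n_snp < sp$min_snp) next
      if (len < sp$min_length_kb * 1000) next
      if ((len / 1000) / n_snp > sp$max_density_kb_per_snp) next
      res[[length(res) + 1L]] <- data.frame(
        s = s, e = e, start_bp = pos[s], end_bp = pos[e],
        n_snp = n_snp, length_bp = len,
        n_het = sum(g[s:e] == 1L, na.rm = TRUE),
        n_missing = sum(is.na(g[s:e])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(s = integer(), e = integer(), start_bp = numeric(),
               end_bp = numeric(), n_snp = integer(), length_bp = numeric(),
               n_het = integer(), n_missing = integer(),
               stringsAsFactors = FALSE)
}

split_at_gaps <- function(s, e, pos, max_gap_bp) {
  if (e <= s) return(list(c(s, e)))
  gaps <- which(diff(pos[s:e]) > max_gap_bp)
  if (!length(gaps)) return(list(c(s, e)))
  bounds <- c(s - 1L, s - 1L + gaps, e)
  lapply(seq_len(length(bounds) - 1L),
         function(i) c(bounds[i] + 1L, bounds[i + 1L]))
}

#' @export
print.roh_set <- function(x, ...) {
  ni <- attr(x, "n_individuals")
  if (is.null(ni)) ni <- length(unique(x$iid))
  cat("roh_set: ", nrow(x), " runs of homozygosity in ", ni,
      " individuals\n", sep = "")
  if (nrow(x) > 0) {
    cat("  total length: ", sprintf("%.1f", sum(x$length_bp) / 1e6),
        " Mb; mean run: ", sprintf("%.2f", mean(x$length_bp) / 1e6),
        " Mb\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.roh_set <- function(object, genome_mb = dog_genome_mb, ...) {
  ni <- attr(object, "n_individuals")
  ans <- list(
    n_segments = nrow(object),
    n_individuals = ni,
    per_dog = summarize_per_dog(object, attr(object, "individuals")),
    classes = if (nrow(object) > 0)
      classify_roh(object, n_individuals = ni, genome_mb = genome_mb)
      else NULL,
    genome_mb = genome_mb)
  class(ans) <- "summary.roh_set"
  ans
}

#' @export
print.summary.roh_set <- function(x, ...) {
  cat("ROH summary: ", x$n_segments, " segments, ", x$n_individuals,
      " individuals\n", sep = "")
  cat("  runs per individual: mean ", sprintf("%.2f", x$per_dog$mean_n),
      " +/- ", sprintf("%.2f", x$per_dog$sd_n), " (sd)\n", sep = "")
  if (!is.null(x$classes)) {
    cat("  length classes (genome ", x$genome_mb, " Mb):\n", sep = "")
    print.data.frame(x$classes, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.roh_set <- function(x, ...) {
  pd <- summarize_per_dog(x, attr(x, "individuals"))$per_dog
  graphics::plot(pd$n_roh, pd$total_mb,
                 xlab = "ROH per individual",
                 ylab = "total length in ROH (Mb)",
                 main = "ROH burden per individual", pch = 19, ...)
  invisible(x)
}
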