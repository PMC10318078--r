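#' Read PLINK text PED/MAP genotypes
#'
#' Parses a whitespace-delimited PED/MAP pair into a [genotype_matrix()].
#' The MAP file must have four columns (chromosome, SNP id, genetic
#' position in cM, physical position in bp); the genetic position is read
#' and carried along but not used by the pipeline, which is physical-
#' distance based. The PED file has six leading columns (family id,
#' individual id, father, mother, sex, phenotype) followed by two allele
#' columns per SNP; the allele symbol `"0"` denotes a missing call.
#'
#' Loci are sorted by (chromosome, position) on load; within a chromosome
#' positions must be strictly increasing after sorting. At each locus the
#' lexicographically smaller observed allele becomes allele 1, so calls
#' are coded deterministically even though PED carries no ref/alt
#' orientation.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @seealso [write_ped_map()] for the inverse operation.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  if (length(map_lines) == 0L) {
    loci <- data.frame(chrom = character(), snp_id = character(),
                       cm = character(), bp = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    toks <- strsplit(trimws(map_lines), "[ \t]+")
    nf <- lengths(toks)
    if (any(nf != 4L))
      stop("MAP format error: line ", which(nf != 4L)[1],
           " has ", nf[nf != 4L][1], " fields (expected 4)")
    m <- matrix(unlist(toks), ncol = 4L, byrow = TRUE)
    loci <- data.frame(chrom = m[, 1], snp_id = m[, 2], cm = m[, 3],
                       bp = as.numeric(m[, 4]), stringsAsFactors = FALSE)
  }
  n_loci <- nrow(loci)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_ind <- length(ped_lines)
  expected <- 6L + 2L * n_loci

  individuals <- data.frame(fid = character(), iid = character(),
                            pat = character(), mat = character(),
                            sex = character(), phenotype = character(),
                            stringsAsFactors = FALSE)
  A1 <- matrix(character(), n_ind, n_loci)
  A2 <- matrix(character(), n_ind, n_loci)
  if (n_ind > 0L) {
    toks <- strsplit(trimws(ped_lines), "[ \t]+")
    nf <- lengths(toks)
    if (any(nf != expected)) {
      bad <- which(nf != expected)[1]
      stop("PED format error: line ", bad, " has ", nf[bad],
           " fields but the MAP lists ", n_loci, " loci (expected ",
           expected, ")")
    }
    tm <- matrix(unlist(toks), nrow = n_ind, byrow = TRUE)
    individuals <- data.frame(
      fid = tm[, 1], iid = tm[, 2], pat = tm[, 3], mat = tm[, 4],
      sex = tm[, 5], phenotype = tm[, 6], stringsAsFactors = FALSE)
    if (n_loci > 0L) {
      A1 <- tm[, 6L + 2L * seq_len(n_loci) - 1L, drop = FALSE]
      A2 <- tm[, 6L + 2L * seq_len(n_loci), drop = FALSE]
    }
  }

  enc <- encode_calls(A1, A2, loci$snp_id, n_loci)
  gm_unsorted <- list(calls = enc$calls, alleles = enc$alleles)

  ord <- order(chrom_rank(loci$chrom), loci$bp)
  genotype_matrix(gm_unsorted$calls[, ord, drop = FALSE],
                  individuals,
                  loci[ord, , drop = FALSE],
                  gm_unsorted$alleles[ord, , drop = FALSE])
}

# Turn paired allele-symbol matrices (individuals x loci) into 0/1/2/NA
# calls against the lexicographically smaller observed allele.
encode_calls <- function(A1, A2, snp_ids, n_loci) {
  n_ind <- nrow(A1)
  lev <- sort(setdiff(unique(c(A1, A2)), "0"))
  big <- length(lev) + 1L
  C1 <- matrix(match(A1, lev, nomatch = 0L), n_ind, n_loci)
  C2 <- matrix(match(A2, lev, nomatch = 0L), n_ind, n_loci)
  # PLINK half-missing genotypes are treated as missing
  miss <- C1 == 0L | C2 == 0L
  M1 <- C1; M1[miss] <- big
  M2 <- C2; M2[miss] <- big
  cmin <- rep(big, n_loci)
  cmax <- rep(0L, n_loci)
  for (i in seq_len(n_ind)) {
    cmin <- pmin(cmin, M1[i, ], M2[i, ])
    cmax <- pmax(cmax, C1[i, ], C2[i, ])
  }
  if (length(lev) > 0L) {
    n_distinct <- rep(0L, n_loci)
    for (k in seq_along(lev)) {
      n_distinct <- n_distinct +
        (colSums(C1 == k) + colSums(C2 == k) > 0L)
    }
    if (any(n_distinct > 2L)) {
      bad <- snp_ids[which(n_distinct > 2L)[1]]
      stop("validation error: locus ", bad,
           " has more than two distinct alleles")
    }
  } else {
    n_distinct <- rep(0L, n_loci)
  }
  a2_code <- ifelse(n_distinct == 2L, cmax, NA_integer_)
  # transpose so per-locus vectors recycle down columns
  g <- (t(C1) == a2_code) + (t(C2) == a2_code)
  g[is.na(a2_code) & n_distinct > 0L, ] <- 0L
  g[t(miss)] <- NA_integer_
  calls <- t(g)
  a1_sym <- ifelse(cmin < big, lev[cmin], NA_character_)
  a2_sym <- ifelse(!is.na(a2_code), lev[a2_code], NA_character_)
  alleles <- cbind(a1 = a1_sym, a2 = a2_sym)
  list(calls = calls, alleles = alleles)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' Emits files that [read_ped_map()] reads back to an identical object:
#' missing calls become `"0 0"`, homozygotes repeat the stored allele
#' symbol, and the MAP preserves the genetic-position column as read.
#'
#' @param gm A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `gm`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  loci <- gm$loci
  map_lines <- if (nrow(loci) > 0) {
    paste(loci$chrom, loci$snp_id, loci$cm,
          format(loci$bp, scientific = FALSE, trim = TRUE))
  } else character()
  writeLines(map_lines, map_path)

  n_ind <- n_individuals(gm)
  n_loc <- n_loci(gm)
  ped_lines <- character(n_ind)
  if (n_ind > 0) {
    gt <- t(gm$calls)                      # loci x individuals
    a1 <- gm$alleles[, "a1"]
    a2 <- gm$alleles[, "a2"]
    s1 <- ifelse(gt == 2L, a2, a1)         # recycles per locus
    s2 <- ifelse(gt == 0L, a1, a2)
    s1[is.na(gt)] <- "0"
    s2[is.na(gt)] <- "0"
    ind <- gm$individuals
    for (i in seq_len(n_ind)) {
      geno <- if (n_loc > 0) rbind(s1[, i], s2[, i]) else character()
      ped_lines[i] <- paste(c(ind$fid[i], ind$iid[i], ind$pat[i],
                              ind$mat[i], ind$sex[i], ind$phenotype[i],
                              as.vector(geno)), collapse = " ")
    }
  }
  writeLines(ped_lines, ped_path)
  invisible(gm)
}
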