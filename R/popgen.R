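#' Per-locus Weir-Cockerham F-statistics between the sexes
#'
#' Computes, for every locus, the Weir-Cockerham (1984) variance components
#' with the two sexes as groups: `a` (among groups), `b` (among individuals
#' within groups) and `c` (within individuals), and from them
#' `fst = a / (a + b + c)` and the pooled fixation index
#' `fis = 1 - c / (b + c)`. Estimates use per-locus complete cases within
#' each sex; loci with fewer than two complete genotypes in either sex, or
#' monomorphic among complete genotypes (zero total variance), are reported
#' as `NA` rather than dropped. Negative estimates are kept as computed.
#'
#' At a fully sex-linked locus in a balanced sample (all males heterozygous,
#' all females homozygous) these estimators return exactly `fst = 0.5` and
#' `fis = -1`, the diagnostic signature the window screen looks for.
#'
#' @param G a [genotype_matrix()].
#' @param sexes a [sex_map()] covering every sample in `G`.
#' @return A data.frame of per-locus statistics: `chrom`, `pos`, `n_m`,
#'   `n_f` (complete genotypes per sex), `p_m`, `p_f` (alt-allele
#'   frequencies), `ho_m`, `ho_f` (observed heterozygosity), `maf` (pooled
#'   minor-allele frequency), `a`, `b`, `c`, `fst`, `fis`.
#' @references Weir BS, Cockerham CC (1984). Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst_fis <- function(G, sexes) {
  validate_genotype_matrix(G)
  sx <- sexes_for(G, sexes)
  gm <- G$genotypes[sx == "male", , drop = FALSE]
  gf <- G$genotypes[sx == "female", , drop = FALSE]

  n1 <- colSums(!is.na(gm))
  n2 <- colSums(!is.na(gf))
  p1 <- colSums(gm, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gf, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(gm == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gf == 1L, na.rm = TRUE) / n2

  ntot <- n1 + n2
  nbar <- ntot / 2
  nc <- ntot - (n1^2 + n2^2) / ntot
  pbar <- (n1 * p1 + n2 * p2) / ntot
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / ntot

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  usable <- n1 >= 2L & n2 >= 2L
  # denominators that cancel exactly in real arithmetic (monomorphic data,
  # or both sexes fixed for opposite alleles) can leave float dust; any
  # legitimate polymorphism keeps them orders of magnitude above this
  zero <- function(x) abs(x) < 1e-12
  fst <- ifelse(usable & !zero(a + b + cc), a / (a + b + cc), NA_real_)
  fis <- ifelse(usable & !zero(b + cc), 1 - cc / (b + cc), NA_real_)
  a[!usable] <- b[!usable] <- cc[!usable] <- NA_real_

  pooled <- (colSums(gm, na.rm = TRUE) + colSums(gf, na.rm = TRUE)) /
    (2 * ntot)
  out <- data.frame(
    chrom = G$loci$chrom, pos = G$loci$pos,
    n_m = n1, n_f = n2,
    p_m = ifelse(n1 > 0, p1, NA_real_),
    p_f = ifelse(n2 > 0, p2, NA_real_),
    ho_m = ifelse(n1 > 0, h1, NA_real_),
    ho_f = ifelse(n2 > 0, h2, NA_real_),
    maf = ifelse(ntot > 0, pmin(pooled, 1 - pooled), NA_real_),
    a = a, b = b, c = cc, fst = fst, fis = fis,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Observed heterozygosity per sex
#'
#' Heterozygote proportion among complete genotypes, separately for males
#' and females at every locus.
#'
#' @inheritParams wc_fst_fis
#' @return A data.frame with columns `chrom`, `pos`, `ho_m`, `ho_f`.
#' @export
per_sex_heterozygosity <- function(G, sexes) {
  st <- wc_fst_fis(G, sexes)
  st[c("chrom", "pos", "ho_m", "ho_f")]
}

#' Filter loci on pooled minor-allele frequency
#'
#' The pooled MAF is computed over all non-missing genotypes of both sexes;
#' loci with `maf >= min_maf` are retained. With `min_maf = 0` only
#' genotype-free loci (all missing) are removed.
#'
#' @param G a [genotype_matrix()].
#' @param min_maf minimum pooled minor-allele frequency in `[0, 0.5]`
#'   (default 0.2, suited to an expected sex-linked frequency of 0.25).
#' @return A [genotype_matrix()] with the retained loci.
#' @export
maf_filter <- function(G, min_maf = 0.2) {
  if (!is.numeric(min_maf) || length(min_maf) != 1L ||
      min_maf < 0 || min_maf > 0.5) {
    stop("min_maf must be a single number in [0, 0.5]")
  }
  validate_genotype_matrix(G)
  n <- colSums(!is.na(G$genotypes))
  p <- colSums(G$genotypes, na.rm = TRUE) / (2 * n)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= min_maf
  subset_loci(G, keep)
}

#' Theoretical expectations under a single-locus SD system
#'
#' For a fully sex-linked biallelic SNP with the heterogametic sex
#' heterozygous and the homogametic sex homozygous, in a balanced sample:
#' `fst = 0.5`, `fis = -1`, and pooled allele frequencies 0.75 for the
#' shared (X or Z) allele and 0.25 for the sex-limited (Y or W) allele.
#' The magnitudes are identical for XY and ZW; only which sex is
#' heterogametic swaps.
#'
#' @param system `"XY"` (males heterogametic) or `"ZW"` (females).
#' @return Named numeric vector `fst`, `fis`, `p_common_allele`,
#'   `p_sex_limited_allele`.
#' @export
expected_sd_values <- function(system = c("XY", "ZW")) {
  if (length(system) == 1L && !system %in% c("XY", "ZW")) {
    stop("unknown SD system: ", system, " (expected \"XY\" or \"ZW\")")
  }
  system <- match.arg(system)
  c(fst = 0.5, fis = -1, p_common_allele = 0.75, p_sex_limited_allele = 0.25)
}
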