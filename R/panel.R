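#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' Conditional hypergeometric test of equal allele frequencies in two
#' groups: p is the total probability of tables (given fixed margins) no
#' more probable than the one observed, the same convention as
#' `stats::fisher.test` for 2x2 tables.
#'
#' @param alt1,ref1 alternate/reference allele counts in group 1.
#' @param alt2,ref2 alternate/reference allele counts in group 2.
#' @return p-value in (0, 1]; 1 for degenerate margins.
#' @export
fisher_allelic_p <- function(alt1, ref1, alt2, ref2) {
  m <- alt1 + ref1
  n <- alt2 + ref2
  k <- alt1 + alt2
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(alt1, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Validate a candidate SNP panel in a larger sexed sample
#'
#' Recomputes the discovery statistics per SNP (Weir-Cockerham FST and
#' pooled FIS via [wc_fst_fis()]) and tests male/female allele-frequency
#' differentiation with a two-sided Fisher exact test on the 2x2 table of
#' allele counts by sex. No multiple-testing correction is applied unless
#' `bonferroni = TRUE`.
#'
#' @param G_panel a [genotype_matrix()] of panel genotypes (few loci, many
#'   samples), e.g. from [read_vcf()] or [read_panel_tsv()].
#' @param sexes a [sex_map()] covering all panel samples.
#' @param bonferroni if `TRUE`, add `p_diff_adj = min(1, p * n_snps)`.
#' @return A data.frame with one row per SNP: `snp_id` (`chrom_pos`),
#'   `fst`, `fis`, `p_diff`, per-sex genotype counts
#'   (`n_hom_ref_m`, `n_het_m`, `n_hom_alt_m` and the `_f` versions) and
#'   allele counts (`alt_m`, `ref_m`, `alt_f`, `ref_f`).
#' @export
validate_panel <- function(G_panel, sexes, bonferroni = FALSE) {
  st <- wc_fst_fis(G_panel, sexes)
  sx <- sexes_for(G_panel, sexes)
  gm <- G_panel$genotypes[sx == "male", , drop = FALSE]
  gf <- G_panel$genotypes[sx == "female", , drop = FALSE]
  count_codes <- function(g, code) colSums(g == code, na.rm = TRUE)
  alt_m <- colSums(gm, na.rm = TRUE)
  ref_m <- 2 * colSums(!is.na(gm)) - alt_m
  alt_f <- colSums(gf, na.rm = TRUE)
  ref_f <- 2 * colSums(!is.na(gf)) - alt_f
  p_diff <- vapply(seq_len(n_loci(G_panel)), function(j) {
    fisher_allelic_p(alt_m[j], ref_m[j], alt_f[j], ref_f[j])
  }, numeric(1))
  out <- data.frame(
    snp_id = paste(st$chrom, st$pos, sep = "_"),
    chrom = st$chrom, pos = st$pos,
    fst = st$fst, fis = st$fis, p_diff = p_diff,
    n_hom_ref_m = count_codes(gm, 0L), n_het_m = count_codes(gm, 1L),
    n_hom_alt_m = count_codes(gm, 2L),
    n_hom_ref_f = count_codes(gf, 0L), n_het_f = count_codes(gf, 1L),
    n_hom_alt_f = count_codes(gf, 2L),
    alt_m = alt_m, ref_m = ref_m, alt_f = alt_f, ref_f = ref_f,
    stringsAsFactors = FALSE
  )
  if (bonferroni) out$p_diff_adj <- pmin(1, out$p_diff * nrow(out))
  rownames(out) <- NULL
  out
}

#' Select assayable panel SNPs from candidate regions
#'
#' For each candidate region, picks the SNPs whose (FST, FIS) pattern is
#' closest (Euclidean distance) to the fully sex-linked expectation
#' (0.5, -1), restricted to SNPs with no neighbouring SNP within
#' `spacing_bp` on either side (assay designability, as for mass-spec
#' genotyping primers).
#'
#' @param stats per-locus statistics from [wc_fst_fis()] for the full SNP
#'   set (neighbours are looked up here).
#' @param regions candidate regions from [call_candidates()].
#' @param n_per_region SNPs to select per region (default 2).
#' @param spacing_bp exclusion half-window around each SNP (default 100).
#' @return A data.frame of selected SNPs (`region`, `chrom`, `pos`,
#'   `snp_id`, `fst`, `fis`, `dist`). Regions with no eligible SNP
#'   contribute no rows and raise a warning.
#' @export
select_panel_snps <- function(stats, regions, n_per_region = 2,
                              spacing_bp = 100) {
  stats <- sort_stats(stats)
  target <- expected_sd_values("XY")[c("fst", "fis")]
  picks <- lapply(seq_len(nrow(regions)), function(r) {
    member <- seq.int(regions$first_idx[r], regions$last_idx[r])
    chrom <- regions$chrom[r]
    cand <- stats[member, , drop = FALSE]
    cand <- cand[!is.na(cand$fst) & !is.na(cand$fis), , drop = FALSE]
    if (nrow(cand)) {
      on_chrom <- stats$pos[stats$chrom == chrom]
      isolated <- vapply(cand$pos, function(p) {
        sum(abs(on_chrom - p) <= spacing_bp) == 1L  # itself only
      }, logical(1))
      cand <- cand[isolated, , drop = FALSE]
    }
    if (!nrow(cand)) {
      warning(sprintf("region %s:%d-%d has no eligible SNP", chrom,
                      regions$start_pos[r], regions$end_pos[r]))
      return(NULL)
    }
    cand$dist <- sqrt((cand$fst - target[["fst"]])^2 +
                        (cand$fis - target[["fis"]])^2)
    cand <- cand[order(cand$dist, cand$pos), , drop = FALSE]
    cand <- utils::head(cand, n_per_region)
    data.frame(region = r, chrom = cand$chrom, pos = cand$pos,
               snp_id = paste(cand$chrom, cand$pos, sep = "_"),
               fst = cand$fst, fis = cand$fis, dist = cand$dist,
               stringsAsFactors = FALSE)
  })
  picks <- picks[!vapply(picks, is.null, logical(1))]
  if (!length(picks)) {
    return(data.frame(region = integer(0), chrom = character(0),
                      pos = integer(0), snp_id = character(0),
                      fst = numeric(0), fis = numeric(0), dist = numeric(0)))
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}
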