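#' Simulation configuration for a sex-linked region
#'
#' Describes a diploid population with an equal-sex design and one
#' chromosome carrying a recombination-suppressed SD block. Within the
#' block, a contiguous core of `n_fully_linked` SNPs is fully sex-linked:
#' the single shared Y (or W) haplotype carries the alternate allele and
#' every X (or Z) haplotype the reference, so the heterogametic sex is
#' heterozygous and the homogametic sex homozygous at those sites, giving
#' pooled allele frequencies 0.75 / 0.25 in a balanced sample. Remaining
#' block SNPs are sex-linked with probability `partial_linkage` and
#' background-like otherwise. Background SNPs draw an allele frequency from
#' `Beta(alpha, beta)` and genotypes `Binomial(2, q)` per individual,
#' independent of sex. Genotyping error flips a genotype to one of the
#' other two codes uniformly; missingness is applied last.
#'
#' Defaults mirror a small discovery design: 5 + 5 samples, a 10 Mb
#' chromosome at 2.2 SNPs/kb with a 2 Mb block, 50 fully linked SNPs,
#' 1 percent genotyping error.
#'
#' @param n_males,n_females sample sizes (default 5 each).
#' @param chrom_length_bp chromosome length (default 10e6).
#' @param snp_density SNPs per kb (default 2.2).
#' @param sd_block numeric length-2, block start/end in bp
#'   (default 4e6-6e6).
#' @param n_fully_linked fully sex-linked SNPs forming the block core
#'   (default 50).
#' @param partial_linkage probability a non-core block SNP is sex-linked
#'   (default 0.05).
#' @param background_alpha,background_beta Beta parameters for background
#'   allele frequencies (default 0.5, 0.5: a U-shaped, SFS-like spectrum).
#' @param error_rate per-genotype miscall probability (default 0.01).
#' @param missing_rate per-genotype missingness (default 0.02).
#' @param system `"XY"` (males heterogametic) or `"ZW"`.
#' @param chrom chromosome name in the output (default `"chr1"`).
#' @param seed optional integer seed; [simulate_population()] is
#'   deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_males = 5, n_females = 5, chrom_length_bp = 10e6,
                       snp_density = 2.2, sd_block = c(4e6, 6e6),
                       n_fully_linked = 50, partial_linkage = 0.05,
                       background_alpha = 0.5, background_beta = 0.5,
                       error_rate = 0.01, missing_rate = 0.02,
                       system = c("XY", "ZW"), chrom = "chr1", seed = NULL) {
  system <- match.arg(system)
  stopifnot(n_males >= 1, n_females >= 1, chrom_length_bp >= 1000,
            snp_density > 0, length(sd_block) == 2L,
            n_fully_linked >= 0, background_alpha > 0, background_beta > 0)
  if (sd_block[1L] < 1 || sd_block[2L] > chrom_length_bp ||
      sd_block[1L] >= sd_block[2L]) {
    stop("sd_block must lie within the chromosome with start < end")
  }
  for (r in c(partial_linkage, error_rate, missing_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  structure(list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    chrom_length_bp = chrom_length_bp, snp_density = snp_density,
    sd_block = sd_block, n_fully_linked = as.integer(n_fully_linked),
    partial_linkage = partial_linkage,
    background_alpha = background_alpha, background_beta = background_beta,
    error_rate = error_rate, missing_rate = missing_rate,
    system = system, chrom = chrom, seed = seed
  ), class = "sim_config")
}

#' Simulate genotypes with an embedded sex-linked block
#'
#' Generates a [genotype_matrix()], [sex_map()] and ground truth under the
#' model described in [sim_config()]. Sex-linked SNPs code the heterogametic
#' sex heterozygous (one shared sex-limited haplotype, i.e. complete
#' recombination suppression) and the homogametic sex homozygous reference;
#' all other SNPs are sex-independent background. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `genotypes` (a `genotype_matrix`), `sexes`
#'   (a `sex_map`) and `truth` (class `sim_truth`): `block_start`,
#'   `block_end`, `system`, `linked` (logical per SNP), and
#'   `fully_linked_idx` (indices of the core SNPs).
#' @export
simulate_population <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(cfg$seed)
  }
  n <- cfg$n_males + cfg$n_females
  het_sex_is_male <- cfg$system == "XY"
  n_snps <- max(1L, round(cfg$chrom_length_bp / 1000 * cfg$snp_density))
  if (n_snps > cfg$chrom_length_bp) stop("snp_density too high for chromosome")
  pos <- sort(sample.int(cfg$chrom_length_bp, n_snps))
  in_block <- pos >= cfg$sd_block[1L] & pos <= cfg$sd_block[2L]
  if (cfg$n_fully_linked > 0 && sum(in_block) < cfg$n_fully_linked) {
    stop(sprintf("SD block contains only %d SNPs but n_fully_linked = %d",
                 sum(in_block), cfg$n_fully_linked))
  }

  linked <- rep(FALSE, n_snps)
  fully_idx <- integer(0)
  if (cfg$n_fully_linked > 0) {
    block_idx <- which(in_block)
    mid_rank <- which.min(abs(pos[block_idx] - mean(cfg$sd_block)))
    start_rank <- min(max(1L, mid_rank - cfg$n_fully_linked %/% 2L),
                      length(block_idx) - cfg$n_fully_linked + 1L)
    fully_idx <- block_idx[start_rank:(start_rank + cfg$n_fully_linked - 1L)]
    linked[fully_idx] <- TRUE
  }
  rest <- which(in_block & !linked)
  if (length(rest) && cfg$partial_linkage > 0) {
    linked[rest] <- stats::runif(length(rest)) < cfg$partial_linkage
  }

  g <- matrix(0L, nrow = n, ncol = n_snps)
  bg <- which(!linked)
  if (length(bg)) {
    q <- stats::rbeta(length(bg), cfg$background_alpha, cfg$background_beta)
    g[, bg] <- matrix(
      stats::rbinom(n * length(bg), 2L, rep(q, each = n)),
      nrow = n
    )
  }
  het_rows <- if (het_sex_is_male) seq_len(cfg$n_males) else
    cfg$n_males + seq_len(cfg$n_females)
  g[het_rows, linked] <- 1L  # one Y/W haplotype, alt allele; X/Z carry ref

  if (cfg$error_rate > 0) {
    flip <- which(stats::runif(length(g)) < cfg$error_rate)
    if (length(flip)) {
      g[flip] <- (g[flip] + sample(c(1L, 2L), length(flip),
                                   replace = TRUE)) %% 3L
    }
  }
  if (cfg$missing_rate > 0) {
    g[stats::runif(length(g)) < cfg$missing_rate] <- NA_integer_
  }

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L),
                character(1))
  ids <- c(sprintf("m%02d", seq_len(cfg$n_males)),
           sprintf("f%02d", seq_len(cfg$n_females)))
  loci <- data.frame(chrom = cfg$chrom, pos = pos, ref = unname(ref),
                     alt = unname(alt), qual = 60, stringsAsFactors = FALSE)
  G <- genotype_matrix(g, loci, ids)
  sexes <- sex_map(rep(c("male", "female"), c(cfg$n_males, cfg$n_females)),
                   ids)
  truth <- structure(list(
    block_start = cfg$sd_block[1L], block_end = cfg$sd_block[2L],
    system = cfg$system, chrom = cfg$chrom,
    linked = linked, fully_linked_idx = fully_idx, pos = pos
  ), class = "sim_truth")
  list(genotypes = G, sexes = sexes, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %s block %s:%d-%d, %d sex-linked SNPs (%d fully linked core)\n",
              x$system, x$chrom, as.integer(x$block_start),
              as.integer(x$block_end), sum(x$linked),
              length(x$fully_linked_idx)))
  invisible(x)
}

#' Write simulation truth as JSON
#'
#' @param truth a `sim_truth` from [simulate_population()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(
    list(system = truth$system, chrom = truth$chrom,
         block_start = truth$block_start, block_end = truth$block_end,
         linked_pos = truth$pos[truth$linked],
         fully_linked_pos = truth$pos[truth$fully_linked_idx]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
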