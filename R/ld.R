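#' Composite genotypic r-squared between two loci
#'
#' The squared Pearson correlation of allele-dosage genotype codes (0/1/2)
#' over samples with complete genotypes at both loci. This "composite" LD
#' measure needs no phasing, which is the point here: X/Y phase is unknown.
#' It is invariant to allele relabelling (`g -> 2 - g`) at either locus.
#'
#' @param g_i,g_j integer genotype vectors over the same samples.
#' @return r-squared in `[0, 1]`, or `NA` if fewer than two complete pairs
#'   remain or either locus is monomorphic among them.
#' @export
genotypic_r2 <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g_i[ok]
  y <- g_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Monte-Carlo exact test of genotypic disequilibrium
#'
#' Probability test for independence of the two-locus genotype contingency
#' table: the null distribution is generated by permuting one locus's
#' genotypes among individuals (which holds both genotype margins fixed),
#' and the p-value is the probability of a table no more probable than the
#' observed one under the generalized hypergeometric law. The Monte-Carlo
#' estimate is `(1 + #extreme) / (iterations + 1)` with its standard error.
#'
#' @param g_i,g_j integer genotype vectors over the same samples.
#' @param iterations number of Monte-Carlo permutations (default 10000).
#' @param seed optional integer seed for reproducibility (local to the
#'   test; the caller's RNG state is restored).
#' @return A list with `p_value`, `se` (Monte-Carlo standard error),
#'   `n_pairs` (complete-genotype sample count) and `iterations`.
#'   Degenerate tables (a single genotype class at either locus) give
#'   `p_value = 1` by convention.
#' @export
ld_exact_test <- function(g_i, g_j, iterations = 10000, seed = NULL) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  x <- g_i[ok]
  y <- g_j[ok]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(p_value = 1, se = 0, n_pairs = n, iterations = 0L))
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  B <- as.integer(iterations)
  lf <- lfactorial(0:n)
  obs <- table_logfact(x, y, lf)
  perm <- matrix(0L, nrow = B, ncol = n)
  for (b in seq_len(B)) perm[b, ] <- y[sample.int(n)]
  codes <- matrix(3L * rep(x, each = B), nrow = B) + perm
  slf <- numeric(B)
  for (v in 0:8) {
    cnt <- rowSums(codes == v)
    slf <- slf + lf[cnt + 1L]
  }
  # P(table) is proportional to 1/prod(cell!), so "at most as probable"
  # means a cell-log-factorial sum at least as large as observed
  extreme <- sum(slf >= obs - 1e-9)
  p <- (1 + extreme) / (B + 1)
  list(p_value = p, se = sqrt(p * (1 - p) / B), n_pairs = n, iterations = B)
}

table_logfact <- function(x, y, lf = lfactorial(0:length(x))) {
  cnt <- tabulate(3L * x + y + 1L, nbins = 9L)
  sum(lf[cnt + 1L])
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Pairwise LD across a candidate region
#'
#' Computes composite genotypic r-squared and the Monte-Carlo exact test for
#' every pair of the selected loci, and summarizes long-range LD as the
#' maximum inter-locus distance among significant pairs.
#'
#' @param G a [genotype_matrix()].
#' @param loci_idx integer indices of the loci to analyse; they must lie on
#'   a single chromosome.
#' @param sig_level significance level used for the long-range summary
#'   (default 0.01).
#' @param iterations Monte-Carlo iterations per pair (default 10000).
#' @param seed optional integer seed; pair-level seeds are derived from it
#'   so results do not depend on pair order.
#' @param max_loci if more than this many loci are requested they are
#'   thinned evenly to keep the quadratic pair count tractable
#'   (default 40).
#' @return A data.frame with one row per pair: `chrom`, `pos_i`, `pos_j`,
#'   `dist_bp`, `r2`, `p_value`, `se`, `n_pairs`. Attributes:
#'   `max_sig_dist_bp` (maximum distance with `p < sig_level`; `NA` if no
#'   pair is significant) and `sig_level`.
#' @export
ld_matrix <- function(G, loci_idx, sig_level = 0.01, iterations = 10000,
                      seed = NULL, max_loci = 40) {
  validate_genotype_matrix(G)
  loci_idx <- sort(unique(as.integer(loci_idx)))
  if (any(loci_idx < 1L | loci_idx > n_loci(G))) {
    stop("loci_idx out of range")
  }
  chroms <- unique(G$loci$chrom[loci_idx])
  if (length(chroms) > 1L) {
    stop("LD region must lie on a single chromosome; got: ",
         paste(chroms, collapse = ", "))
  }
  if (length(loci_idx) > max_loci) {
    loci_idx <- loci_idx[unique(round(seq(1L, length(loci_idx),
                                          length.out = max_loci)))]
  }
  m <- length(loci_idx)
  if (m < 2L) {
    out <- data.frame(chrom = character(0), pos_i = integer(0),
                      pos_j = integer(0), dist_bp = integer(0),
                      r2 = numeric(0), p_value = numeric(0),
                      se = numeric(0), n_pairs = integer(0))
    attr(out, "max_sig_dist_bp") <- NA_integer_
    attr(out, "sig_level") <- sig_level
    return(out)
  }
  pairs <- utils::combn(m, 2L)
  # identical genotype-pair patterns (common inside a fully linked block)
  # get one Monte-Carlo run, not thousands of equivalent ones
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- loci_idx[pairs[1L, k]]
    j <- loci_idx[pairs[2L, k]]
    gi <- G$genotypes[, i]
    gj <- G$genotypes[, j]
    key <- paste(c(gi, NA, gj), collapse = ",")
    pair_seed <- if (is.null(seed)) NULL else
      (seed + 7919L * k) %% .Machine$integer.max
    ex <- get0(key, envir = cache)
    if (is.null(ex)) {
      ex <- ld_exact_test(gi, gj, iterations = iterations, seed = pair_seed)
      assign(key, ex, envir = cache)
    }
    data.frame(chrom = G$loci$chrom[i], pos_i = G$loci$pos[i],
               pos_j = G$loci$pos[j],
               dist_bp = G$loci$pos[j] - G$loci$pos[i],
               r2 = genotypic_r2(gi, gj), p_value = ex$p_value,
               se = ex$se, n_pairs = ex$n_pairs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sig <- !is.na(out$p_value) & out$p_value < sig_level
  attr(out, "max_sig_dist_bp") <-
    if (any(sig)) max(out$dist_bp[sig]) else NA_integer_
  attr(out, "sig_level") <- sig_level
  out
}
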