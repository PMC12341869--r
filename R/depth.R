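#' Sex-biased read-depth test for a candidate gene
#'
#' Checks for a sex-linked duplication by comparing library-size-normalized
#' read counts over a gene between males and females: a male-specific
#' duplication would roughly double the male-to-female depth ratio. The
#' p-value comes from a two-sided permutation test of sex labels on the
#' normalized depths (exact enumeration of all label assignments when there
#' are at most `max_enumerate` of them, Monte-Carlo otherwise).
#'
#' @param table a depth table ([read_depth_table()]): columns `sample_id`,
#'   `sex`, `gene_id`, `read_count`, `library_size`.
#' @param gene_id gene to test.
#' @param iterations Monte-Carlo permutations when enumeration is not used
#'   (default 10000).
#' @param seed optional integer seed for the Monte-Carlo path.
#' @param max_enumerate enumerate all label assignments when
#'   `choose(n, n_males)` does not exceed this (default 20000, which covers
#'   any design with up to 12 samples).
#' @param n_boot bootstrap replicates for a descriptive 95 percent
#'   percentile interval on the ratio (0 = skip).
#' @return A list: `ratio` (mean male normalized depth over mean female
#'   normalized depth; `NA` with a `note` if the female mean is zero),
#'   `p_value`, `method` (`"enumeration"` or `"monte-carlo"`), `n_m`,
#'   `n_f`, and optionally `ci` (bootstrap percentile interval).
#' @export
depth_ratio_test <- function(table, gene_id, iterations = 10000,
                             seed = NULL, max_enumerate = 20000,
                             n_boot = 0) {
  tab <- table[table$gene_id == gene_id, , drop = FALSE]
  if (!nrow(tab)) stop("no depth rows for gene: ", gene_id)
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicated sample rows for gene: ", gene_id)
  }
  depth <- tab$read_count / tab$library_size
  is_m <- tab$sex == "male"
  n_m <- sum(is_m)
  n_f <- sum(!is_m)
  if (n_m < 2L || n_f < 2L) {
    stop("need at least 2 samples of each sex with counts for ", gene_id)
  }
  mean_f <- mean(depth[!is_m])
  mean_m <- mean(depth[is_m])
  if (mean_f == 0) {
    return(list(ratio = NA_real_, p_value = NA_real_, method = "undefined",
                n_m = n_m, n_f = n_f,
                note = "female mean normalized depth is zero; ratio undefined"))
  }
  obs <- abs(mean_m - mean_f)
  n <- n_m + n_f
  tol <- 1e-12 * max(1, obs)
  if (choose(n, n_m) <= max_enumerate) {
    sets <- utils::combn(n, n_m)
    diffs <- apply(sets, 2L, function(ix) {
      abs(mean(depth[ix]) - mean(depth[-ix]))
    })
    p <- mean(diffs >= obs - tol)
    method <- "enumeration"
  } else {
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    B <- as.integer(iterations)
    diffs <- vapply(seq_len(B), function(b) {
      ix <- sample.int(n, n_m)
      abs(mean(depth[ix]) - mean(depth[-ix]))
    }, numeric(1))
    p <- (1 + sum(diffs >= obs - tol)) / (B + 1)
    method <- "monte-carlo"
  }
  out <- list(ratio = mean_m / mean_f, p_value = p, method = method,
              n_m = n_m, n_f = n_f)
  if (n_boot > 0) {
    ratios <- vapply(seq_len(n_boot), function(b) {
      dm <- mean(sample(depth[is_m], n_m, replace = TRUE))
      df <- mean(sample(depth[!is_m], n_f, replace = TRUE))
      if (df == 0) NA_real_ else dm / df
    }, numeric(1))
    out$ci <- stats::quantile(ratios, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
  }
  out
}
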