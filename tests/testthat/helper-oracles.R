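# Independent oracles, deliberately coded from a different formulation than
# the package: variance components come from an explicit nested ANOVA over
# allele copies (alleles within individuals within sex groups), not from the
# frequency/heterozygosity shortcut formulas used in R/popgen.R.

# g_m, g_f: integer dosage vectors (0/1/2, NA = missing) for one locus.
# Returns list(a, b, c, fst, fis); NA when <2 complete genotypes in a group
# or when a denominator is zero.
oracle_wc <- function(g_m, g_f) {
  g_m <- g_m[!is.na(g_m)]
  g_f <- g_f[!is.na(g_f)]
  if (length(g_m) < 2L || length(g_f) < 2L) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                fst = NA_real_, fis = NA_real_))
  }
  groups <- list(g_m, g_f)
  r <- 2L
  n_i <- vapply(groups, length, integer(1))
  n_tot <- sum(n_i)
  p_ind <- unlist(groups) / 2            # per-individual allele frequency
  p_grp <- vapply(groups, function(g) mean(g) / 2, numeric(1))
  p_all <- sum(unlist(groups)) / (2 * n_tot)

  # sums of squares over the 2 * n_tot allele copies
  ss_within <- sum(unlist(lapply(groups, function(g) {
    vapply(g, function(y) {
      copies <- c(rep(1, y), rep(0, 2 - y))
      sum((copies - y / 2)^2)
    }, numeric(1))
  })))
  ss_ind <- 2 * sum((p_ind - rep(p_grp, n_i))^2)
  ss_grp <- 2 * sum(n_i * (p_grp - p_all)^2)

  ms_within <- ss_within / n_tot
  ms_ind <- ss_ind / (n_tot - r)
  ms_grp <- ss_grp / (r - 1)
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)

  a <- (ms_grp - ms_ind) / (2 * n_c)
  b <- (ms_ind - ms_within) / 2
  cc <- ms_within
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc != 0) a / (a + b + cc) else NA_real_,
       fis = if (b + cc != 0) 1 - cc / (b + cc) else NA_real_)
}

# Two-sided Fisher probability-test p for a 2x2 allele-count table, by
# direct enumeration of the conditional distribution with choose().
oracle_fisher <- function(alt1, ref1, alt2, ref2) {
  m <- alt1 + ref1
  n <- alt2 + ref2
  k <- alt1 + alt2
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  pr <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, alt1) * choose(n, k - alt1) / choose(m + n, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# All permutations of seq_len(n) as an n! x n matrix (n <= 8 intended).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact genotypic-disequilibrium probability test by full enumeration of
# permutations of one genotype vector (holds both margins fixed).
oracle_ld_exact <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(1)
  tab_lf <- function(yy) {
    cnt <- tabulate(3L * x + yy + 1L, nbins = 9L)
    sum(lfactorial(cnt))
  }
  obs <- tab_lf(y)
  pm <- all_perms(n)
  vals <- apply(pm, 1L, function(ix) tab_lf(y[ix]))
  mean(vals >= obs - 1e-9)
}

# Exhaustive two-sided permutation test of sex labels on normalized depths.
oracle_depth_p <- function(depth, n_m) {
  n <- length(depth)
  obs <- abs(mean(depth[seq_len(n_m)]) - mean(depth[-seq_len(n_m)]))
  sets <- combn(n, n_m)
  diffs <- apply(sets, 2L, function(ix) {
    abs(mean(depth[ix]) - mean(depth[-ix]))
  })
  mean(diffs >= obs - 1e-12 * max(1, obs))
}
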