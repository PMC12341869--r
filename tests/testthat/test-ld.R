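test_that("genotypic r2 basics and dosage-flip invariance", {
  g <- c(0L, 1L, 2L, 1L, 0L, 2L)
  expect_equal(genotypic_r2(g, g), 1)
  expect_equal(genotypic_r2(g, 2L - g), 1)
  expect_true(is.na(genotypic_r2(g, rep(1L, 6))))   # monomorphic partner
  expect_true(is.na(genotypic_r2(c(0L, NA), c(1L, 0L))))  # < 2 complete pairs
  set.seed(21)
  for (i in 1:50) {
    a <- as.integer(rbinom(12, 2, 0.5))
    b <- as.integer(rbinom(12, 2, 0.4))
    b[1:2] <- NA
    r2 <- genotypic_r2(a, b)
    ok <- !is.na(b)
    if (var(a[ok]) > 0 && var(b[ok]) > 0) {
      expect_equal(r2, cor(a[ok], b[ok])^2)
      expect_equal(genotypic_r2(2L - a, b), r2, tolerance = 1e-12)
    }
  }
})

test_that("mean null r2 is near 1/(n-1)", {
  set.seed(22)
  n <- 10
  vals <- replicate(1000, {
    genotypic_r2(as.integer(rbinom(n, 2, 0.5)),
                 as.integer(rbinom(n, 2, 0.5)))
  })
  expect_lt(abs(mean(vals, na.rm = TRUE) - 1 / (n - 1)), 0.02)
})

test_that("exact test is deterministic under a seed and degenerate-safe", {
  x <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  y <- c(1L, 1L, 0L, 2L, 0L, 2L, 0L, 1L)
  a <- ld_exact_test(x, y, iterations = 500, seed = 99)
  b <- ld_exact_test(x, y, iterations = 500, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$n_pairs, 8L)
  expect_equal(ld_exact_test(x, rep(1L, 8))$p_value, 1)
  expect_equal(ld_exact_test(rep(0L, 8), y)$p_value, 1)
})

test_that("Monte-Carlo p matches full permutation enumeration (<= 8 samples)", {
  set.seed(23)
  cases <- list(
    list(x = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
         y = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)),
    list(x = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L),
         y = c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L)),
    list(x = as.integer(rbinom(7, 2, 0.5)),
         y = as.integer(rbinom(7, 2, 0.5))),
    list(x = c(0L, 0L, 1L, 1L, 2L, 2L),
         y = c(2L, 2L, 1L, 1L, 0L, 0L))
  )
  for (cs in cases) {
    if (length(unique(cs$x)) < 2L || length(unique(cs$y)) < 2L) next
    exact <- oracle_ld_exact(cs$x, cs$y)
    mc <- ld_exact_test(cs$x, cs$y, iterations = 6000, seed = 1)
    expect_lt(abs(mc$p_value - exact), 3 * max(mc$se, 1e-3))
  }
})

test_that("null p-values are not anti-conservative", {
  set.seed(24)
  p <- replicate(400, {
    ld_exact_test(as.integer(rbinom(10, 2, 0.5)),
                  as.integer(rbinom(10, 2, 0.5)), iterations = 300)$p_value
  })
  for (alpha in c(0.05, 0.1)) {
    expect_lte(mean(p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / 400) + 0.01)
  }
})

test_that("ld_matrix enumerates pairs and summarizes long-range LD", {
  sim <- simulate_population(sim_config(error_rate = 0, missing_rate = 0,
                                        seed = 5))
  core <- sim$truth$fully_linked_idx
  idx5 <- core[1:5]
  res <- ld_matrix(sim$genotypes, idx5, iterations = 20000, seed = 3)
  expect_equal(nrow(res), 10L)     # C(5,2)
  expect_equal(res$r2, rep(1, 10)) # identical male-het/female-hom patterns
  expect_true(all(res$p_value < 0.01))  # exact p = 2 * 5!5!/10! ~ 0.0079
  expect_equal(attr(res, "max_sig_dist_bp"), max(res$dist_bp))

  # within-block r2 exceeds the background mean
  set.seed(25)
  bg <- sample(which(!sim$truth$linked), 8)
  bg_res <- ld_matrix(sim$genotypes, bg, iterations = 200, seed = 4)
  expect_gt(mean(res$r2), mean(bg_res$r2, na.rm = TRUE))

  # loci on different chromosomes are rejected
  G2 <- make_gm(cbind(c(0L, 1L, 2L, 1L), c(1L, 0L, 1L, 2L)),
                chrom = c("c1", "c2"), pos = c(100L, 100L))
  expect_error(ld_matrix(G2, 1:2), "single chromosome")

  # thinning caps the quadratic pair count
  res_thin <- ld_matrix(sim$genotypes, core, iterations = 50, seed = 1,
                        max_loci = 10)
  expect_equal(nrow(res_thin), choose(10, 2))
})
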