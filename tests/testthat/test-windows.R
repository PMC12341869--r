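fake_stats <- function(n, chrom = "c1", fst = NULL, fis = NULL,
                       pos = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fst)) fst <- runif(n, -0.1, 0.6)
  if (is.null(fis)) fis <- runif(n, -1, 0.5)
  if (is.null(pos)) pos <- sort(sample.int(n * 1000L, n))
  data.frame(chrom = chrom, pos = pos, fst = fst, fis = fis,
             ho_m = runif(n), ho_f = runif(n))
}

test_that("window count is L - k + 1 per chromosome and never spans chroms", {
  st <- rbind(fake_stats(12, "c1", seed = 1), fake_stats(5, "c2"))
  w <- sliding_windows(st, screen_config(window_k = 10))
  expect_equal(nrow(w), 3L)          # 12 - 10 + 1; c2 has < k SNPs
  expect_equal(unique(w$chrom), "c1")
  expect_equal(w$start_pos, st$pos[1:3])
  expect_equal(w$end_pos, st$pos[10:12])
  expect_equal(nrow(sliding_windows(fake_stats(9), screen_config(10))), 0L)
})

test_that("window_k below 2 is rejected", {
  expect_error(screen_config(window_k = 1), "window_k")
  expect_error(screen_config(shift = 2), "shift")
})

test_that("window means equal direct recomputation over defined values", {
  set.seed(11)
  st <- fake_stats(60)
  st$fst[sample(60, 12)] <- NA
  st$fis[sample(60, 12)] <- NA
  st <- st[order(st$pos), ]
  k <- 10
  w <- sliding_windows(st, screen_config(window_k = k))
  for (i in seq_len(nrow(w))) {
    member <- seq(w$first_idx[i], w$last_idx[i])
    expect_equal(w$mean_fst[i], mean(st$fst[member], na.rm = TRUE))
    expect_equal(w$mean_fis[i], mean(st$fis[member], na.rm = TRUE))
    expect_equal(w$n_defined[i],
                 sum(!is.na(st$fst[member]) & !is.na(st$fis[member])))
  }
  expect_equal(w$low_confidence, w$n_defined < k / 2)
  # constant-value window
  st2 <- fake_stats(10, fst = rep(0.4, 10), fis = rep(-0.7, 10))
  w2 <- sliding_windows(st2, screen_config(window_k = 10))
  expect_equal(w2$mean_fst, 0.4)
})

test_that("candidate calling enforces dual thresholds and the strict span rule", {
  cfg <- screen_config(window_k = 10)
  # one passing window spanning 2000 bp
  st <- fake_stats(10, fst = rep(0.35, 10), fis = rep(-0.6, 10),
                   pos = as.integer(seq(1000, 3000, length.out = 10)))
  r <- call_candidates(sliding_windows(st, cfg), st, cfg)
  expect_equal(nrow(r), 1L)
  expect_true(r$passes_span)
  expect_equal(r$span_bp, 2001L)

  # fst below threshold: no region no matter how negative fis is
  st$fst <- rep(0.25, 10)
  expect_equal(nrow(call_candidates(sliding_windows(st, cfg), st, cfg)), 0L)

  # span of exactly 1000 bp fails the strict > 1 kb rule but is retained
  st <- fake_stats(10, fst = rep(0.5, 10), fis = rep(-1, 10),
                   pos = as.integer(seq(1, 1000, length.out = 10)))
  r <- call_candidates(sliding_windows(st, cfg), st, cfg)
  expect_equal(r$span_bp, 1000L)
  expect_false(r$passes_span)
})

test_that("overlapping passing windows merge into one region; separated signals do not", {
  cfg <- screen_config(window_k = 5)
  n <- 60
  fst <- rep(0, n); fis <- rep(0, n)
  fst[11:25] <- 0.5; fis[11:25] <- -1    # contiguous signal
  fst[41:47] <- 0.5; fis[41:47] <- -1    # second, distant signal
  st <- fake_stats(n, fst = fst, fis = fis,
                   pos = seq(1000L, by = 500L, length.out = n))
  w <- sliding_windows(st, cfg)
  r <- call_candidates(w, st, cfg)
  expect_equal(nrow(r), 2L)
  # independent re-derivation of the merge: passing windows, chained while
  # they share SNPs
  pass <- which(w$mean_fst >= cfg$fst_min & w$mean_fis <= cfg$fis_max)
  runs <- split(pass, cumsum(c(TRUE, diff(w$first_idx[pass]) >
                                 cfg$window_k - 1L)))
  expect_equal(r$first_idx,
               unname(vapply(runs, function(p) min(w$first_idx[p]),
                             integer(1))))
  expect_equal(r$last_idx,
               unname(vapply(runs, function(p) max(w$last_idx[p]),
                             integer(1))))
  # each region contains the full diagnostic signal it was called from
  expect_lte(r$first_idx[1], 11L); expect_gte(r$last_idx[1], 25L)
  expect_lte(r$first_idx[2], 41L); expect_gte(r$last_idx[2], 47L)
  # region means equal direct recomputation over member SNPs
  expect_equal(r$mean_fst, vapply(seq_len(2), function(i) {
    mean(st$fst[r$first_idx[i]:r$last_idx[i]])
  }, numeric(1)))
  expect_equal(r$mean_fis, vapply(seq_len(2), function(i) {
    mean(st$fis[r$first_idx[i]:r$last_idx[i]])
  }, numeric(1)))
})

test_that("raising fst_min or lowering fis_max never adds regions", {
  set.seed(12)
  st <- fake_stats(300)
  st$fst <- st$fst + rep(c(0, 0.4), c(200, 100))
  st$fis <- st$fis - rep(c(0, 0.6), c(200, 100))
  st <- st[order(st$pos), ]
  base <- call_candidates(sliding_windows(st, screen_config()), st,
                          screen_config())
  for (cfg2 in list(screen_config(fst_min = 0.45),
                    screen_config(fis_max = -0.8))) {
    r2 <- call_candidates(sliding_windows(st, cfg2), st, cfg2)
    expect_lte(nrow(r2), nrow(base))
    for (i in seq_len(nrow(r2))) {
      expect_true(any(r2$start_pos[i] >= base$start_pos &
                        r2$start_pos[i] <= base$end_pos))
    }
  }
})

test_that("screen output is invariant to input row order", {
  set.seed(13)
  st <- rbind(fake_stats(40, "c2"), fake_stats(40, "c1"))
  st$fst[10:25] <- 0.5; st$fis[10:25] <- -0.9
  shuffled <- st[sample(nrow(st)), ]
  cfg <- screen_config()
  expect_equal(sliding_windows(shuffled, cfg), sliding_windows(st, cfg))
  expect_equal(call_candidates(sliding_windows(shuffled, cfg), shuffled, cfg),
               call_candidates(sliding_windows(st, cfg), st, cfg))
})

test_that("classification follows per-sex heterozygosity with margin delta", {
  cfg <- screen_config()
  region <- data.frame(first_idx = 1L, last_idx = 5L)
  st <- data.frame(ho_m = rep(1, 5), ho_f = rep(0, 5))
  expect_equal(classify_system(region, st, cfg), "XY")
  expect_equal(classify_system(region, data.frame(ho_m = 0, ho_f = 1)[rep(1, 5), ], cfg),
               "ZW")
  expect_equal(classify_system(region, data.frame(ho_m = 0.5, ho_f = 0.5)[rep(1, 5), ], cfg),
               "ambiguous")
  # difference exactly at delta is not enough
  st3 <- data.frame(ho_m = rep(0.6, 5), ho_f = rep(0.4, 5))
  expect_equal(classify_system(region, st3, cfg), "ambiguous")
})
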