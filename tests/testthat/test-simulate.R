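test_that("fully linked sites show the diagnostic XX/XY pattern at zero error", {
  cfg <- sim_config(error_rate = 0, missing_rate = 0, seed = 51)
  sim <- simulate_population(cfg)
  G <- sim$genotypes
  sx <- unclass(sim$sexes)[G$sample_ids]
  core <- sim$truth$fully_linked_idx
  expect_length(core, 50)
  g_core <- G$genotypes[, core, drop = FALSE]
  expect_true(all(g_core[sx == "male", ] == 1L))
  expect_true(all(g_core[sx == "female", ] == 0L))
  # pooled alt (Y) allele frequency is exactly n_m / (2 (n_m + n_f)) = 0.25
  expect_equal(unname(colMeans(g_core) / 2), rep(0.25, 50))
  # and the screen statistics hit the theoretical expectations exactly
  st <- wc_fst_fis(subset_loci(G, core), sim$sexes)
  expect_equal(st$fst, rep(0.5, 50), tolerance = 1e-12)
  expect_equal(st$fis, rep(-1, 50), tolerance = 1e-12)
  # core SNPs sit inside the declared block
  expect_true(all(G$loci$pos[core] >= sim$truth$block_start &
                    G$loci$pos[core] <= sim$truth$block_end))
})

test_that("ZW system mirrors the pattern onto females", {
  sim <- simulate_population(sim_config(system = "ZW", error_rate = 0,
                                        missing_rate = 0, seed = 52))
  sx <- unclass(sim$sexes)[sim$genotypes$sample_ids]
  g_core <- sim$genotypes$genotypes[, sim$truth$fully_linked_idx]
  expect_true(all(g_core[sx == "female", ] == 1L))
  expect_true(all(g_core[sx == "male", ] == 0L))
})

test_that("simulation is deterministic under seed, byte-for-byte after export", {
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_population(sim_config(seed = 53))$genotypes, p1)
  write_vcf(simulate_population(sim_config(seed = 53))$genotypes, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and different seeds differ
  p3 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_population(sim_config(seed = 54))$genotypes, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("simulated VCF round-trips through read_vcf", {
  sim <- simulate_population(sim_config(chrom_length_bp = 2e5,
                                        sd_block = c(5e4, 1.5e5),
                                        n_fully_linked = 30, seed = 55))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  G2 <- read_vcf(path, min_qual = 20)
  attr(G2, "load_report") <- NULL
  expect_equal(G2, sim$genotypes)
})

test_that("background between-sex FST is centred at zero", {
  sim <- simulate_population(sim_config(n_fully_linked = 0,
                                        partial_linkage = 0,
                                        chrom_length_bp = 6e6,
                                        error_rate = 0, missing_rate = 0,
                                        seed = 56))
  st <- wc_fst_fis(sim$genotypes, sim$sexes)
  expect_gte(nrow(st), 10000)
  # the among-sex variance component is the unbiased measure of "no
  # differentiation": its mean sits within Monte-Carlo error of zero
  a <- st$a[!is.na(st$a)]
  expect_lt(abs(mean(a)), 3 * sd(a) / sqrt(length(a)))
  # the ratio estimator carries a small positive finite-sample bias at
  # n = 5 + 5; it stays well inside the screen's working tolerance
  fst <- st$fst[!is.na(st$fst)]
  expect_lt(abs(mean(fst)), 0.01)
})

test_that("genotyping error shrinks the heterozygote-excess signal", {
  mean_fis <- vapply(c(0, 0.1), function(err) {
    sim <- simulate_population(sim_config(n_males = 20, n_females = 20,
                                          chrom_length_bp = 2e6,
                                          sd_block = c(5e5, 15e5),
                                          n_fully_linked = 200,
                                          error_rate = err,
                                          missing_rate = 0, seed = 57))
    st <- wc_fst_fis(subset_loci(sim$genotypes,
                                 sim$truth$fully_linked_idx), sim$sexes)
    mean(st$fis, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean_fis[1] + 1), 1e-12)   # -1 exactly at zero error
  expect_gt(mean_fis[2], mean_fis[1])      # |fis| shrinks with error
})

test_that("configs that cannot host the block are rejected", {
  expect_error(simulate_population(
    sim_config(sd_block = c(1, 2000), n_fully_linked = 50, seed = 58)),
    "n_fully_linked")
  expect_error(sim_config(sd_block = c(5e6, 4e6)), "sd_block")
  expect_error(sim_config(error_rate = 1.5), "rates")
  expect_error(sim_config(system = "XO"))
})
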