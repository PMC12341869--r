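# Small in-code fixtures shared across test files.

# Build a genotype_matrix from a samples x loci code matrix.
make_gm <- function(g, pos = NULL, chrom = "c1", qual = 60,
                    ids = NULL) {
  g <- as.matrix(g)
  n <- nrow(g); L <- ncol(g)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  ref <- rep_len(c("A", "C"), L)
  alt <- rep_len(c("G", "T"), L)
  genotype_matrix(g, data.frame(chrom = rep_len(chrom, L),
                                pos = as.integer(pos),
                                ref = ref, alt = alt,
                                qual = rep_len(qual, L)),
                  ids)
}

# Balanced male/female sex map for the first n_m / last n_f samples of G.
make_sexes <- function(G, n_m = n_samples(G) %/% 2) {
  n <- n_samples(G)
  sex_map(rep(c("male", "female"), c(n_m, n - n_m)), G$sample_ids)
}

# The fully sex-linked configuration: all males het, all females hom-ref.
sd_locus_gm <- function(n_m = 5, n_f = 5) {
  g <- matrix(c(rep(1L, n_m), rep(0L, n_f)), ncol = 1)
  make_gm(g, pos = 1000L,
          ids = c(sprintf("m%02d", seq_len(n_m)),
                  sprintf("f%02d", seq_len(n_f))))
}

# Random genotype configuration for oracle comparisons; returns list with
# male/female genotype vectors including missing values.
random_config <- function(n_range = 2:20, miss = 0.1) {
  n_m <- sample(n_range, 1)
  n_f <- sample(n_range, 1)
  q <- runif(1, 0.05, 0.95)
  gm <- rbinom(n_m, 2, q)
  gf <- rbinom(n_f, 2, runif(1, 0.05, 0.95))
  gm[runif(n_m) < miss] <- NA
  gf[runif(n_f) < miss] <- NA
  list(g_m = as.integer(gm), g_f = as.integer(gf))
}

# Run wc_fst_fis on a single-locus configuration given as two vectors.
wc_one <- function(g_m, g_f) {
  g <- matrix(c(g_m, g_f), ncol = 1)
  G <- make_gm(g, pos = 500L,
               ids = c(sprintf("m%02d", seq_along(g_m)),
                       sprintf("f%02d", seq_along(g_f))))
  sx <- sex_map(rep(c("male", "female"), c(length(g_m), length(g_f))),
                G$sample_ids)
  wc_fst_fis(G, sx)
}

# Minimal VCF text writer for io tests (header + given body lines).
write_test_vcf <- function(body, samples = c("s1", "s2"), path = NULL) {
  if (is.null(path)) path <- withr::local_tempfile(fileext = ".vcf",
                                                   .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, qual, gts) {
  paste(c(chrom, pos, ".", ref, alt, qual, ".", ".", "GT", gts),
        collapse = "\t")
}
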