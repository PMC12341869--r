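#' Run the whole SD-region screen
#'
#' Executes the pipeline end to end: VCF loading with the QUAL filter,
#' pooled-MAF filtering, per-locus Weir-Cockerham FST/FIS between sexes,
#' sliding-window averaging, dual-threshold candidate calling with XY/ZW
#' classification, and pairwise LD over the top candidate region. Writes
#' `locus_stats.tsv`, `windows.tsv`, `regions.tsv`, `ld_top_region.tsv`
#' and a JSON `manifest.json` recording parameters, the seed and SNP counts
#' after each filter stage. Reports are byte-identical across runs with the
#' same inputs and seed.
#'
#' @param vcf path to a VCF, or a [genotype_matrix()].
#' @param sexes path to a sex-map TSV, or a [sex_map()].
#' @param outdir output directory, created if needed.
#' @param qual_min minimum variant QUAL (default 20; ignored when `vcf` is
#'   already a `genotype_matrix`).
#' @param maf_min minimum pooled minor-allele frequency (default 0.2).
#' @param cfg a [screen_config()].
#' @param ld run LD over the top `passes_span` region (default `TRUE`).
#' @param ld_max_loci,ld_iterations,ld_sig_level LD settings passed to
#'   [ld_matrix()] (defaults 25, 10000, 0.01).
#' @param seed integer seed for the LD Monte-Carlo tests (default 1).
#' @param quiet suppress progress messages (default `FALSE`).
#' @return Invisibly, a list: `stats`, `windows`, `regions`, `ld`
#'   (`NULL` if not run), `manifest`.
#' @export
run_screen <- function(vcf, sexes, outdir, qual_min = 20, maf_min = 0.2,
                       cfg = screen_config(), ld = TRUE, ld_max_loci = 25,
                       ld_iterations = 10000, ld_sig_level = 0.01,
                       seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t_read <- function() {
    if (inherits(vcf, "genotype_matrix")) vcf else read_vcf(vcf, qual_min)
  }
  G <- with_stage("read_vcf", t_read)
  rep0 <- attr(G, "load_report")
  n_input <- if (is.null(rep0)) n_loci(G) else rep0$n_records
  say("read_vcf: %d SNPs retained (of %d records)", n_loci(G), n_input)

  sexes <- with_stage("read_sex_map", function() {
    if (inherits(sexes, "sex_map")) sexes else read_sex_map(sexes)
  })
  n_qual <- n_loci(G)
  G <- with_stage("maf_filter", function() maf_filter(G, maf_min))
  say("maf_filter (MAF >= %g): %d SNPs", maf_min, n_loci(G))

  stats <- with_stage("wc_fst_fis", function() wc_fst_fis(G, sexes))
  windows <- with_stage("sliding_windows", function() {
    sliding_windows(stats, cfg)
  })
  say("sliding_windows (k = %d): %d windows on %d chromosome(s)",
      cfg$window_k, nrow(windows), length(unique(stats$chrom)))
  regions <- with_stage("call_candidates", function() {
    call_candidates(windows, stats, cfg)
  })
  say("call_candidates: %d region(s), %d passing the span rule",
      nrow(regions), sum(regions$passes_span))

  ld_res <- NULL
  top <- NULL
  if (ld && any(regions$passes_span)) {
    pass <- regions[regions$passes_span, , drop = FALSE]
    top <- pass[which.max(pass$mean_fst), , drop = FALSE]
    ld_res <- with_stage("ld_matrix", function() {
      idx <- seq.int(top$first_idx, top$last_idx)
      stats_key <- paste(stats$chrom, stats$pos)
      g_key <- paste(G$loci$chrom, G$loci$pos)
      ld_matrix(G, match(stats_key[idx], g_key),
                sig_level = ld_sig_level, iterations = ld_iterations,
                seed = seed, max_loci = ld_max_loci)
    })
    say("ld_matrix: %d pairs in top region %s:%d-%d", nrow(ld_res),
        top$chrom, top$start_pos, top$end_pos)
  }

  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_tsv(stats, file.path(outdir, "locus_stats.tsv"))
  write_screen_report(windows, regions, outdir)
  if (!is.null(ld_res)) {
    write_tsv(ld_res, file.path(outdir, "ld_top_region.tsv"))
  }
  manifest <- list(
    parameters = list(
      qual_min = qual_min, maf_min = maf_min, window_k = cfg$window_k,
      shift = cfg$shift, fst_min = cfg$fst_min, fis_max = cfg$fis_max,
      min_span_bp = cfg$min_span_bp, classify_delta = cfg$classify_delta,
      ld = ld, ld_max_loci = ld_max_loci, ld_iterations = ld_iterations,
      ld_sig_level = ld_sig_level
    ),
    seed = seed,
    samples = list(n_total = n_samples(G),
                   n_male = sum(unclass(sexes) == "male"),
                   n_female = sum(unclass(sexes) == "female")),
    counts = list(
      n_records = n_input,
      n_after_qual = n_qual,
      n_after_maf = n_loci(G),
      n_windows = nrow(windows),
      n_regions = nrow(regions),
      n_passes_span = sum(regions$passes_span)
    ),
    top_region = if (is.null(top)) NULL else
      list(chrom = top$chrom, start_pos = top$start_pos,
           end_pos = top$end_pos, span_bp = top$span_bp,
           mean_fst = top$mean_fst, mean_fis = top$mean_fis,
           classification = top$classification,
           max_sig_ld_dist_bp = if (is.null(ld_res)) NULL else
             attr(ld_res, "max_sig_dist_bp"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(stats = stats, windows = windows, regions = regions,
                 ld = ld_res, manifest = manifest))
}

with_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}
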