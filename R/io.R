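#' Read biallelic SNP genotypes from a VCF file
#'
#' Loads a VCF (4.x, GT field required) and keeps biallelic SNP records with
#' `QUAL >= min_qual`. Multiallelic records and indels are dropped and counted
#' in the load report (`attr(x, "load_report")`). Records with a missing QUAL
#' are treated as QUAL 0. Half-called genotypes (e.g. `0/.`) become `NA`;
#' phase separators (`|` vs `/`) are ignored. A QUAL exactly at `min_qual` is
#' retained: only scores strictly below the threshold are removed.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param min_qual minimum variant QUAL to retain (default 20).
#' @return A [genotype_matrix()] with loci sorted by (chrom, pos), plus a
#'   `load_report` attribute listing record counts at each filter.
#' @export
read_vcf <- function(path, min_qual = 20) {
  if (!is.numeric(min_qual) || length(min_qual) != 1L || min_qual < 0) {
    stop("min_qual must be a single non-negative number")
  }
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path)
  if (ncol(gt) == 0L) stop("VCF contains no samples: ", path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  qual <- VariantAnnotation::qual(vcf)
  qual[is.na(qual)] <- 0

  n_records <- length(pos)
  multi <- n_alt != 1L
  alt <- rep(NA_character_, n_records)
  alt[!multi] <- as.character(unlist(alt_list[!multi]))
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | alt == "*" |
                       !ref %in% c("A", "C", "G", "T"))
  low_qual <- !multi & !indel & qual < min_qual
  keep <- !multi & !indel & !low_qual

  idx <- which(keep)
  loci <- data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
                     alt = alt[idx], qual = qual[idx],
                     stringsAsFactors = FALSE)
  dup <- duplicated(loci[c("chrom", "pos")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicated record at %s:%d in %s",
                 loci$chrom[i], loci$pos[i], path))
  }
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  g <- t(vapply(seq_along(idx), function(j) gt_to_code(gt[idx[j], ]),
                integer(ncol(gt))))
  if (length(idx) == 0L) g <- matrix(integer(0), nrow = ncol(gt), ncol = 0L)
  else g <- t(g[ord, , drop = FALSE])

  out <- genotype_matrix(g, loci, colnames(gt))
  attr(out, "load_report") <- list(
    n_records = n_records,
    n_multiallelic = sum(multi),
    n_indel = sum(indel),
    n_low_qual = sum(low_qual),
    n_retained = length(idx)
  )
  out
}

# "0/1", "1|1", "./.", "0/." -> 1L, 2L, NA, NA. Vectorised over samples.
gt_to_code <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  a <- strsplit(gt, "/", fixed = TRUE)
  vapply(a, function(al) {
    if (length(al) != 2L || any(al == ".") || anyNA(al)) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al)) return(NA_integer_)
    sum(al != 0L)
  }, integer(1))
}

#' Read a sample-to-sex map from TSV
#'
#' Expects two tab-separated columns, sample id and sex, with or without a
#' `sample_id<TAB>sex` header line. Sex labels `M`, `F`, `male`, `female`
#' are accepted case-insensitively.
#'
#' @param path path to the TSV file.
#' @return A [sex_map()].
#' @export
read_sex_map <- function(path) {
  if (!file.exists(path)) stop("cannot read sex map: no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("sample_id", "sex"),
                           colClasses = "character")
  if (nrow(tab) && identical(tolower(tab$sample_id[1L]), "sample_id")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (!nrow(tab)) stop("sex map is empty: ", path)
  sex_map(tab$sex, tab$sample_id)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 with a GT field per sample. Missing genotypes are
#' written as `./.`. Reading the file back with [read_vcf()] (at a
#' `min_qual` no higher than the stored QUALs) reproduces the object.
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  validate_genotype_matrix(G)
  codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")
  )
  if (n_loci(G)) {
    gt <- matrix(codes[G$genotypes + 1L], nrow = n_samples(G))
    gt[is.na(gt)] <- "./."
    gt_cols <- apply(gt, 2L, paste, collapse = "\t")
    body <- paste(G$loci$chrom, G$loci$pos, ".", G$loci$ref, G$loci$alt,
                  format(G$loci$qual, trim = TRUE, digits = 15,
                         scientific = FALSE),
                  ".", ".", "GT", gt_cols, sep = "\t")
  } else {
    body <- character(0)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write window and candidate-region reports
#'
#' Writes `windows.tsv` (one row per sliding window) and `regions.tsv`
#' (one row per merged candidate region) into `dir`. Columns and number
#' formatting are stable across runs on identical input.
#'
#' @param windows data.frame from [sliding_windows()] (may have zero rows).
#' @param regions data.frame from [call_candidates()] (may have zero rows).
#' @param dir output directory, created if needed.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_screen_report <- function(windows, regions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wpath <- file.path(dir, "windows.tsv")
  rpath <- file.path(dir, "regions.tsv")
  wcols <- c("chrom", "start_pos", "end_pos", "n_snps", "n_defined",
             "mean_fst", "mean_fis", "low_confidence")
  rcols <- c("chrom", "start_pos", "end_pos", "span_bp", "n_snps",
             "mean_fst", "mean_fis", "classification", "passes_span")
  write_tsv(windows[intersect(wcols, names(windows))], wpath, wcols)
  write_tsv(regions[intersect(rcols, names(regions))], rpath, rcols)
  invisible(c(windows = wpath, regions = rpath))
}

# Header-stable TSV writer used by all reports.
write_tsv <- function(df, path, columns = names(df)) {
  df <- as.data.frame(df)
  for (cl in setdiff(columns, names(df))) df[[cl]] <- logical(0)
  df <- df[columns]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-sample per-gene read-depth table
#'
#' Expects a TSV with header columns `sample_id`, `sex`, `gene_id`,
#' `read_count`, `library_size` (the depth substrate for
#' [depth_ratio_test()]).
#'
#' @param path path to the TSV file.
#' @return A data.frame with normalized sex labels.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) stop("cannot read depth table: no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("sample_id", "sex", "gene_id", "read_count", "library_size")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("depth table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab$sex <- unclass(sex_map(tab$sex, seq_along(tab$sex)))
  if (any(tab$read_count < 0)) stop("read_count must be non-negative")
  if (any(tab$library_size <= 0)) stop("library_size must be positive")
  if (any(tab$read_count > tab$library_size)) {
    stop("read_count exceeds library_size")
  }
  tab
}

#' Read a simple panel genotype TSV
#'
#' Accepts the long format typical of array/MassARRAY exports: columns
#' `sample_id`, `snp_id` (formatted `chrom_pos`), `genotype` (0/1/2 or
#' two-letter like `AG`; empty or `NA` = missing). Returns a
#' [genotype_matrix()] with QUAL fixed at 99.
#'
#' @param path path to the TSV file.
#' @return A [genotype_matrix()].
#' @export
read_panel_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read panel TSV: no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("sample_id", "snp_id", "genotype")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("panel TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parts <- regmatches(tab$snp_id, regexpr("_[0-9]+$", tab$snp_id))
  chrom <- sub("_[0-9]+$", "", tab$snp_id)
  pos <- as.integer(sub("^_", "", parts))
  if (anyNA(pos)) stop("snp_id must look like <chrom>_<pos>")
  code <- suppressWarnings(as.integer(tab$genotype))
  two <- !is.na(tab$genotype) & grepl("^[ACGT]{2}$", tab$genotype)
  samples <- unique(tab$sample_id)
  key <- paste(chrom, pos, sep = "_")
  snp_keys <- unique(key[order(chrom, pos)])
  g <- matrix(NA_integer_, nrow = length(samples), ncol = length(snp_keys),
              dimnames = list(samples, snp_keys))
  ref <- alt <- stats::setNames(rep(NA_character_, length(snp_keys)), snp_keys)
  for (i in seq_len(nrow(tab))) {
    k <- key[i]
    if (two[i]) {
      al <- strsplit(tab$genotype[i], "")[[1L]]
      for (a in al) {
        if (is.na(ref[k])) ref[k] <- a
        else if (a != ref[k] && is.na(alt[k])) alt[k] <- a
      }
      g[tab$sample_id[i], k] <-
        if (al[1L] != al[2L]) 1L else if (al[1L] == ref[k]) 0L else 2L
    } else if (!is.na(code[i]) && code[i] %in% 0:2) {
      g[tab$sample_id[i], k] <- code[i]
    }
  }
  ref[is.na(ref)] <- "A"
  fill <- is.na(alt) | alt == ref
  alt[fill] <- ifelse(ref[fill] == "C", "T", "C")
  loci <- data.frame(chrom = sub("_[0-9]+$", "", snp_keys),
                     pos = as.integer(sub("^.*_", "", snp_keys)),
                     ref = unname(ref), alt = unname(alt), qual = 99,
                     stringsAsFactors = FALSE)
  ord <- order(loci$chrom, loci$pos)
  genotype_matrix(g[, ord, drop = FALSE], loci[ord, , drop = FALSE], samples)
}
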