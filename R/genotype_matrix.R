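#' Genotype matrix container
#'
#' Bundles a samples x loci matrix of diploid genotype codes with locus
#' coordinates. Codes are 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) and `NA` (missing, including half-calls).
#' Loci are biallelic SNPs sorted by (chromosome, position) with strictly
#' increasing positions within a chromosome.
#'
#' @param genotypes integer matrix, samples in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom` (character), `pos`
#'   (integer, 1-based), `ref`, `alt` (single-character alleles) and
#'   `qual` (numeric).
#' @param sample_ids character vector of unique sample names, one per row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `loci`, `sample_ids`.
#' @examples
#' g <- rbind(s1 = c(0L, 1L), s2 = c(1L, NA))
#' loci <- data.frame(chrom = "c1", pos = c(10L, 20L),
#'                    ref = "A", alt = c("G", "T"), qual = 60)
#' gm <- genotype_matrix(g, loci, c("s1", "s2"))
#' n_loci(gm)
#' @export
genotype_matrix <- function(genotypes, loci, sample_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(sample_ids)) {
    stop("sample_ids are required (rownames of `genotypes` or explicit)")
  }
  sample_ids <- as.character(sample_ids)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols)) {
    stop("loci is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$qual <- as.numeric(loci$qual)
  rownames(genotypes) <- sample_ids
  rownames(loci) <- NULL
  obj <- structure(
    list(genotypes = genotypes, loci = loci, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(x) {
  g <- x$genotypes
  if (nrow(g) != length(x$sample_ids)) {
    stop("genotype matrix has ", nrow(g), " rows but ",
         length(x$sample_ids), " sample ids")
  }
  if (ncol(g) != nrow(x$loci)) {
    stop("genotype matrix has ", ncol(g), " columns but ",
         nrow(x$loci), " loci")
  }
  if (anyDuplicated(x$sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(x$sample_ids[duplicated(x$sample_ids)]), collapse = ", "))
  }
  bad <- !(g %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(x$loci)) {
    if (any(x$loci$pos < 1L, na.rm = TRUE)) stop("locus positions must be >= 1")
    if (any(x$loci$ref == x$loci$alt)) stop("ref and alt alleles must differ")
    ord <- order(x$loci$chrom, x$loci$pos)
    if (!identical(ord, seq_len(nrow(x$loci)))) {
      stop("loci must be sorted by (chrom, pos)")
    }
    same <- duplicated(x$loci[c("chrom", "pos")])
    if (any(same)) {
      i <- which(same)[1L]
      stop(sprintf("duplicated locus %s:%d", x$loci$chrom[i], x$loci$pos[i]))
    }
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_loci <- function(x) nrow(x$loci)

#' @rdname genotype_matrix
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Subset a genotype matrix by locus
#'
#' @param x a `genotype_matrix`.
#' @param idx integer or logical index into the loci.
#' @return A `genotype_matrix` with the selected loci, original order kept.
#' @export
subset_loci <- function(x, idx) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- sort(unique(as.integer(idx)))
  genotype_matrix(x$genotypes[, idx, drop = FALSE],
                  x$loci[idx, , drop = FALSE],
                  x$sample_ids)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic SNPs\n",
              n_samples(x), n_loci(x)))
  if (n_loci(x)) {
    cat("chromosomes:", paste(unique(x$loci$chrom), collapse = ", "), "\n")
  }
  rep <- attr(x, "load_report")
  if (!is.null(rep)) {
    cat(sprintf("load report: %d records; dropped %d multiallelic, %d indel, %d low-qual\n",
                rep$n_records, rep$n_multiallelic, rep$n_indel, rep$n_low_qual))
  }
  invisible(x)
}

#' Sample-to-sex map
#'
#' A named character vector mapping sample ids to `"male"` / `"female"`.
#' Input labels `M`, `F`, `male`, `female` are accepted case-insensitively.
#'
#' @param sexes character vector of sex labels.
#' @param sample_ids sample names, one per label.
#' @return A named character vector of class `sex_map` with values
#'   `"male"` or `"female"`.
#' @examples
#' sex_map(c("M", "f"), c("s1", "s2"))
#' @export
sex_map <- function(sexes, sample_ids = names(sexes)) {
  if (is.null(sample_ids)) stop("sample ids are required")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id in sex map: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  key <- tolower(trimws(as.character(sexes)))
  out <- c(m = "male", male = "male", f = "female", female = "female")[key]
  if (anyNA(out)) {
    stop("unknown sex label(s): ",
         paste(unique(sexes[is.na(out)]), collapse = ", "),
         " (expected M/F/male/female)")
  }
  structure(stats::setNames(unname(out), sample_ids), class = "sex_map")
}

#' @export
print.sex_map <- function(x, ...) {
  cat(sprintf("sex_map: %d samples (%d male, %d female)\n",
              length(x), sum(x == "male"), sum(x == "female")))
  invisible(x)
}

# Sexes aligned to the samples of G, erroring on any sample without a sex.
sexes_for <- function(G, sexes) {
  s <- unclass(sexes)[G$sample_ids]
  if (anyNA(s)) {
    stop("sample(s) missing from sex map: ",
         paste(G$sample_ids[is.na(s)], collapse = ", "))
  }
  unname(s)
}
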