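#' Screen configuration
#'
#' Parameters for the sliding-window candidate screen. Defaults reflect a
#' 10-SNP window shifted one SNP at a time, dual thresholds
#' `mean FST >= 0.3` and `mean FIS <= -0.5` (relaxed from the fully
#' sex-linked expectations 0.5 / -1 because not every SNP in a window is
#' expected to be diagnostic), and a strict `> 1 kb` physical span rule for
#' a region to count as a confident candidate.
#'
#' @param window_k window size in SNPs (>= 2; default 10).
#' @param shift window shift in SNPs; only 1 is supported.
#' @param fst_min minimum window mean FST, in (0, 1) (default 0.3).
#' @param fis_max maximum window mean FIS, negative (default -0.5).
#' @param min_span_bp a merged region must span strictly more than this many
#'   bp (first to last SNP, inclusive) to pass the span rule (default 1000).
#' @param classify_delta margin on the per-sex heterozygosity difference for
#'   XY/ZW classification (default 0.2).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window_k = 10, shift = 1, fst_min = 0.3,
                          fis_max = -0.5, min_span_bp = 1000,
                          classify_delta = 0.2) {
  window_k <- as.integer(window_k)
  if (is.na(window_k) || window_k < 2L) {
    stop("window_k must be an integer >= 2")
  }
  if (!identical(as.integer(shift), 1L)) {
    stop("only shift = 1 (one SNP between consecutive windows) is supported")
  }
  if (!is.numeric(fst_min) || fst_min <= 0 || fst_min >= 1) {
    stop("fst_min must lie in (0, 1)")
  }
  if (!is.numeric(fis_max) || fis_max >= 0) stop("fis_max must be negative")
  if (!is.numeric(min_span_bp) || min_span_bp < 0) {
    stop("min_span_bp must be >= 0")
  }
  if (!is.numeric(classify_delta) || classify_delta < 0 ||
      classify_delta > 1) {
    stop("classify_delta must lie in [0, 1]")
  }
  structure(list(window_k = window_k, shift = 1L, fst_min = fst_min,
                 fis_max = fis_max, min_span_bp = min_span_bp,
                 classify_delta = classify_delta),
            class = "screen_config")
}

#' Sliding-window means of per-SNP FST and FIS
#'
#' Slides a `window_k`-SNP window one SNP at a time along each chromosome
#' (windows never span chromosomes) and averages the defined per-SNP values;
#' `NA` statistics are excluded from the means, and `n_defined` counts the
#' SNPs with both statistics defined. Windows with fewer than half their
#' SNPs defined are flagged `low_confidence`.
#'
#' @param stats per-locus statistics from [wc_fst_fis()] (any data.frame
#'   with `chrom`, `pos`, `fst`, `fis`), position-sorted within chromosome.
#' @param cfg a [screen_config()].
#' @return A data.frame with one row per window: `chrom`, `start_pos`,
#'   `end_pos` (positions of the first and last SNP), `first_idx`,
#'   `last_idx` (row indices into `stats`), `n_snps`, `n_defined`,
#'   `mean_fst`, `mean_fis`, `low_confidence`. A chromosome with fewer than
#'   `window_k` usable SNPs contributes no windows.
#' @export
sliding_windows <- function(stats, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  stats <- sort_stats(stats)
  k <- cfg$window_k
  pieces <- lapply(split(seq_len(nrow(stats)), stats$chrom), function(rows) {
    L <- length(rows)
    if (L < k) return(NULL)
    n_win <- L - k + 1L
    i <- seq_len(n_win)
    fst <- stats$fst[rows]
    fis <- stats$fis[rows]
    sum_fst <- c(0, cumsum(ifelse(is.na(fst), 0, fst)))
    cnt_fst <- c(0L, cumsum(!is.na(fst)))
    sum_fis <- c(0, cumsum(ifelse(is.na(fis), 0, fis)))
    cnt_fis <- c(0L, cumsum(!is.na(fis)))
    cnt_both <- c(0L, cumsum(!is.na(fst) & !is.na(fis)))
    nf <- cnt_fst[i + k] - cnt_fst[i]
    ni <- cnt_fis[i + k] - cnt_fis[i]
    nb <- cnt_both[i + k] - cnt_both[i]
    data.frame(
      chrom = stats$chrom[rows[1L]],
      start_pos = stats$pos[rows[i]],
      end_pos = stats$pos[rows[i + k - 1L]],
      first_idx = rows[i],
      last_idx = rows[i + k - 1L],
      n_snps = k,
      n_defined = nb,
      mean_fst = ifelse(nf > 0, (sum_fst[i + k] - sum_fst[i]) / nf, NA_real_),
      mean_fis = ifelse(ni > 0, (sum_fis[i + k] - sum_fis[i]) / ni, NA_real_),
      low_confidence = nb < k / 2,
      stringsAsFactors = FALSE
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    return(data.frame(chrom = character(0), start_pos = integer(0),
                      end_pos = integer(0), first_idx = integer(0),
                      last_idx = integer(0), n_snps = integer(0),
                      n_defined = integer(0), mean_fst = numeric(0),
                      mean_fis = numeric(0), low_confidence = logical(0)))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

sort_stats <- function(stats) {
  needed <- c("chrom", "pos", "fst", "fis")
  missing_cols <- setdiff(needed, names(stats))
  if (length(missing_cols)) {
    stop("stats is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  rownames(stats) <- NULL
  stats
}

#' Call candidate SD regions from threshold-passing windows
#'
#' Windows with `mean_fst >= fst_min` and `mean_fis <= fis_max` are merged
#' whenever they share SNPs (with a 1-SNP shift, a contiguous signal
#' otherwise emits a near-duplicate region per window). Region means are
#' recomputed over the union of member SNPs. Regions spanning strictly more
#' than `min_span_bp` get `passes_span = TRUE`; shorter regions are retained
#' with `passes_span = FALSE` so they can still be inspected.
#'
#' @param windows output of [sliding_windows()].
#' @param stats the per-locus statistics the windows were built from
#'   ([wc_fst_fis()] output), used for region means and classification.
#' @param cfg a [screen_config()].
#' @return A data.frame with one row per region: `chrom`, `start_pos`,
#'   `end_pos`, `span_bp` (`end - start + 1`), `first_idx`, `last_idx`,
#'   `n_snps`, `n_windows`, `mean_fst`, `mean_fis`, `classification`
#'   (`"XY"`, `"ZW"` or `"ambiguous"`; `"unclassified"` when `stats` lacks
#'   per-sex heterozygosity), `passes_span`.
#' @export
call_candidates <- function(windows, stats, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  stats <- sort_stats(stats)
  empty <- data.frame(chrom = character(0), start_pos = integer(0),
                      end_pos = integer(0), span_bp = integer(0),
                      first_idx = integer(0), last_idx = integer(0),
                      n_snps = integer(0), n_windows = integer(0),
                      mean_fst = numeric(0), mean_fis = numeric(0),
                      classification = character(0), passes_span = logical(0))
  if (!nrow(windows)) return(empty)
  pass <- !is.na(windows$mean_fst) & !is.na(windows$mean_fis) &
    windows$mean_fst >= cfg$fst_min & windows$mean_fis <= cfg$fis_max
  w <- windows[pass, , drop = FALSE]
  if (!nrow(w)) return(empty)
  w <- w[order(w$chrom, w$first_idx), , drop = FALSE]
  # merge windows sharing at least one SNP (same chromosome, index overlap)
  new_run <- c(TRUE, w$chrom[-1L] != w$chrom[-nrow(w)] |
                 w$first_idx[-1L] > cummax_by_run(w)[-nrow(w)])
  grp <- cumsum(new_run)
  pieces <- lapply(split(seq_len(nrow(w)), grp), function(rows) {
    first <- min(w$first_idx[rows])
    last <- max(w$last_idx[rows])
    member <- seq.int(first, last)
    fst <- stats$fst[member]
    fis <- stats$fis[member]
    data.frame(
      chrom = w$chrom[rows[1L]],
      start_pos = stats$pos[first],
      end_pos = stats$pos[last],
      span_bp = stats$pos[last] - stats$pos[first] + 1L,
      first_idx = first, last_idx = last,
      n_snps = length(member), n_windows = length(rows),
      mean_fst = mean(fst, na.rm = TRUE),
      mean_fis = mean(fis, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$classification <- vapply(seq_len(nrow(out)), function(i) {
    classify_system(out[i, , drop = FALSE], stats, cfg)
  }, character(1))
  out$passes_span <- out$span_bp > cfg$min_span_bp
  out[order(out$chrom, out$start_pos), , drop = FALSE]
}

# running max of last_idx within the current merge scan
cummax_by_run <- function(w) {
  out <- w$last_idx
  for (i in seq_len(nrow(w))[-1L]) {
    if (w$chrom[i] == w$chrom[i - 1L]) out[i] <- max(out[i], out[i - 1L])
  }
  out
}

#' Classify a candidate region as XY, ZW or ambiguous
#'
#' Uses mean observed heterozygosity of the region's member SNPs per sex:
#' a male excess greater than `classify_delta` calls `"XY"` (males
#' heterogametic), the mirrored female excess calls `"ZW"`; anything closer
#' is `"ambiguous"`.
#'
#' @param region one row of the [call_candidates()] output (needs
#'   `first_idx` / `last_idx`).
#' @param stats per-locus statistics carrying `ho_m` and `ho_f`.
#' @param cfg a [screen_config()] (supplies `classify_delta`).
#' @return `"XY"`, `"ZW"`, `"ambiguous"`, or `"unclassified"` when per-sex
#'   heterozygosity is unavailable.
#' @export
classify_system <- function(region, stats, cfg = screen_config()) {
  if (!all(c("ho_m", "ho_f") %in% names(stats))) return("unclassified")
  member <- seq.int(region$first_idx, region$last_idx)
  hm <- mean(stats$ho_m[member], na.rm = TRUE)
  hf <- mean(stats$ho_f[member], na.rm = TRUE)
  if (is.nan(hm) || is.nan(hf)) return("unclassified")
  d <- cfg$classify_delta
  if (hm - hf > d) "XY" else if (hf - hm > d) "ZW" else "ambiguous"
}
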