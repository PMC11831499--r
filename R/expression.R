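#' Normalize a count matrix to FPKM, TPM, or miRNA reads-per-million
#'
#' FPKM divides each count by the feature length in kilobases and the sample's
#' total mapped fragments in millions. TPM first converts counts to
#' length-normalized rates and rescales each sample so the column sums to one
#' million. miRNA abundance has no length term: it is simply
#' `count / column total * 1e6` (reads per million), the convention for mature
#' miRNA counts whose lengths are essentially constant.
#'
#' @param counts Numeric matrix of non-negative integer counts, features in
#'   rows (rownames = feature ids), samples in columns.
#' @param mode One of `"fpkm"`, `"tpm"`, `"mirna_tpm"`.
#' @param lengths Numeric vector of feature lengths in nucleotides, named by
#'   feature id or parallel to rows. Required for `"fpkm"` and `"tpm"`.
#' @return Numeric matrix of the same shape with attribute `unit` set to the
#'   mode.
#' @export
normalize_counts <- function(counts, mode = c("fpkm", "tpm", "mirna_tpm"),
                             lengths = NULL) {
  mode <- match.arg(mode)
  counts <- .check_count_matrix(counts)
  colsum <- colSums(counts)
  if (any(colsum <= 0)) {
    stop("zero column sum for sample(s): ",
         paste(colnames(counts)[colsum <= 0], collapse = ", "))
  }
  if (mode %in% c("fpkm", "tpm")) {
    if (is.null(lengths)) {
      stop("feature lengths are required for mode '", mode, "'")
    }
    if (!is.null(names(lengths))) {
      miss <- setdiff(rownames(counts), names(lengths))
      if (length(miss) > 0) {
        stop("missing lengths for features: ",
             paste(utils::head(miss, 5), collapse = ", "))
      }
      lengths <- lengths[rownames(counts)]
    }
    if (length(lengths) != nrow(counts) || any(!is.finite(lengths)) ||
        any(lengths <= 0)) {
      stop("lengths must be positive and one per feature")
    }
  }
  out <- switch(mode,
    fpkm = {
      # count / (length_kb * libsize_millions)
      sweep(counts / (lengths / 1e3), 2, colsum / 1e6, "/")
    },
    tpm = {
      rate <- counts / (lengths / 1e3)
      sweep(rate, 2, colSums(rate), "/") * 1e6
    },
    mirna_tpm = sweep(counts, 2, colsum, "/") * 1e6
  )
  attr(out, "unit") <- mode
  out
}

#' Detectability filter
#'
#' A feature is detectable when its expression is at least `min_value` in at
#' least `min_fraction` of the samples; "at least 10% of n samples" is read as
#' `ceiling(min_fraction * n)` samples.
#'
#' @param expr Expression matrix (FPKM for mRNA/lncRNA, TPM for miRNA).
#' @param min_value Expression threshold (default 0.5).
#' @param min_fraction Minimum fraction of samples (default 0.10).
#' @return Character vector of detectable feature ids.
#' @export
detectable <- function(expr, min_value = 0.5, min_fraction = 0.10) {
  stopifnot(is.matrix(expr), min_value >= 0,
            min_fraction >= 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(expr))
  hits <- rowSums(expr >= min_value)
  rownames(expr)[hits >= need]
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Per-sample scaling factors for count normalization prior to differential
#' testing. The reference sample is the one whose 75th-percentile count
#' fraction is closest to the mean of those fractions. For every other sample,
#' per-feature log2 ratios (M) and average log2 abundances (A) relative to the
#' reference are computed over features nonzero in both; the most extreme 30%
#' of M values and 5% of A values are trimmed, and the factor is the
#' precision-weighted mean of the remaining M values (weights from the
#' delta-method binomial variance). Factors are rescaled so their geometric
#' mean is exactly 1.
#'
#' @param counts Count matrix, features x samples.
#' @param logratio_trim Fraction of M values trimmed (default 0.3).
#' @param sum_trim Fraction of A values trimmed (default 0.05).
#' @return Named numeric vector of factors, one per sample.
#' @export
scaling_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- .check_count_matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero counts for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, p = 0.75)
  ref <- if (stats::median(f75) < 1e-20) {
    which.max(colSums(sqrt(counts)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One TMM factor: obs vs ref with given library sizes.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

.check_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("counts must be non-negative integers (row %d, column %d)",
                 bad[1], bad[2]))
  }
  counts
}
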