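#' Select the soft-threshold power by scale-free fit
#'
#' For each candidate power beta, the unsigned adjacency is
#' `|cor(x_i, x_j)|^beta` (pairwise Pearson) and the connectivity of a gene is
#' its adjacency row sum (excluding self). The scale-free fit R^2 is the
#' squared correlation from regressing log10 bin frequency on log10 mean bin
#' connectivity over 10 connectivity bins (empty bins dropped); a positive
#' slope zeroes the fit. The chosen beta is the minimal one whose R^2 exceeds
#' `r2_min`; when none qualifies the fallback beta 6 is returned with
#' `warning = TRUE`.
#'
#' @param expr Expression matrix, samples x genes (log2(TPM + 0.001)
#'   transformed upstream).
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_min Scale-free fit threshold (default 0.75, strict `>`).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List: `beta`, `warning`, `fit` (data.frame power/r_squared/slope).
#' @export
select_soft_power <- function(expr, powers = 1:20, r2_min = 0.75,
                              n_bins = 10) {
  expr <- .check_expr_genes(expr)
  cors <- abs(stats::cor(expr))
  diag(cors) <- 0
  if (all(cors >= 1 - 1e-12)) stop("constant connectivity: all genes identical")
  fit <- do.call(rbind, lapply(powers, function(b) {
    k <- rowSums(cors^b)
    sf <- .scale_free_fit(k, n_bins)
    data.frame(power = b, r_squared = sf$r2, slope = sf$slope)
  }))
  ok <- fit$power[fit$r_squared > r2_min]
  if (length(ok) > 0) {
    list(beta = min(ok), warning = FALSE, fit = fit)
  } else {
    list(beta = 6, warning = TRUE, fit = fit)
  }
}

# R^2 of log10(freq) ~ log10(k) over equal-width bins; 0 if slope > 0.
# Equal-width binning is the convention for this fit index; log-spaced bins
# collapse to the sampling-noise floor of the correlations at realistic
# sample sizes and carry no signal.
.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = 0, slope = NA_real_))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = NA_real_))
  x <- log10(kmean[keep])
  y <- log10(freq[keep] / sum(freq[keep]))
  m <- stats::lm(y ~ x)
  slope <- stats::coef(m)[2]
  r2 <- summary(m)$r.squared
  if (!is.finite(slope)) return(list(r2 = 0, slope = NA_real_))
  list(r2 = if (slope > 0) 0 else r2, slope = unname(slope))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - |cor|^beta`, cut statically at height `cut_height`; clusters smaller
#' than `min_size` go to module 0 (grey/unassigned). Modules whose eigengenes
#' are closer than `merge_height` (eigengene dissimilarity `1 - cor`) are
#' merged iteratively until stable. The eigengene of a module is the first
#' principal component of its standardized member profiles, sign-oriented so
#' its mean correlation with members is positive, scaled to unit norm.
#'
#' @param expr Expression matrix, samples x genes.
#' @param beta Soft power (see [select_soft_power()]).
#' @param min_size Minimum module size (default 30).
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param cut_height Static tree-cut height (default 0.99).
#' @return List: `labels` (named integer vector, 0 = unassigned), `eigengenes`
#'   (samples x modules matrix, columns "ME<label>"), `beta`.
#' @export
detect_modules <- function(expr, beta, min_size = 30, merge_height = 0.25,
                           cut_height = 0.99) {
  expr <- .check_expr_genes(expr)
  diss <- 1 - abs(stats::cor(expr))^beta
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- stats::cutree(hc, h = cut_height)
  labels <- .drop_small(labels, min_size)
  repeat {
    merged <- .merge_close_modules(expr, labels, merge_height)
    if (identical(merged, labels)) break
    labels <- .drop_small(merged, min_size)
  }
  labels <- .relabel_by_size(labels)
  names(labels) <- colnames(expr)
  eig <- .module_eigengenes(expr, labels)
  list(labels = labels, eigengenes = eig, beta = beta)
}

.check_expr_genes <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 3) stop("need at least 3 features (genes in columns)")
  if (any(apply(expr, 2, stats::sd) == 0)) {
    stop("constant connectivity: zero-variance gene(s) present")
  }
  expr
}

.drop_small <- function(labels, min_size) {
  sizes <- table(labels[labels != 0])
  small <- as.integer(names(sizes)[sizes < min_size])
  labels[labels %in% small] <- 0L
  labels
}

.relabel_by_size <- function(labels) {
  sizes <- sort(table(labels[labels != 0]), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  out <- integer(length(labels))
  nz <- labels != 0
  out[nz] <- map[as.character(labels[nz])]
  out
}

# merge the single closest pair of eigengenes under merge_height
.merge_close_modules <- function(expr, labels, merge_height) {
  mods <- sort(unique(labels[labels != 0]))
  if (length(mods) < 2) return(labels)
  eig <- .module_eigengenes(expr, labels)
  d <- 1 - stats::cor(eig)
  diag(d) <- Inf
  if (min(d) >= merge_height) return(labels)
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  keep <- mods[min(ij)]
  drop <- mods[max(ij)]
  labels[labels == drop] <- keep
  labels
}

.module_eigengenes <- function(expr, labels) {
  mods <- sort(unique(labels[labels != 0]))
  if (length(mods) == 0) {
    return(matrix(numeric(0), nrow = nrow(expr), ncol = 0))
  }
  eig <- vapply(mods, function(m) {
    sub <- scale(expr[, labels == m, drop = FALSE])
    pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    if (mean(stats::cor(pc, sub)) < 0) pc <- -pc
    pc / sqrt(sum(pc^2))
  }, numeric(nrow(expr)))
  colnames(eig) <- paste0("ME", mods)
  rownames(eig) <- rownames(expr)
  eig
}

#' Module-trait correlation
#'
#' Pearson correlation between each module eigengene and each numeric trait,
#' with a t-distribution p-value on n - 2 degrees of freedom. Constant traits
#' yield `NA` with a reason.
#'
#' @param eigengenes Samples x modules matrix (from [detect_modules()]).
#' @param traits Samples x traits numeric matrix or data.frame (binary traits
#'   coded 0/1).
#' @return List of matrices `r` and `p` (modules x traits), plus `notes`.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == nrow(eigengenes))
  n <- nrow(traits)
  r <- matrix(NA_real_, ncol(eigengenes), ncol(traits),
              dimnames = list(colnames(eigengenes), colnames(traits)))
  p <- r
  notes <- character(0)
  for (j in seq_len(ncol(traits))) {
    if (stats::sd(traits[, j]) == 0) {
      notes <- c(notes, sprintf("trait '%s' is constant; correlation undefined",
                                colnames(traits)[j]))
      next
    }
    rj <- stats::cor(eigengenes, traits[, j])
    tj <- rj * sqrt((n - 2) / pmax(1 - rj^2, 1e-300))
    r[, j] <- rj
    p[, j] <- 2 * stats::pt(abs(tj), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, notes = notes)
}

#' Members of trait-associated modules
#'
#' Selects all members of modules whose eigengene-trait absolute correlation
#' meets `r_min`, used to define the module arm of the NNR union.
#'
#' @param labels Module labels from [detect_modules()].
#' @param mtc Output of [module_trait_correlation()].
#' @param trait Trait column name.
#' @param r_min Minimum |r| (default 0.8).
#' @return Character vector of feature ids.
#' @export
trait_module_members <- function(labels, mtc, trait, r_min = 0.8) {
  stopifnot(trait %in% colnames(mtc$r))
  hit <- rownames(mtc$r)[!is.na(mtc$r[, trait]) &
                         abs(mtc$r[, trait]) >= r_min]
  mods <- as.integer(sub("^ME", "", hit))
  names(labels)[labels %in% mods]
}
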