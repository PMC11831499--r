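#' Method-of-moments common dispersion
#'
#' Per feature, the negative-binomial dispersion is estimated from the pooled
#' within-group moments of factor-normalized counts,
#' `phi_g = max(0, (s2 - m) / m^2)`, and the common dispersion is the median of
#' `phi_g` over features with positive mean, floored at 1e-8.
#'
#' @param counts Count matrix, features x samples.
#' @param group Factor or vector of group labels, one per sample.
#' @param factors Optional per-sample scaling factors (effective library size
#'   multipliers); defaults to 1.
#' @return Common dispersion (single number).
#' @export
estimate_dispersion <- function(counts, group, factors = NULL) {
  counts <- .check_count_matrix(counts)
  group <- as.factor(group)
  stopifnot(length(group) == ncol(counts))
  if (all(counts == 0)) stop("all counts are zero; cannot estimate dispersion")
  if (max(table(group)) < 2) stop("need >= 2 replicates in at least one group")
  norm <- .normalized_counts(counts, factors)
  phis <- apply(norm, 1, .mom_phi, group = group)
  phis <- phis[!is.na(phis)]
  if (length(phis) == 0) stop("no features with positive mean")
  max(stats::median(phis), 1e-8)
}

# pooled within-group method-of-moments dispersion for one feature
.mom_phi <- function(x, group) {
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  groups <- split(x, group)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) return(NA_real_)
  df <- sum(vapply(groups, length, 1L)) - length(groups)
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / df
  max(0, (s2 - m) / m^2)
}

.normalized_counts <- function(counts, factors = NULL) {
  lib <- colSums(counts)
  if (!is.null(factors)) lib <- lib * factors
  eff <- lib / exp(mean(log(lib)))
  sweep(counts, 2, eff, "/")
}

#' Exact negative-binomial two-group test
#'
#' Conditions on the pooled count of each group: with common dispersion phi,
#' the group sums of factor-adjusted counts are negative-binomial with sizes
#' proportional to the group sizes and a shared success probability, so the
#' conditional distribution of one group's sum given the total is free of the
#' mean. The two-sided p-value sums the conditional probabilities of all
#' outcomes no more likely than the observed one (minimum-likelihood method).
#' Log2 fold change (B over A) uses prior-count-augmented normalized group
#' means.
#'
#' @param counts Count matrix.
#' @param group Two-level factor over samples; the fold change is level 2 over
#'   level 1.
#' @param phi Common NB dispersion (see [estimate_dispersion()]).
#' @param factors Optional per-sample scaling factors.
#' @param prior_count Prior count added to normalized group means for the fold
#'   change (default 1).
#' @param allow_n1 If `FALSE` (default), groups with a single sample are an
#'   error; if `TRUE`, p = 1 is returned for every feature.
#' @return data.frame with columns `feature`, `log2fc`, `pvalue`, `mean_a`,
#'   `mean_b`.
#' @export
nb_test <- function(counts, group, phi, factors = NULL, prior_count = 1,
                    allow_n1 = FALSE) {
  counts <- .check_count_matrix(counts)
  group <- as.factor(group)
  stopifnot(length(group) == ncol(counts), nlevels(group) == 2,
            phi >= 0)
  nA <- sum(group == levels(group)[1])
  nB <- sum(group == levels(group)[2])
  degenerate <- min(nA, nB) < 2
  if (degenerate && !allow_n1) {
    stop("each group needs >= 2 samples (set allow_n1 = TRUE to emit p = 1)")
  }
  norm <- .normalized_counts(counts, factors)
  a_idx <- group == levels(group)[1]
  mean_a <- rowMeans(norm[, a_idx, drop = FALSE])
  mean_b <- rowMeans(norm[, !a_idx, drop = FALSE])
  log2fc <- log2(mean_b + prior_count) - log2(mean_a + prior_count)
  sA <- round(rowSums(norm[, a_idx, drop = FALSE]))
  sB <- round(rowSums(norm[, !a_idx, drop = FALSE]))
  pvalue <- if (degenerate) {
    rep(1, nrow(counts))
  } else {
    vapply(seq_len(nrow(counts)), function(i) {
      .exact_nb_p(sA[i], sB[i], nA, nB, phi)
    }, numeric(1))
  }
  data.frame(feature = rownames(counts), log2fc = log2fc, pvalue = pvalue,
             mean_a = mean_a, mean_b = mean_b, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Conditional exact NB p-value: P over all splits (a, s - a) of the pooled
# count s whose probability does not exceed that of the observed split.
.exact_nb_p <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  phi <- max(phi, 1e-8)
  mhat <- s / (nA + nB)
  a <- 0:s
  logp <- stats::dnbinom(a, size = nA / phi, mu = nA * mhat, log = TRUE) +
          stats::dnbinom(s - a, size = nB / phi, mu = nB * mhat, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  obs <- p[sA + 1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]) / sum(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' reported in the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  bad <- which(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)
  if (length(bad) > 0) {
    stop("p-values outside [0, 1] at index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-class NR thresholds
#'
#' The default cascade: mRNA and lncRNA at q <= 0.05 and |log2FC| >= 1;
#' miRNA at q <= 0.1 and |log2FC| >= 0.75; circRNA at q <= 0.05 and
#' log2FC >= 0 (any significant change).
#'
#' @param rna_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"circRNA"`.
#' @return List with `rna_class`, `q_max`, `abs_log2fc_min`.
#' @export
class_thresholds <- function(rna_class = c("mRNA", "lncRNA", "miRNA",
                                           "circRNA")) {
  rna_class <- match.arg(rna_class)
  th <- switch(rna_class,
    mRNA    = list(q_max = 0.05, abs_log2fc_min = 1),
    lncRNA  = list(q_max = 0.05, abs_log2fc_min = 1),
    miRNA   = list(q_max = 0.10, abs_log2fc_min = 0.75),
    circRNA = list(q_max = 0.05, abs_log2fc_min = 0))
  c(list(rna_class = rna_class), th)
}

#' Classify regulated features from a DE table
#'
#' @param de data.frame with columns `feature`, `log2fc`, `qvalue` (and
#'   optionally `rna_class`, checked against the thresholds).
#' @param thresholds Output of [class_thresholds()] or a list with `q_max`
#'   and `abs_log2fc_min`.
#' @return List with character vectors `up` and `down` (disjoint) and the
#'   thresholds used.
#' @export
classify_regulated <- function(de, thresholds) {
  stopifnot(all(c("feature", "log2fc", "qvalue") %in% names(de)))
  if (!is.null(de$rna_class) && !is.null(thresholds$rna_class)) {
    if (any(de$rna_class != thresholds$rna_class)) {
      stop("DE table rna_class does not match thresholds rna_class")
    }
  }
  sig <- de$qvalue <= thresholds$q_max
  up <- sig & de$log2fc >= thresholds$abs_log2fc_min
  down <- sig & de$log2fc <= -thresholds$abs_log2fc_min & !up
  list(up = de$feature[up], down = de$feature[down], thresholds = thresholds)
}

#' Tissue-specificity of regulated sets
#'
#' @param sets Named list (one element per tissue) of character vectors of
#'   regulated feature ids (up and down pooled).
#' @return List with `membership` (data.frame feature x n_tissues) and
#'   `fractions` (named vector: fraction of the union regulated in exactly
#'   1, 2, ... tissues).
#' @export
tissue_specificity <- function(sets) {
  stopifnot(length(sets) >= 1)
  all_feats <- unique(unlist(sets))
  n_tis <- vapply(all_feats, function(f) {
    sum(vapply(sets, function(s) f %in% s, logical(1)))
  }, integer(1))
  membership <- data.frame(feature = all_feats, n_tissues = n_tis,
                           row.names = NULL, stringsAsFactors = FALSE)
  fractions <- vapply(seq_along(sets), function(k) mean(n_tis == k),
                      numeric(1))
  names(fractions) <- paste0("in_", seq_along(sets), "_tissue")
  list(membership = membership, fractions = fractions)
}

#' Union of DE-based and module-based regulated sets (NNR definition)
#'
#' Direction tags are preserved where consistent; a feature tagged up in one
#' input and down in the other becomes `"mixed"`.
#'
#' @param de_set,module_set Lists with `up` and `down` character vectors
#'   (a plain character vector is treated as direction-less, tagged "any").
#' @return data.frame with columns `feature`, `direction`.
#' @export
define_nnr <- function(de_set, module_set) {
  tag <- function(s) {
    if (is.character(s)) {
      return(data.frame(feature = s, direction = rep("any", length(s)),
                        stringsAsFactors = FALSE))
    }
    rbind(data.frame(feature = s$up, direction = rep("up", length(s$up)),
                     stringsAsFactors = FALSE),
          data.frame(feature = s$down, direction = rep("down", length(s$down)),
                     stringsAsFactors = FALSE))
  }
  both <- rbind(tag(de_set), tag(module_set))
  if (nrow(both) == 0) {
    return(data.frame(feature = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  dir_of <- vapply(split(both$direction, both$feature), function(d) {
    d <- unique(d)
    real <- setdiff(d, "any")
    if (length(real) == 0) "any"
    else if (length(real) == 1) real
    else "mixed"
  }, character(1))
  data.frame(feature = names(dir_of), direction = unname(dir_of),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter alternative-splicing events by delta-PSI and FDR
#'
#' PSI (percent spliced in) is inclusion / (inclusion + skip) per sample;
#' delta-PSI is the absolute difference of group mean PSIs. Significance comes
#' from a two-sided Fisher exact test on the pooled 2x2 inclusion/skip table,
#' BH-adjusted over events. Events are retained when q <= `q_max` and
#' delta-PSI > `dpsi_min`.
#'
#' @param events data.frame with one row per event and list-columns or
#'   matrices `inc_a`, `skip_a`, `inc_b`, `skip_b` of per-sample counts; or
#'   numeric matrices with events in rows.
#' @param dpsi_min Minimum absolute PSI difference (default 0.1, strict).
#' @param q_max FDR ceiling (default 0.05).
#' @return data.frame: `event`, `dpsi`, `pvalue`, `qvalue`, `retained`.
#' @export
as_filter <- function(events, dpsi_min = 0.1, q_max = 0.05) {
  need <- c("inc_a", "skip_a", "inc_b", "skip_b")
  stopifnot(all(need %in% names(events)))
  get_mat <- function(x) {
    if (is.list(x) && !is.data.frame(x)) do.call(rbind, x) else as.matrix(x)
  }
  inc_a <- get_mat(events$inc_a); skip_a <- get_mat(events$skip_a)
  inc_b <- get_mat(events$inc_b); skip_b <- get_mat(events$skip_b)
  if (any(inc_a < 0) || any(skip_a < 0) || any(inc_b < 0) || any(skip_b < 0)) {
    stop("negative inclusion/skip counts")
  }
  n_ev <- nrow(inc_a)
  psi_a <- rowMeans(inc_a / (inc_a + skip_a))
  psi_b <- rowMeans(inc_b / (inc_b + skip_b))
  dpsi <- abs(psi_a - psi_b)
  pvalue <- vapply(seq_len(n_ev), function(i) {
    tab <- matrix(c(sum(inc_a[i, ]), sum(skip_a[i, ]),
                    sum(inc_b[i, ]), sum(skip_b[i, ])), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  qvalue <- bh_adjust(pvalue)
  event <- if (!is.null(events$event)) events$event else seq_len(n_ev)
  data.frame(event = event, dpsi = dpsi, pvalue = pvalue, qvalue = qvalue,
             retained = qvalue <= q_max & dpsi > dpsi_min,
             stringsAsFactors = FALSE)
}

#' Over-representation analysis (hypergeometric)
#'
#' Per term, the upper-tail hypergeometric probability of observing at least
#' the seen overlap between the query set and the term's genes, with the
#' universe as population; BH-adjusted across terms.
#'
#' @param query Character vector of feature ids (must be within `universe`).
#' @param universe Character vector, the testable population.
#' @param terms Named list: term id -> character vector of member genes.
#' @param q_max Significance ceiling on the adjusted p (default 0.05, strict
#'   `<` per convention).
#' @return data.frame: `term`, `overlap`, `term_size`, `pvalue`, `qvalue`,
#'   `fold`, `significant`.
#' @export
ora_enrich <- function(query, universe, terms, q_max = 0.05) {
  extra <- setdiff(query, universe)
  if (length(extra) > 0) {
    stop("query features not in universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  M <- length(unique(universe))
  n <- length(unique(query))
  res <- lapply(names(terms), function(tm) {
    genes <- intersect(terms[[tm]], universe)
    K <- length(genes)
    x <- length(intersect(genes, query))
    p <- hypergeom_upper(x, M, K, n)
    fold <- if (K > 0 && n > 0) (x / n) / (K / M) else NA_real_
    data.frame(term = tm, overlap = x, term_size = K, pvalue = p, fold = fold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$qvalue <- bh_adjust(out$pvalue)
  out$significant <- out$qvalue < q_max
  out[order(out$pvalue), c("term", "overlap", "term_size", "pvalue", "qvalue",
                           "fold", "significant")]
}

#' Upper-tail hypergeometric probability P(X >= x)
#'
#' Population of size `M` with `K` successes; `n` draws without replacement.
#' `P(X >= 0) = 1` by convention.
#'
#' @param x Observed overlap.
#' @param M Population size.
#' @param K Successes in population.
#' @param n Draws.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper <- function(x, M, K, n) {
  stopifnot(K <= M, n <= M, x >= 0)
  if (x == 0) return(1)
  stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE)
}
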