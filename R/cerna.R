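#' Filter lncRNA-miRNA decoy candidate pairs
#'
#' A (lncRNA, miRNA) pair survives when: it has at least one MRE at confidence
#' >= `min_confidence`; the lncRNA is not a precursor mimic of that miRNA;
#' both members are nodulation-regulated in the focal contrast with opposite
#' directions (miRNA up with lncRNA down, or vice versa); and their expression
#' is negatively correlated across the contrast's samples.
#'
#' @param sites MRE table from [scan_all_mres()] (lncRNA targets).
#' @param mimic_table Output of [precursor_mimic_table()] (or NULL for none).
#' @param lnc_sets,mirna_sets Regulated sets from [classify_regulated()] for
#'   the focal contrast.
#' @param lnc_expr,mirna_expr Expression matrices (features x samples) over
#'   the contrast's samples.
#' @param min_confidence Confidence gate (default 0.5, `>=`).
#' @param require_direction,require_negative_r Toggles for the two sub-gates
#'   of the negative-relation rule (both default TRUE).
#' @return data.frame: `lncrna`, `mirna`, `best_confidence`, `r`,
#'   `lnc_direction`, `mirna_direction`, plus the evidence flags.
#' @export
lncrna_mirna_pairs <- function(sites, mimic_table, lnc_sets, mirna_sets,
                               lnc_expr, mirna_expr, min_confidence = 0.5,
                               require_direction = TRUE,
                               require_negative_r = TRUE) {
  if (nrow(sites) == 0) return(.empty_pairs())
  agg <- stats::aggregate(confidence ~ mirna + target, data = sites, FUN = max)
  names(agg)[names(agg) == "target"] <- "lncrna"
  names(agg)[names(agg) == "confidence"] <- "best_confidence"
  dir_of <- function(sets, f) {
    if (f %in% sets$up) "up" else if (f %in% sets$down) "down" else NA_character_
  }
  out <- list()
  for (k in seq_len(nrow(agg))) {
    l <- agg$lncrna[k]; m <- agg$mirna[k]
    conf_ok <- agg$best_confidence[k] >= min_confidence
    mimic <- FALSE
    if (!is.null(mimic_table)) {
      hit <- mimic_table$mimic[mimic_table$lncrna == l & mimic_table$mirna == m]
      mimic <- length(hit) > 0 && any(hit)
    }
    ld <- dir_of(lnc_sets, l); md <- dir_of(mirna_sets, m)
    if (is.na(ld) || is.na(md)) next  # not NR in this contrast: skipped
    dir_ok <- !require_direction || (ld != md)
    r <- NA_real_
    if (l %in% rownames(lnc_expr) && m %in% rownames(mirna_expr)) {
      shared <- intersect(colnames(lnc_expr), colnames(mirna_expr))
      x <- lnc_expr[l, shared]; y <- mirna_expr[m, shared]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) r <- stats::cor(x, y)
    }
    r_ok <- !require_negative_r || (!is.na(r) && r < 0)
    out[[length(out) + 1]] <- data.frame(
      lncrna = l, mirna = m, best_confidence = agg$best_confidence[k], r = r,
      lnc_direction = ld, mirna_direction = md, conf_ok = conf_ok,
      not_mimic = !mimic, dir_ok = dir_ok, r_ok = r_ok,
      pass = conf_ok && !mimic && dir_ok && r_ok, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(.empty_pairs())
  do.call(rbind, out)
}

.empty_pairs <- function() {
  data.frame(lncrna = character(0), mirna = character(0),
             best_confidence = numeric(0), r = numeric(0),
             lnc_direction = character(0), mirna_direction = character(0),
             conf_ok = logical(0), not_mimic = logical(0),
             dir_ok = logical(0), r_ok = logical(0), pass = logical(0),
             stringsAsFactors = FALSE)
}

#' Shared-MRE hypergeometric test for (lncRNA, mRNA) pairs
#'
#' For every pair with at least one shared binding miRNA, the upper-tail
#' hypergeometric probability of the overlap `x` between the lncRNA's miRNA
#' set (K) and the mRNA's miRNA set (N) in a universe of `M` miRNAs, with BH
#' adjustment across all tested pairs.
#'
#' @param lnc_mirna_sets Named list: lncRNA id -> character vector of binding
#'   miRNA ids.
#' @param mrna_mirna_sets Named list: mRNA id -> character vector of binding
#'   miRNA ids.
#' @param universe Character vector of miRNA ids forming the population; by
#'   default the union of all miRNAs appearing in either set list.
#' @return data.frame: `lncrna`, `mrna`, `x`, `K`, `N`, `M`, `pvalue`,
#'   `qvalue`.
#' @export
shared_mre_test <- function(lnc_mirna_sets, mrna_mirna_sets, universe = NULL) {
  if (is.null(universe)) {
    universe <- unique(c(unlist(lnc_mirna_sets), unlist(mrna_mirna_sets)))
  }
  M <- length(universe)
  out <- list()
  for (l in names(lnc_mirna_sets)) {
    K <- length(unique(lnc_mirna_sets[[l]]))
    if (K > M) stop("lncRNA miRNA set larger than universe for ", l)
    for (g in names(mrna_mirna_sets)) {
      shared <- intersect(lnc_mirna_sets[[l]], mrna_mirna_sets[[g]])
      x <- length(shared)
      if (x == 0) next
      N <- length(unique(mrna_mirna_sets[[g]]))
      if (N > M) stop("mRNA miRNA set larger than universe for ", g)
      out[[length(out) + 1]] <- data.frame(
        lncrna = l, mrna = g, x = x, K = K, N = N, M = M,
        pvalue = hypergeom_upper(x, M, K, N), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(lncrna = character(0), mrna = character(0),
                      x = integer(0), K = integer(0), N = integer(0),
                      M = integer(0), pvalue = numeric(0), qvalue = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$qvalue <- bh_adjust(res$pvalue)
  res
}

#' Assemble the ceRNA network from filtered evidence
#'
#' A triplet (lncRNA decoy, miRNA core, mRNA target) is retained when its
#' (lncRNA, miRNA) pair passed [lncrna_mirna_pairs()], the miRNA has an MRE on
#' the mRNA at confidence >= `min_confidence`, the (lncRNA, mRNA) shared-MRE
#' q-value is <= `q_max`, and the lncRNA-mRNA expression correlation is
#' >= `r_pos_min`.
#'
#' @param pairs Output of [lncrna_mirna_pairs()].
#' @param mrna_sites MRE table for mRNA targets (from [scan_all_mres()]).
#' @param shared Output of [shared_mre_test()].
#' @param lnc_expr,mrna_expr Expression matrices over the contrast samples.
#' @param de_dirs Optional named list of direction lookups for node
#'   attributes: elements `lncRNA`, `miRNA`, `mRNA`, each a
#'   [classify_regulated()] result.
#' @param q_max Shared-MRE FDR gate (default 0.05).
#' @param r_pos_min lncRNA-mRNA correlation gate (default 0.6).
#' @param min_confidence Confidence gate on the mRNA-side MRE (default 0.5).
#' @param competes_edges Add lncRNA-mRNA "competes" edges (default TRUE).
#' @return List: `triplets` (data.frame), `network` (igraph).
#' @export
assemble_network <- function(pairs, mrna_sites, shared, lnc_expr, mrna_expr,
                             de_dirs = NULL, q_max = 0.05, r_pos_min = 0.6,
                             min_confidence = 0.5, competes_edges = TRUE) {
  passed <- pairs[pairs$pass, , drop = FALSE]
  trip <- list()
  if (nrow(passed) > 0 && nrow(mrna_sites) > 0 && nrow(shared) > 0) {
    mrna_conf <- stats::aggregate(confidence ~ mirna + target,
                                  data = mrna_sites, FUN = max)
    shared_cols <- intersect(colnames(lnc_expr), colnames(mrna_expr))
    for (k in seq_len(nrow(passed))) {
      l <- passed$lncrna[k]; m <- passed$mirna[k]
      hits <- mrna_conf[mrna_conf$mirna == m &
                        mrna_conf$confidence >= min_confidence, , drop = FALSE]
      for (g in hits$target) {
        sh <- shared[shared$lncrna == l & shared$mrna == g, , drop = FALSE]
        if (nrow(sh) == 0 || sh$qvalue[1] > q_max) next
        if (!(l %in% rownames(lnc_expr)) || !(g %in% rownames(mrna_expr))) next
        x <- lnc_expr[l, shared_cols]; y <- mrna_expr[g, shared_cols]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r_lm <- stats::cor(x, y)
        if (r_lm < r_pos_min) next
        trip[[length(trip) + 1]] <- data.frame(
          lncrna = l, mirna = m, mrna = g, x = sh$x[1], K = sh$K[1],
          N = sh$N[1], M = sh$M[1], pvalue = sh$pvalue[1],
          qvalue = sh$qvalue[1], r_lnc_mrna = r_lm, r_lnc_mirna = passed$r[k],
          lnc_direction = passed$lnc_direction[k],
          mirna_direction = passed$mirna_direction[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  triplets <- if (length(trip) > 0) {
    unique(do.call(rbind, trip))
  } else {
    data.frame(lncrna = character(0), mirna = character(0),
               mrna = character(0), x = integer(0), K = integer(0),
               N = integer(0), M = integer(0), pvalue = numeric(0),
               qvalue = numeric(0), r_lnc_mrna = numeric(0),
               r_lnc_mirna = numeric(0), lnc_direction = character(0),
               mirna_direction = character(0), stringsAsFactors = FALSE)
  }
  network <- .build_cerna_graph(triplets, de_dirs, competes_edges)
  list(triplets = triplets, network = network)
}

.build_cerna_graph <- function(triplets, de_dirs, competes_edges) {
  if (nrow(triplets) == 0) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna, type = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna, type = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna, type = "mRNA", stringsAsFactors = FALSE)))
  dir_lookup <- function(id, type) {
    if (is.null(de_dirs) || is.null(de_dirs[[type]])) return(NA_character_)
    s <- de_dirs[[type]]
    if (id %in% s$up) "up" else if (id %in% s$down) "down" else NA_character_
  }
  nodes$direction <- mapply(dir_lookup, nodes$id, nodes$type)
  edges <- rbind(
    data.frame(from = triplets$lncrna, to = triplets$mirna, etype = "decoy",
               stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna, to = triplets$mrna, etype = "targets",
               stringsAsFactors = FALSE))
  if (competes_edges) {
    edges <- rbind(edges, data.frame(from = triplets$lncrna,
                                     to = triplets$mrna, etype = "competes",
                                     stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a ceRNA network as GraphML and SIF
#'
#' @param network igraph object from [assemble_network()].
#' @param graphml_path,sif_path Output paths (NULL to skip either).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, graphml_path = NULL, sif_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(sif_path)) {
    if (igraph::ecount(network) > 0) {
      e <- igraph::as_data_frame(network, what = "edges")
      writeLines(paste(e$from, e$etype, e$to, sep = "\t"), sif_path)
    } else {
      writeLines(character(0), sif_path)
    }
    written <- c(written, sif_path)
  }
  invisible(written)
}

#' Binding miRNA sets per target from an MRE table
#'
#' @param sites MRE table (from [scan_all_mres()]).
#' @param min_confidence Confidence floor for a site to count (default 0.5).
#' @return Named list: target id -> character vector of miRNA ids.
#' @export
mirna_sets_from_sites <- function(sites, min_confidence = 0.5) {
  keep <- sites[sites$confidence >= min_confidence, , drop = FALSE]
  if (nrow(keep) == 0) return(list())
  lapply(split(keep$mirna, keep$target), unique)
}
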