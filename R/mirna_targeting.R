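#' Scan a transcript for miRNA response elements
#'
#' Slides the reverse complement of the miRNA along the target (ungapped) and
#' scores each offset with a plant-style complementarity penalty: 1 per
#' mismatch, 0.5 per G:U wobble, doubled at miRNA positions 2-13 (1-based from
#' the miRNA 5' end). Sites with penalty <= `cutoff` are reported; overlapping
#' candidates are resolved greedily, keeping the lowest-scoring site (ties to
#' the leftmost). Confidence is `1 - score / (cutoff + 1)`, a monotone map so
#' a perfect site has confidence 1 and the paper-style confidence gate of 0.5
#' corresponds to penalty 2.5 at the default cutoff 4.
#'
#' @param mirna miRNA sequence (character, ACGU or ACGT; 18-26 nt).
#' @param target Target transcript sequence (ACGU or ACGT).
#' @param cutoff Maximum penalty for a reported site (default 4).
#' @param mirna_id,target_id Optional ids carried into the output.
#' @return data.frame: `mirna`, `target`, `start` (0-based on the target),
#'   `end` (exclusive), `score`, `confidence`.
#' @export
scan_mres <- function(mirna, target, cutoff = 4.0,
                      mirna_id = "mirna", target_id = "target") {
  q <- .encode_rna(reverse_complement(mirna))
  t_enc <- .encode_rna(target)
  L <- length(q)
  if (L < 18 || L > 26) stop("miRNA length must be 18-26 nt, got ", L)
  n_off <- length(t_enc) - L + 1
  empty <- data.frame(mirna = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_off < 1) return(empty)
  # weights in query orientation: query index i covers miRNA position L-i+1
  mirna_pos <- L:1
  w <- ifelse(mirna_pos >= 2 & mirna_pos <= 13, 2, 1)
  # penalty lookup: rows = query base, cols = target base (A,C,G,U = 1..4)
  pen <- matrix(1, 4, 4)
  diag(pen) <- 0
  pen[2, 4] <- 0.5  # query C (miRNA G) vs target U
  pen[1, 3] <- 0.5  # query A (miRNA U) vs target G
  win <- matrix(t_enc[outer(seq_len(L), seq_len(n_off) - 1L, "+")],
                nrow = L)
  scores <- colSums(matrix(pen[cbind(rep(q, n_off), as.vector(win))],
                           nrow = L) * w)
  cand <- which(scores <= cutoff)
  if (length(cand) == 0) return(empty)
  ord <- cand[order(scores[cand], cand)]
  taken <- logical(length(t_enc))
  keep <- integer(0)
  for (i in ord) {
    span <- i:(i + L - 1)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  data.frame(mirna = mirna_id, target = target_id,
             start = keep - 1L, end = keep - 1L + L,
             score = scores[keep],
             confidence = 1 - scores[keep] / (cutoff + 1),
             stringsAsFactors = FALSE)
}

#' Scan many miRNAs against many targets
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param targets Named character vector of target transcript sequences.
#' @param cutoff Penalty cutoff (default 4).
#' @return data.frame of sites from [scan_mres()] pooled across pairs.
#' @export
scan_all_mres <- function(mirnas, targets, cutoff = 4.0) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(targets)))
  res <- list()
  for (m in names(mirnas)) {
    for (tg in names(targets)) {
      hit <- scan_mres(mirnas[[m]], targets[[tg]], cutoff = cutoff,
                       mirna_id = m, target_id = tg)
      if (nrow(hit) > 0) res[[length(res) + 1]] <- hit
    }
  }
  if (length(res) == 0) {
    return(data.frame(mirna = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Flag lncRNAs that mimic miRNA precursors
#'
#' TRUE when the lncRNA and the precursor share an ungapped alignment window
#' of at least `min_window` nt with identity >= `min_identity`. Every diagonal
#' of the (lncRNA x precursor) comparison is scanned with a prefix-sum scheme
#' that is exact over all window lengths >= `min_window`.
#'
#' @param lncrna lncRNA sequence.
#' @param precursor Precursor (pre-miRNA) sequence, >= `min_window` nt.
#' @param min_identity Identity threshold (default 0.9).
#' @param min_window Minimum alignment window (default 55 nt).
#' @return Logical flag.
#' @export
precursor_mimic <- function(lncrna, precursor, min_identity = 0.9,
                            min_window = 55) {
  x <- .encode_rna(lncrna)
  y <- .encode_rna(precursor)
  if (length(y) < min_window) {
    stop("precursor must be at least ", min_window, " nt")
  }
  if (length(x) < min_window) return(FALSE)
  nx <- length(x); ny <- length(y)
  # diagonals: offset d aligns x[i] with y[i - d]
  for (d in (-(ny - min_window)):(nx - min_window)) {
    i0 <- max(1, 1 + d); i1 <- min(nx, ny + d)
    len <- i1 - i0 + 1
    if (len < min_window) next
    match <- x[i0:i1] == y[(i0 - d):(i1 - d)]
    # identity >= t over a window  <=>  sum(match - t) >= 0
    s <- cumsum(c(0, match - min_identity))
    run_min <- cummin(s[1:(len - min_window + 1)])
    if (any(s[(min_window + 1):(len + 1)] - run_min >= -1e-9)) return(TRUE)
  }
  FALSE
}

#' Precursor-mimic flags for lncRNA and precursor sets
#'
#' @param lncrnas Named character vector of lncRNA sequences.
#' @param precursors Named character vector of precursor sequences; names are
#'   the miRNA ids they give rise to.
#' @return data.frame: `lncrna`, `mirna`, `mimic`.
#' @export
precursor_mimic_table <- function(lncrnas, precursors) {
  grid <- expand.grid(lncrna = names(lncrnas), mirna = names(precursors),
                      stringsAsFactors = FALSE)
  grid$mimic <- mapply(function(l, m) {
    precursor_mimic(lncrnas[[l]], precursors[[m]])
  }, grid$lncrna, grid$mirna)
  grid
}

#' Reverse complement of a nucleotide sequence
#'
#' Accepts DNA or RNA; the output uses the input's alphabet (T stays T,
#' U stays U).
#'
#' @param seq Character scalar.
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", seq)
  # preserve RNA alphabet: if input had U (and no T), complement A -> U
  if (grepl("[Uu]", seq) && !grepl("[Tt]", seq)) {
    comp <- chartr("Tt", "Uu", comp)
  }
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# encode ACGU/ACGT (case-insensitive) as integers 1..4; U == T
.encode_rna <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L)
  enc <- code[v]
  if (anyNA(enc)) {
    stop("invalid character in sequence at position ", which(is.na(enc))[1])
  }
  unname(enc)
}

#' Mutate alternating pairing positions of an MRE
#'
#' Validation-construct helper: given a target sequence and an MRE interval,
#' replaces every other base of the site with its complement, abolishing
#' pairing at six or more positions for a typical 21-nt site while preserving
#' length and composition class.
#'
#' @param target Target sequence.
#' @param start 0-based site start.
#' @param end 0-based exclusive site end.
#' @param step Mutate every `step`-th position (default 2).
#' @return Mutated sequence (character scalar).
#' @export
mutate_mre <- function(target, start, end, step = 2) {
  v <- strsplit(target, "")[[1]]
  stopifnot(start >= 0, end <= length(v), end > start)
  idx <- seq(start + 1, end, by = step)
  v[idx] <- chartr("ACGTUacgtu", "TGCAAtgcaa", v[idx])
  paste(v, collapse = "")
}
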