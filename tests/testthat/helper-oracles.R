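# Independent reference implementations used as oracles by the tests.

# Exact upper-tail hypergeometric probability by direct enumeration.
hyper_tail_enum <- function(x, M, K, n) {
  if (x == 0) return(1)
  j <- x:min(K, n)
  sum(choose(K, j) * choose(M - K, n - j)) / choose(M, n)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Naive per-offset MRE scorer working directly in miRNA/target pairing space:
# miRNA position p (1-based from the 5' end) pairs antiparallel with the
# target base at offset start + L - p. Penalties: 0 for Watson-Crick, 0.5 for
# G:U wobble (either orientation), 1 otherwise; doubled at positions 2-13.
naive_scan_mres <- function(mirna, target, cutoff = 4,
                            mirna_id = "mirna", target_id = "target") {
  m <- strsplit(toupper(chartr("Tt", "Uu", mirna)), "")[[1]]
  tv <- strsplit(toupper(chartr("Tt", "Uu", target)), "")[[1]]
  L <- length(m)
  n_off <- length(tv) - L + 1
  empty <- data.frame(mirna = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_off < 1) return(empty)
  perfect <- c(A = "U", C = "G", G = "C", U = "A")
  pair_pen <- function(mb, tb) {
    if (perfect[[mb]] == tb) return(0)
    if (mb == "G" && tb == "U") return(0.5)
    if (mb == "U" && tb == "G") return(0.5)
    1
  }
  scores <- vapply(seq_len(n_off), function(s) {
    tot <- 0
    for (p in seq_len(L)) {
      w <- if (p >= 2 && p <= 13) 2 else 1
      tot <- tot + w * pair_pen(m[p], tv[s + L - p])
    }
    tot
  }, numeric(1))
  cand <- which(scores <= cutoff)
  if (length(cand) == 0) return(empty)
  ord <- cand[order(scores[cand], cand)]
  taken <- logical(length(tv))
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
             score = scores[keep], confidence = 1 - scores[keep] / (cutoff + 1),
             stringsAsFactors = FALSE)
}

# Brute-force precursor-mimic flag over every (i, j, len >= min_window)
# ungapped window pair; only usable for short sequences.
naive_mimic <- function(x, y, min_identity = 0.9, min_window = 55) {
  xv <- strsplit(toupper(chartr("Tt", "Uu", x)), "")[[1]]
  yv <- strsplit(toupper(chartr("Tt", "Uu", y)), "")[[1]]
  nx <- length(xv); ny <- length(yv)
  if (nx < min_window || ny < min_window) return(FALSE)
  for (i in seq_len(nx - min_window + 1)) {
    for (j in seq_len(ny - min_window + 1)) {
      maxlen <- min(nx - i + 1, ny - j + 1)
      mm <- cumsum(xv[i:(i + maxlen - 1)] == yv[j:(j + maxlen - 1)])
      lens <- min_window:maxlen
      if (any(mm[lens] >= min_identity * lens - 1e-9)) return(TRUE)
    }
  }
  FALSE
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# A random sequence of given length from a local RNG stream.
random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exact complement site for a miRNA (what a penalty-0 MRE looks like).
perfect_site <- function(mirna) reverse_complement(mirna)
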