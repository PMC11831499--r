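test_that("estimate_dispersion recovers a planted dispersion", {
  set.seed(21)
  counts <- matrix(rnbinom(3000 * 6, mu = 100, size = 1 / 0.2), 3000, 6,
                   dimnames = list(paste0("g", 1:3000), paste0("s", 1:6)))
  phi <- estimate_dispersion(counts, rep(c("a", "b"), each = 3))
  expect_gt(phi, 0.1)
  expect_lt(phi, 0.35)
})

test_that("estimate_dispersion validates input", {
  counts <- matrix(0L, 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_error(estimate_dispersion(counts, c("a", "b")), "all counts are zero")
  counts[1, 1] <- 5L
  expect_error(estimate_dispersion(counts, c("a", "b")),
               ">= 2 replicates")
})

test_that("nb_test is symmetric under label swap", {
  set.seed(22)
  counts <- matrix(rnbinom(200 * 6, mu = 60, size = 10), 200, 6,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  g <- rep(c("a", "b"), each = 3)
  res <- nb_test(counts, g, phi = 0.1)
  swapped <- nb_test(counts, rep(c("b", "a"), each = 3), phi = 0.1)
  expect_equal(res$pvalue, swapped$pvalue, tolerance = 1e-12)
  expect_equal(res$log2fc, -swapped$log2fc, tolerance = 1e-12)
})

test_that("nb_test reduces to the exact binomial test as phi -> 0", {
  # in the phi -> 0 limit the conditional distribution is Binomial(s, 1/2);
  # minimum-likelihood tie inclusion is sensitive to ~1e-10 approximation
  # error near exactly-tied outcomes, so the oracle brackets the p-value
  # between strict-inclusion and loose-inclusion binomial tail sums
  set.seed(23)
  counts <- matrix(rpois(50 * 4, 40), 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  g <- rep(c("a", "b"), each = 2)
  # neutralize library-size normalization so the conditioning statistic is
  # the raw group sum the binomial oracle uses
  f <- 1 / colSums(counts)
  res <- nb_test(counts, g, phi = 1e-12, factors = f)
  sA <- rowSums(counts[, 1:2])
  sB <- rowSums(counts[, 3:4])
  for (i in seq_len(nrow(counts))) {
    s <- sA[i] + sB[i]
    d <- dbinom(0:s, s, 0.5)
    obs <- d[sA[i] + 1]
    p_strict <- sum(d[d <= obs * (1 - 1e-4)]) + obs
    p_loose <- sum(d[d <= obs * (1 + 1e-4)])
    expect_gte(res$pvalue[i], p_strict - 1e-6)
    expect_lte(res$pvalue[i], p_loose + 1e-6)
  }
})

test_that("nb_test flags planted differences and handles n = 1 groups", {
  set.seed(24)
  null_counts <- matrix(rnbinom(5 * 6, mu = 100, size = 10), 5, 6)
  de_counts <- cbind(matrix(rnbinom(5 * 3, mu = 25, size = 10), 5, 3),
                     matrix(rnbinom(5 * 3, mu = 400, size = 10), 5, 3))
  counts <- rbind(null_counts, de_counts)
  dimnames(counts) <- list(paste0("g", 1:10), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- nb_test(counts, g, phi = 0.1)
  expect_true(all(res$pvalue[6:10] < 0.01))
  expect_true(all(res$log2fc[6:10] > 0))
  expect_error(nb_test(counts[, c(1, 4, 5, 6)], c("a", "b", "b", "b"),
                       phi = 0.1), "allow_n1")
  res1 <- nb_test(counts[, c(1, 4, 5, 6)], c("a", "b", "b", "b"),
                  phi = 0.1, allow_n1 = TRUE)
  expect_true(all(res1$pvalue == 1))
})

test_that("bh_adjust matches p.adjust and validates input", {
  set.seed(25)
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  expect_error(bh_adjust(c(0.5, NA)), "outside")
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("class_thresholds encodes the per-class cascade", {
  expect_equal(class_thresholds("mRNA")[c("q_max", "abs_log2fc_min")],
               list(q_max = 0.05, abs_log2fc_min = 1))
  expect_equal(class_thresholds("lncRNA")[c("q_max", "abs_log2fc_min")],
               list(q_max = 0.05, abs_log2fc_min = 1))
  expect_equal(class_thresholds("miRNA")[c("q_max", "abs_log2fc_min")],
               list(q_max = 0.10, abs_log2fc_min = 0.75))
  expect_equal(class_thresholds("circRNA")[c("q_max", "abs_log2fc_min")],
               list(q_max = 0.05, abs_log2fc_min = 0))
  expect_error(class_thresholds("tRNA"))
})

test_that("classify_regulated keeps boundaries inclusive and sets disjoint", {
  de <- data.frame(
    feature = c("f1", "f2", "f3", "f4", "f5", "f6"),
    log2fc  = c(1.0,  -1.0,  0.99, 2.0,  -3.0, 1.5),
    qvalue  = c(0.05, 0.05,  0.01, 0.051, 0.05, 0.0),
    stringsAsFactors = FALSE)
  got <- classify_regulated(de, class_thresholds("mRNA"))
  expect_setequal(got$up, c("f1", "f6"))
  expect_setequal(got$down, c("f2", "f5"))
  expect_length(intersect(got$up, got$down), 0)
  # circRNA: any significant change counts, lfc 0 goes to "up" only
  circ <- data.frame(feature = c("c1", "c2"), log2fc = c(0, -0.2),
                     qvalue = c(0.01, 0.01), stringsAsFactors = FALSE)
  gotc <- classify_regulated(circ, class_thresholds("circRNA"))
  expect_setequal(gotc$up, "c1")
  expect_setequal(gotc$down, "c2")
  expect_error(
    classify_regulated(cbind(de, rna_class = "miRNA"),
                       class_thresholds("mRNA")),
    "does not match")
})

test_that("tissue_specificity computes exact fractions", {
  sets <- list(root = c("a", "b", "c"), cotyledon = c("b", "d"),
               leaf = c("b"))
  got <- tissue_specificity(sets)
  # union a,b,c,d: a 1, b 3, c 1, d 1 -> 3/4 in one tissue, 1/4 in three
  expect_equal(unname(got$fractions), c(0.75, 0, 0.25))
  expect_equal(got$membership$n_tissues[got$membership$feature == "b"], 3L)
})

test_that("define_nnr unions sets and resolves directions", {
  de <- list(up = c("a", "b"), down = c("c"))
  mods <- c("b", "c", "d")
  got <- define_nnr(de, mods)
  expect_setequal(got$feature, c("a", "b", "c", "d"))
  expect_identical(got$direction[got$feature == "a"], "up")
  expect_identical(got$direction[got$feature == "d"], "any")
  # conflicting directions become "mixed"
  got2 <- define_nnr(list(up = "x", down = character(0)),
                     list(up = character(0), down = "x"))
  expect_identical(got2$direction, "mixed")
  empty <- define_nnr(character(0), character(0))
  expect_identical(nrow(empty), 0L)
})

test_that("as_filter applies the delta-PSI and FDR gates", {
  events <- data.frame(event = c("e1", "e2", "e3"))
  events$inc_a <- matrix(c(90, 85, 80,   50, 52, 48,   10, 12, 11), 3,
                         byrow = TRUE)
  events$skip_a <- matrix(c(10, 15, 20,  50, 48, 52,   90, 88, 89), 3,
                          byrow = TRUE)
  events$inc_b <- matrix(c(30, 35, 25,   50, 49, 51,   12, 10, 9), 3,
                         byrow = TRUE)
  events$skip_b <- matrix(c(70, 65, 75,  50, 51, 49,   88, 90, 91), 3,
                          byrow = TRUE)
  got <- as_filter(events)
  # e1: large PSI change -> retained; e2, e3: no change -> not retained
  expect_true(got$retained[1])
  expect_false(any(got$retained[2:3]))
  # p-value equals the pooled-table Fisher test
  tab <- matrix(c(sum(events$inc_a[1, ]), sum(events$skip_a[1, ]),
                  sum(events$inc_b[1, ]), sum(events$skip_b[1, ])), 2)
  expect_equal(got$pvalue[1], fisher.test(tab)$p.value)
  expect_error(as_filter(within(events, inc_a[1] <- -1)), "negative")
})

test_that("ora_enrich matches manual hypergeometric p-values", {
  universe <- paste0("g", 1:50)
  terms <- list(t1 = paste0("g", 1:10), t2 = paste0("g", 40:50))
  query <- paste0("g", 1:8)
  got <- ora_enrich(query, universe, terms)
  p1 <- phyper(8 - 1, 10, 40, 8, lower.tail = FALSE)
  expect_equal(got$pvalue[got$term == "t1"], p1)
  expect_equal(got$pvalue[got$term == "t2"], 1)  # zero overlap
  expect_equal(got$qvalue, p.adjust(got$pvalue, "BH"))
  expect_error(ora_enrich(c("g1", "zz"), universe, terms), "not in universe")
})

test_that("hypergeom_upper handles edge cases", {
  expect_equal(hypergeom_upper(0, 10, 3, 4), 1)
  expect_equal(hypergeom_upper(3, 10, 3, 3), 1 / choose(10, 3))
  expect_error(hypergeom_upper(1, 5, 6, 2))
})
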