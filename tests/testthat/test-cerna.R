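# A small hand-built evidence set used across the ceRNA tests: one genuine
# decoy relation (L1, m1/m2, G1) plus distractors failing single gates.
make_evidence <- function() {
  set.seed(61)
  n <- 12
  samples <- paste0("s", 1:n)
  z <- scale(rnorm(n))[, 1]
  lnc_expr <- rbind(L1 = 2 + z, L2 = 2 + z, L3 = rnorm(n))
  mir_expr <- rbind(m1 = 1 - z + rnorm(n, sd = 0.05),
                    m2 = 1 - z + rnorm(n, sd = 0.05),
                    m3 = 1 + z)  # positively correlated with L2
  mrna_expr <- rbind(G1 = 3 + z + rnorm(n, sd = 0.05),
                     G2 = rnorm(n))
  colnames(lnc_expr) <- colnames(mir_expr) <- colnames(mrna_expr) <- samples
  lnc_sites <- data.frame(
    mirna = c("m1", "m2", "m3", "m1"),
    target = c("L1", "L1", "L2", "L3"),
    start = 0L, end = 21L, score = c(0, 1, 0, 0),
    confidence = c(1, 0.8, 1, 1), stringsAsFactors = FALSE)
  mrna_sites <- data.frame(
    mirna = c("m1", "m2", "m3"),
    target = c("G1", "G1", "G2"),
    start = 0L, end = 21L, score = 0, confidence = 1,
    stringsAsFactors = FALSE)
  mimic <- data.frame(lncrna = "L3", mirna = "m1", mimic = TRUE,
                      stringsAsFactors = FALSE)
  lnc_sets <- list(up = c("L1", "L2"), down = "L3")
  mir_sets <- list(up = character(0), down = c("m1", "m2", "m3"))
  list(lnc_expr = lnc_expr, mir_expr = mir_expr, mrna_expr = mrna_expr,
       lnc_sites = lnc_sites, mrna_sites = mrna_sites, mimic = mimic,
       lnc_sets = lnc_sets, mir_sets = mir_sets)
}

test_that("mirna_sets_from_sites applies the confidence floor", {
  ev <- make_evidence()
  sets <- mirna_sets_from_sites(ev$lnc_sites, min_confidence = 0.9)
  expect_setequal(sets$L1, "m1")  # m2 at 0.8 drops out
  expect_setequal(sets$L2, "m3")
  sets2 <- mirna_sets_from_sites(ev$lnc_sites, min_confidence = 0.5)
  expect_setequal(sets2$L1, c("m1", "m2"))
  expect_identical(mirna_sets_from_sites(ev$lnc_sites[0, ]), list())
})

test_that("shared_mre_test matches manual hypergeometric values", {
  lnc_sets <- list(L1 = c("m1", "m2", "m3"))
  mrna_sets <- list(G1 = c("m1", "m2", "m4", "m5"), G2 = c("m6"))
  universe <- paste0("m", 1:10)
  got <- shared_mre_test(lnc_sets, mrna_sets, universe)
  # only the x >= 1 pair is tested
  expect_identical(got$lncrna, "L1")
  expect_identical(got$mrna, "G1")
  expect_identical(got$x, 2L)
  expect_equal(got$pvalue, hyper_tail_enum(2, 10, 3, 4))
  expect_equal(got$pvalue, 70 / 210)
  expect_error(shared_mre_test(list(L1 = paste0("m", 1:5)), mrna_sets,
                               paste0("m", 1:3)), "larger than universe")
  empty <- shared_mre_test(list(L1 = "m1"), list(G1 = "m2"))
  expect_identical(nrow(empty), 0L)
})

test_that("lncrna_mirna_pairs applies each gate independently", {
  ev <- make_evidence()
  pairs <- lncrna_mirna_pairs(ev$lnc_sites, ev$mimic, ev$lnc_sets,
                              ev$mir_sets, ev$lnc_expr, ev$mir_expr)
  key <- paste(pairs$lncrna, pairs$mirna)
  # L1-m1 and L1-m2: all gates pass
  expect_true(all(pairs$pass[key %in% c("L1 m1", "L1 m2")]))
  # L2-m3: positively correlated, so the negative-correlation gate fails
  expect_false(pairs$pass[key == "L2 m3"])
  expect_false(pairs$r_ok[key == "L2 m3"])
  expect_true(pairs$dir_ok[key == "L2 m3"])
  # L3-m1: precursor mimic excluded
  expect_false(pairs$pass[key == "L3 m1"])
  expect_false(pairs$not_mimic[key == "L3 m1"])
  # disabling the sub-gates admits the correlation failure
  relaxed <- lncrna_mirna_pairs(ev$lnc_sites, ev$mimic, ev$lnc_sets,
                                ev$mir_sets, ev$lnc_expr, ev$mir_expr,
                                require_direction = FALSE,
                                require_negative_r = FALSE)
  expect_true(relaxed$pass[paste(relaxed$lncrna, relaxed$mirna) == "L2 m3"])
  # features that are not NR in the contrast are skipped entirely
  no_nr <- lncrna_mirna_pairs(ev$lnc_sites, ev$mimic,
                              list(up = "L1", down = character(0)),
                              list(up = character(0), down = "m1"),
                              ev$lnc_expr, ev$mir_expr)
  expect_identical(paste(no_nr$lncrna, no_nr$mirna), "L1 m1")
  expect_identical(nrow(lncrna_mirna_pairs(ev$lnc_sites[0, ], NULL,
                                           ev$lnc_sets, ev$mir_sets,
                                           ev$lnc_expr, ev$mir_expr)), 0L)
})

test_that("assemble_network retains the planted triplet only", {
  ev <- make_evidence()
  pairs <- lncrna_mirna_pairs(ev$lnc_sites, ev$mimic, ev$lnc_sets,
                              ev$mir_sets, ev$lnc_expr, ev$mir_expr)
  # test only the candidate decoy so the single shared-MRE p-value
  # (x = 2, K = 2, N = 2, M = 7 -> 1/21) clears the FDR gate
  lnc_mir <- mirna_sets_from_sites(ev$lnc_sites)["L1"]
  mrna_mir <- mirna_sets_from_sites(ev$mrna_sites)
  universe <- paste0("m", 1:7)
  shared <- shared_mre_test(lnc_mir, mrna_mir, universe)
  net <- assemble_network(pairs, ev$mrna_sites, shared, ev$lnc_expr,
                          ev$mrna_expr,
                          de_dirs = list(lncRNA = ev$lnc_sets,
                                         miRNA = ev$mir_sets,
                                         mRNA = list(up = "G1",
                                                     down = character(0))))
  expect_setequal(net$triplets$lncrna, "L1")
  expect_setequal(net$triplets$mirna, c("m1", "m2"))
  expect_setequal(net$triplets$mrna, "G1")
  expect_true(all(net$triplets$r_lnc_mrna >= 0.6))
  g <- net$network
  expect_setequal(igraph::V(g)$name, c("L1", "m1", "m2", "G1"))
  expect_setequal(igraph::V(g)$type[igraph::V(g)$name == "L1"], "lncRNA")
  expect_identical(igraph::V(g)$direction[igraph::V(g)$name == "G1"], "up")
  expect_setequal(unique(igraph::E(g)$etype),
                  c("decoy", "targets", "competes"))
})

test_that("assemble_network handles empty evidence", {
  ev <- make_evidence()
  empty_pairs <- lncrna_mirna_pairs(ev$lnc_sites[0, ], NULL, ev$lnc_sets,
                                    ev$mir_sets, ev$lnc_expr, ev$mir_expr)
  net <- assemble_network(empty_pairs, ev$mrna_sites[0, ],
                          shared_mre_test(list(), list()),
                          ev$lnc_expr, ev$mrna_expr)
  expect_identical(nrow(net$triplets), 0L)
  expect_equal(igraph::vcount(net$network), 0)
})

test_that("export_network writes parseable GraphML and SIF", {
  ev <- make_evidence()
  pairs <- lncrna_mirna_pairs(ev$lnc_sites, ev$mimic, ev$lnc_sets,
                              ev$mir_sets, ev$lnc_expr, ev$mir_expr)
  shared <- shared_mre_test(mirna_sets_from_sites(ev$lnc_sites)["L1"],
                            mirna_sets_from_sites(ev$mrna_sites),
                            paste0("m", 1:7))
  net <- assemble_network(pairs, ev$mrna_sites, shared, ev$lnc_expr,
                          ev$mrna_expr)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  export_network(net$network, gml, sif)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(net$network))
  expect_equal(igraph::ecount(back), igraph::ecount(net$network))
  lines <- readLines(sif)
  expect_equal(length(lines), as.integer(igraph::ecount(net$network)))
  expect_true(all(lengths(strsplit(lines, "\t")) == 3))
})
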