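test_that("reverse_complement handles DNA and RNA and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AACG"), "CGTT")
  expect_identical(reverse_complement("AACGU"), "ACGUU")
  set.seed(31)
  s <- random_seq(80, c("A", "C", "G", "T"))
  expect_identical(reverse_complement(reverse_complement(s)), s)
  r <- random_seq(80)
  expect_identical(reverse_complement(reverse_complement(r)), r)
})

test_that("a perfect complement site scores 0 with confidence 1", {
  set.seed(32)
  mir <- random_seq(21)
  target <- paste0(random_seq(60, c("A", "C")), perfect_site(mir),
                   random_seq(60, c("A", "C")))
  hit <- scan_mres(mir, target)
  exact <- hit[hit$score == 0, ]
  expect_identical(nrow(exact), 1L)
  expect_identical(exact$start, 60L)
  expect_identical(exact$end, 81L)
  expect_equal(exact$confidence, 1)
})

test_that("mismatch and wobble penalties follow the position-weighted rule", {
  set.seed(33)
  mir <- "UGACCUAGCAAGGUCAUCGAU"  # 21 nt
  site <- perfect_site(mir)
  pad <- function(core) paste0(strrep("A", 30), core, strrep("A", 30))
  flip <- function(core, p) {
    # corrupt the target base pairing miRNA position p to "C", which neither
    # pairs nor wobbles with the U (p = 1) and C (p = 5) bases used below;
    # the site index pairing miRNA position p is L - p + 1
    v <- strsplit(core, "")[[1]]
    v[nchar(core) - p + 1] <- "C"
    paste(v, collapse = "")
  }
  base <- scan_mres(mir, pad(site))$score[1]
  expect_equal(base, 0)
  # position 1 (outside 2-13): weight 1
  s1 <- scan_mres(mir, pad(flip(site, 1)))
  expect_equal(min(s1$score), 1)
  # position 5 (inside 2-13): weight 2
  s5 <- scan_mres(mir, pad(flip(site, 5)))
  expect_equal(min(s5$score), 2)
  # G:U wobble at position 5: miRNA G pairing target U, penalty 0.5 * 2
  p_g <- which(strsplit(mir, "")[[1]] == "G")
  p_g <- p_g[p_g >= 2 & p_g <= 13][1]
  v <- strsplit(site, "")[[1]]
  v[nchar(site) - p_g + 1] <- "U"
  sw <- scan_mres(mir, pad(paste(v, collapse = "")))
  expect_equal(min(sw$score), 1)
})

test_that("scan_mres equals the naive per-offset oracle on random input", {
  set.seed(34)
  for (k in 1:25) {
    mir <- random_seq(sample(18:26, 1))
    target <- random_seq(300)
    # also plant a near-perfect site in half the cases so hits exist
    if (k %% 2 == 0) {
      site <- perfect_site(mir)
      at <- sample(300 - nchar(site), 1)
      target <- paste0(substr(target, 1, at), site,
                       substr(target, at + nchar(site) + 1, 300))
    }
    expect_equal(scan_mres(mir, target), naive_scan_mres(mir, target))
  }
})

test_that("scan_mres is invariant to the T/U alphabet", {
  set.seed(35)
  mir <- random_seq(21)
  target <- paste0(random_seq(40), perfect_site(mir), random_seq(40))
  a <- scan_mres(mir, target)
  b <- scan_mres(chartr("U", "T", mir), chartr("U", "T", target))
  expect_equal(a, b)
})

test_that("scan_mres validates length and alphabet", {
  expect_error(scan_mres(random_seq(10), random_seq(100)), "18-26")
  expect_error(scan_mres(paste0(random_seq(20), "X"), random_seq(100)),
               "invalid character")
  # target shorter than the site: no hits
  expect_identical(nrow(scan_mres(random_seq(21), random_seq(10))), 0L)
})

test_that("scan_all_mres pools ids across pairs", {
  set.seed(36)
  mirs <- c(m1 = random_seq(21), m2 = random_seq(21))
  tg <- c(t1 = paste0(random_seq(30), perfect_site(mirs["m1"]),
                      random_seq(30)))
  got <- scan_all_mres(mirs, tg)
  expect_true(all(c("m1") %in% got$mirna))
  expect_true(all(got$target == "t1"))
  expect_error(scan_all_mres(unname(mirs), tg))
})

test_that("mutate_mre abolishes a planted site", {
  set.seed(37)
  mir <- random_seq(21)
  target <- paste0(random_seq(50), perfect_site(mir), random_seq(50))
  before <- scan_mres(mir, target)
  expect_gte(nrow(before), 1)
  mutated <- mutate_mre(target, before$start[1], before$end[1])
  expect_identical(nchar(mutated), nchar(target))
  after <- scan_mres(mir, mutated)
  expect_false(any(after$start == before$start[1] & after$score == 0))
})

test_that("precursor_mimic detects an embedded precursor fragment", {
  set.seed(38)
  pre <- random_seq(120)
  lnc_hit <- paste0(random_seq(100), substr(pre, 20, 90), random_seq(100))
  lnc_miss <- random_seq(300)
  expect_true(precursor_mimic(lnc_hit, pre))
  expect_false(precursor_mimic(lnc_miss, pre))
  # lncRNA shorter than the window can never mimic
  expect_false(precursor_mimic(random_seq(40), pre))
  expect_error(precursor_mimic(lnc_hit, random_seq(40)), "at least 55")
})

test_that("precursor_mimic handles the exact identity boundary", {
  set.seed(39)
  pre <- random_seq(60)
  # copy with mismatches at every 10th position: any window of length w >= 55
  # has at most ceiling(w/10) = 6 mismatches over w = 55..60; identity of the
  # full 60-window is 54/60 = 0.9 exactly -> mimic
  v <- strsplit(pre, "")[[1]]
  rot <- c(A = "C", C = "G", G = "U", U = "A")
  at <- seq(5, 60, by = 10)
  v[at] <- rot[v[at]]
  exact <- paste(v, collapse = "")
  expect_true(precursor_mimic(exact, pre))
  # mismatches at every 5th position: every 55+ window is ~20% mismatched
  v2 <- strsplit(pre, "")[[1]]
  at2 <- seq(3, 60, by = 5)
  v2[at2] <- rot[v2[at2]]
  dense <- paste(v2, collapse = "")
  expect_false(precursor_mimic(dense, pre))
})

test_that("precursor_mimic equals the brute-force window oracle", {
  set.seed(40)
  for (k in 1:12) {
    pre <- random_seq(60)
    lnc <- if (k %% 3 == 0) {
      paste0(random_seq(20), substr(pre, 1, 58), random_seq(20))
    } else if (k %% 3 == 1) {
      # noisy copy: random identity near the threshold
      v <- strsplit(pre, "")[[1]]
      at <- sample(60, sample(3:9, 1))
      rot <- c(A = "C", C = "G", G = "U", U = "A")
      v[at] <- rot[v[at]]
      paste0(random_seq(10), paste(v, collapse = ""), random_seq(10))
    } else {
      random_seq(90)
    }
    expect_identical(precursor_mimic(lnc, pre), naive_mimic(lnc, pre),
                     info = paste("case", k))
  }
})

test_that("precursor_mimic_table covers all pairs", {
  set.seed(41)
  pres <- c(p1 = random_seq(80), p2 = random_seq(80))
  lncs <- c(l1 = paste0(random_seq(30), pres[["p1"]], random_seq(30)),
            l2 = random_seq(140))
  tab <- precursor_mimic_table(lncs, pres)
  expect_identical(nrow(tab), 4L)
  expect_true(tab$mimic[tab$lncrna == "l1" & tab$mirna == "p1"])
  expect_false(tab$mimic[tab$lncrna == "l2" & tab$mirna == "p2"])
})
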