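test_that("overlap metrics match hand-computable cases", {
  # |P|=2, |G|=2, |P∩G|=1 on a 2x2 grid
  P <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  G <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_equal(dsc(P, G), 0.5)
  expect_equal(sen(P, G), 0.5)
  expect_equal(ppv(P, G), 0.5)
  expect_equal(voe(P, G), 1 - 1 / 3)
  expect_equal(rvd(P, G), 0)
  # specificity on a hand-worked 2x2 case: P={(0,0),(0,1)}, G={(0,1),(1,1)} -> TN={(1,0)}
  P2 <- matrix(0L, 2, 2); P2[1, 1] <- 1L; P2[1, 2] <- 1L
  G2 <- matrix(0L, 2, 2); G2[1, 2] <- 1L; G2[2, 2] <- 1L
  expect_equal(spe(P2, G2), 0.5)
})

test_that("metric conventions for identical, disjoint and degenerate masks", {
  m <- random_mask(8, 8, 0.4)
  nonempty <- m; nonempty[1] <- 1L
  expect_equal(dsc(nonempty, nonempty), 1)
  expect_equal(voe(nonempty, nonempty), 0)
  expect_equal(rvd(nonempty, nonempty), 0)
  expect_equal(spe(nonempty, nonempty), 1)
  disj_a <- matrix(0L, 4, 4); disj_a[1, 1] <- 1L
  disj_b <- matrix(0L, 4, 4); disj_b[4, 4] <- 1L
  expect_equal(dsc(disj_a, disj_b), 0)
  expect_equal(voe(disj_a, disj_b), 1)
  empty <- matrix(0L, 4, 4)
  expect_equal(dsc(empty, empty), 1)   # declared convention
  expect_equal(voe(empty, empty), 0)
  expect_true(is.na(sen(disj_a, empty)))
  expect_true(is.na(rvd(disj_a, empty)))
  expect_true(is.na(ppv(empty, disj_b)))
  expect_equal(rvd(empty, disj_b), -1) # empty prediction lower bound
  # complement prediction: union covers everything -> specificity 0
  expect_equal(spe(1L - disj_b, disj_b), 0)
  # printed-formula audit variant lacks the factor 2
  expect_equal(dsc(nonempty, nonempty, printed_formula = TRUE), 0.5)
})

test_that("metrics agree with per-pixel loop oracles on random masks", {
  set.seed(101)
  for (i in 1:200) {
    P <- random_mask(16, 16, runif(1, 0.05, 0.6))
    G <- random_mask(16, 16, runif(1, 0.05, 0.6))
    ct <- oracle_counts(P, G)
    if (ct$tp + ct$fn > 0) expect_equal(sen(P, G), ct$tp / (ct$tp + ct$fn))
    if (ct$tp + ct$fp > 0) expect_equal(ppv(P, G), ct$tp / (ct$tp + ct$fp))
    if (ct$tn + ct$fp > 0) expect_equal(spe(P, G), ct$tn / (ct$tn + ct$fp))
    den <- 2 * ct$tp + ct$fp + ct$fn
    if (den > 0) expect_equal(dsc(P, G), 2 * ct$tp / den)
    un <- ct$tp + ct$fp + ct$fn
    if (un > 0) expect_equal(voe(P, G), 1 - ct$tp / un)
    if (ct$tp + ct$fn > 0)
      expect_equal(rvd(P, G), (ct$tp + ct$fp - ct$tp - ct$fn) / (ct$tp + ct$fn))
    # DSC = 2J/(1+J) with J the Jaccard index (consistency identity)
    if (un > 0) {
      J <- 1 - voe(P, G)
      expect_equal(dsc(P, G), 2 * J / (1 + J), tolerance = 1e-12)
    }
  }
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test", {
  # complete separation with n = m = 4: 2 of the 70 assignments are as extreme
  expect_equal(round(mann_whitney_exact(1:4, 5:8), 3), 0.029)
  expect_equal(mann_whitney_exact(1:4, 5:8), 2 / 70)
  # single identical value per group: only one distinguishable split
  expect_equal(mann_whitney_exact(3, 3), 1)
  # symmetry
  set.seed(11)
  a <- rnorm(5); b <- rnorm(4)
  expect_equal(mann_whitney_exact(a, b), mann_whitney_exact(b, a))
  # tie-free samples: must agree with the exact test in stats::wilcox.test
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(3)
    expect_equal(mann_whitney_exact(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # brute-force enumeration oracle for n = m = 3 (20 assignments)
  brute <- function(a, b) {
    pooled <- c(a, b)
    r <- rank(pooled)
    n1 <- length(a)
    mu <- n1 * length(b) / 2
    dev <- function(idx) abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mu)
    obs <- dev(seq_len(n1))
    combs <- utils::combn(length(pooled), n1)
    mean(apply(combs, 2, dev) >= obs - 1e-9)
  }
  for (i in 1:20) {
    a <- sample(1:5, 3, replace = TRUE)  # with ties
    b <- sample(1:5, 3, replace = TRUE)
    expect_equal(mann_whitney_exact(a, b), brute(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney_exact(numeric(0), 1), "empty")
})

test_that("directory evaluation pairs files and aggregates", {
  pd <- withr::local_tempdir()
  gd <- withr::local_tempdir()
  set.seed(3)
  for (i in 1:4) {
    m <- random_mask(16, 16, 0.3)
    png::writePNG(m + 0, file.path(pd, sprintf("m%02d.png", i)))
    png::writePNG(m + 0, file.path(gd, sprintf("m%02d.png", i)))
  }
  rep <- evaluate(pd, gd)
  expect_equal(nrow(rep), 4)
  expect_true(all(c("dsc", "sen", "spe", "ppv", "voe", "rvd") %in% names(rep)))
  expect_equal(unname(attr(rep, "means")[["dsc"]]), 1)
  expect_equal(unname(attr(rep, "means")[["voe"]]), 0)
  # orphan file is an error naming it
  png::writePNG(random_mask(16, 16) + 0, file.path(pd, "orphan.png"))
  expect_error(evaluate(pd, gd), "orphan")
})
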