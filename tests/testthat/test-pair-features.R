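test_that("auroc reproduces hand-worked and brute-force values", {
  expect_equal(auroc(c(3, 4, 5), c(1, 2)), 1.0)
  expect_equal(auroc(c(1, 2), c(1, 2)), 0.5)
  # 9 comparisons, one tie: 5.5/9
  expect_equal(auroc(c(2, 3, 5), c(1, 3, 4)), 5.5 / 9)
  expect_error(auroc(numeric(0), 1), "non-empty")
})

test_that("auroc equals exhaustive pair counting on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    n1 <- sample(1:50, 1); n0 <- sample(1:50, 1)
    # coarse grid forces plenty of ties
    cases <- sample(1:8, n1, replace = TRUE)
    controls <- sample(1:8, n0, replace = TRUE)
    expect_equal(auroc(cases, controls), bruteAuroc(cases, controls))
    # antisymmetry under group swap
    expect_equal(auroc(cases, controls), 1 - auroc(controls, cases))
  }
  # agreement with the rank-sum statistic as an independent library check
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25)
  w <- suppressWarnings(wilcox.test(x, y))$statistic
  expect_equal(auroc(x, y), unname(w) / (30 * 25))
})

test_that("pair screening matches an independent Mann-Whitney count", {
  set.seed(13)
  sig <- 2^matrix(rnorm(6 * 20, rep(runif(6, 8, 11), 20), 0.4), 6, 20,
                  dimnames = list(paste0("p", 1:6), paste0("s", 1:20)))
  is_case <- rep(c(TRUE, FALSE), each = 10)
  pairs <- evaluatePairs(BloodExpressionSet(sig), is_case)
  expect_equal(nrow(pairs), 15 * 2)  # all 15 pairs in both modes
  expect_false(any(pairs$probe_a == pairs$probe_b))
  expect_true(all(pairs$auroc >= 0.5))
  l2 <- log2(sig)
  for (i in seq_len(nrow(pairs))) {
    f <- if (pairs$mode[i] == "ratio")
      l2[pairs$probe_a[i], ] - l2[pairs$probe_b[i], ]
    else log2(sig[pairs$probe_a[i], ] + sig[pairs$probe_b[i], ])
    u <- bruteAuroc(f[is_case], f[!is_case])
    expect_equal(pairs$auroc[i], max(u, 1 - u))
    expect_identical(pairs$oriented[i], u < 0.5)
  }
})

test_that("shared multiplicative confounder: ratio informative, singles not", {
  cohort <- confoundedPairCohort()
  sig <- signals(cohort$es); is_case <- cohort$is_case
  l2 <- log2(sig)
  ua <- bruteAuroc(l2["pa", is_case], l2["pa", !is_case])
  ub <- bruteAuroc(l2["pb", is_case], l2["pb", !is_case])
  expect_lt(abs(ua - 0.5), 0.15)
  expect_lt(abs(ub - 0.5), 0.15)
  pairs <- evaluatePairs(cohort$es, is_case, modes = "ratio")
  expect_identical(pairs$klass, "significant")
  expect_gt(pairs$auroc, 0.95)
})

test_that("orientation flips feature sign and AUROC exactly", {
  set.seed(33)
  sig <- 2^matrix(rnorm(2 * 16, 9, 0.5), 2, 16,
                  dimnames = list(c("a", "b"), paste0("s", 1:16)))
  is_case <- rep(c(TRUE, FALSE), 8)
  l2 <- log2(sig)
  u_ab <- auroc((l2["a", ] - l2["b", ])[is_case],
                (l2["a", ] - l2["b", ])[!is_case])
  u_ba <- auroc((l2["b", ] - l2["a", ])[is_case],
                (l2["b", ] - l2["a", ])[!is_case])
  expect_equal(u_ab, 1 - u_ba)
  p <- data.frame(probe_a = "a", probe_b = "b", mode = "ratio",
                  oriented = TRUE)
  f_flip <- pairFeatureValues(sig, p)
  p$oriented <- FALSE
  expect_equal(drop(f_flip), -drop(pairFeatureValues(sig, p)))
})

test_that("ratio features are invariant to per-sample scaling", {
  set.seed(17)
  sig <- 2^matrix(rnorm(4 * 12, 9, 0.5), 4, 12,
                  dimnames = list(paste0("p", 1:4), paste0("s", 1:12)))
  pairs <- data.frame(probe_a = c("p1", "p2"), probe_b = c("p3", "p4"),
                      mode = "ratio", oriented = c(FALSE, TRUE))
  f0 <- pairFeatureValues(sig, pairs)
  scale <- runif(12, 0.1, 10)
  f1 <- pairFeatureValues(sweep(sig, 2, scale, `*`), pairs)
  expect_equal(f0, f1, tolerance = 1e-12)
  # sum features do NOT have this property
  spair <- data.frame(probe_a = "p1", probe_b = "p3", mode = "sum",
                      oriented = FALSE)
  expect_false(isTRUE(all.equal(pairFeatureValues(sig, spair),
                                pairFeatureValues(sig * 2, spair))))
})

test_that("sum pairs need a complementary-noise AUROC gain", {
  # pa and pb carry the same signal with anti-correlated noise: the sum
  # cancels the noise and beats either single probe
  set.seed(55)
  n <- 60; is_case <- rep(c(TRUE, FALSE), each = n / 2)
  eps <- rnorm(n, 0, 0.6)
  la <- 9 + 0.4 * is_case + eps
  lb <- 9 + 0.4 * is_case - eps
  sig <- rbind(pa = 2^la, pb = 2^lb)
  colnames(sig) <- paste0("s", 1:n)
  pairs <- evaluatePairs(BloodExpressionSet(sig), is_case, modes = "sum")
  expect_identical(pairs$klass, "significant")
  expect_gt(pairs$sum_gain, 0.05)
  # uncorrelated-noise probes: no gain, so no significant sum pair
  lc <- 9 + 0.4 * is_case + rnorm(n, 0, 0.6)
  ld <- 9 + 0.4 * is_case + rnorm(n, 0, 0.6)
  sig2 <- rbind(pc = 2^lc, pd = 2^ld)
  colnames(sig2) <- paste0("s", 1:n)
  pairs2 <- evaluatePairs(BloodExpressionSet(sig2), is_case,
                          modes = "sum", sum_margin = 0.2)
  expect_identical(pairs2$klass, "neither")
})

test_that("screening requires positive signals and two probes", {
  sig <- matrix(c(0, 10, 20, 30), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(evaluatePairs(sig, c(TRUE, FALSE)), "filter")
  expect_error(
    evaluatePairs(matrix(100, 1, 4, dimnames = list("a", paste0("s", 1:4))),
                  rep(c(TRUE, FALSE), 2)), "2 retained probes")
})

test_that("suppressor rule: near-0.5 AUROC plus correlation with a significant pair", {
  set.seed(77)
  n <- 400; is_case <- rep(c(TRUE, FALSE), each = n / 2)
  conf <- rnorm(n, 0, 1)
  # m/ref: disease shift contaminated by the confounder -> significant
  lm_ <- 9 + 1.2 * is_case + conf + rnorm(n, 0, 0.2)
  lref <- 9 + rnorm(n, 0, 0.2)
  # u1/u2: confounder only -> AUROC ~ 0.5, correlated with m/ref feature
  lu1 <- 9 + conf + rnorm(n, 0, 0.2)
  lu2 <- 9 + rnorm(n, 0, 0.2)
  sig <- rbind(m = 2^lm_, ref = 2^lref, u1 = 2^lu1, u2 = 2^lu2)
  colnames(sig) <- paste0("s", 1:n)
  pairs <- evaluatePairs(BloodExpressionSet(sig), is_case, modes = "ratio")
  feats <- pairFeatureValues(sig, pairs)
  pairs <- findSuppressors(pairs, feats)
  lab <- pairLabels(pairs)
  expect_identical(pairs$klass[lab == "m/ref"], "significant")
  expect_identical(pairs$klass[lab %in% c("u1/u2", "u2/u1")], "suppressor")
  # an AUROC >= 0.7 pair can never be a suppressor, whatever its correlation
  expect_false(any(pairs$klass == "suppressor" &
                     abs(pairs$auroc - 0.5) > 0.05))

  # with the suppressor included, a logistic panel generalizes better
  set.seed(78)
  conf2 <- rnorm(n, 0, 1)
  lm2 <- 9 + 1.2 * is_case + conf2 + rnorm(n, 0, 0.2)
  lref2 <- 9 + rnorm(n, 0, 0.2)
  lu12 <- 9 + conf2 + rnorm(n, 0, 0.2)
  lu22 <- 9 + rnorm(n, 0, 0.2)
  test_sig <- rbind(m = 2^lm2, ref = 2^lref2, u1 = 2^lu12, u2 = 2^lu22)
  colnames(test_sig) <- paste0("t", 1:n)
  keep <- lab %in% c("m/ref", "u1/u2", "u2/u1")
  p_both <- fitPanel(feats[keep, , drop = FALSE], is_case,
                     pairs[keep, , drop = FALSE])
  p_sig <- fitPanel(feats[lab == "m/ref", , drop = FALSE], is_case,
                    pairs[lab == "m/ref", , drop = FALSE])
  s_both <- panelScore(p_both, test_sig)
  s_sig <- panelScore(p_sig, test_sig)
  expect_gt(auroc(s_both[is_case], s_both[!is_case]),
            auroc(s_sig[is_case], s_sig[!is_case]))
})

test_that("no significant pairs yields a warning and no suppressors", {
  pairs <- data.frame(probe_a = "a", probe_b = "b", mode = "ratio",
                      oriented = FALSE, auroc = 0.51, klass = "neither")
  f <- matrix(rnorm(10), 1, 10)
  expect_warning(out <- findSuppressors(pairs, f), "no significant")
  expect_false(any(out$klass == "suppressor"))
})
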