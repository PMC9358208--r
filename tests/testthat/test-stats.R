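test_that("midrank Spearman agrees with the base implementation, ties included", {
  set.seed(101)
  for (i in 1:20) {
    x <- sample(0:6, 13, replace = TRUE)   # discrete, tied, Likert-like
    y <- rnorm(13) + x
    if (sd(x) == 0) next
    expect_equal(spearman(x, y), cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_equal(spearman(1:10, 1:10), 1.0)
  expect_error(spearman(rep(1, 5), 1:5), class = "ich_domain_error")
  expect_error(spearman(1:4, 1:5), class = "ich_domain_error")
  expect_error(spearman(1:2, 2:1), class = "ich_domain_error")
})

test_that("Spearman equals the d^2 shortcut on tie-free data and behaves under transforms", {
  set.seed(7)
  for (i in 1:10) {
    x <- sample(100, 9); y <- sample(100, 9)
    d <- rank(x) - rank(y)
    shortcut <- 1 - 6 * sum(d^2) / (9^3 - 9)
    expect_equal(spearman(x, y), shortcut, tolerance = 1e-12)
    # invariant under strictly increasing transforms, antisymmetric under reversal
    expect_equal(spearman(exp(x / 50), y), spearman(x, y))
    expect_equal(spearman(-x, y), -spearman(x, y))
  }
})

test_that("all orderings of (1,2,3) match the exhaustive rank-correlation oracle", {
  y <- c(10, 20, 30)
  oracle <- function(x, y) {            # enumeration-based rank correlation
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
    expect_equal(spearman(p, y), oracle(p, y))
})

test_that("permutation p-values agree with full enumeration and cor.test", {
  expect_equal(as.numeric(spearman_p(0, 10)), 1.0)
  x <- c(3, 1, 4, 5, 2); y <- c(2, 1, 3, 5, 4)
  r <- spearman(x, y)
  # independent oracle: cor.test's exact Spearman p (full 120-permutation null)
  ct <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(spearman_p(r, 5, method = "exact_perm"), unname(ct$p.value))
  # t-approximation p is monotone decreasing in |r| at fixed n
  ps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r) as.numeric(spearman_p(r, 13)), 0)
  expect_true(all(diff(ps) < 0))
  degenerate <- spearman_p(1, 8)
  expect_equal(as.numeric(degenerate), 0)
  expect_true(attr(degenerate, "degenerate"))
})

test_that("Bonferroni correction multiplies and clamps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_error(bonferroni(0.1, 0), class = "ich_domain_error")
  ms <- vapply(1:10, function(m) bonferroni(0.02, m), 0)
  expect_true(all(diff(ms) >= 0))
})

test_that("Fisher-z power reaches 0.8 at rho 0.71 with n 13 and is monotone", {
  expect_gte(correlation_power(0.71, 13, 0.05), 0.80)
  expect_equal(correlation_power(0, 13), 0.025)  # alpha/2 per tail under the null
  pn <- vapply(c(8, 13, 20, 50), function(n) correlation_power(0.6, n), 0)
  expect_true(all(diff(pn) > 0))
  pr <- vapply(c(0.3, 0.5, 0.7, 0.9), function(r) correlation_power(r, 13), 0)
  expect_true(all(diff(pr) > 0))
  expect_error(correlation_power(0.5, 3), class = "ich_domain_error")
})

test_that("Mann-Whitney exact p matches enumeration and wilcox.test", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_two_sided, 0.1)  # 2/20 assignments are as extreme
  expect_equal(mw$method, "exact")
  set.seed(11)
  for (i in 1:10) {
    a <- sample(1000, 5); b <- sample(2000, 5)
    if (any(duplicated(c(a, b)))) next
    got <- mann_whitney(a, b, method = "exact")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(got$u_statistic, unname(ref$statistic))
    expect_equal(got$p_two_sided, unname(ref$p.value))
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "ich_domain_error")
})

test_that("normal-approximation p tracks the exact p within 0.02 on tie-free draws", {
  set.seed(23)
  done <- 0
  while (done < 8) {
    a <- rnorm(6); b <- rnorm(6) + 0.5
    if (any(duplicated(c(a, b)))) next
    ex <- mann_whitney(a, b, method = "exact")$p_two_sided
    ap <- mann_whitney(a, b, method = "approx")$p_two_sided
    expect_lt(abs(ex - ap), 0.02)
    done <- done + 1
  }
  # identical multisets: U = n^2/2 and p in the no-evidence region
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$u_statistic, 8)
  expect_gte(same$p_two_sided, 0.9)
})

test_that("Hedge's g applies the chosen small-sample correction", {
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3) + 0), 0)
  expect_equal(hedges_g(c(1, 2, 3), c(4, 5, 6), "standard_J"), -2.4)  # d=-3, J=0.8
  expect_equal(hedges_g(c(1, 2, 3), c(4, 5, 6), "fixed_percent", q = 0.04),
               -3 * 0.96)
  set.seed(3)
  a <- rnorm(8); b <- rnorm(9, 1)
  d <- (mean(a) - mean(b)) / sqrt(((7) * var(a) + 8 * var(b)) / 15)
  expect_lte(abs(hedges_g(a, b)), abs(d))
  expect_error(hedges_g(rep(1, 4), rep(1, 4)), class = "ich_domain_error")
})

test_that("composite markers sum components with counts on the K/uL scale", {
  co <- ich_cohort()
  expect_equal(composite_marker(co, "ich_score"), co$ich_score)
  expect_equal(composite_marker(co, c("ich_score", "nlr")), co$ich_score + co$nlr)
  expect_equal(composite_marker(co, c("ich_score", "rogue_n_count")),
               co$ich_score + co$rogue_n_count / 1000)
  expect_error(composite_marker(co, "not_a_column"), class = "ich_config_error")
  co2 <- co; co2$nlr[co2$id == 5] <- NA
  expect_error(composite_marker(co2, c("ich_score", "nlr")), "id 5",
               class = "ich_validation_error")
})

test_that("the correlation report classifies strength as specified", {
  co <- ich_cohort()
  rep1 <- correlation_report(co, rbind(c("iph_vol", "phe_vol")), m = 15)
  expect_equal(round(rep1$r, 2), 0.78)
  expect_equal(rep1$strength_class, "strong")
  # a self-pair is perfectly correlated and strong for any admissible m
  for (m in c(1, 10, 100)) {
    selfp <- correlation_report(co, rbind(c("gcs", "gcs")), m = m)
    expect_equal(selfp$r, 1)
    expect_equal(selfp$strength_class, "strong")
  }
  # p_bonf >= p_raw always
  rep3 <- severity_table3(co, m = 15)
  expect_true(all(rep3$p_bonf >= rep3$p_raw))
  expect_true(all(abs(rep3$r) <= 1))
})
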