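glm_fixture <- function(xi_ctrl, tot_ctrl, xi_trt, tot_trt) {
  n_c <- length(xi_ctrl); n_t <- length(xi_trt)
  sheet <- make_sheet(dox_days = c(rep(0, n_c), rep(21, n_t)))
  r <- make_ratios(rep("g1", n_c + n_t), sheet$sample_id,
                   xi = c(xi_ctrl, xi_trt),
                   xa = c(tot_ctrl - xi_ctrl, tot_trt - xi_trt))
  fit_binomial_glm(r, sheet, c("untreated", "dox21d"))
}

test_that("identical groups give a null treatment effect", {
  res <- glm_fixture(c(50L, 50L), c(100L, 100L), c(50L, 50L), c(100L, 100L))
  expect_equal(res$beta_treatment, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_true(res$estimable)
})

test_that("boundary groups (all-zero or all-total Xi) are not estimable", {
  res0 <- glm_fixture(c(30L, 28L), c(100L, 100L), c(0L, 0L), c(100L, 100L))
  expect_false(res0$estimable)
  expect_true(is.na(res0$p_value))
  res1 <- glm_fixture(c(30L, 28L), c(100L, 100L), c(100L, 100L), c(100L, 100L))
  expect_false(res1$estimable)
})

test_that("GLM matches an independent Newton logistic-MLE oracle", {
  set.seed(101)
  for (i in 1:12) {
    n_c <- sample(1:3, 1); n_t <- sample(1:3, 1)
    tot_c <- sample(50:300, n_c, replace = TRUE)
    tot_t <- sample(50:300, n_t, replace = TRUE)
    xi_c <- rbinom(n_c, tot_c, runif(1, 0.15, 0.6))
    xi_t <- rbinom(n_t, tot_t, runif(1, 0.05, 0.5))
    if (sum(xi_c) == 0 || sum(xi_t) == 0 ||
        sum(xi_c) == sum(tot_c) || sum(xi_t) == sum(tot_t)) next
    res <- glm_fixture(xi_c, tot_c, xi_t, tot_t)
    orc <- oracle_binom_glm(c(xi_c, xi_t), c(tot_c, tot_t),
                            c(rep(0, n_c), rep(1, n_t)))
    expect_equal(res$beta_treatment, orc$beta, tolerance = 1e-6)
    expect_equal(res$p_value, orc$p_value, tolerance = 1e-6)
  }
})

test_that("swapping the contrast negates beta and keeps the p value", {
  sheet <- make_sheet(dox_days = c(0, 0, 21, 21))
  r <- make_ratios(rep("g1", 4), sheet$sample_id,
                   xi = c(40L, 35L, 12L, 15L), xa = c(60L, 70L, 90L, 88L))
  fwd <- fit_binomial_glm(r, sheet, c("untreated", "dox21d"))
  rev <- fit_binomial_glm(r, sheet, c("dox21d", "untreated"))
  expect_equal(fwd$beta_treatment, -rev$beta_treatment, tolerance = 1e-9)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-9)
  expect_error(fit_binomial_glm(r, sheet, c("untreated", "dox3d")),
               class = "xe_config_error")
})

test_that("Holm and BH adjustment match brute-force textbook procedures", {
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.03, "holm"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), class = "xe_value_error")

  set.seed(7)
  for (i in 1:60) {
    m <- sample(1:25, 1)
    p <- round(runif(m), sample(1:4, 1))  # rounding induces ties
    expect_equal(adjust_pvalues(p, "holm"), oracle_holm(p))
    expect_equal(adjust_pvalues(p, "benjamini_hochberg"), oracle_bh(p))
    # Holm is always at least as powerful as one-step Bonferroni
    expect_true(all(adjust_pvalues(p, "holm") <= pmin(1, m * p) + 1e-12))
  }

  # NA propagation: family size counts only observed p values
  p <- c(0.01, NA, 0.04)
  out <- adjust_pvalues(p, "holm")
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], oracle_holm(c(0.01, 0.04)))
})

test_that("silencing calls require significance and a >= 50% ratio reduction", {
  tests <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                      condition_control = "untreated",
                      condition_treated = "dox21d",
                      estimable = TRUE,
                      p_adjusted = c(0.001, 0.001, 0.2, 0.001))
  cm <- data.frame(
    gene_id = rep(c("gA", "gB", "gC", "gD"), each = 2),
    condition_label = rep(c("untreated", "dox21d"), 4),
    mean_ratio = c(0.40, 0.15,  0.40, 0.30,  0.40, 0.10,  0, 0.10))
  out <- call_silencing(tests, cm)
  sil <- setNames(out$silenced_by_dox, out$gene_id)
  expect_true(sil[["gA"]])                    # reduction 0.625, significant
  expect_false(sil[["gB"]])                   # reduction 0.25 < 0.5
  expect_false(sil[["gC"]])                   # not significant
  expect_false(sil[["gD"]])                   # control mean 0 -> undefined
  expect_false(out$reduction_defined[out$gene_id == "gD"])
  expect_equal(out$reduction_fraction[out$gene_id == "gA"], 0.625)
})

test_that("moving treated ratios toward control never creates a silencing call", {
  tests <- data.frame(gene_id = "g", condition_control = "untreated",
                      condition_treated = "dox21d", estimable = TRUE,
                      p_adjusted = 0.001)
  treated_means <- seq(0.05, 0.40, by = 0.05)
  calls <- vapply(treated_means, function(tm) {
    cm <- data.frame(gene_id = "g",
                     condition_label = c("untreated", "dox21d"),
                     mean_ratio = c(0.40, tm))
    call_silencing(tests, cm)$silenced_by_dox
  }, TRUE)
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("group comparisons agree with exact rank-sum enumeration", {
  x <- c(1.2, 1.2, 1.2, 1.2)
  out <- compare_categories(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(out$p_value, 1)

  set.seed(33)
  for (i in 1:8) {
    x <- rnorm(4); y <- rnorm(5)
    res <- compare_categories(c(x, y), rep(c("a", "b"), c(4, 5)))
    expect_equal(res$p_value, oracle_wilcox_exact(x, y), tolerance = 1e-12)
  }
  expect_error(compare_categories(rnorm(5), rep(c("a", "b"), c(3, 2)),
                                  paired = TRUE), class = "xe_value_error")
})

test_that("rank-sum test detects a one-sd shift at n = 50", {
  set.seed(99)
  hits <- vapply(1:100, function(i) {
    x <- rnorm(50); y <- rnorm(50, mean = 1)
    compare_categories(c(x, y), rep(c("a", "b"), each = 50))$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("escape-Xist correlation matches the closed-form coefficient", {
  x <- c(1, 2, 3, 4)
  out <- correlate_escape_xist(-x, x)
  expect_equal(out$r, -1)
  expect_error(correlate_escape_xist(rep(0.3, 4), x),
               class = "xe_value_error")
  expect_error(correlate_escape_xist(x[1:2], x[1:2]), class = "xe_value_error")

  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    out <- correlate_escape_xist(a, b)
    expect_equal(out$r, oracle_pearson(b, a), tolerance = 1e-12)
  }
})
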