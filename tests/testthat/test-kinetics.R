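test_that("noiseless decay curves are recovered essentially exactly", {
  t <- rep(c(0, 3, 7, 14, 21), each = 2)
  a <- 0.4; k <- log(2) / 3; b <- 0.1
  ratio <- a * exp(-k * t) + b
  fit <- fit_decay(t, ratio, "offset")
  expect_true(fit$converged)
  expect_equal(fit$a, 0.4, tolerance = 1e-4)
  expect_equal(fit$k, 0.2310, tolerance = 1e-3)
  expect_equal(fit$b, 0.1, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("degenerate trajectories are flagged, not fitted", {
  t <- rep(c(0, 3, 7, 14, 21), each = 2)
  flat <- fit_decay(t, rep(0.3, length(t)), "offset")
  expect_false(flat$converged)
  expect_equal(flat$reason, "zero_variance")
  sel <- select_model(flat, fit_decay(t, rep(0.3, length(t)), "no_offset"))
  expect_equal(sel$selected_model, "unreliable")
  expect_true(is.na(sel$half_life_days))

  expect_error(fit_decay(c(0, 3), c(0.4, 0.2), "offset"),
               class = "xe_insufficient_data_error")
})

test_that("half-life is ln(2)/k with a guarded domain", {
  expect_identical(half_life(log(2)), 1)
  expect_equal(half_life(0.1), 6.9315, tolerance = 1e-4)
  expect_error(half_life(0), class = "xe_value_error")
  expect_error(half_life(-1), class = "xe_value_error")
  k <- exp(seq(log(0.01), log(5), length.out = 7))
  expect_equal(half_life(k) * k, rep(log(2), 7))
})

test_that("BIC selection penalizes the offset and breaks ties toward no_offset", {
  mkfit <- function(model, rss, n = 15) {
    list(model = model, a = 0.4, k = 0.2, b = 0.05, rss = rss,
         r_squared = 0.9, n_obs = n, converged = TRUE,
         reason = NA_character_)
  }
  # identical RSS: the extra parameter can only hurt -> no_offset
  sel <- select_model(mkfit("offset", 0.01), mkfit("no_offset", 0.01))
  expect_equal(sel$selected_model, "no_offset")
  expect_false(sel$residual_escape)
  # a large enough RSS improvement flips the decision
  sel2 <- select_model(mkfit("offset", 0.001), mkfit("no_offset", 0.01))
  expect_equal(sel2$selected_model, "offset")
  expect_true(sel2$residual_escape)
})

test_that("offset fit never has higher RSS than the nested no-offset fit", {
  set.seed(21)
  for (i in 1:20) {
    tr <- simulate_trajectory(runif(1, 0.25, 0.6), runif(1, 0.08, 0.8),
                              sample(c(0, 0.2), 1), depth = 200)
    off <- fit_decay(tr$t, tr$ratio, "offset")
    no <- fit_decay(tr$t, tr$ratio, "no_offset")
    if (off$converged && no$converged) {
      expect_lte(off$rss, no$rss + 1e-9)
    }
  }
})

test_that("fitted minima are not beaten by a dense profile-grid search", {
  set.seed(8)
  for (i in 1:6) {
    tr <- simulate_trajectory(runif(1, 0.3, 0.6), runif(1, 0.1, 0.7),
                              sample(c(0, 0.15), 1), depth = 300)
    for (model in c("offset", "no_offset")) {
      fit <- fit_decay(tr$t, tr$ratio, model)
      expect_true(fit$converged)
      best <- oracle_decay_best_rss(tr$t, tr$ratio, model == "offset")
      expect_lte(fit$rss, best + 1e-8)
    }
  }
})

test_that("rescaling time rescales k and preserves fit quality and selection", {
  set.seed(12)
  tr <- simulate_trajectory(0.5, 0.3, 0.12, depth = 400)
  f1o <- fit_decay(tr$t, tr$ratio, "offset")
  f1n <- fit_decay(tr$t, tr$ratio, "no_offset")
  cc <- 2.5
  f2o <- fit_decay(tr$t * cc, tr$ratio, "offset")
  f2n <- fit_decay(tr$t * cc, tr$ratio, "no_offset")
  expect_equal(f2o$k, f1o$k / cc, tolerance = 1e-4)
  expect_equal(f2o$b, f1o$b, tolerance = 1e-5)
  expect_equal(f2o$r_squared, f1o$r_squared, tolerance = 1e-6)
  s1 <- select_model(f1o, f1n)
  s2 <- select_model(f2o, f2n)
  expect_equal(s2$selected_model, s1$selected_model)
  expect_equal(s2$half_life_days, s1$half_life_days * cc, tolerance = 1e-3)
})

test_that("decay constants are recovered from binomial-noise trajectories", {
  set.seed(14)
  rel_err <- vapply(1:12, function(i) {
    k_true <- runif(1, 0.1, 0.6)
    tr <- simulate_trajectory(runif(1, 0.3, 0.6), k_true, 0, depth = 200)
    sel <- select_model(fit_decay(tr$t, tr$ratio, "offset"),
                        fit_decay(tr$t, tr$ratio, "no_offset"))
    abs(sel$k - k_true) / k_true
  }, 0)
  expect_lt(median(rel_err), 0.15)
})

test_that("neighbouring genes with shared kinetics give a small permutation p", {
  # clustered layout: genes inside a cluster share their decay constant
  set.seed(31)
  n_cl <- 5; per <- 4
  genes <- sprintf("g%02d", seq_len(n_cl * per))
  start <- unlist(lapply(seq_len(n_cl), function(c)
    (c - 1) * 1e6 + (seq_len(per) - 1) * 3e4))
  ann <- make_annotation(genes, start)
  k_cl <- runif(n_cl, 0.1, 0.9)
  hl <- log(2) / rep(k_cl, each = per) * exp(rnorm(n_cl * per, 0, 0.05))
  fits <- data.frame(gene_id = genes, selected_model = "no_offset",
                     half_life_days = hl)
  res <- neighbor_similarity_test(fits, ann, n_permutations = 500, seed = 2)
  expect_true(res$applicable)
  expect_lt(res$p_value, 0.05)
  # seeded determinism
  res2 <- neighbor_similarity_test(fits, ann, n_permutations = 500, seed = 2)
  expect_identical(res$p_value, res2$p_value)

  # degenerate: all half-lives equal -> observed 0 but never "significant"
  fits$half_life_days <- 3
  dg <- neighbor_similarity_test(fits, ann, n_permutations = 200, seed = 2)
  expect_equal(dg$observed_statistic, 0)
  expect_equal(dg$p_value, 1)
  expect_error(neighbor_similarity_test(fits, ann), class = "xe_config_error")
})
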