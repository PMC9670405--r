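test_that("the L-method recovers an exact two-segment knee with zero error", {
  e <- generate_elbow_points(knee = 40, left_slope = 2, right_slope = 0,
                             noise_sd = 0, xs = 1:80)
  res <- l_method(e$xs, e$ys)
  expect_equal(res$knee_x, 40)
  expect_equal(min(res$error_profile$total_error), 0, tolerance = 1e-9)
  # appending a long plateau far right leaves the knee unchanged
  e2 <- list(xs = c(e$xs, 81:160), ys = c(e$ys, rep(e$ys[80], 80)))
  expect_equal(l_method(e2$xs, e2$ys)$knee_x, 40)
  expect_error(l_method(1:3, 1:3), "at least 4")
})

test_that("a single straight line yields a flat profile and a warning", {
  expect_warning(res <- l_method(1:20, 2 * (1:20) + 1), "flat")
  expect_equal(res$knee_x, 2) # smallest candidate
  expect_lt(max(res$error_profile$total_error), 1e-9)
})

test_that("the L-method matches a brute-force split scan on noisy curves", {
  set.seed(91)
  for (i in 1:20) {
    e <- generate_elbow_points(knee = sample(10:60, 1), left_slope = runif(1, 0.5, 3),
                               right_slope = runif(1, 0, 0.2),
                               noise_sd = 0.05, xs = 1:80, seed = i)
    got <- l_method(e$xs, e$ys)
    ref <- l_method_reference(e$xs, e$ys)
    expect_equal(got$knee_x, ref$knee_x)
    expect_equal(got$error_profile$total_error, ref$total_error,
                 tolerance = 1e-8)
  }
})

test_that("the knee is scale-equivariant in y", {
  e <- generate_elbow_points(35, 1.5, 0.05, noise_sd = 0.03, xs = 1:70,
                             seed = 4)
  expect_equal(l_method(e$xs, e$ys)$knee_x,
               l_method(e$xs, 7.3 * e$ys)$knee_x)
})

test_that("the sigmoid fit recovers noiseless 4PL parameters", {
  m <- 5:100
  truth <- list(A = 0.5, K = 0.98, M = 20, B = 0.3)
  U <- truth$A + (truth$K - truth$A) / (1 + exp(-truth$B * (m - truth$M)))
  fit <- fit_sigmoid(data.frame(m = m, U = U))
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$A, truth$A, tolerance = 1e-3)
  expect_equal(fit$K, truth$K, tolerance = 1e-3)
  expect_equal(fit$M, truth$M, tolerance = 1e-2)
  expect_equal(fit$B, truth$B, tolerance = 1e-2)
  expect_lte(fit$K, 1)
  # fitted curve is non-decreasing
  expect_true(all(diff(predict(fit, seq(5, 100, by = 0.5))) >= 0))
})

test_that("degenerate constant curves refuse to fit and fall back to raw", {
  pts <- data.frame(m = 5:30, U = rep(1, 26))
  fit <- fit_sigmoid(pts)
  expect_false(fit$converged)
  expect_warning( # the raw fallback then warns again about the flat profile
    expect_warning(res <- find_inflection(pts, mode = "fitted"),
                   "falling back"),
    "flat")
  expect_equal(res$mode, "raw")
  expect_error(fit_sigmoid(data.frame(m = 1:4, U = 1:4 / 4)), "at least 5")
})

test_that("raw and fitted modes agree on noiseless sigmoid samples", {
  m <- 2:60
  U <- 0.4 + 0.58 / (1 + exp(-0.45 * (m - 12)))
  pts <- data.frame(m = m, U = U)
  raw <- find_inflection(pts, "raw")
  fitted <- find_inflection(pts, "fitted")
  expect_equal(fitted$knee_m, raw$knee_m, tolerance = 1)
  # bookkeeping: reported U is the curve value at the knee
  expect_equal(raw$U_at_knee, U[match(raw$knee_m, m)])
  expect_equal(fitted$U_at_knee,
               predict(fitted$fit, fitted$knee_m), tolerance = 1e-9)
})

test_that("sparse schedules move the fitted knee by at most 2", {
  m <- 2:60
  set.seed(93)
  U <- pmin(1, 0.4 + 0.58 / (1 + exp(-0.45 * (m - 12))) + rnorm(59, 0, 0.004))
  dense <- find_inflection(data.frame(m = m, U = U), "fitted")
  idx <- seq(1, length(m), by = 3)
  sparse <- find_inflection(data.frame(m = m[idx], U = U[idx]), "fitted")
  expect_lte(abs(dense$knee_m - sparse$knee_m), 2)
})

test_that("robustness replicates are counted, seeded and summarized", {
  spec <- benchmark_scenario("k8_wellsep")
  mat <- subsample(generate_mixture(spec), 0.25, seed = 1)
  cfg <- inflect_config(som_k = 36, schedule = seq(2, 16, by = 2), seed = 1)
  rep <- replicate_robustness(mat, cfg, fraction = 0.8, R = 3, base_seed = 5)
  expect_length(rep$knees, 3)
  expect_equal(rep$sem, sd(rep$knees) / sqrt(3))
  expect_equal(rep$seeds, 5 + 1:3)
  expect_true(rep$min <= rep$mean && rep$mean <= rep$max)
  expect_length(rep$knees_raw, 3)
  expect_length(rep$unimodality_sets, 3)
  expect_error(replicate_robustness(mat, cfg, R = 1), "at least 2")
})
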