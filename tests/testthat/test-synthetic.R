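test_that("mixture draws respect weights, truncation and determinism", {
  pops <- list(list(name = "a", weight = 0.5, mean = c(1, 2), sd = c(0.3, 0.3)),
               list(name = "b", weight = 0.5, mean = c(3, 0), sd = c(0.3, 0.3)))
  spec <- mixture_spec(10000, pops, c("X", "Y"), seed = 11)
  m <- generate_mixture(spec)
  counts <- table(m$labels)
  expect_true(all(abs(counts - 5000) <= 3 * sqrt(10000 * 0.25)))
  expect_true(all(m$values >= 0)) # truncated at zero
  expect_identical(generate_mixture(spec)$values, m$values)
  expect_error(mixture_spec(10, list(list(name = "a", weight = -1,
                                          mean = 0, sd = 1)), "X"),
               "non-negative")
  expect_error(mixture_spec(10, list(list(name = "a", weight = 1,
                                          mean = 0, sd = 0)), "X"),
               "positive")
})

test_that("label-conditional means match the spec within 3 standard errors", {
  spec <- benchmark_scenario("k8_wellsep")
  m <- generate_mixture(spec)
  for (p in c(1, 4, 8)) {
    sp <- spec$populations[[p]]
    idx <- m$labels == sp$name
    n <- sum(idx)
    got <- colMeans(m$values[idx, ])
    # clamping at zero shifts a mean-0 marker to E[max(N(0, sd), 0)] = sd/sqrt(2*pi)
    expect_mean <- ifelse(sp$mean == 0, 0.3 / sqrt(2 * pi), sp$mean)
    expect_true(all(abs(got - expect_mean) < 3 * 0.3 / sqrt(n) + 1e-3))
  }
})

test_that("tight single populations pass the QC in most draws", {
  passes <- 0
  for (s in 1:20) {
    pops <- list(list(name = "a", weight = 1, mean = rep(2, 3),
                      sd = rep(0.3, 3)))
    m <- generate_mixture(mixture_spec(2000, pops, paste0("M", 1:3)), seed = s)
    qc <- evaluate_metaclustering(m, rep(1L, 2000))
    passes <- passes + all(qc$pass)
  }
  expect_gte(passes / 20, 0.9)
})

test_that("rare populations are present in every draw at realistic sizes", {
  spec <- benchmark_scenario("k20_with_rare")
  for (s in 1:5) {
    m <- generate_mixture(spec, seed = s)
    counts <- table(factor(m$labels, levels = sprintf("pop%02d", 1:20)))
    expect_true(all(counts[c("pop19", "pop20")] >= 1))
    # expected ~250 events each at weight 0.005 of 50000
    expect_true(all(abs(counts[c("pop19", "pop20")] - 250) < 100))
  }
})

test_that("scenario specs are frozen and structurally correct", {
  s1 <- benchmark_scenario("k8_wellsep")
  expect_identical(s1, benchmark_scenario("k8_wellsep")) # bit-identical
  expect_length(s1$populations, 8)
  expect_equal(s1$n_events, 20000L)
  # pairwise population separation at least 4
  mu <- t(vapply(s1$populations, `[[`, numeric(5), "mean"))
  seps <- as.matrix(dist(mu))
  expect_gte(min(seps[upper.tri(seps)]), 4)
  s2 <- benchmark_scenario("k8_with_bimodal")
  expect_equal(s2$populations[[8]]$bimodal, c(M5 = 3))
  s3 <- benchmark_scenario("k20_with_rare")
  expect_length(s3$populations, 20)
  expect_equal(sum(vapply(s3$populations, `[[`, numeric(1), "weight")), 1)
  expect_error(benchmark_scenario("nope"))
})

test_that("bimodal offsets split a marker into two modes the dip catches", {
  spec <- benchmark_scenario("k8_with_bimodal")
  m <- generate_mixture(spec)
  x <- m$values[m$labels == "pop08", "M5"]
  expect_lt(dip_pvalue(dip_statistic(x), length(x), "table"), 0.001)
  # roughly half the events carry the offset
  expect_equal(mean(x > 1.5), 0.5, tolerance = 0.05)
})

test_that("elbow generator is exact at zero noise and degenerate when equal", {
  e <- generate_elbow_points(40, 2, 0, 0, xs = 1:80)
  expect_equal(l_method(e$xs, e$ys)$knee_x, 40)
  ed <- generate_elbow_points(40, 1, 1, 0, xs = 1:80)
  expect_warning(l_method(ed$xs, ed$ys), "flat") # single straight line
  expect_error(generate_elbow_points(90, 1, 0, 0, xs = 1:80), "within")
})
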