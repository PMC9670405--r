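test_that("IQR check follows the linear-interpolation quartile convention", {
  expect_equal(iqr_check(rep(1.3, 10)), list(iqr = 0, pass = TRUE))
  r <- iqr_check(c(0, 0, 0, 2.5, 2.5, 2.5))
  expect_equal(r$iqr, 2.5) # Q1 = 0, Q3 = 2.5 under p*(n-1)+1 positioning
  expect_false(r$pass)     # default threshold is 2
  expect_true(iqr_check(c(0, 2, 2, 2), threshold = 2)$pass) # boundary passes
  expect_error(iqr_check(numeric(0)), "empty")
})

test_that("QC matrices have m x n shape and calibrated pass behavior", {
  set.seed(81)
  n <- 3 * 2000
  part <- rep(1:3, each = 2000)
  vals <- matrix(rnorm(n * 4, 1.5, 0.3), n, 4) # tight unimodal everywhere
  vals[part == 2, 3] <- c(rnorm(1000, 1, 0.3), rnorm(1000, 5, 0.3)) # bimodal
  em <- expression_matrix(pmax(vals, 0), paste0("M", 1:4))
  qc <- evaluate_metaclustering(em, part)
  expect_equal(dim(qc$pass), c(3L, 4L))
  expect_false(qc$pass[2, 3])          # the planted bimodal cell fails
  expect_lt(qc$dip_p[2, 3], 0.05)
  expect_true(all(qc$pass[-c(2 + 3 * 2)])) # every other cell passes
  expect_equal(qc$U, 11 / 12)
  expect_equal(unimodality_fraction(qc), qc$U)
})

test_that("a single tight population passes everywhere with U = 1", {
  set.seed(82)
  em <- expression_matrix(pmax(matrix(rnorm(2000 * 3, 2, 0.3), 2000, 3), 0),
                          paste0("M", 1:3))
  qc <- evaluate_metaclustering(em, rep(1L, 2000))
  expect_true(all(qc$pass))
  expect_equal(qc$U, 1)
})

test_that("dip rejects planted separation-4 bimodality with high power", {
  set.seed(83)
  hits <- 0
  for (i in 1:40) {
    x <- c(rnorm(1000, 2, 1), rnorm(1000, 6, 1)) # 4 sd-units apart
    hits <- hits + (dip_pvalue(dip_statistic(x), 2000, "table") < 0.05)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("U is invariant to marker order and metacluster relabeling", {
  set.seed(84)
  em <- expression_matrix(matrix(rnorm(900 * 3, 2, 0.4), 900, 3),
                          c("A", "B", "C"))
  part <- sample(1:3, 900, TRUE)
  qc1 <- evaluate_metaclustering(em, part)
  qc2 <- evaluate_metaclustering(em, c(2L, 3L, 1L)[part],
                                 qc_markers = c("C", "A", "B"))
  expect_equal(qc1$U, qc2$U)
})

test_that("tiny cells are flagged as passes and small clusters still count", {
  set.seed(85)
  em <- expression_matrix(matrix(rnorm(103, 2, 0.3), 103, 1), "A")
  part <- c(rep(1L, 100), rep(2L, 3)) # cluster 2 below min_events
  qc <- evaluate_metaclustering(em, part, min_events = 5)
  expect_true(qc$flagged[2, 1])
  expect_true(qc$pass[2, 1])
  expect_true(is.na(qc$dip_p[2, 1]))
  expect_false(qc$flagged[1, 1])
  # empty metacluster ids drop out of the denominator
  part2 <- c(rep(1L, 100), rep(3L, 3))
  qc2 <- evaluate_metaclustering(em, part2)
  expect_equal(qc2$m_realized, 2L)
  expect_equal(qc2$U, 1)
  expect_error(evaluate_metaclustering(em, part, qc_markers = "Z"),
               "unknown QC marker")
})

test_that("U is monotone in the QC thresholds", {
  # pass requires dip_p >= alpha AND iqr <= threshold: relaxing the IQR limit
  # can only raise U, while raising alpha is stricter and can only lower it
  set.seed(86)
  vals <- cbind(c(rnorm(600, 1, 1.2), rnorm(600, 3.4, 1.2)),
                rnorm(1200, 2, 0.8))
  em <- expression_matrix(pmax(vals, 0), c("A", "B"))
  part <- rep(1:3, 400)
  grid_alpha <- c(0.01, 0.05, 0.2)
  grid_iqr <- c(1, 2, 3)
  Us <- sapply(grid_alpha, function(a) sapply(grid_iqr, function(thr)
    evaluate_metaclustering(em, part, alpha = a, iqr_threshold = thr)$U))
  expect_true(all(apply(Us, 1, diff) <= 0)) # non-increasing in alpha
  expect_true(all(apply(Us, 2, diff) >= 0)) # non-decreasing in threshold
})

test_that("the unimodality set orders targets and rejects duplicates", {
  mk <- function(m, U) structure(list(m = m, U = U), class = "qc_matrix")
  uset <- assemble_unimodality_set(list(mk(20, 0.9), mk(5, 0.5), mk(10, 0.7)))
  expect_equal(uset$m, c(5, 10, 20))
  expect_equal(uset$U, c(0.5, 0.7, 0.9))
  expect_error(assemble_unimodality_set(list()), "no QC")
  expect_error(assemble_unimodality_set(list(mk(5, 0.5), mk(5, 0.6))),
               "duplicate")
})

test_that("marker performance curves average back to U", {
  set.seed(87)
  em <- expression_matrix(pmax(matrix(rnorm(1500 * 3, 2, 0.5), 1500, 3), 0),
                          c("A", "B", "C"))
  qcs <- lapply(c(2, 3, 5), function(m)
    evaluate_metaclustering(em, rep_len(seq_len(m), 1500)))
  perfA <- marker_performance(qcs, "A")
  expect_equal(perfA$m, c(2, 3, 5))
  expect_true(all(perfA$fraction >= 0 & perfA$fraction <= 1))
  avg <- Reduce(`+`, lapply(c("A", "B", "C"),
                            function(j) marker_performance(qcs, j)$fraction)) / 3
  expect_equal(avg, vapply(qcs, `[[`, numeric(1), "U"))
  expect_error(marker_performance(qcs, "Z"), "absent")
})
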