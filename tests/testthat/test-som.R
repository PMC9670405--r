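test_that("grid_from_k factorizes as squarely as possible", {
  expect_equal(grid_from_k(225)[c("rows", "cols")], list(rows = 15L, cols = 15L))
  expect_equal(grid_from_k(375)[c("rows", "cols")], list(rows = 15L, cols = 25L))
  expect_equal(grid_from_k(10)[c("rows", "cols")], list(rows = 2L, cols = 5L))
  expect_error(grid_from_k(3), ">= 4")
  # small primes keep a 1 x k strip; large primes round up to a composite
  expect_equal(grid_from_k(7)[c("rows", "cols")], list(rows = 1L, cols = 7L))
  suppressMessages(g <- grid_from_k(23))
  expect_equal(g$k, 24L)
  expect_equal(g$rows * g$cols, 24L)
})

test_that("training is shaped, seeded and reproducible", {
  set.seed(31)
  em <- expression_matrix(matrix(rnorm(500 * 3), 500, 3))
  s1 <- train_som(em, 4, 5, epochs = 3, seed = 9)
  s2 <- train_som(em, 4, 5, epochs = 3, seed = 9)
  expect_equal(dim(s1$codebook), c(20L, 3L))
  expect_identical(s1$codebook, s2$codebook) # bit-identical
  s3 <- train_som(em, 4, 5, epochs = 3, seed = 10)
  expect_false(identical(s1$codebook, s3$codebook))
  expect_error(train_som(subsample(em, 0.03, 1), 4, 5), "at least as many")
})

test_that("the SOM settles on replicated far-apart points", {
  pts <- as.matrix(expand.grid(c(0, 10, 20), c(0, 10, 20))) # min distance 10
  em <- expression_matrix(pts[rep(1:9, each = 50), ], c("A", "B"))
  som <- train_som(em, 3, 3, epochs = 10, seed = 1)
  qe <- assign_events(som, em)$quantization_error
  expect_lt(qe, 1) # under 10% of the minimal inter-point distance
})

test_that("training never worsens the seed-initialized fit", {
  set.seed(33)
  em <- expression_matrix(matrix(rnorm(2000 * 4, sample(0:4, 8000, TRUE)),
                                 2000, 4))
  som <- train_som(em, 5, 5, epochs = 5, seed = 2)
  init <- fake_som(em$values[som$init_idx, , drop = FALSE], em$marker_names)
  expect_lte(assign_events(som, em)$quantization_error,
             assign_events(init, em)$quantization_error)
})

test_that("assignment maps to nearest node with low-index ties", {
  cb <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1))
  som <- fake_som(cb, c("A", "B"))
  em <- expression_matrix(rbind(cb[5, ],      # exact hit -> node 5
                                c(0.5, 0)),   # equidistant nodes 1 and 2
                          c("A", "B"))
  asg <- assign_events(som, em)
  expect_equal(asg$node_of_event, c(5L, 1L))
  expect_equal(sum(asg$node_sizes), 2L)
  # idempotence: codebook rows assign to themselves
  self <- assign_events(som, expression_matrix(cb, c("A", "B")))
  expect_equal(self$node_of_event, 1:6)
  expect_error(assign_events(som, expression_matrix(cb, c("A", "C"))),
               "marker sets")
})

test_that("nodes are pure on a well-separated mixture", {
  pops <- lapply(1:4, function(p)
    list(name = paste0("p", p), weight = 0.25,
         mean = c(10 * (p %% 2), 10 * (p %/% 3), 5), sd = rep(0.3, 3)))
  m <- generate_mixture(mixture_spec(4000, pops, c("x", "y", "z"), seed = 5))
  som <- train_som(m, 4, 4, seed = 2)
  asg <- assign_events(som, m)
  purity <- vapply(seq_len(som$k), function(g) {
    idx <- asg$node_of_event == g
    if (!any(idx)) return(1)
    max(table(m$labels[idx])) / sum(idx)
  }, numeric(1))
  expect_equal(min(purity), 1)
})
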