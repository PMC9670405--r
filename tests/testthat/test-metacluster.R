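test_that("the default target ladder follows the documented steps and caps", {
  s <- build_schedule(375, max_m = 320, backend = "hierarchical")
  expect_equal(s$targets, c(5:50, seq(55, 150, by = 5), seq(160, 320, by = 10)))
  expect_equal(s$cap, 375L)
  # consensus cap at 90% of the node count
  s2 <- build_schedule(100, max_m = 95, backend = "consensus")
  expect_equal(s2$cap, 90L)
  expect_equal(max(s2$targets), 90L)
  expect_error(build_schedule(100, backend = "consensus", explicit = c(10, 91)),
               "90%")
  expect_equal(build_schedule(100, explicit = c(10, 5, 10, 20))$targets,
               c(5L, 10L, 20L))
})

test_that("hierarchical cuts hit the trivial ends and the brute-force optimum", {
  set.seed(71)
  centers <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  cb <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(9, 0, 0.2), 3), 2, centers[i, ], "+")))
  som <- fake_som(cb)
  expect_equal(hierarchical_metacluster(som, som$k)$metacluster_of_node,
               1:som$k) # every node its own metacluster
  expect_equal(hierarchical_metacluster(som, 1)$metacluster_of_node,
               rep(1L, som$k))
  expect_error(hierarchical_metacluster(som, 0), "m must be")
  got <- hierarchical_metacluster(som, 4)$metacluster_of_node
  best <- best_ward_partition(cb, 4)$assignment
  expect_equal(canonical_partition(got), canonical_partition(best))
})

test_that("cuts from one dendrogram are nested and merge costs monotone", {
  set.seed(72)
  som <- fake_som(matrix(rnorm(30 * 4), 30, 4))
  results <- lapply(2:29, function(m) hierarchical_metacluster(som, m))
  for (i in seq_len(length(results) - 1)) {
    fine <- results[[i + 1]]$metacluster_of_node  # m + 1 clusters
    coarse <- results[[i]]$metacluster_of_node    # m clusters
    # each coarse cluster is a union of fine clusters
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  h <- stats::hclust(stats::dist(som$codebook), method = "ward.D2")
  expect_true(all(diff(h$height) >= -1e-9))
})

test_that("hierarchical cut matches a reference Ward implementation", {
  set.seed(73)
  som <- fake_som(matrix(rnorm(25 * 3), 25, 3))
  for (m in c(2, 5, 11)) {
    ref <- stats::cutree(stats::hclust(stats::dist(som$codebook), "ward.D2"), m)
    got <- hierarchical_metacluster(som, m)$metacluster_of_node
    expect_equal(canonical_partition(got), canonical_partition(unname(ref)))
  }
})

test_that("consensus matrices verify the Monti invariants", {
  set.seed(74)
  som <- fake_som(matrix(rnorm(24 * 3), 24, 3))
  cm <- consensus_metacluster(som, 4, reps = 40, seed = 3)$consensus
  v <- cm$values
  expect_equal(v, t(v))
  expect_equal(diag(v), rep(1, 24))
  expect_true(all(v >= 0 & v <= 1))
  # denominator definition on a hand-checkable co-draw count
  expect_identical(consensus_metacluster(som, 4, reps = 40, seed = 3)$consensus$values,
                   v) # deterministic given seed
})

test_that("consensus separates far groups with near-certain co-clustering", {
  set.seed(75)
  cb <- rbind(sweep(matrix(rnorm(30, 0, 0.3), 10), 2, c(0, 0, 0), "+"),
              sweep(matrix(rnorm(30, 0, 0.3), 10), 2, c(20, 0, 0), "+"))
  som <- fake_som(cb)
  out <- consensus_metacluster(som, 2, reps = 50, seed = 4)
  v <- out$consensus$values
  grp <- rep(1:2, each = 10)
  between <- v[grp == 1, grp == 2]
  within <- c(v[grp == 1, grp == 1][lower.tri(diag(10))],
              v[grp == 2, grp == 2][lower.tri(diag(10))])
  expect_equal(max(between), 0)
  expect_true(all(within >= 0.95))
  expect_equal(canonical_partition(out$result$metacluster_of_node),
               canonical_partition(grp))
  expect_error(consensus_metacluster(som, 19), "90%")
})

test_that("event lists compose the two maps into a partition", {
  asg <- structure(list(node_of_event = c(1L, 2L, 2L, 3L, 4L, 4L),
                        node_sizes = c(1L, 2L, 1L, 2L)),
                   class = "node_assignment")
  res <- structure(list(m_target = 2L, metacluster_of_node = c(1L, 1L, 2L, 2L),
                        backend = "hierarchical"),
                   class = "metacluster_result")
  lists <- events_per_metacluster(res, asg)
  expect_equal(lists[[1]], 1:3) # union of node 1 and node 2 events
  expect_equal(lists[[2]], 4:6)
  expect_equal(sort(unlist(lists)), 1:6) # partition of all events
  # identity map: metacluster sizes equal node sizes
  id <- structure(list(m_target = 4L, metacluster_of_node = 1:4,
                       backend = "hierarchical"),
                  class = "metacluster_result")
  expect_equal(lengths(events_per_metacluster(id, asg)), asg$node_sizes)
})
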