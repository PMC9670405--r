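# Independent reference implementations used as oracles. These deliberately
# take the slow, direct route (explicit enumeration of constraints / splits /
# partitions) so they share no code path with the package.

# Dip statistic by direct chord enumeration on the ECDF tube, O(K^3).
# A unimodal CDF within distance d of the ECDF must pass through
# [B_j - d, A_j + d] at every unique value u_j; convex-side feasibility of a
# prefix requires every chord of the upper bounds to clear the lower bounds,
# and mirrored for the concave suffix. Modes between points and at points
# (where a CDF atom absorbs one constraint) are both enumerated.
dip_reference <- function(sample) {
  x <- sort(as.numeric(sample)); n <- length(x)
  r <- rle(x); u <- r$values; K <- length(u)
  Bc <- cumsum(r$lengths) / n; Ac <- c(0, Bc[-K])
  P <- Po <- numeric(K)
  prev <- 0
  for (t in 1:K) {
    dev_all <- -Inf; dev_excl <- -Inf
    for (aa in 1:t) {
      js <- aa:t
      denom <- u[t] - u[aa]
      chord <- if (denom == 0) rep(Ac[t], length(js))
               else Ac[aa] + (Ac[t] - Ac[aa]) * (u[js] - u[aa]) / denom
      dev <- Bc[js] - chord
      dev_all <- max(dev_all, dev)
      if (any(js < t)) dev_excl <- max(dev_excl, dev[js < t])
    }
    P[t] <- max(prev, dev_all)
    Po[t] <- max(prev, dev_excl, 0)
    prev <- P[t]
  }
  S <- So <- numeric(K)
  nxt <- 0
  for (t in K:1) {
    dev_all <- -Inf; dev_excl <- -Inf
    for (bb in t:K) {
      js <- t:bb
      denom <- u[bb] - u[t]
      chord <- if (denom == 0) rep(Bc[t], length(js))
               else Bc[t] + (Bc[bb] - Bc[t]) * (u[js] - u[t]) / denom
      dev <- chord - Ac[js]
      dev_all <- max(dev_all, dev)
      if (any(js > t)) dev_excl <- max(dev_excl, dev[js > t])
    }
    S[t] <- max(nxt, dev_all)
    So[t] <- max(nxt, dev_excl, 0)
    nxt <- S[t]
  }
  best <- Inf
  for (t in 0:K) {
    left <- if (t >= 1) P[t] else 0
    right <- if (t + 1 <= K) S[t + 1] else 0
    best <- min(best, max(left, right))
  }
  for (t in 1:K) best <- min(best, max(Po[t], So[t]))
  max(0.5 * best, 1 / (2 * n))
}

# L-method by brute force: ordinary lm() per side for every admissible split.
l_method_reference <- function(xs, ys) {
  b <- length(xs)
  total <- sapply(2:(b - 1), function(c) {
    left <- lm(y ~ x, data.frame(x = xs[1:c], y = ys[1:c]))
    right <- lm(y ~ x, data.frame(x = xs[c:b], y = ys[c:b]))
    rl <- sqrt(mean(resid(left)^2))
    rr <- sqrt(mean(resid(right)^2))
    ((c - 1) * rl + (b - c) * rr) / (b - 1)
  })
  list(knee_x = xs[(2:(b - 1))[which.min(total)]], total_error = total)
}

# Exhaustive minimum-Ward-cost partition into exactly g groups, by recursive
# enumeration of restricted growth strings with branch-and-bound pruning on
# the (monotone) within-group sum of squares.
best_ward_partition <- function(X, g) {
  n <- nrow(X); d <- ncol(X)
  assign <- integer(n)
  best_cost <- Inf; best_assign <- NULL
  gsum <- matrix(0, g, d); gsq <- numeric(g); gn <- integer(g)
  cost_now <- 0
  recurse <- function(i, used) {
    if (cost_now >= best_cost) return()
    if (i > n) {
      if (used == g) { best_cost <<- cost_now; best_assign <<- assign[1:n] }
      return()
    }
    if (g - used > n - i + 1) return() # not enough items left to fill groups
    x <- X[i, ]
    for (grp in seq_len(min(used + 1, g))) {
      old_n <- gn[grp]; old_sum <- gsum[grp, ]; old_sq <- gsq[grp]
      new_n <- old_n + 1
      new_sum <- old_sum + x
      new_sq <- old_sq + sum(x^2)
      old_cost <- if (old_n > 0) old_sq - sum(old_sum^2) / old_n else 0
      new_cost <- new_sq - sum(new_sum^2) / new_n
      delta <- new_cost - old_cost
      gn[grp] <<- new_n; gsum[grp, ] <<- new_sum; gsq[grp] <<- new_sq
      cost_now <<- cost_now + delta
      assign[i] <<- grp
      recurse(i + 1, max(used, grp))
      gn[grp] <<- old_n; gsum[grp, ] <<- old_sum; gsq[grp] <<- old_sq
      cost_now <<- cost_now - delta
    }
  }
  recurse(1, 0)
  list(assignment = best_assign, cost = best_cost)
}

# normalize a partition to canonical labels (order of first appearance)
canonical_partition <- function(p) as.integer(factor(p, levels = unique(p)))

# fabricate a som_model around a given codebook (for backend-only tests)
fake_som <- function(codebook, marker_names = colnames(codebook)) {
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(codebook)))
  colnames(codebook) <- marker_names
  structure(list(codebook = codebook, rows = nrow(codebook), cols = 1L,
                 k = nrow(codebook), epochs = 0L, seed = 0L,
                 marker_names = marker_names),
            class = "som_model")
}
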