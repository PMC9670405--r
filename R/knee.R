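#' L-method knee detection
#'
#' Salvador-Chan knee finding: every admissible split of the curve into a left
#' and a right part (at least two points each, sharing the split point) gets
#' an ordinary least-squares line per side; the total error is the
#' segment-length-weighted RMSE
#' `((c - 1) * rmse_left + (b - c) * rmse_right) / (b - 1)` for a split at
#' point `c` of `b`. The knee is the split with the least total error; ties
#' resolve to the smallest x (fewer clusters, more statistical power).
#'
#' @param xs strictly increasing x positions (at least 4).
#' @param ys y values.
#' @return A list with `knee_x`, `knee_index`, and `error_profile` (data frame
#'   of candidate `x` and `total_error`).
#' @export
l_method <- function(xs, ys) {
  b <- length(xs)
  if (b < 4) stop("l_method needs at least 4 points")
  if (length(ys) != b) stop("xs and ys lengths differ")
  if (any(diff(xs) <= 0)) stop("xs must be strictly increasing")

  # prefix sums give each side's OLS residual sum of squares in O(1)
  cx <- cumsum(xs); cy <- cumsum(ys)
  cxx <- cumsum(xs^2); cyy <- cumsum(ys^2); cxy <- cumsum(xs * ys)
  sse <- function(i, j) { # OLS SSE over points i..j (j - i + 1 >= 2)
    n <- j - i + 1
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    vx <- sxx - sx^2 / n
    vy <- syy - sy^2 / n
    vxy <- sxy - sx * sy / n
    max(0, vy - vxy^2 / vx)
  }
  cands <- 2:(b - 1)
  total <- vapply(cands, function(c) {
    rl <- sqrt(sse(1, c) / c)
    rr <- sqrt(sse(c, b) / (b - c + 1))
    ((c - 1) * rl + (b - c) * rr) / (b - 1)
  }, numeric(1))
  if (diff(range(total)) < 1e-12)
    warning("flat L-method error profile (curve has no knee); ",
            "returning the smallest candidate")
  best <- cands[which.min(total)] # which.min takes the first, i.e. smallest x
  list(knee_x = xs[best], knee_index = best,
       error_profile = data.frame(x = xs[cands], total_error = total))
}

#' Fit a four-parameter logistic to the unimodality set
#'
#' Least-squares fit of `U(x) = A + (K - A) / (1 + exp(-B * (x - M)))` with
#' `A` in `[0, 1]`, `K` in `[A, 1]`, `B` in `(0, 10]` and `M` within the
#' evaluated range, initialized from the data (A = min U, K = max U, M at the
#' half-rise, B = 0.1). On optimizer failure or a degenerate (constant) curve
#' the fit is returned with `converged = FALSE` rather than raising, and the
#' caller falls back to raw-mode knee detection.
#'
#' @param points a `unimodality_set` (or data frame with columns `m`, `U`)
#'   with at least 5 points.
#' @return An object of class `sigmoid_fit`: parameters `A`, `K`, `M`, `B`,
#'   `rmse`, `converged`, and `predict(fit, x)` support.
#' @export
fit_sigmoid <- function(points) {
  if (nrow(points) < 5) stop("sigmoid fit needs at least 5 points")
  x <- points$m
  y <- points$U
  out <- list(A = NA_real_, K = NA_real_, M = NA_real_, B = NA_real_,
              rmse = NA_real_, converged = FALSE)
  class(out) <- "sigmoid_fit"
  if (stats::sd(y) < 1e-12) return(out) # constant curve: no sigmoid
  A0 <- min(y); K0 <- max(y)
  M0 <- x[which.min(abs(y - (A0 + K0) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(U ~ A + (K - A) / (1 + exp(-B * (m - M))),
                      data = data.frame(m = x, U = y),
                      start = list(A = A0, K = K0, B = 0.1, M = M0),
                      lower = c(A = 0, K = 0, B = 1e-4, M = min(x)),
                      upper = c(A = 1, K = 1, B = 10, M = max(x)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  p <- stats::coef(fit)
  if (p[["K"]] < p[["A"]] - 1e-8) return(out)
  out$A <- unname(p[["A"]]); out$K <- unname(p[["K"]])
  out$B <- unname(p[["B"]]); out$M <- unname(p[["M"]])
  out$rmse <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- TRUE
  out
}

#' @export
predict.sigmoid_fit <- function(object, x, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  object$A + (object$K - object$A) / (1 + exp(-object$B * (x - object$M)))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("sigmoid_fit: A=%.4f K=%.4f M=%.2f B=%.4f (rmse %.2e)\n",
                x$A, x$K, x$M, x$B, x$rmse))
  else cat("sigmoid_fit: not converged\n")
  invisible(x)
}

#' Locate the inflection point of the unimodality curve
#'
#' In `"fitted"` mode (the default, and the more stable choice on noisy
#' curves) a four-parameter logistic is fitted to the set, evaluated at every
#' integer metacluster number spanning the evaluated targets, and the
#' L-method applied to that dense curve; sparse schedules therefore still
#' yield integer knees. In `"raw"` mode (also the fallback when the sigmoid
#' does not converge) the L-method runs on the evaluated points directly.
#'
#' @param points a `unimodality_set` with at least 5 points.
#' @param mode `"fitted"` or `"raw"`.
#' @return An object of class `inflection_result`: `knee_m`, `U_at_knee`,
#'   `mode` (the mode actually used), `error_profile`, and `fit` (the
#'   `sigmoid_fit`, or NULL in raw mode).
#' @export
find_inflection <- function(points, mode = c("fitted", "raw")) {
  mode <- match.arg(mode)
  if (nrow(points) < 5) stop("need at least 5 evaluated targets")
  fit <- NULL
  if (mode == "fitted") {
    fit <- fit_sigmoid(points)
    if (!fit$converged) {
      warning("sigmoid fit did not converge; falling back to raw mode")
      mode <- "raw"
      fit <- NULL
    }
  }
  if (mode == "fitted") {
    xs <- seq(min(points$m), max(points$m))
    ys <- predict(fit, xs)
  } else {
    xs <- points$m
    ys <- points$U
  }
  lm_res <- l_method(xs, ys)
  knee_m <- as.integer(lm_res$knee_x)
  structure(list(knee_m = knee_m,
                 U_at_knee = ys[lm_res$knee_index],
                 mode = mode, error_profile = lm_res$error_profile,
                 fit = fit),
            class = "inflection_result")
}

#' @export
print.inflection_result <- function(x, ...) {
  cat(sprintf("inflection_result: knee at m = %d (U = %.4f, %s mode)\n",
              x$knee_m, x$U_at_knee, x$mode))
  invisible(x)
}

#' Knee robustness over subsample replicates
#'
#' Draws `R` subsamples of the data, reruns the full SOM, metaclustering and
#' QC pipeline on each (replicate `r` re-seeds both the subsampling and the
#' SOM with `base_seed + r`, so replicates differ even at `fraction = 1`),
#' and summarizes the spread of the recovered knees. Knees are recorded in
#' both raw and fitted mode from the same unimodality sets, so the two modes'
#' stability can be compared on identical replicates.
#'
#' @param matrix an [expression_matrix()] restricted to clustering markers.
#' @param config an [inflect_config()].
#' @param fraction subsample fraction, in (0, 1].
#' @param R number of replicates (>= 2).
#' @param base_seed integer; replicate `r` uses `base_seed + r`.
#' @return An object of class `robustness_report`: `knees` (configured mode),
#'   `mean`, `sem` (sd / sqrt(R)), `min`, `max`, `R`, `seeds`, plus
#'   `knees_raw`, `knees_fitted` and the per-replicate `unimodality_sets`.
#' @export
replicate_robustness <- function(matrix, config = inflect_config(),
                                 fraction = 0.9, R = 15, base_seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (R < 2) stop("need at least 2 replicates for a spread estimate")
  seeds <- base_seed + seq_len(R)
  usets <- vector("list", R)
  knees_raw <- knees_fitted <- integer(R)
  for (r in seq_len(R)) {
    res <- tryCatch({
      sub <- subsample(matrix, fraction, seed = seeds[r])
      cfg <- config
      cfg$seed <- seeds[r]
      curve <- pipeline_curve(sub, cfg)
      list(uset = curve$uset,
           raw = find_inflection(curve$uset, mode = "raw"),
           fitted = suppressWarnings(find_inflection(curve$uset,
                                                     mode = "fitted")))
    }, error = function(e) e)
    if (inherits(res, "error"))
      stop("replicate ", r, " failed: ", conditionMessage(res))
    usets[[r]] <- res$uset
    knees_raw[r] <- res$raw$knee_m
    knees_fitted[r] <- res$fitted$knee_m
  }
  knees <- if (identical(config$knee_mode, "raw")) knees_raw else knees_fitted
  structure(list(knees = knees, mean = mean(knees),
                 sem = stats::sd(knees) / sqrt(R),
                 min = min(knees), max = max(knees), fraction = fraction,
                 R = R, seeds = seeds, knees_raw = knees_raw,
                 knees_fitted = knees_fitted, unimodality_sets = usets),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "robustness_report: %d replicates (%.0f%% subsamples), knees %d-%d, mean %.2f, SEM %.2f\n",
    x$R, 100 * x$fraction, x$min, x$max, x$mean, x$sem))
  invisible(x)
}
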