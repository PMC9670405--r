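#' Hartigan dip statistic
#'
#' The dip is the smallest uniform (sup-norm) distance between the empirical
#' CDF of the sample and any unimodal CDF, i.e. any distribution function that
#' is convex left of its mode and concave right of it. Small values indicate a
#' unimodal sample. The statistic is bounded by `1/(2n)` from below and `0.25`
#' from above; the two-point sample attains `0.25`, and the bound `1/(2n)` is
#' attained e.g. by equally spaced values.
#'
#' Ties are allowed; the computation collapses the sample to its unique values
#' and works on the ECDF jump structure directly.
#'
#' @param sample numeric vector, `n >= 2`, finite.
#' @return The dip statistic, a single number in `[1/(2n), 0.25]`.
#' @seealso [dip_pvalue()]
#' @export
dip_statistic <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2) stop("dip requires at least 2 observations")
  if (!all(is.finite(sample))) stop("dip requires finite values")
  .dip_stat_cpp(sample)
}

#' Dip test p-value
#'
#' The null reference is the dip of uniform(0, 1) samples of the same size,
#' the standard calibration for the dip test. Two mechanisms are available:
#'
#' * `"table"` interpolates a bundled null-quantile table (pre-computed once
#'   by seeded Monte Carlo from uniform samples over a grid of sample sizes),
#'   linearly in `sqrt(n) * D` within a table row and linearly in `log(n)`
#'   across rows. Fast and deterministic; used by the pipeline.
#' * `"montecarlo"` draws `B` fresh uniform null samples of size `n` and
#'   returns `p = (1 + #\{D_b >= D\}) / (B + 1)`.
#'
#' For `n` below the table minimum (4) the table mode falls back to Monte
#' Carlo with a warning.
#'
#' @param D dip statistic(s); may be a vector (all for the same `n`).
#' @param n sample size the statistic was computed from.
#' @param method `"table"` or `"montecarlo"`.
#' @param B Monte-Carlo replicates.
#' @param seed integer seed for the Monte-Carlo draw.
#' @return p-value(s) in `[0, 1]`, same length as `D`.
#' @export
dip_pvalue <- function(D, n, method = c("table", "montecarlo"), B = 2000,
                       seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(D), n >= 2)
  if (method == "table" && n < 4) {
    warning("n below dip null table minimum (4); falling back to Monte Carlo")
    method <- "montecarlo"
  }
  if (method == "montecarlo") {
    null <- dip_null_sample(n, B, seed)
    return(vapply(D, function(d) (1 + sum(null >= d)) / (B + 1), numeric(1)))
  }
  tab <- dip_null_table()
  ns <- tab$n
  probs <- tab$probs
  q <- tab$quantiles # length(ns) x length(probs), dip quantiles
  # work on the sqrt(n) * D scale, interpolating across log(n)
  p_at <- function(row, s) {
    sq <- sqrt(ns[row]) * q[row, ]
    # cdf level of s under this row's null; monotone in s
    if (s <= sq[1]) return(0)
    if (s >= sq[length(sq)]) return(1)
    approx(sq, probs, xout = s, ties = "ordered")$y
  }
  vapply(D, function(d) {
    s <- sqrt(n) * d
    if (n <= ns[1]) {
      lev <- p_at(1, s)
    } else if (n >= ns[length(ns)]) {
      lev <- p_at(length(ns), s)
    } else {
      hi <- which(ns >= n)[1]
      lo <- hi - 1L
      w <- (log(n) - log(ns[lo])) / (log(ns[hi]) - log(ns[lo]))
      lev <- (1 - w) * p_at(lo, s) + w * p_at(hi, s)
    }
    max(0, min(1, 1 - lev))
  }, numeric(1))
}

#' Monte-Carlo null sample of the dip statistic
#'
#' Dips of `B` independent uniform(0, 1) samples of size `n`, the calibration
#' distribution of the dip test.
#'
#' @param n sample size.
#' @param B number of replicates.
#' @param seed integer seed.
#' @return Numeric vector of `B` dip values.
#' @export
dip_null_sample <- function(n, B, seed = 1L) {
  with_seed(seed, .dip_null_mc_cpp(as.integer(n), as.integer(B)))
}

# cached bundled null-quantile table (generated by tools/make_dip_null_table.R)
dip_null_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "dip_null_quantiles.csv",
                          package = "inflectr", mustWork = TRUE)
      df <- utils::read.csv(path, check.names = FALSE)
      cache <<- list(n = df[[1]],
                     probs = as.numeric(sub("^p", "", names(df)[-1])),
                     quantiles = as.matrix(df[, -1, drop = FALSE]))
    }
    cache
  }
})
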