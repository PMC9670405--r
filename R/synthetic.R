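#' Specify a synthetic cytometry-like mixture
#'
#' Populations are Gaussian on the arcsinh-transformed scale (the scale the
#' QC thresholds apply to), truncated at 0 to mimic the non-negativity of
#' transformed mass-cytometry counts. A population may carry deliberate
#' bimodal offsets: on the named markers its events split 50/50 between the
#' population mean and mean + offset.
#'
#' @param n_events number of events to draw.
#' @param populations list; each element a list with `name`, `weight`
#'   (non-negative; normalized to sum 1), `mean` and `sd` (vectors, one entry
#'   per marker), and optional `bimodal` (named numeric vector of offsets,
#'   names in `marker_names`).
#' @param marker_names marker names.
#' @param seed integer seed baked into the spec.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_events, populations, marker_names, seed = 1L) {
  d <- length(marker_names)
  w <- vapply(populations, function(p) p$weight, numeric(1))
  if (any(w < 0)) stop("population weights must be non-negative")
  if (sum(w) <= 0) stop("population weights must sum to a positive value")
  for (p in populations) {
    if (length(p$mean) != d || length(p$sd) != d)
      stop("population '", p$name, "': mean/sd length must match marker count")
    if (any(p$sd <= 0)) stop("population '", p$name, "': sds must be positive")
    if (!is.null(p$bimodal) && !all(names(p$bimodal) %in% marker_names))
      stop("population '", p$name, "': bimodal offsets name unknown markers")
  }
  structure(list(n_events = as.integer(n_events), populations = populations,
                 marker_names = as.character(marker_names),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Draw a synthetic mixture dataset
#'
#' @param spec a [mixture_spec()].
#' @param seed optional seed overriding the one baked into the spec.
#' @return An [expression_matrix()] on the transformed scale, with per-event
#'   population names as labels.
#' @export
generate_mixture <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "mixture_spec"))
  n <- spec$n_events
  d <- length(spec$marker_names)
  P <- length(spec$populations)
  w <- vapply(spec$populations, function(p) p$weight, numeric(1))
  w <- w / sum(w)
  with_seed(seed, {
    pop <- sample.int(P, n, replace = TRUE, prob = w)
    values <- matrix(0, n, d)
    for (p in seq_len(P)) {
      idx <- which(pop == p)
      if (!length(idx)) next
      sp <- spec$populations[[p]]
      for (j in seq_len(d))
        values[idx, j] <- rnorm(length(idx), sp$mean[j], sp$sd[j])
      if (!is.null(sp$bimodal)) {
        for (mk in names(sp$bimodal)) {
          j <- match(mk, spec$marker_names)
          shift <- runif(length(idx)) < 0.5
          values[idx[shift], j] <- values[idx[shift], j] + sp$bimodal[[mk]]
        }
      }
    }
    values <- pmax(values, 0)
    labels <- vapply(spec$populations, function(p) p$name, character(1))[pop]
    expression_matrix(values, spec$marker_names, cofactor = 5, labels = labels)
  })
}

#' Noisy two-segment test curves for knee detection
#'
#' Piecewise-linear y over the given x grid with a slope change at the knee,
#' plus Gaussian noise; `noise_sd = 0` gives exact two-segment data.
#'
#' @param knee x position of the slope change (within the range of `xs`).
#' @param left_slope,right_slope slopes of the two segments.
#' @param noise_sd standard deviation of the additive noise.
#' @param xs integer x grid.
#' @param seed integer seed.
#' @return A list with `xs` and `ys`.
#' @export
generate_elbow_points <- function(knee, left_slope, right_slope, noise_sd = 0,
                                  xs = seq_len(100), seed = 1L) {
  if (knee < min(xs) || knee > max(xs)) stop("knee must lie within xs")
  ys <- ifelse(xs <= knee, left_slope * (xs - min(xs)),
               left_slope * (knee - min(xs)) + right_slope * (xs - knee))
  if (noise_sd > 0) ys <- ys + with_seed(seed, rnorm(length(xs), 0, noise_sd))
  list(xs = xs, ys = ys)
}

#' Frozen benchmark scenarios
#'
#' Versioned mixture specifications used throughout the test-bench:
#'
#' * `k8_wellsep`: 8 equally weighted populations over 5 markers, population
#'   means on a \{0, 4\} grid with pairwise separation >= 4, all sds 0.3,
#'   20,000 events. All marker distributions are unimodal within populations,
#'   so a clustering that recovers the populations drives the unimodality
#'   fraction to ~1 and the knee to ~8.
#' * `k8_with_bimodal`: as above, but one population carries a deliberate
#'   bimodal offset of 3 on one marker, so that cell fails the dip test until
#'   the metaclustering splits the two sub-modes.
#' * `k20_with_rare`: 20 populations over 10 markers, 50,000 events, two
#'   populations at weight 0.005 (rare subsets the SOM overclustering must
#'   still capture).
#'
#' The specs are frozen constants; changing them is a breaking change.
#'
#' @param name scenario name.
#' @return A [mixture_spec()], bit-identical across calls.
#' @export
benchmark_scenario <- function(name = c("k8_wellsep", "k8_with_bimodal",
                                        "k20_with_rare")) {
  name <- match.arg(name)
  pat8 <- rbind(c(0, 0, 0, 0, 0), c(4, 0, 0, 0, 0), c(0, 4, 0, 0, 0),
                c(0, 0, 4, 0, 0), c(0, 0, 0, 4, 0), c(0, 0, 0, 0, 4),
                c(4, 4, 0, 0, 0), c(0, 0, 4, 4, 0))
  markers5 <- paste0("M", 1:5)
  pops8 <- lapply(seq_len(8), function(p)
    list(name = sprintf("pop%02d", p), weight = 1 / 8, mean = pat8[p, ],
         sd = rep(0.3, 5)))
  if (name == "k8_wellsep")
    return(mixture_spec(20000L, pops8, markers5, seed = 101L))
  if (name == "k8_with_bimodal") {
    pops8[[8]]$bimodal <- c(M5 = 3) # pop08 has mean 0 on M5: modes at 0 and 3
    return(mixture_spec(20000L, pops8, markers5, seed = 102L))
  }
  # k20_with_rare: bit patterns of 1..20 over 10 markers, scaled to {0, 4}
  pat20 <- t(vapply(seq_len(20), function(i)
    4 * as.integer(intToBits(i))[1:10], numeric(10)))
  markers10 <- paste0("M", 1:10)
  w <- c(rep((1 - 0.01) / 18, 18), 0.005, 0.005)
  pops20 <- lapply(seq_len(20), function(p)
    list(name = sprintf("pop%02d", p), weight = w[p], mean = pat20[p, ],
         sd = rep(0.3, 10)))
  mixture_spec(50000L, pops20, markers10, seed = 103L)
}
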