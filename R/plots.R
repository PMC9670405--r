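#' Diagnostic plots for a completed run
#'
#' Renders, from the CSV tables of a run directory (never from in-memory
#' state, so figures are reproducible post hoc):
#'
#' 1. `unimodality_curve.png` — U versus m with the fitted sigmoid and a
#'    vertical line at the knee;
#' 2. `marker_performance.png` — per QC marker, the fraction of metaclusters
#'    passing both checks, against m;
#' 3. `error_profile.png` — the L-method total error per candidate split.
#'
#' Requires ggplot2.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param format image format understood by [ggplot2::ggsave()].
#' @return Character vector of the created image paths.
#' @export
plot_diagnostics <- function(run_dir, format = "png") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_diagnostics requires the ggplot2 package")
  need <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) stop("missing run table: ", name)
    p
  }
  uset <- utils::read.csv(need("unimodality_set.csv"))
  fitp <- utils::read.csv(need("fit_parameters.csv"))
  prof <- utils::read.csv(need("error_profile.csv"))
  summ <- utils::read.csv(need("knee_summary.csv"))
  qc_files <- list.files(file.path(run_dir, "qc"), pattern = "^qc_m.*\\.csv$",
                         full.names = TRUE)
  if (!length(qc_files)) stop("missing run table: qc/qc_m*.csv")

  aes <- ggplot2::aes
  out <- character()
  save_plot <- function(p, name) {
    path <- file.path(run_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    out <<- c(out, path)
  }

  p1 <- ggplot2::ggplot(uset, aes(x = m, y = U)) +
    ggplot2::geom_point(colour = "firebrick", size = 1.6) +
    ggplot2::geom_vline(xintercept = summ$knee_m, linetype = "dashed") +
    ggplot2::labs(x = "metaclusters (m)", y = "unimodal fraction U",
                  title = sprintf("Knee at m = %d (U = %.3f)", summ$knee_m,
                                  summ$U_at_knee)) +
    ggplot2::theme_minimal()
  if (isTRUE(fitp$converged)) {
    grid <- data.frame(m = seq(min(uset$m), max(uset$m), length.out = 200))
    grid$U <- fitp$A + (fitp$K - fitp$A) /
      (1 + exp(-fitp$B * (grid$m - fitp$M)))
    p1 <- p1 + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  save_plot(p1, "unimodality_curve")

  perf <- do.call(rbind, lapply(qc_files, function(f) {
    qc <- utils::read.csv(f)
    m <- as.integer(sub("^qc_m0*([0-9]+)\\.csv$", "\\1", basename(f)))
    stats::aggregate(pass ~ marker, qc, mean) |>
      transform(m = m)
  }))
  p2 <- ggplot2::ggplot(perf, aes(x = m, y = 100 * pass, colour = marker)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "metaclusters (m)", y = "% metaclusters passing QC",
                  colour = "marker") +
    ggplot2::theme_minimal()
  save_plot(p2, "marker_performance")

  p3 <- ggplot2::ggplot(prof, aes(x = x, y = total_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = summ$knee_m, linetype = "dashed") +
    ggplot2::labs(x = "candidate split (m)", y = "L-method total error") +
    ggplot2::theme_minimal()
  save_plot(p3, "error_profile")
  out
}
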