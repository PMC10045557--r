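#' Construct a state-space trajectory
#'
#' Validates and tags a uniformly sampled 3-D time series. The sampling rate
#' is taken from `fs` or inferred from the `t` column.
#'
#' @param df Data frame with columns `x`, `y`, `z` and optionally `t`.
#' @param fs Sampling rate (samples per unit time); inferred from `t` when
#'   missing.
#' @return An `nf_trajectory` tibble with attribute `fs`.
#' @export
as_trajectory <- function(df, fs = NULL) {
  df <- as_tibble(df)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) abort("Trajectory needs columns x, y, z.")
  if (is.null(fs)) {
    if (!"t" %in% names(df)) abort("Supply `fs` or a `t` column.")
    dt <- diff(df$t)
    if (any(abs(dt - median(dt)) > 1e-6 * median(dt))) {
      abort("Trajectory must be uniformly sampled.")
    }
    fs <- 1 / median(dt)
  }
  if (fs <= 0) abort("`fs` must be positive.")
  if (nrow(df) < 64) abort("Trajectory needs at least 64 samples.")
  if (any(!is.finite(as.matrix(df[need])))) abort("Trajectory values must be finite.")
  if (!"t" %in% names(df)) df <- dplyr::mutate(df, t = dplyr::row_number() / fs,
                                               .before = 1)
  structure(df, fs = fs, class = c("nf_trajectory", class(tibble())))
}

#' Sampling rate of a trajectory
#' @param traj An `nf_trajectory`.
#' @return Samples per unit time.
#' @export
sampling_rate <- function(traj) {
  fs <- attr(traj, "fs")
  if (is.null(fs)) abort("Not an nf_trajectory (no sampling rate).")
  fs
}

#' Delay-coordinate embedding
#'
#' Standard Takens delay embedding of a scalar series: row \eqn{i} is
#' \eqn{(s_i, s_{i+\tau}, \ldots, s_{i+(d-1)\tau})}.
#'
#' @param series Scalar time series.
#' @param dim Embedding dimension (>= 1).
#' @param lag Sample lag \eqn{\tau} (>= 1).
#' @return A `(length - (dim-1)*lag)` by `dim` matrix.
#' @export
delay_embed <- function(series, dim, lag = 1) {
  n <- length(series)
  dim <- as.integer(dim); lag <- as.integer(lag)
  if (dim < 1 || lag < 1) abort("`dim` and `lag` must be >= 1.")
  if (n <= (dim - 1) * lag) abort("Series too short for this embedding.")
  rows <- n - (dim - 1) * lag
  out <- matrix(0, rows, dim)
  for (j in seq_len(dim)) out[, j] <- series[seq_len(rows) + (j - 1) * lag]
  out
}

#' Trajectory plot
#'
#' Time courses of the three state-space dimensions.
#'
#' @param object An `nf_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nf_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x", "y", "z"),
                              names_to = "dimension")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~dimension, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}
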