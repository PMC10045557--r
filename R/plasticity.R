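#' Hebbian outer-product weight matrix
#'
#' Classical Hebbian learning over a training set of `p` patterns on `k`
#' units: \eqn{w_{ij} = (1/p)\sum_{a=1}^{p} x_i^a x_j^a}, the average
#' outer product ("units that fire together wire together"). The result is
#' exactly symmetric; the diagonal (mean squared activity) is retained
#' unless `zero_diagonal = TRUE`.
#'
#' @param patterns A p-by-k matrix or data frame of signed pattern values.
#' @param zero_diagonal Zero out the self-connection diagonal?
#' @return A k-by-k symmetric weight matrix.
#' @export
#' @examples
#' hebbian_weights(rbind(c(1, 1), c(1, -1)))
hebbian_weights <- function(patterns, zero_diagonal = FALSE) {
  x <- as.matrix(patterns)
  if (nrow(x) < 1 || ncol(x) < 2) abort("Need >= 1 pattern over >= 2 units.")
  if (any(!is.finite(x))) abort("Pattern values must be finite.")
  w <- crossprod(x) / nrow(x)
  if (zero_diagonal) diag(w) <- 0
  dimnames(w) <- NULL
  w
}

#' Linear activation of a unit
#'
#' \eqn{z = \pm(\sum_i w_i x_i + b)}: weighted input sum plus bias, with the
#' sign convention exposed as `polarity`.
#'
#' @param weights Input weight vector.
#' @param x Input vector, same length as `weights`.
#' @param b Bias.
#' @param polarity `+1` (default) or `-1`.
#' @return Signed scalar activation.
#' @export
activation <- function(weights, x, b = 0, polarity = 1) {
  if (length(weights) != length(x)) abort("`weights` and `x` lengths differ.")
  polarity * (sum(weights * x) + b)
}

#' Quantum-neuron activation
#'
#' The state-overlap form of the activation,
#' \eqn{z = (w \cdot x + b) / (N + 1)} with `N` the number of inputs. When
#' weights and inputs are \eqn{\pm 1} and \eqn{|b| \le 1} the result is a
#' valid overlap magnitude, \eqn{|z| \le 1} (1 for identical state vectors,
#' 0 for orthogonal ones). Algebraically this is [activation()] divided by
#' \eqn{N + 1}.
#'
#' @inheritParams activation
#' @return Scalar activation; bounded in \[-1, 1\] under the \eqn{\pm 1}
#'   encoding.
#' @export
quantum_activation <- function(weights, x, b = 0) {
  if (length(weights) != length(x)) abort("`weights` and `x` lengths differ.")
  (sum(weights * x) + b) / (length(x) + 1)
}

#' Covariance coupling of attachment probabilities
#'
#' Sample covariance, across growth steps, of each node pair's attachment
#' probabilities. Rising positive covariance marks Hebbian-like
#' strengthening of the pair's coupling; negative covariance marks
#' anti-Hebbian weakening (extinction/inhibition); near-zero is neutral.
#'
#' @param prob_history A steps-by-nodes matrix of attachment probabilities
#'   (nodes absent at a step carry probability 0), or a `grown_network`
#'   grown with `record_history = TRUE`.
#' @param tol Magnitude below which a covariance is labeled neutral.
#' @return A `coupling_matrix` list with fields `cov` (symmetric matrix) and
#'   `labels` (character matrix: strengthening / weakening / neutral).
#' @export
attachment_covariance <- function(prob_history, tol = 1e-9) {
  if (inherits(prob_history, "grown_network")) {
    prob_history <- prob_history$prob_history
    if (is.null(prob_history)) {
      abort("Network was grown without `record_history = TRUE`.")
    }
  }
  p <- as.matrix(prob_history)
  if (nrow(p) < 2) abort("Need at least 2 steps of probability history.")
  cv <- stats::cov(p)
  dimnames(cv) <- NULL
  labels <- matrix("neutral", nrow(cv), ncol(cv))
  labels[cv > tol] <- "strengthening"
  labels[cv < -tol] <- "weakening"
  structure(list(cov = cv, labels = labels, tol = tol),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("<coupling_matrix>", nrow(x$cov), "nodes;",
      sum(x$labels == "strengthening" & upper.tri(x$labels)), "strengthening /",
      sum(x$labels == "weakening" & upper.tri(x$labels)), "weakening pairs\n")
  invisible(x)
}

#' @rdname attachment_covariance
#' @param x A `coupling_matrix`.
#' @param ... Unused.
#' @export
tidy.coupling_matrix <- function(x, ...) {
  n <- nrow(x$cov)
  idx <- which(upper.tri(x$cov, diag = TRUE), arr.ind = TRUE)
  tibble(node_i = idx[, 1], node_j = idx[, 2],
         covariance = x$cov[idx], label = x$labels[idx])
}
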