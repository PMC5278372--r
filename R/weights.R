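#' Analytic Hierarchy Process weights from a pairwise-comparison matrix
#'
#' Derives priority weights as the normalised principal eigenvector of a
#' positive reciprocal comparison matrix (Saaty's AHP), together with the
#' consistency diagnostics: `lambda_max`, the consistency index
#' `CI = (lambda_max - n) / (n - 1)` and the consistency ratio
#' `CR = CI / RI(n)` using Saaty's random-index table. A matrix with
#' `CR > 0.10` is conventionally considered too inconsistent; this raises a
#' warning, not an error. For `n <= 2` reciprocal matrices are always
#' consistent and `CR` is defined as 0.
#'
#' The eigenvector is computed by power iteration (tolerance 1e-10, at most
#' 10000 iterations), which is deterministic and exact for consistent
#' matrices.
#'
#' @param m Square positive matrix with unit diagonal and reciprocal
#'   symmetry `m[j, i] = 1 / m[i, j]` (checked to 1e-9); 2 <= n <= 10.
#'   Optionally with dimnames naming the items.
#' @return A list: `weights` (named, sums to 1), `lambda_max`, `CI`, `CR`.
#' @examples
#' ahp_weights(matrix(c(1, 0.5, 2, 1), 2, 2))$weights
#' @export
ahp_weights <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  if (n < 2L || n > 10L) stop("pairwise matrix must have 2 <= n <= 10 items")
  if (any(m <= 0)) stop("pairwise matrix must be strictly positive")
  if (max(abs(diag(m) - 1)) > 1e-9) stop("pairwise matrix diagonal must be 1")
  if (max(abs(m * t(m) - 1)) > 1e-9 * max(m))
    stop("pairwise matrix is not reciprocal (m[j,i] != 1/m[i,j])")
  w <- rep(1 / n, n)
  for (it in seq_len(10000L)) {
    v <- as.vector(m %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < 1e-10) { w <- v; break }
    w <- v
  }
  lambda_max <- sum(m %*% w)       # sum(A w) = lambda since sum(w) = 1
  ci <- if (n > 2L) (lambda_max - n) / (n - 1) else 0
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)[n]
  cr <- if (n <= 2L || ri == 0) 0 else ci / ri
  if (cr > 0.10)
    warning(sprintf("consistency ratio %.3f exceeds 0.10", cr))
  labels <- rownames(m) %||% paste0("item", seq_len(n))
  list(weights = stats::setNames(w, labels),
       lambda_max = lambda_max, CI = ci, CR = cr)
}

#' Validate a directly supplied weight vector
#'
#' Published studies often report only the final AHP weights, not the
#' comparison matrices behind them. This accepts such a vector verbatim
#' after checking nonnegativity and that it sums to 1.
#'
#' @param w Named (or unnamed) numeric vector.
#' @param tol Tolerance on the sum; default 1e-9. Published tables rounded
#'   to 3 decimals need a looser value such as 1e-3.
#' @return The validated vector, renormalised exactly to sum 1.
#' @export
weight_vector <- function(w, tol = 1e-9) {
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > tol)
    stop(sprintf("weights sum to %.6f, not 1 (tolerance %g)", sum(w), tol))
  w / sum(w)
}
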