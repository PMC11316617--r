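#' Log-determinant acyclicity function
#'
#' Evaluates the continuous acyclicity measure
#' \deqn{h(W) = -\log\det(sI - W \odot W) + d \log s,}
#' where \eqn{\odot} is the element-wise (Hadamard) product. The function is
#' zero exactly when the support of `W` is a directed acyclic graph and
#' strictly positive when the support contains a directed cycle, provided `W`
#' lies inside the function's domain (spectral radius of \eqn{W \odot W}
#' below `s`).
#'
#' @param W square numeric matrix of signed edge weights (zero diagonal).
#' @param s positive scalar of the log-determinant form; `1` by default.
#' @return Non-negative scalar `h(W)`.
#' @seealso [acyclicity_logdet_gradient()], [acyclicity_expm()]
#' @export
#' @examples
#' W <- matrix(0, 3, 3); W[2, 1] <- 0.8
#' acyclicity_logdet(W)          # 0: support is acyclic
#' W[1, 2] <- 0.5
#' acyclicity_logdet(W) > 0      # TRUE: 2-cycle
acyclicity_logdet <- function(W, s = 1) {
  W <- check_square_weights(W)
  if (!is.numeric(s) || length(s) != 1 || s <= 0) {
    stop_param("s must be a positive scalar")
  }
  d <- nrow(W)
  M <- diag(s, d) - W * W
  dt <- determinant(M, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus)) {
    stop_param("sI - W*W has a non-positive determinant: the spectral radius ",
               "of the squared weights exceeds s, outside the domain of h(W)")
  }
  as.numeric(-dt$modulus + d * log(s))
}

#' Analytic gradient of the log-determinant acyclicity function
#'
#' The gradient of [acyclicity_logdet()] with respect to `W`:
#' \eqn{\nabla h(W) = 2\,(sI - W\odot W)^{-T} \odot W}.
#'
#' @inheritParams acyclicity_logdet
#' @return A `d x d` numeric matrix.
#' @export
acyclicity_logdet_gradient <- function(W, s = 1) {
  W <- check_square_weights(W)
  d <- nrow(W)
  M <- diag(s, d) - W * W
  dt <- determinant(M, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus)) {
    stop_param("sI - W*W has a non-positive determinant: the spectral radius ",
               "of the squared weights exceeds s, outside the domain of h(W)")
  }
  G <- 2 * t(solve(M)) * W
  dimnames(G) <- dimnames(W)
  G
}

#' Trace-exponential acyclicity function
#'
#' The earlier matrix-exponential acyclicity measure
#' \eqn{h(W) = \mathrm{tr}\, e^{W \odot W} - d}, defined for every real `W`.
#' Zero exactly on acyclic supports; provided as an alternative constraint
#' backend for the structure learner.
#'
#' @inheritParams acyclicity_logdet
#' @return Non-negative scalar.
#' @export
acyclicity_expm <- function(W) {
  W <- check_square_weights(W)
  d <- nrow(W)
  E <- Matrix::expm(Matrix::Matrix(W * W, sparse = FALSE))
  as.numeric(sum(Matrix::diag(E)) - d)
}
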