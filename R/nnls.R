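# Non-negative least squares (Lawson-Hanson active set).

#' Non-negative least squares
#'
#' Solves min ||A w - y||_2 subject to w >= 0 with the Lawson-Hanson
#' active-set algorithm.  At the optimum the gradient of the objective is
#' zero on the support and nonnegative on the zero set (KKT conditions).
#'
#' @param A numeric matrix (M x P).
#' @param y numeric vector (M).
#' @return list with \code{w} (nonnegative weights), \code{residual}
#'   (Euclidean residual norm) and \code{iterations}.
#' @export
nnlsFit <- function(A, y) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (any(!is.finite(A)) || any(!is.finite(y)))
    stop("non-finite entries in NNLS input")
  res <- .nnlsCpp(A, y)
  list(w = drop(res$x), residual = res$residual, iterations = res$iterations)
}
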