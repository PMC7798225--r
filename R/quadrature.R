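#' Gauss-Hermite quadrature rule for standard-normal expectations
#'
#' Returns nodes `z` and weights `w` such that `sum(w * f(z))`
#' approximates `E[f(Z)]` for `Z ~ N(0, 1)`.  The physicists' rule from
#' [pracma::gaussHermite()] is rescaled by `sqrt(2)` and `1/sqrt(pi)`.
#'
#' @param n number of nodes (>= 2).
#' @return list with numeric vectors `z` and `w`; `sum(w) == 1` and
#'   `sum(w * z^2) == 1` to machine precision.
#' @export
gh_rule <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  gh <- pracma::gaussHermite(as.integer(n))
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Tensor-product rule for a standard bivariate normal: returns expanded
# vectors za, zb, w of length n^2.
gh_rule_2d <- function(n) {
  g <- gh_rule(n)
  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  list(za = g$z[idx$a], zb = g$z[idx$b], w = g$w[idx$a] * g$w[idx$b])
}
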