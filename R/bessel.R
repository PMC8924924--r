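# Spherical Bessel radial basis ------------------------------------------------

#' Construct a spherical Bessel radial basis
#'
#' The basis on \eqn{[0, R_c]} is
#' \deqn{b_n(d) = \sqrt{2/R_c}\, j_0(z_{0n} d / R_c), \qquad
#'       j_0(x) = \sin(x)/x, \quad z_{0n} = n\pi,}
#' the zeroth-order spherical Bessel functions scaled so each \eqn{b_n}
#' vanishes exactly at the cutoff (its argument hits the n-th zero of
#' \eqn{j_0} there). No smooth cutoff envelope is applied: the kernels are
#' used for scoring, not for forces.
#'
#' @param cutoff \eqn{R_c} in Angstrom.
#' @param n_basis number of basis functions \eqn{N_b}.
#' @return object of class \code{bessel_basis}.
#' @export
bessel_basis <- function(cutoff, n_basis = 16L) {
  stopifnot(cutoff > 0, n_basis >= 1)
  structure(list(cutoff = cutoff, n_basis = as.integer(n_basis),
                 zeros = seq_len(n_basis) * pi),
            class = "bessel_basis")
}

#' Evaluate the Bessel basis at distances
#'
#' \code{d = 0} is handled by the analytic limit \eqn{j_0(0) = 1}, so every
#' basis function takes the value \eqn{\sqrt{2/R_c}} there; at
#' \code{d = cutoff} every basis function is exactly 0.
#'
#' @param d distances in Angstrom, each in \eqn{[0, R_c]}.
#' @param basis \code{bessel_basis}.
#' @return matrix \code{length(d)} x \code{n_basis}.
#' @export
bessel_basis_values <- function(d, basis) {
  stopifnot(inherits(basis, "bessel_basis"))
  if (any(d < 0 | d > basis$cutoff))
    stop("distances must lie in [0, cutoff]")
  norm <- sqrt(2 / basis$cutoff)
  x <- outer(d / basis$cutoff, basis$zeros)   # arguments z_0n * d / Rc
  v <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
  out <- norm * v
  # exact zero at the cutoff (sin(n*pi) is already ~1e-16, pin it to 0)
  out[d == basis$cutoff, ] <- 0
  matrix(out, nrow = length(d))
}
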