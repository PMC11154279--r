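# Linear-quadratic protraction corrections for the long exposure times of
# low-dose-rate microbeam irradiations.

#' Lea-Catcheside protraction factor
#'
#' For a constant-dose-rate exposure of duration `time_h` with
#' mono-exponential sublesion repair at rate `lambda_per_h`, the
#' Lea-Catcheside factor discounting the quadratic term of the
#' linear-quadratic model is
#' \deqn{G = \frac{2}{\lambda T}\left(1 - \frac{1 - e^{-\lambda T}}{\lambda T}\right).}
#' The instantaneous-exposure limit `G = 1` is evaluated with a series
#' expansion below `lambda * T = 1e-4` for numerical stability.
#'
#' @param lambda_per_h Repair rate, 1/h (>= 0).
#' @param time_h Exposure time, h (>= 0).
#' @return The protraction factor in \[0, 1\] (vectorised).
#' @export
#' @examples
#' lea_catcheside_g(0.5, 1) # ~0.85 for late-responding tissue over 1 h
lea_catcheside_g <- function(lambda_per_h, time_h) {
  if (any(lambda_per_h < 0) || any(time_h < 0)) {
    abort("`lambda_per_h` and `time_h` must be non-negative")
  }
  lt <- lambda_per_h * time_h
  out <- numeric(length(lt))
  small <- lt < 1e-4
  # series: G = 1 - lt/3 + lt^2/12 - ...
  out[small] <- 1 - lt[small] / 3 + lt[small]^2 / 12
  x <- lt[!small]
  out[!small] <- 2 / x * (1 - (1 - exp(-x)) / x)
  out
}

#' Equivalent acute (short-exposure) dose
#'
#' The single-fraction short-exposure dose with the same linear-quadratic
#' biological effect as a protracted dose `d_protracted` delivered with
#' protraction factor `G`: the positive root of
#' \deqn{D_s^2 + (\alpha/\beta) D_s - \left[(\alpha/\beta) D_p + G D_p^2\right] = 0,}
#' which satisfies the biologically-effective-dose identity
#' `D_s (1 + D_s/(a/b)) = D_p (1 + G D_p/(a/b))` and reduces to
#' `D_s = D_p` at `G = 1`.
#'
#' @param d_protracted Protracted dose, Gy (> 0).
#' @param g Protraction factor in \[0, 1\] (see [lea_catcheside_g()]).
#' @param alpha_beta Tissue alpha/beta ratio, Gy (> 0).
#' @return Equivalent short-exposure dose in Gy (vectorised).
#' @export
#' @examples
#' g <- lea_catcheside_g(0.5, 1)
#' equivalent_short_dose(10, g, alpha_beta = 2)
equivalent_short_dose <- function(d_protracted, g, alpha_beta) {
  if (any(d_protracted <= 0) || any(alpha_beta <= 0)) {
    abort("`d_protracted` and `alpha_beta` must be positive")
  }
  if (any(g < 0 | g > 1)) abort("`g` must lie in [0, 1]")
  disc <- (alpha_beta / 2)^2 + alpha_beta * d_protracted + g * d_protracted^2
  if (any(disc < 0)) abort("negative discriminant (invalid inputs)")
  -alpha_beta / 2 + sqrt(disc)
}
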