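#' Temperature-dependent aggregate population model
#'
#' The fraction N_A(T) of dye molecules in the aggregated (excimer) state
#' follows a logistic melting curve: close to `n_solid` well below the
#' transition, close to `n_liquid` well above it, with midpoint `t_mid`
#' and steepness scale `width`. The plateaus are deliberately not 1/0:
#' even far from the transition a small complementary population remains
#' (aggregate-dominated red emission persists at 50 C and monomer emission
#' at 25 C). The monomer fraction is always N_M = 1 - N_A.
#'
#' @param n_solid Aggregate fraction at the low-temperature plateau.
#' @param n_liquid Aggregate fraction at the high-temperature plateau.
#' @param t_mid Transition midpoint in degrees C.
#' @param width Transition steepness scale in degrees C (> 0).
#' @return An object of class `population_model`.
#' @export
population_model <- function(n_solid = 0.97, n_liquid = 0.03,
                             t_mid = 36.8, width = 0.9) {
  if (!(n_liquid >= 0 && n_liquid < n_solid && n_solid <= 1)) {
    stop("need 0 <= n_liquid < n_solid <= 1", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  structure(list(n_solid = n_solid, n_liquid = n_liquid,
                 t_mid = t_mid, width = width),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf(
    "<population_model: N_A %.3f -> %.3f, midpoint %.2f C, width %.3f C>\n",
    x$n_solid, x$n_liquid, x$t_mid, x$width))
  invisible(x)
}

#' Aggregate-state fraction at a temperature
#'
#' Evaluates N_A(T) = n_liquid + (n_solid - n_liquid) /
#' (1 + exp((T - t_mid)/width)): smooth, strictly decreasing in T, with
#' its steepest slope at `t_mid`.
#'
#' @param model A [population_model()].
#' @param temperature Temperature(s) in degrees C.
#' @return Aggregate fraction(s) in `[n_liquid, n_solid]`.
#' @export
population_fraction <- function(model, temperature) {
  stopifnot(inherits(model, "population_model"))
  model$n_liquid + (model$n_solid - model$n_liquid) /
    (1 + exp((temperature - model$t_mid) / model$width))
}

#' Temperature derivative of the aggregate fraction
#'
#' Analytic dN_A/dT of the logistic melting curve; always negative, with
#' extremal magnitude (n_solid - n_liquid)/(4 width) at `t_mid`.
#'
#' @inheritParams population_fraction
#' @return dN_A/dT in 1/degrees C.
#' @export
population_fraction_deriv <- function(model, temperature) {
  stopifnot(inherits(model, "population_model"))
  s <- 1 / (1 + exp((temperature - model$t_mid) / model$width))
  -(model$n_solid - model$n_liquid) * s * (1 - s) / model$width
}
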