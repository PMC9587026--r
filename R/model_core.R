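# Structural relations of the feedback loop: beta-cell secretion, insulin
# receptor/effector signalling, regulated hepatic glucose production and
# glucose arrival, plus the first-order (ASIA) kinetics that map rates to
# concentrations.  All quantities in SI units.

#' Beta-cell insulin secretion rate
#'
#' Saturation (Michaelis-Menten) kinetics of glucose-stimulated insulin
#' secretion: \eqn{S = G_\beta G / (D_\beta + G)}.  Bounded above by the
#' secretory capacity \eqn{G_\beta}.
#'
#' @param G glucose concentration (mol/L), non-negative.
#' @param params a \code{\link{spina_parameters}} object.
#' @return Secretion rate S in mol/s.
#' @examples
#' p <- spina_parameters()
#' insulin_secretion_rate(p$Dbeta, p)  # half-saturation: Gbeta/2
#' @export
insulin_secretion_rate <- function(G, params = spina_parameters()) {
  if (any(!is.finite(G)) || any(G < 0))
    stop("glucose concentration must be non-negative", call. = FALSE)
  params$Gbeta * G / (params$Dbeta + G)
}

#' Insulin receptor and effector signalling
#'
#' The proximal signal is the saturable receptor response
#' \eqn{M = G_R I / (D_R + I)} (mol/s); the distal signal is the
#' dimensionless effector output \eqn{N = G_E M}, which divisively
#' inhibits hepatic glucose production.  N is monotone increasing in I
#' with supremum \eqn{G_E G_R}.
#'
#' @param I insulin concentration (mol/L), non-negative.
#' @param params a \code{\link{spina_parameters}} object.
#' @return A list with components \code{M} (mol/s) and \code{N}
#'   (dimensionless), each the same length as \code{I}.
#' @examples
#' p <- spina_parameters()
#' insulin_signal(p$DR, p)$N  # half-saturation: GE*GR/2 = 57.5
#' @export
insulin_signal <- function(I, params = spina_parameters()) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("insulin concentration must be non-negative", call. = FALSE)
  M <- params$GR * I / (params$DR + I)
  list(M = M, N = params$GE * M)
}

#' Regulated endogenous glucose production
#'
#' Non-competitive divisive inhibition of constitutive glucose production
#' by the distal insulin signal: \eqn{Q = P / (1 + N)}.
#'
#' @param P constitutive production rate (mol/s), non-negative.
#' @param N distal insulin signal (dimensionless), non-negative.
#' @return Regulated production rate Q in mol/s; \eqn{Q \le P}.
#' @export
regulated_production <- function(P, N) {
  if (any(!is.finite(P)) || any(P < 0) || any(!is.finite(N)) || any(N < 0))
    stop("P and N must be non-negative", call. = FALSE)
  P / (1 + N)
}

#' Glucose arrival rate
#'
#' Total glucose influx: intestinal absorption plus regulated endogenous
#' production, \eqn{R = W + Q}.
#'
#' @param W intestinal absorption rate (mol/s), non-negative.
#' @param Q regulated production rate (mol/s), non-negative.
#' @return Arrival rate R in mol/s.
#' @export
glucose_arrival <- function(W, Q) {
  if (any(!is.finite(W)) || any(W < 0) || any(!is.finite(Q)) || any(Q < 0))
    stop("W and Q must be non-negative", call. = FALSE)
  W + Q
}

#' Time derivative of an ASIA element
#'
#' First-order kinetics of distribution and elimination (von Bertalanffy
#' form): \eqn{dy/dt = \alpha x(t) - \beta y(t)}, with
#' \eqn{\alpha = 1/V_D}.
#'
#' @param y current concentration (mol/L).
#' @param x input rate (mol/s).
#' @param alpha dilution factor (1/L).
#' @param beta elimination rate constant (1/s).
#' @return dy/dt in mol/(L s).
#' @export
asia_derivative <- function(y, x, alpha, beta) {
  x * alpha - beta * y
}

#' Step response of an ASIA element
#'
#' Closed-form transitional behaviour under a constant input:
#' \eqn{y(t) = \alpha x/\beta + K e^{-\beta t}} with
#' \eqn{K = y_0 - \alpha x/\beta} fixed by the initial condition, so that
#' \eqn{y(0) = y_0} and \eqn{y(\infty) = \alpha x/\beta}.
#'
#' @param x_const constant input rate (mol/s).
#' @param alpha dilution factor (1/L).
#' @param beta elimination rate constant (1/s).
#' @param y0 initial concentration (mol/L).
#' @param t time (s), non-negative; may be a vector.
#' @return y(t) in mol/L.
#' @export
asia_step_response <- function(x_const, alpha, beta, y0, t) {
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  y_inf <- alpha * x_const / beta
  y_inf + (y0 - y_inf) * exp(-beta * t)
}
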