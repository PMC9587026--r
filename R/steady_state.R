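# Closed-form fasting (equifinal) steady state of the closed loop, and an
# independent fixed-point oracle based on the loop's iterative map.

#' Lumped coefficients of the steady-state glucose map
#'
#' Collapses the loop gains into the two constants of the scalar glucose
#' map: \eqn{K_1 = G_E G_R G_3 G_\beta / (D_R + G_3 G_\beta)}
#' (dimensionless) and \eqn{K_2 = D_R D_\beta / (D_R + G_3 G_\beta)}
#' (mol/L), where \eqn{G_3 = \alpha_I/\beta_I}.
#'
#' @param params a \code{\link{spina_parameters}} object.
#' @return Named numeric vector \code{c(K1, K2)}; K2 in mol/L.
#' @examples
#' k_coefficients(spina_parameters())  # K1 ~ 10.73, K2 ~ 6.35 mmol/L
#' @export
k_coefficients <- function(params) {
  G3 <- asia_gain(params$alphaI, params$betaI)
  denom <- params$DR + G3 * params$Gbeta
  c(K1 = params$GE * params$GR * G3 * params$Gbeta / denom,
    K2 = params$DR * params$Dbeta / denom)
}

#' Equifinal fasting steady state of the feedback loop
#'
#' Solves the closed loop analytically for the fasting case (W = 0).  The
#' steady-state glucose concentration satisfies the quadratic
#' \eqn{a G^2 + b G + c = 0} with \eqn{a = 1 + K_1},
#' \eqn{b = K_2 - G_1 P} and \eqn{c = -G_1 K_2 P}.  Because c < 0 the two
#' roots have opposite signs; the positive root is the unique equifinal
#' glucose concentration, and insulin follows from
#' \eqn{I = G_3 G_\beta G / (D_\beta + G)}.
#'
#' @param params a \code{\link{spina_parameters}} object.
#' @return An object of class \code{"spina_steady"}: a list with K1, K2,
#'   the quadratic coefficients a, b, c, the \code{discriminant}, both
#'   \code{roots}, and the steady-state concentrations \code{G_inf} and
#'   \code{I_inf} (mol/L).
#' @examples
#' ss <- equifinal_state(spina_parameters())
#' c(G = ss$G_inf * 1e3, I = ss$I_inf * 1e12)  # ~4.34 mmol/L, ~63 pmol/L
#' @export
equifinal_state <- function(params) {
  k <- k_coefficients(params)
  G1 <- asia_gain(params$alphaG, params$betaG)
  G3 <- asia_gain(params$alphaI, params$betaI)
  a <- 1 + k[["K1"]]
  b <- k[["K2"]] - G1 * params$P
  cc <- -G1 * k[["K2"]] * params$P
  disc <- b^2 - 4 * a * cc
  if (disc <= 0)  # cannot occur for positive parameters (c < 0)
    stop("internal error: non-positive discriminant in steady-state ",
         "quadratic", call. = FALSE)
  roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  G_inf <- roots[1]
  I_inf <- G3 * params$Gbeta * G_inf / (params$Dbeta + G_inf)
  structure(list(K1 = k[["K1"]], K2 = k[["K2"]], a = a, b = b, c = cc,
                 discriminant = disc, roots = roots,
                 G_inf = G_inf, I_inf = I_inf, params = params),
            class = "spina_steady")
}

#' @export
print.spina_steady <- function(x, ...) {
  cat("Equifinal fasting steady state\n")
  cat(sprintf("  K1 = %.4f, K2 = %.4f mmol/L\n", x$K1, x$K2 * 1e3))
  cat(sprintf("  G(inf) = %.4f mmol/L\n", x$G_inf * 1e3))
  cat(sprintf("  I(inf) = %.2f pmol/L\n", x$I_inf * 1e12))
  invisible(x)
}

#' Fixed-point iteration of the steady-state glucose map
#'
#' Independent route to the fasting steady state: iterates the scalar map
#' \eqn{G \mapsto G_1 P / (1 + K_1 G/(K_2 + G))} (W = 0) until successive
#' iterates differ by less than \code{tol}.  Agrees with the closed-form
#' quadratic root of \code{\link{equifinal_state}}; used as a numerical
#' oracle in the package's own tests.
#'
#' @param params a \code{\link{spina_parameters}} object.
#' @param G_start starting glucose concentration (mol/L), > 0.
#' @param max_iter maximum number of iterations.
#' @param tol absolute convergence tolerance on G (mol/L).
#' @return Fixed-point glucose concentration (mol/L).
#' @export
fixed_point_iteration <- function(params, G_start = 5e-3,
                                  max_iter = 1e6, tol = 1e-12) {
  if (!is.finite(G_start) || G_start <= 0)
    stop("G_start must be strictly positive", call. = FALSE)
  k <- k_coefficients(params)
  G1P <- asia_gain(params$alphaG, params$betaG) * params$P
  G <- G_start
  for (i in seq_len(max_iter)) {
    G_new <- G1P / (1 + k[["K1"]] * G / (k[["K2"]] + G))
    if (abs(G_new - G) < tol) return(G_new)
    G <- G_new
  }
  stop("fixed-point iteration did not converge after ", max_iter,
       " iterations (last iterate ", format(G), " mol/L)", call. = FALSE)
}
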