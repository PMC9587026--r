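# Time-domain simulation of the closed insulin-glucose loop: two coupled
# first-order (ASIA) states driven by the structural signals of the model
# core.  Integration uses deSolve's fixed-step classical Runge-Kutta.

#' Construct a simulation protocol
#'
#' Defines the exogenous glucose input of a simulation run.
#' \itemize{
#'   \item \code{fasting}: no intestinal absorption, \eqn{W(t) = 0}.
#'   \item \code{ogtt}: oral dose absorbed with a single-exponential
#'     profile \eqn{W(t) = f D k_a e^{-k_a t}} where D is the dose in mol,
#'     f the bioavailable fraction and \eqn{k_a} the absorption rate
#'     constant, so that \eqn{\int_0^\infty W\,dt = f D}.
#'   \item \code{ivgtt}: an intravenous bolus applied as an instantaneous
#'     concentration increment of \eqn{dose \times \alpha_G} (mol/L),
#'     consistent with \eqn{\alpha_G = 1/V_D}.
#' }
#'
#' @param kind protocol type: \code{"fasting"}, \code{"ogtt"} or
#'   \code{"ivgtt"}.
#' @param dose glucose dose in grams. Defaults: 75 g for an oGTT,
#'   0.3 g/kg x 70 kg = 21 g for an ivGTT, 0 for fasting.
#' @param f oral bioavailable fraction (oGTT only), default 0.8.
#' @param ka oral absorption rate constant in 1/s (oGTT only),
#'   default 1/1800 (absorption half-life about 21 min).
#' @param bolus_time time of the intravenous bolus in s (ivGTT only).
#' @param glucose_molar_mass_g molar mass used to convert grams to mol.
#' @return An object of class \code{"spina_protocol"} with the absorption
#'   profile \code{W_fun(t)} (mol/s) and any bolus event.
#' @examples
#' ogtt <- make_protocol("ogtt")          # 75 g oral load
#' ivgtt <- make_protocol("ivgtt", 21)    # 21 g iv bolus
#' @export
make_protocol <- function(kind = c("fasting", "ogtt", "ivgtt"),
                          dose = NULL, f = 0.8, ka = 1 / 1800,
                          bolus_time = 0, glucose_molar_mass_g = 180.18) {
  kind <- match.arg(kind)
  if (is.null(dose))
    dose <- switch(kind, fasting = 0, ogtt = 75, ivgtt = 21)
  if (!is.finite(dose) || dose < 0)
    stop("dose must be non-negative", call. = FALSE)
  if (kind == "ogtt" && (f <= 0 || f > 1))
    stop("bioavailable fraction f must be in (0, 1]", call. = FALSE)
  dose_mol <- dose / glucose_molar_mass_g
  W_fun <- if (kind == "ogtt" && dose > 0) {
    force(f); force(ka); force(dose_mol)
    function(t) f * dose_mol * ka * exp(-ka * pmax(t, 0)) * (t >= 0)
  } else {
    function(t) rep(0, length(t))
  }
  bolus <- if (kind == "ivgtt" && dose > 0)
    list(time = bolus_time, amount_mol = dose_mol) else NULL
  structure(list(kind = kind, dose_g = dose, f = f, ka = ka,
                 W_fun = W_fun, bolus = bolus,
                 dose_mol = dose_mol),
            class = "spina_protocol")
}

#' Simulate the closed insulin-glucose feedback loop
#'
#' Integrates the two coupled state equations
#' \deqn{dG/dt = \alpha_G (W(t) + Q(t)) - \beta_G G, \quad
#'       dI/dt = \alpha_I S(t) - \beta_I I}
#' where S, M, N and Q are the structural signals of the model core,
#' using the classical fixed-step 4th-order Runge-Kutta scheme.
#' Intravenous boluses are applied as instantaneous state increments
#' between steps, never smeared over a step.
#'
#' @param params a \code{\link{spina_parameters}} object.
#' @param protocol a \code{\link{make_protocol}} object; default fasting.
#' @param t_end simulation end time (s), > 0.
#' @param dt fixed integration step (s), in (0, 60].
#' @param initial optional numeric vector \code{c(G0, I0)} in mol/L;
#'   defaults to the analytic equifinal state.
#' @return An object of class \code{"spina_trajectory"}: a data.frame
#'   with columns \code{t, G, I, S, M, N, Q, R, W} (SI units) and
#'   metadata attributes (\code{params}, \code{protocol}, \code{dt}).
#' @examples
#' p <- spina_parameters()
#' traj <- simulate_homeostasis(p, t_end = 3600, dt = 10)
#' tail(traj, 1)$G * 1e3  # mmol/L, stays at the steady state
#' @export
simulate_homeostasis <- function(params, protocol = make_protocol("fasting"),
                                 t_end = 86400, dt = 1, initial = NULL) {
  stopifnot(inherits(params, "spina_params"),
            inherits(protocol, "spina_protocol"))
  if (!is.finite(t_end) || t_end <= 0)
    stop("t_end must be strictly positive", call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt > 60)
    stop("dt must be in (0, 60] s", call. = FALSE)
  if (is.null(initial)) {
    ss <- equifinal_state(params)
    initial <- c(G = ss$G_inf, I = ss$I_inf)
  } else {
    if (length(initial) != 2 || any(!is.finite(initial)) || any(initial < 0))
      stop("initial must be c(G0, I0), both finite and non-negative",
           call. = FALSE)
    initial <- c(G = unname(initial[1]), I = unname(initial[2]))
  }

  W_fun <- protocol$W_fun
  derivs <- function(t, y, parms) {
    G <- max(y[[1]], 0); I <- max(y[[2]], 0)
    S <- params$Gbeta * G / (params$Dbeta + G)
    M <- params$GR * I / (params$DR + I)
    N <- params$GE * M
    Q <- params$P / (1 + N)
    R <- W_fun(t) + Q
    list(c(params$alphaG * R - params$betaG * G,
           params$alphaI * S - params$betaI * I))
  }

  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  events <- NULL
  if (!is.null(protocol$bolus)) {
    b <- protocol$bolus
    dG <- b$amount_mol * params$alphaG
    if (b$time <= 0) {
      initial[["G"]] <- initial[["G"]] + dG
    } else {
      ev_t <- times[which.min(abs(times - b$time))]  # snap to the grid
      events <- list(data = data.frame(var = "G", time = ev_t,
                                       value = dG, method = "add"))
    }
  }

  out <- deSolve::ode(y = initial, times = times, func = derivs,
                      parms = NULL, method = "rk4", events = events)
  out <- as.data.frame(out)
  names(out)[1] <- "t"
  if (any(!is.finite(out$G)) || any(!is.finite(out$I)) ||
      any(out$G < -1e-12) || any(out$I < -1e-15))
    stop("integration produced a non-finite or negative state; ",
         "reduce dt", call. = FALSE)
  out$G <- pmax(out$G, 0)
  out$I <- pmax(out$I, 0)
  out$S <- params$Gbeta * out$G / (params$Dbeta + out$G)
  out$M <- params$GR * out$I / (params$DR + out$I)
  out$N <- params$GE * out$M
  out$Q <- params$P / (1 + out$N)
  out$W <- W_fun(out$t)
  out$R <- out$W + out$Q
  out <- out[, c("t", "G", "I", "S", "M", "N", "Q", "R", "W")]
  structure(out, class = c("spina_trajectory", "data.frame"),
            params = params, protocol = protocol, dt = dt)
}

#' Summarise a simulated trajectory
#'
#' @param traj a \code{"spina_trajectory"} from
#'   \code{\link{simulate_homeostasis}}.
#' @param sample_times_min times (minutes) at which insulin is reported.
#' @return A list: peak glucose and its time, glucose at 120 min, insulin
#'   at the requested sampling times, terminal state, and the settling
#'   time after which glucose stays within 1\% of its terminal value.
#' @export
summarize_trajectory <- function(traj, sample_times_min = c(0, 30, 60, 120)) {
  if (!inherits(traj, "spina_trajectory") || nrow(traj) == 0)
    stop("traj must be a non-empty spina_trajectory", call. = FALSE)
  ipk <- which.max(traj$G)
  G_term <- traj$G[nrow(traj)]
  I_term <- traj$I[nrow(traj)]
  # last time glucose is outside +/- 1% of the terminal value
  outside <- abs(traj$G - G_term) > 0.01 * G_term
  settle <- if (any(outside)) traj$t[max(which(outside))] else traj$t[1]
  at <- function(t_s, col) {
    if (t_s > max(traj$t)) return(NA_real_)
    stats::approx(traj$t, traj[[col]], xout = t_s)$y
  }
  list(G_peak = traj$G[ipk], t_peak = traj$t[ipk],
       G_120min = at(7200, "G"),
       I_samples = vapply(sample_times_min * 60, at, numeric(1), col = "I"),
       G_terminal = G_term, I_terminal = I_term,
       settling_time = settle)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' Exports the trajectory table (columns \code{t,G,I,S,M,N,Q,R,W}, SI
#' units, full precision) and a \code{<path>.json} sidecar recording the
#' parameter set, protocol and step size.
#'
#' @param traj a \code{"spina_trajectory"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "spina_trajectory"))
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 15, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  prot <- attr(traj, "protocol")
  meta <- list(params = export_parameters(attr(traj, "params")),
               protocol = list(kind = prot$kind, dose_g = prot$dose_g,
                               f = prot$f, ka = prot$ka),
               dt = attr(traj, "dt"),
               integrator = "rk4",
               package_version = as.character(utils::packageVersion("spinacarb")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
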