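# Canonical internal units are strict SI-derived throughout the package:
# concentrations in mol/L, rates in mol/s, time in s.  Conventional display
# units (mmol/L, pmol/L, mg/dL, uU/mL, pmol/s) appear only at I/O boundaries.

# Default structure parameters of the feedback loop, in SI units.
.default_params <- list(
  alphaG = 0.11,     # glucose dilution factor 1/V_D, 1/L
  betaG  = 7.1e-4,   # glucose clearance rate constant, 1/s
  Gbeta  = 2.8e-12,  # beta-cell secretory capacity, mol/s (2.8 pmol/s)
  Dbeta  = 7e-3,     # glucose EC50 at beta cells, mol/L (7 mmol/L)
  alphaI = 0.2,      # insulin dilution factor, 1/L
  betaI  = 3.4e-3,   # insulin clearance rate constant, 1/s
  GR     = 2.3,      # insulin receptor gain, mol/s
  DR     = 1.6e-9,   # insulin EC50 at its receptor, mol/L (1.6 nmol/L)
  GE     = 50,       # effector gain, s/mol
  P      = 150e-6,   # constitutive endogenous glucose production, mol/s
  W      = 0         # intestinal glucose absorption rate, mol/s
)

# Scale factor from the conventional unit used in parameter files to SI.
.param_file_scale <- c(
  alphaG = 1, betaG = 1, Gbeta = 1e-12, Dbeta = 1e-3, alphaI = 1,
  betaI = 1, GR = 1, DR = 1e-9, GE = 1, P = 1e-6, W = 1e-6
)

#' Structure parameters of the insulin-glucose feedback loop
#'
#' Constructs a validated parameter set for the feedback model.  All values
#' are stored internally in SI units (mol/L, mol/s, 1/L, 1/s, s/mol).  The
#' derived ASIA gains \eqn{G_1 = \alpha_G/\beta_G} and
#' \eqn{G_3 = \alpha_I/\beta_I} (s/L) are always recomputed from their
#' defining fields and never stored independently.
#'
#' @param alphaG glucose dilution factor (1/L), the reciprocal of the
#'   glucose volume of distribution.
#' @param betaG glucose clearance rate constant (1/s).
#' @param Gbeta beta-cell secretory capacity (mol/s).
#' @param Dbeta glucose EC50 at the beta cell (mol/L).
#' @param alphaI insulin dilution factor (1/L).
#' @param betaI insulin clearance rate constant (1/s).
#' @param GR insulin receptor gain (mol/s).
#' @param DR insulin EC50 at its receptor (mol/L).
#' @param GE effector gain (s/mol).
#' @param P constitutive endogenous glucose production rate (mol/s).
#' @param W intestinal glucose absorption rate (mol/s); 0 when fasting.
#'
#' @return An object of class \code{"spina_params"}: a named list of the
#'   eleven structure parameters in SI units, with a \code{"provenance"}
#'   attribute recording which fields were user-set and which are defaults.
#'
#' @details The defaults describe a healthy reference subject: secretory
#'   capacity 2.8 pmol/s, receptor gain 2.3 mol/s, glucose EC50 7 mmol/L,
#'   insulin EC50 1.6 nmol/L, endogenous glucose production 150 umol/s.
#'   With these values the fasting steady state of the closed loop lies at
#'   about 4.34 mmol/L glucose and 63 pmol/L insulin.
#'
#' @examples
#' p <- spina_parameters()
#' asia_gain(p$alphaG, p$betaG)  # G1, about 155 s/L
#' @export
spina_parameters <- function(alphaG = 0.11, betaG = 7.1e-4,
                             Gbeta = 2.8e-12, Dbeta = 7e-3,
                             alphaI = 0.2, betaI = 3.4e-3,
                             GR = 2.3, DR = 1.6e-9, GE = 50,
                             P = 150e-6, W = 0) {
  p <- list(alphaG = alphaG, betaG = betaG, Gbeta = Gbeta, Dbeta = Dbeta,
            alphaI = alphaI, betaI = betaI, GR = GR, DR = DR, GE = GE,
            P = P, W = W)
  user_set <- names(p)[!vapply(names(p), function(nm) {
    identical(p[[nm]], .default_params[[nm]])
  }, logical(1))]
  validate_parameters(p)
  structure(p, class = "spina_params",
            provenance = list(user_set = user_set))
}

validate_parameters <- function(p) {
  strict <- setdiff(names(.default_params), "W")
  bad <- character(0)
  for (nm in strict) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <- c(bad, nm)
  }
  if (!is.numeric(p$W) || length(p$W) != 1L || !is.finite(p$W) || p$W < 0)
    bad <- c(bad, "W")
  if (length(bad))
    stop("invalid parameter value(s) for: ", paste(bad, collapse = ", "),
         " (all structure parameters must be > 0; W must be >= 0)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.spina_params <- function(x, ...) {
  cat("Insulin-glucose feedback structure parameters\n")
  disp <- c(alphaG = "1/L", betaG = "1/s", Gbeta = "pmol/s",
            Dbeta = "mmol/L", alphaI = "1/L", betaI = "1/s",
            GR = "mol/s", DR = "nmol/L", GE = "s/mol", P = "umol/s",
            W = "umol/s")
  for (nm in names(disp)) {
    val <- x[[nm]] / .param_file_scale[[nm]]
    cat(sprintf("  %-7s %12.6g %s\n", nm, val, disp[[nm]]))
  }
  cat(sprintf("  derived G1 = %.4f s/L, G3 = %.4f s/L\n",
              asia_gain(x$alphaG, x$betaG), asia_gain(x$alphaI, x$betaI)))
  invisible(x)
}

#' Rate constant from half-life
#'
#' First-order elimination: \eqn{\beta = \ln(2)/t_{1/2}}.
#'
#' @param t_half half-life in seconds; must be strictly positive.
#' @return Rate constant in 1/s.
#' @examples
#' rate_constant_from_half_life(976.3)  # about 7.1e-4, glucose
#' @export
rate_constant_from_half_life <- function(t_half) {
  if (!is.numeric(t_half) || any(!is.finite(t_half)) || any(t_half <= 0))
    stop("half-life must be strictly positive", call. = FALSE)
  log(2) / t_half
}

#' ASIA steady-state gain
#'
#' An ASIA (Analog Signal memory with Intrinsic Adjustment) element converts
#' a secretion or absorption rate into a concentration by first-order
#' kinetics; at steady state it acts as the linear gain
#' \eqn{G = \alpha/\beta} (s/L).
#'
#' @param alpha dilution factor (1/L), i.e. 1/V_D.
#' @param beta elimination rate constant (1/s).
#' @return Gain in s/L.
#' @examples
#' asia_gain(0.11, 7.1e-4)  # G1 for glucose
#' asia_gain(0.2, 3.4e-3)   # G3 for insulin
#' @export
asia_gain <- function(alpha, beta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) ||
      any(!is.finite(beta)) || any(beta <= 0))
    stop("alpha and beta must be strictly positive", call. = FALSE)
  alpha / beta
}

#' Unit conventions for conversion between SI and conventional units
#'
#' @param insulin_pmolL_per_uUmL conversion factor for insulin,
#'   pmol/L per uU/mL (default 6.0; some laboratories use 6.945).
#' @param glucose_mgdL_per_mmolL conversion factor for glucose,
#'   mg/dL per mmol/L (default 18.018, from a molar mass of 180.18 g/mol).
#' @return An object of class \code{"spina_units"}.
#' @export
unit_convention <- function(insulin_pmolL_per_uUmL = 6.0,
                            glucose_mgdL_per_mmolL = 18.018) {
  if (insulin_pmolL_per_uUmL <= 0 || glucose_mgdL_per_mmolL <= 0)
    stop("conversion factors must be strictly positive", call. = FALSE)
  structure(list(insulin_pmolL_per_uUmL = insulin_pmolL_per_uUmL,
                 glucose_mgdL_per_mmolL = glucose_mgdL_per_mmolL),
            class = "spina_units")
}

# factor that converts one unit of `unit` into mol/L, per analyte
.unit_to_molar <- function(kind, unit, units) {
  tab <- switch(kind,
    glucose = c("mol/L" = 1, "mmol/L" = 1e-3,
                "mg/dL" = 1e-3 / units$glucose_mgdL_per_mmolL),
    insulin = c("mol/L" = 1, "nmol/L" = 1e-9, "pmol/L" = 1e-12,
                "uU/mL" = 1e-12 * units$insulin_pmolL_per_uUmL),
    stop("unknown quantity kind '", kind,
         "' (supported: glucose, insulin)", call. = FALSE))
  if (!unit %in% names(tab))
    stop("unknown ", kind, " unit '", unit, "' (supported: ",
         paste(names(tab), collapse = ", "), ")", call. = FALSE)
  tab[[unit]]
}

#' Convert a concentration between supported units
#'
#' Linear rescaling of glucose or insulin concentrations between SI and
#' conventional units.  Exact identity when \code{from} equals \code{to}.
#'
#' @param value numeric vector of concentrations.
#' @param kind \code{"glucose"} or \code{"insulin"}.
#' @param from,to unit names. Glucose: \code{"mol/L"}, \code{"mmol/L"},
#'   \code{"mg/dL"}. Insulin: \code{"mol/L"}, \code{"nmol/L"},
#'   \code{"pmol/L"}, \code{"uU/mL"}.
#' @param units a \code{\link{unit_convention}} object.
#' @return Converted numeric vector.
#' @examples
#' convert_quantity(5, "glucose", "mmol/L", "mg/dL")   # 90.09
#' convert_quantity(60, "insulin", "pmol/L", "uU/mL")  # 10
#' @export
convert_quantity <- function(value, kind = c("glucose", "insulin"),
                             from, to, units = unit_convention()) {
  kind <- match.arg(kind)
  if (from == to) {
    .unit_to_molar(kind, from, units)  # still validate the unit name
    return(value)
  }
  value * .unit_to_molar(kind, from, units) / .unit_to_molar(kind, to, units)
}

#' Load a parameter set from a configuration file or list
#'
#' Parameter files are flat JSON objects whose keys are the structure
#' parameter symbols (\code{alphaG}, \code{betaG}, \code{Gbeta},
#' \code{Dbeta}, \code{alphaI}, \code{betaI}, \code{GR}, \code{DR},
#' \code{GE}, \code{P}, \code{W}) and whose values are numbers in the
#' conventional units of each parameter (Gbeta in pmol/s, Dbeta in mmol/L,
#' DR in nmol/L, P and W in umol/s; dilution factors in 1/L, rate constants
#' in 1/s, GE in s/mol).  Missing keys are filled with the defaults;
#' unknown keys are rejected.
#'
#' @param config path to a JSON file, or a named list/vector of overrides
#'   in the same conventional units.  \code{NULL} or an empty list yields
#'   the full default set.
#' @return A \code{"spina_params"} object (SI units internally).
#' @examples
#' load_parameters(list(Gbeta = 1.0))  # 1 pmol/s, all else default
#' @export
load_parameters <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  config <- as.list(config)
  unknown <- setdiff(names(config), names(.default_params))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(names(.default_params), collapse = ", "),
         ")", call. = FALSE)
  si <- .default_params
  for (nm in names(config))
    si[[nm]] <- as.numeric(config[[nm]]) * .param_file_scale[[nm]]
  validate_parameters(si)
  structure(si, class = "spina_params",
            provenance = list(user_set = names(config)))
}

#' Export a parameter set to the configuration representation
#'
#' Inverse of \code{\link{load_parameters}}: returns the parameter values
#' as a named list in conventional file units, suitable for writing with
#' \code{jsonlite::write_json}.  Loading an exported set reproduces the
#' original exactly.
#'
#' @param params a \code{"spina_params"} object.
#' @return Named list of the eleven parameters in file units.
#' @export
export_parameters <- function(params) {
  stopifnot(inherits(params, "spina_params"))
  out <- lapply(names(.default_params), function(nm) {
    params[[nm]] / .param_file_scale[[nm]]
  })
  names(out) <- names(.default_params)
  out
}
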