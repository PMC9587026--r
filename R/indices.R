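# Static function tests from single fasting samples.  The SPINA estimators
# invert the model's steady-state relations and work in SI units; the
# classical comparators (HOMA, QUICKI) are defined in the conventional
# units of their original publications.
#
# Each index has an internal vector-safe evaluator (returns NA where
# undefined, never throws) used by compute_panel; the exported scalar/
# vector functions add strict scalar error semantics on top.

.spina_gbeta_vec <- function(G, I, params) {
  bad <- !is.finite(G) | G <= 0 | !is.finite(I) | I < 0
  G3 <- asia_gain(params$alphaI, params$betaI)
  out <- I * (params$Dbeta + G) / (G3 * G)
  out[bad] <- NA_real_
  out
}

.spina_gr_vec <- function(G, I, params) {
  bad <- !is.finite(G) | G <= 0 | !is.finite(I) | I <= 0
  G1 <- asia_gain(params$alphaG, params$betaG)
  out <- G1 * params$P * (params$DR + I) / (params$GE * I * G) -
    params$DR / (params$GE * I) - 1 / params$GE
  out[bad] <- NA_real_
  out
}

.homa_ir_vec <- function(G_mmol, I_uU) {
  bad <- !is.finite(G_mmol) | G_mmol <= 0 | !is.finite(I_uU) | I_uU <= 0
  out <- I_uU * G_mmol / 22.5
  out[bad] <- NA_real_
  out
}

.homa_beta_vec <- function(G_mmol, I_uU) {
  bad <- !is.finite(G_mmol) | G_mmol <= 3.5 | !is.finite(I_uU) | I_uU <= 0
  out <- 20 * I_uU / (G_mmol - 3.5)
  out[bad] <- NA_real_
  out
}

.quicki_vec <- function(G_mgdl, I_uU) {
  bad <- !is.finite(G_mgdl) | G_mgdl <= 0 | !is.finite(I_uU) | I_uU <= 0
  out <- 1 / (log10(I_uU) + log10(G_mgdl))
  out[bad] <- NA_real_
  out
}

#' SPINA-GBeta: beta-cell secretory capacity from a fasting sample
#'
#' Inverts the steady-state secretion relation
#' \eqn{I = G_3 G_\beta G/(D_\beta + G)} for the secretory capacity:
#' \deqn{\hat G_\beta = I (D_\beta + G) / (G_3 G).}
#' Defined for every G > 0 and I >= 0 — unlike HOMA-Beta there is no
#' blind zone at low glucose.
#'
#' @param G fasting glucose concentration (mol/L), > 0.
#' @param I fasting insulin concentration (mol/L), >= 0.
#' @param params a \code{\link{spina_parameters}} object supplying
#'   \eqn{G_3 = \alpha_I/\beta_I} and \eqn{D_\beta}.
#' @return Estimated secretory capacity in mol/s (multiply by 1e12 for
#'   pmol/s).  Vector inputs yield \code{NA} where G <= 0; a scalar call
#'   with G <= 0 is an error.
#' @examples
#' ss <- equifinal_state(spina_parameters())
#' spina_gbeta(ss$G_inf, ss$I_inf) * 1e12  # recovers 2.8 pmol/s
#' @export
spina_gbeta <- function(G, I, params = spina_parameters()) {
  if (length(G) == 1L && length(I) == 1L &&
      (!is.finite(G) || G <= 0 || !is.finite(I) || I < 0))
    stop("spina_gbeta requires G > 0 and I >= 0", call. = FALSE)
  .spina_gbeta_vec(G, I, params)
}

#' SPINA-GR: insulin receptor gain from a fasting sample
#'
#' Inverts the steady-state glucose relation for the receptor gain:
#' \deqn{\hat G_R = \frac{G_1 P (D_R + I)}{G_E I G} - \frac{D_R}{G_E I}
#'   - \frac{1}{G_E}.}
#' A higher value means greater insulin sensitivity.  The estimate can be
#' negative for samples inconsistent with the fasting model (glucose above
#' the open-loop value \eqn{G_1 P}); such values are returned unclipped so
#' that downstream code can flag them.
#'
#' @param G fasting glucose concentration (mol/L), > 0.
#' @param I fasting insulin concentration (mol/L), > 0.
#' @param params a \code{\link{spina_parameters}} object supplying
#'   \eqn{G_1 = \alpha_G/\beta_G}, P, \eqn{D_R} and \eqn{G_E}.
#' @return Estimated receptor gain in mol/s.  Vector inputs yield
#'   \code{NA} where G <= 0 or I <= 0; a scalar call with such inputs is
#'   an error.
#' @examples
#' ss <- equifinal_state(spina_parameters())
#' spina_gr(ss$G_inf, ss$I_inf)  # recovers 2.3 mol/s
#' @export
spina_gr <- function(G, I, params = spina_parameters()) {
  if (length(G) == 1L && length(I) == 1L &&
      (!is.finite(G) || G <= 0 || !is.finite(I) || I <= 0))
    stop("spina_gr requires G > 0 and I > 0", call. = FALSE)
  .spina_gr_vec(G, I, params)
}

#' HOMA-IR: homeostasis model assessment of insulin resistance
#'
#' \eqn{HOMA{-}IR = I \cdot G / 22.5} with insulin in uU/mL and glucose
#' in mmol/L.
#'
#' @param G_mmol fasting glucose in mmol/L, > 0.
#' @param I_uU fasting insulin in uU/mL, > 0.
#' @return Dimensionless index; \code{NA} for non-positive vector inputs.
#' @export
homa_ir <- function(G_mmol, I_uU) {
  if (length(G_mmol) == 1L && length(I_uU) == 1L &&
      (!is.finite(G_mmol) || G_mmol <= 0 || !is.finite(I_uU) || I_uU <= 0))
    stop("homa_ir requires positive glucose and insulin", call. = FALSE)
  .homa_ir_vec(G_mmol, I_uU)
}

#' HOMA-Beta: homeostasis model assessment of beta-cell function
#'
#' \eqn{HOMA{-}\beta = 20 I / (G - 3.5)} with insulin in uU/mL and
#' glucose in mmol/L.  The index is undefined (the "HOMA-blind zone")
#' whenever fasting glucose is at or below 3.5 mmol/L (63 mg/dL): there
#' the formula would return an infinite or negative value even though
#' secretory capacity may be high.  Blind-zone samples yield \code{NA}
#' in vectorised calls and an error of class
#' \code{"spina_blind_zone_error"} in scalar calls.
#'
#' @param G_mmol fasting glucose in mmol/L; must exceed 3.5 for a
#'   defined result.
#' @param I_uU fasting insulin in uU/mL, > 0.
#' @return Index in its conventional units; \code{NA} where undefined.
#' @export
homa_beta <- function(G_mmol, I_uU) {
  if (length(G_mmol) == 1L && length(I_uU) == 1L) {
    if (is.finite(G_mmol) && G_mmol <= 3.5)
      stop(structure(class = c("spina_blind_zone_error", "error",
                               "condition"),
                     list(message = paste0(
                       "HOMA-Beta is undefined for fasting glucose <= ",
                       "3.5 mmol/L (HOMA-blind zone); consider SPINA-GBeta"),
                       call = NULL)))
    if (!is.finite(G_mmol) || !is.finite(I_uU) || I_uU <= 0)
      stop("homa_beta requires positive insulin and finite glucose",
           call. = FALSE)
  }
  .homa_beta_vec(G_mmol, I_uU)
}

#' QUICKI: quantitative insulin sensitivity check index
#'
#' \eqn{QUICKI = 1/(\log_{10} I + \log_{10} G)} with insulin in uU/mL
#' and glucose in mg/dL.
#'
#' @param G_mgdl fasting glucose in mg/dL, > 1.
#' @param I_uU fasting insulin in uU/mL, > 1.
#' @return Dimensionless index; \code{NA} for out-of-domain vector inputs.
#' @export
quicki <- function(G_mgdl, I_uU) {
  if (length(G_mgdl) == 1L && length(I_uU) == 1L &&
      (!is.finite(G_mgdl) || G_mgdl <= 0 || !is.finite(I_uU) || I_uU <= 0))
    stop("quicki requires positive glucose and insulin", call. = FALSE)
  .quicki_vec(G_mgdl, I_uU)
}

#' Compute the full index panel for a cohort
#'
#' Evaluates SPINA-GBeta, SPINA-GR, HOMA-Beta, HOMA-IR and QUICKI for
#' every subject-visit record, converting the declared input units to
#' what each index requires.  Missing inputs propagate to missing
#' outputs; HOMA-blind-zone samples and negative SPINA-GR estimates are
#' flagged, never silently altered.
#'
#' @param cohort a cohort table from \code{\link{read_cohort_csv}} or
#'   \code{\link{synthesize_cohort}}, or any data.frame with columns
#'   \code{subject_id}, \code{visit}, \code{glucose}, \code{insulin}.
#' @param params a \code{\link{spina_parameters}} object.
#' @param units a \code{\link{unit_convention}} object.
#' @param glucose_unit,insulin_unit units of the input columns; taken
#'   from the cohort attributes when present.  An error is raised if no
#'   unit is declared — units are never guessed.
#' @return A data.frame (class \code{"spina_panel"}) with columns
#'   \code{subject_id}, \code{visit}, \code{glucose_mmol_L},
#'   \code{insulin_pmol_L}, \code{spina_gbeta_pmol_s},
#'   \code{spina_gr_mol_s}, \code{homa_beta}, \code{homa_ir},
#'   \code{quicki}, and one flag column per index
#'   (\code{"ok"}, \code{"blind_zone"}, \code{"negative"},
#'   \code{"missing_input"} or \code{"nonpositive_input"}).
#' @examples
#' coh <- data.frame(subject_id = "s1", visit = 1L,
#'                   glucose = 4.3378, insulin = 63.02)
#' compute_panel(coh, glucose_unit = "mmol/L", insulin_unit = "pmol/L")
#' @export
compute_panel <- function(cohort, params = spina_parameters(),
                          units = unit_convention(),
                          glucose_unit = attr(cohort, "glucose_unit"),
                          insulin_unit = attr(cohort, "insulin_unit")) {
  if (is.null(glucose_unit) || is.null(insulin_unit))
    stop("glucose_unit and insulin_unit must be declared; ",
         "units are never guessed", call. = FALSE)
  req <- c("subject_id", "visit", "glucose", "insulin")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  G_si <- convert_quantity(cohort$glucose, "glucose", glucose_unit,
                           "mol/L", units)
  I_si <- convert_quantity(cohort$insulin, "insulin", insulin_unit,
                           "mol/L", units)
  G_mmol <- G_si * 1e3
  I_pmol <- I_si * 1e12
  G_mgdl <- convert_quantity(G_mmol, "glucose", "mmol/L", "mg/dL", units)
  I_uU <- convert_quantity(I_pmol, "insulin", "pmol/L", "uU/mL", units)

  n <- nrow(cohort)
  missing_in <- is.na(G_si) | is.na(I_si)
  base_flag <- function(domain_ok) {
    f <- rep("ok", n)
    f[!domain_ok] <- "nonpositive_input"
    f[missing_in] <- "missing_input"
    f
  }
  pos_G <- !is.na(G_si) & G_si > 0
  pos_I <- !is.na(I_si) & I_si > 0
  nn_I <- !is.na(I_si) & I_si >= 0

  gb <- .spina_gbeta_vec(G_si, I_si, params) * 1e12
  gr <- .spina_gr_vec(G_si, I_si, params)
  hb <- .homa_beta_vec(G_mmol, I_uU)
  hi <- .homa_ir_vec(G_mmol, I_uU)
  qk <- .quicki_vec(G_mgdl, I_uU)

  f_gb <- base_flag(pos_G & nn_I)
  f_gr <- base_flag(pos_G & pos_I)
  f_gr[f_gr == "ok" & !is.na(gr) & gr < 0] <- "negative"
  f_hb <- base_flag(pos_G & pos_I)
  f_hb[!missing_in & pos_I & !is.na(G_mmol) & G_mmol > 0 &
         G_mmol <= 3.5] <- "blind_zone"
  f_hi <- base_flag(pos_G & pos_I)
  f_qk <- base_flag(pos_G & pos_I)

  out <- data.frame(subject_id = cohort$subject_id, visit = cohort$visit,
                    glucose_mmol_L = G_mmol, insulin_pmol_L = I_pmol,
                    spina_gbeta_pmol_s = gb, spina_gr_mol_s = gr,
                    homa_beta = hb, homa_ir = hi, quicki = qk,
                    flag_spina_gbeta = f_gb, flag_spina_gr = f_gr,
                    flag_homa_beta = f_hb, flag_homa_ir = f_hi,
                    flag_quicki = f_qk,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(cohort)) out$group <- cohort$group
  class(out) <- c("spina_panel", "data.frame")
  out
}
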