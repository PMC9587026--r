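# Cohort file I/O.  The only cohort format is CSV (RFC 4180, UTF-8,
# "." decimal); units are declared per file, never guessed per row.

#' Read a cohort table from CSV
#'
#' Required columns: \code{subject_id}, \code{visit}, plus glucose and
#' insulin columns (named \code{glucose}/\code{insulin} or with a unit
#' suffix such as \code{glucose_mmol_L} as written by
#' \code{\link{write_cohort_csv}}).  Blank concentration cells become
#' \code{NA} (missing is encoded explicitly, never as 0); any other
#' column is passed through untouched.
#'
#' @param path path to the CSV file.
#' @param glucose_unit,insulin_unit declared units of the concentration
#'   columns (see \code{\link{convert_quantity}} for supported names).
#' @return A data.frame with standardised \code{glucose}/\code{insulin}
#'   columns and unit attributes, ready for \code{\link{compute_panel}}.
#' @export
read_cohort_csv <- function(path, glucose_unit, insulin_unit) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (missing(glucose_unit) || missing(insulin_unit))
    stop("glucose_unit and insulin_unit must be declared", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rename <- function(df, target, aliases) {
    hit <- intersect(c(target, aliases), names(df))
    if (!length(hit))
      stop("required column missing: ", target, call. = FALSE)
    names(df)[names(df) == hit[1]] <- target
    df
  }
  df <- rename(df, "subject_id", character(0))
  df <- rename(df, "visit", character(0))
  df <- rename(df, "glucose", c("glucose_mmol_L", "glucose_mg_dL"))
  df <- rename(df, "insulin", c("insulin_pmol_L", "insulin_uU_mL"))
  for (col in c("glucose", "insulin")) {
    if (is.character(df[[col]])) {
      v <- trimws(df[[col]])
      v[v == ""] <- NA
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("unparseable ", col, " value in row ", bad[1], ": '",
             v[bad[1]], "'", call. = FALSE)
      df[[col]] <- num
    }
  }
  if (any(df$glucose < 0, na.rm = TRUE) || any(df$insulin < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed", call. = FALSE)
  key <- paste(df$subject_id, df$visit)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, visit) pair: ",
         key[duplicated(key)][1], call. = FALSE)
  attr(df, "glucose_unit") <- glucose_unit
  attr(df, "insulin_unit") <- insulin_unit
  message(sprintf("read %d records from %s (%d with missing values)",
                  nrow(df), path,
                  sum(is.na(df$glucose) | is.na(df$insulin))))
  df
}

#' Write a cohort table to CSV with a JSON sidecar
#'
#' Column names carry the units (\code{glucose_mmol_L},
#' \code{insulin_pmol_L}, \code{true_GR_mol_s}, \code{true_Gbeta_pmol_s});
#' values are serialised at full precision (15 significant digits).  A
#' \code{<path>.json} sidecar records the generating spec and seed when
#' the cohort came from \code{\link{synthesize_cohort}}.
#'
#' @param cohort a cohort data.frame with unit attributes (glucose in
#'   mmol/L, insulin in pmol/L).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  nm <- names(df)
  nm[nm == "glucose"] <- "glucose_mmol_L"
  nm[nm == "insulin"] <- "insulin_pmol_L"
  nm[nm == "true_GR"] <- "true_GR_mol_s"
  if ("true_Gbeta" %in% names(df)) {
    df$true_Gbeta <- df$true_Gbeta * 1e12
    nm[nm == "true_Gbeta"] <- "true_Gbeta_pmol_s"
  }
  names(df) <- nm
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    formatC(x, digits = 15, format = "g")
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    meta <- unclass(spec)
    meta$group_mix <- as.list(meta$group_mix)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write an index panel to CSV
#'
#' @param panel a \code{"spina_panel"} from \code{\link{compute_panel}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "spina_panel"))
  df <- as.data.frame(panel)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
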