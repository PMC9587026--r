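# Validation statistics for biomarker cohorts: rank correlation and its
# comparison across dependent correlations, nonparametric group tests with
# multiplicity correction, Bland-Altman method agreement, and the
# ergodicity (repeatability) decomposition for repeated visits.

#' Spearman rank correlation with p-value
#'
#' Midrank-tied Spearman correlation of two paired vectors after pairwise
#' removal of missing values, via \code{stats::cor.test}.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return A list with \code{rho}, \code{p}, and the number of complete
#'   pairs \code{n}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# Fisher z confidence limits for a single correlation
.fisher_ci <- function(r, n, conf) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Zou's confidence interval for the difference of two dependent
#' overlapping correlations
#'
#' Confidence interval for \eqn{\rho_1 - \rho_2} where both correlations
#' share one variable (e.g. two biomarkers correlated with the same
#' clinical measure on the same subjects).  Individual Fisher-z limits
#' are combined by Zou's MOVER approach, accounting for the correlation
#' between the two estimates induced by the overlap.
#'
#' @param rho_1,rho_2 the two correlations, each in (-1, 1).
#' @param rho_overlap correlation between the two non-shared variables.
#' @param n sample size, >= 4.
#' @param conf confidence level, default 0.95.
#' @return A list with \code{low}, \code{high}, and logical
#'   \code{different} (\code{TRUE} when 0 lies outside the interval).
#' @export
zou_ci_difference <- function(rho_1, rho_2, rho_overlap, n, conf = 0.95) {
  if (abs(rho_1) >= 1 || abs(rho_2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (abs(rho_overlap) > 1)
    stop("rho_overlap must lie in [-1, 1]", call. = FALSE)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  ci1 <- .fisher_ci(rho_1, n, conf)
  ci2 <- .fisher_ci(rho_2, n, conf)
  # correlation between the two correlation estimates (overlapping case)
  num <- (rho_overlap - 0.5 * rho_1 * rho_2) *
    (1 - rho_1^2 - rho_2^2 - rho_overlap^2) + rho_overlap^3
  den <- (1 - rho_1^2) * (1 - rho_2^2)
  corr_r1r2 <- num / den
  d <- rho_1 - rho_2
  low <- d - sqrt((rho_1 - ci1[1])^2 + (ci2[2] - rho_2)^2 -
                    2 * corr_r1r2 * (rho_1 - ci1[1]) * (ci2[2] - rho_2))
  high <- d + sqrt((ci1[2] - rho_1)^2 + (rho_2 - ci2[1])^2 -
                     2 * corr_r1r2 * (ci1[2] - rho_1) * (rho_2 - ci2[1]))
  list(low = low, high = high, estimate = d,
       different = (low > 0 || high < 0))
}

#' Nonparametric group comparison with post-hoc pairwise tests
#'
#' Kruskal-Wallis test (tie-corrected) across all groups, followed by
#' pairwise two-sided Mann-Whitney U tests with Benjamini-Hochberg
#' adjustment of the pairwise p-values.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as \code{values}.
#' @return A list with \code{kruskal} (statistic H, df, p),
#'   \code{pairwise} (data.frame of group pairs with raw and BH-adjusted
#'   p-values), and per-group sizes.
#' @export
group_comparison <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  sizes <- table(groups)
  if (length(sizes) < 2)
    stop("need at least 2 groups", call. = FALSE)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = "none",
                                exact = NULL))
  pm <- pw$p.value
  idx <- which(!is.na(pm), arr.ind = TRUE)
  pairs <- data.frame(group_a = rownames(pm)[idx[, 1]],
                      group_b = colnames(pm)[idx[, 2]],
                      p = pm[idx], stringsAsFactors = FALSE)
  pairs$p_adjusted <- stats::p.adjust(pairs$p, method = "BH")
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pairs,
       n_per_group = as.list(sizes))
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two measurement methods on paired data: mean
#' difference (bias), 95\% limits of agreement (bias +/- 1.96 SD of the
#' differences), and the proportional-bias slope from an ordinary
#' least-squares regression of the differences on the pair means.
#'
#' @param a,b paired numeric vectors of equal length >= 3.
#' @return An object of class \code{"spina_bland_altman"}: bias,
#'   \code{loa_low}, \code{loa_high}, \code{sd_diff}, and
#'   \code{proportional_bias} (slope with 95\% CI and p-value).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("a and b must have equal length", call. = FALSE)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  if (s > 0 && stats::sd(m) > 0) {
    fit <- stats::lm(d ~ m)
    cf <- summary(fit)$coefficients
    ci <- stats::confint(fit)["m", ]
    prop <- list(slope = unname(cf["m", "Estimate"]),
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 p = unname(cf["m", "Pr(>|t|)"]))
  } else {
    prop <- list(slope = 0, ci_low = 0, ci_high = 0, p = NA_real_)
  }
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 proportional_bias = prop, n = length(a)),
            class = "spina_bland_altman")
}

#' @export
print.spina_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %.4g, limits of agreement [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  proportional-bias slope %.4g (95%% CI %.4g to %.4g)\n",
              x$proportional_bias$slope, x$proportional_bias$ci_low,
              x$proportional_bias$ci_high))
  invisible(x)
}

#' Ergodicity (repeatability) of a biomarker across repeated visits
#'
#' Decomposes repeated measurements into between-subject and pooled
#' within-subject variance and reports
#' \deqn{e = \frac{Var_{inter}}{Var_{intra} + Var_{inter}},}
#' where \eqn{Var_{inter}} is the unbiased variance of the subject means
#' and \eqn{Var_{intra}} the unweighted mean of the unbiased
#' within-subject variances.  Values of e near 1 indicate strong
#' individual set points (low ergodicity of the cohort); values near 0
#' indicate that within-subject variation dominates.
#'
#' @param values numeric vector of measurements.
#' @param subject subject identifiers, same length as \code{values}.
#' @return An object of class \code{"spina_ergodicity"}: \code{e},
#'   \code{var_inter}, \code{var_intra}, \code{n_subjects},
#'   \code{n_excluded} (subjects dropped for having fewer than 2
#'   non-missing repeats).
#' @export
ergodicity <- function(values, subject) {
  if (length(values) != length(subject))
    stop("values and subject must have equal length", call. = FALSE)
  ok <- !is.na(values) & !is.na(subject)
  values <- values[ok]
  subject <- as.character(subject[ok])
  counts <- table(subject)
  keep <- names(counts)[counts >= 2]
  n_excl <- sum(counts < 2)
  if (n_excl > 0)
    warning(n_excl, " subject(s) with fewer than 2 repeats excluded",
            call. = FALSE)
  if (length(keep) < 2)
    stop("need at least 2 subjects with at least 2 repeats each",
         call. = FALSE)
  sel <- subject %in% keep
  values <- values[sel]
  subject <- subject[sel]
  means <- tapply(values, subject, mean)
  wvars <- tapply(values, subject, stats::var)
  var_inter <- stats::var(as.numeric(means))
  var_intra <- mean(as.numeric(wvars))
  structure(list(e = var_inter / (var_intra + var_inter),
                 var_inter = var_inter, var_intra = var_intra,
                 n_subjects = length(keep), n_excluded = n_excl),
            class = "spina_ergodicity")
}

#' @export
print.spina_ergodicity <- function(x, ...) {
  cat(sprintf(
    "Ergodicity e = %.4f (var_inter %.4g, var_intra %.4g, %d subjects)\n",
    x$e, x$var_inter, x$var_intra, x$n_subjects))
  invisible(x)
}

#' Correlation edge list for a set of biomarkers
#'
#' Pairwise Spearman correlations between all columns of a biomarker
#' matrix, with BH-adjusted p-values — the tabular backbone of a
#' correlation-network map.
#'
#' @param data data.frame of numeric biomarker columns.
#' @return data.frame with columns \code{marker_a, marker_b, rho, p,
#'   p_adjusted}.
#' @export
correlation_edges <- function(data) {
  nm <- names(data)
  if (length(nm) < 2) stop("need at least 2 columns", call. = FALSE)
  cmb <- utils::combn(nm, 2)
  res <- apply(cmb, 2, function(pair) {
    s <- spearman_rho(data[[pair[1]]], data[[pair[2]]])
    c(rho = s$rho, p = s$p)
  })
  out <- data.frame(marker_a = cmb[1, ], marker_b = cmb[2, ],
                    rho = res["rho", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out
}
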