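#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution series, Ct falls linearly in log10 of template amount;
#' the slope of that line gives the per-cycle amplification efficiency
#' `E = (10^(-1/slope) - 1) * 100` percent. A slope of
#' `-1/log10(2) = -3.3219` corresponds to perfect doubling (100%).
#'
#' No rounding happens here; report layers round to 2 decimals.
#'
#' @param slope standard-curve slope in cycles per log10 dilution; must
#'   be negative for an amplifying assay.
#' @return Efficiency in percent.
#' @export
#' @examples
#' efficiency_from_slope(-1 / log10(2))  # 100
#' efficiency_from_slope(-3.352)         # 98.76 after rounding
efficiency_from_slope <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (slope >= 0)
    stop("slope must be negative: a non-negative slope is not an ",
         "amplifying standard curve")
  (10 ^ (-1 / slope) - 1) * 100
}

#' Fit a qPCR standard curve over a dilution series
#'
#' Ordinary least-squares fit of `Ct = intercept + slope * log10(dilution)`
#' with R-squared and the derived amplification efficiency.
#'
#' @param log10_dilution log10 of the relative template amount per
#'   reaction (e.g. a 5-fold series is 0, -0.699, -1.398, ...). At least
#'   3 points and 2 distinct dilutions required.
#' @param ct observed Ct values, same length.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r2`, `efficiency_percent`, `n_points`.
#' @export
fit_standard_curve <- function(log10_dilution, ct) {
  stopifnot(is.numeric(log10_dilution), is.numeric(ct))
  keep <- stats::complete.cases(log10_dilution, ct)
  x <- log10_dilution[keep]; y <- ct[keep]
  if (length(x) != length(ct[keep]) || length(x) < 3L)
    stop("a standard curve needs at least 3 (dilution, ct) points")
  if (length(unique(x)) < 2L)
    stop("degenerate design: all dilution values identical")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  # squared correlation of fitted vs observed (= OLS R2 here); computed
  # directly so an exactly collinear series does not warn
  r2 <- if (stats::sd(y) == 0) 1 else
    1 - sum(stats::residuals(fit) ^ 2) / sum((y - mean(y)) ^ 2)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = r2,
                 efficiency_percent = efficiency_from_slope(slope),
                 n_points = length(x)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: slope %.3f, R2 %.3f, efficiency %.2f%% (n = %d)\n",
    x$slope, x$r2, x$efficiency_percent, x$n_points))
  invisible(x)
}

#' Batch standard-curve fitting from a dilution-series table
#'
#' @param df data frame with columns `gene`, `log10_dilution`, `ct`.
#' @return data frame with one row per gene: `gene`, `slope`, `r2`,
#'   `efficiency_percent` (rounded to 2 decimals, the reporting
#'   convention), `n_points`.
#' @export
fit_standard_curves <- function(df) {
  need <- c("gene", "log10_dilution", "ct")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  rows <- lapply(split(df, df$gene), function(d) {
    sc <- fit_standard_curve(d$log10_dilution, d$ct)
    data.frame(gene = d$gene[1L], slope = sc$slope, r2 = sc$r2,
               efficiency_percent = round(sc$efficiency_percent, 2L),
               n_points = sc$n_points)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
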