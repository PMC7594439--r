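#' Validate an index score against tympanic temperature by linear regression
#'
#' Ordinary least squares of tympanic temperature on the score. For a simple
#' regression the reported R-squared equals the squared Pearson correlation
#' of the two variables.
#'
#' @param scores Numeric index scores (variance > 0, `n >= 3`).
#' @param tympanic Tympanic temperatures, degrees C.
#' @return Object of class `validation_report`: `slope`, `intercept`,
#'   `r_squared`, `n`, `residual_sd`.
#' @export
validate_regression <- function(scores, tympanic) {
  stopifnot(length(scores) == length(tympanic))
  ok <- is.finite(scores) & is.finite(tympanic)
  scores <- scores[ok]; tympanic <- tympanic[ok]
  if (length(scores) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::var(scores) == 0) stop("score variance is zero", call. = FALSE)
  fit <- stats::lm(tympanic ~ scores)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    n = length(scores),
    residual_sd = sm$sigma
  ), class = "validation_report")
}

#' Closed-form R-squared of the linear index from summary tables
#'
#' An analytic oracle requiring no raw data: given the 7x7 correlation matrix
#' of the six predictors and the outcome, per-variable SDs, and the index
#' weights/normalization ranges, the squared correlation between the linear
#' index combination and the outcome is
#' `R^2 = (w' r)^2 / (w' R w)` with `w_i = c_i * sd_i / range_i`, `R` the
#' 6x6 predictor correlation block and `r` the outcome correlation column.
#' It is invariant to the overall scale factor, and uses the positive
#' air-velocity sign: the oracle describes the single linear combination,
#' not the piecewise score with the per-sample sign flip (see the package
#' vignette).
#'
#' @param corr 7x7 correlation matrix with the outcome row/column named
#'   `outcome` (others must match the six index variables); symmetric PD.
#' @param sd Named SD vector covering the six predictors (outcome SD is not
#'   needed: it cancels).
#' @param spec An [ehsra_spec()] supplying coefficients and ranges.
#' @param outcome Name of the outcome variable in `corr` (default
#'   `"tympanic"`).
#' @return Scalar R-squared in `[0, 1]`.
#' @export
closed_form_r2 <- function(corr, sd, spec = default_ehsra_spec(),
                           outcome = "tympanic") {
  corr <- as.matrix(corr)
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (is.null(rownames(corr))) {
    stop("correlation matrix needs dimnames identifying the outcome",
         call. = FALSE)
  }
  if (!(outcome %in% rownames(corr))) {
    stop(sprintf("outcome '%s' not found in correlation matrix", outcome),
         call. = FALSE)
  }
  if (is.null(tryCatch(chol(corr), error = function(e) NULL))) {
    stop("correlation matrix must be positive definite", call. = FALSE)
  }
  preds <- setdiff(rownames(corr), outcome)
  missing <- setdiff(ehsra_vars, preds)
  if (length(missing)) {
    stop("correlation matrix lacks predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sd <- sd[ehsra_vars]
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("sd must be positive for all six predictors", call. = FALSE)
  }
  w <- unname(spec$coefficients[ehsra_vars] * sd / spec$norm_range[ehsra_vars])
  Rxx <- corr[ehsra_vars, ehsra_vars]
  rxy <- corr[ehsra_vars, outcome]
  drop(sum(w * rxy)^2 / (t(w) %*% Rxx %*% w))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "OLS validation: tympanic = %.4f + %.4f * score  (n = %d)\n  R^2 = %.2f, residual SD = %.3f degC\n",
    x$intercept, x$slope, x$n, x$r_squared, x$residual_sd))
  invisible(x)
}
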