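#' @keywords internal
ehsra_vars <- c("t_dry", "t_wet", "t_globe", "v_air", "metabolism", "clo")

#' @keywords internal
ehsra_var_units <- c(
  t_dry = "degC", t_wet = "degC", t_globe = "degC",
  v_air = "m/s", metabolism = "W", clo = "clo"
)

#' Construct an EHSRA index specification
#'
#' An `ehsra_spec` bundles everything needed to turn raw thermal/workload
#' measurements into an index score and a risk label: per-variable weights,
#' min-max normalization constants, the overall x10 scale factor, the skin
#' temperature at which the air-velocity term switches sign, and the ordered
#' risk bands.
#'
#' @param coefficients Named numeric vector of six dimensionless weights, one
#'   per variable (`t_dry`, `t_wet`, `t_globe`, `v_air`, `metabolism`, `clo`).
#' @param norm_min Named numeric vector of normalization minima (same names).
#' @param norm_range Named numeric vector of strictly positive normalization
#'   ranges (same names; `(x - min) / range` is the normalized value).
#' @param scale_factor Scalar multiplier applied to the weighted sum.
#' @param skin_temp_threshold Dry temperature (degrees C) below which the
#'   air-velocity term enters with a negative sign: moving air cools when the
#'   air is cooler than skin.
#' @param bands Data frame with columns `label` (character) and `lower`
#'   (numeric, strictly increasing lower bound of each band; the first is
#'   `-Inf`).
#' @return An object of class `ehsra_spec`.
#' @seealso [default_ehsra_spec()], [ehsra_score()], [classify_risk()]
#' @export
ehsra_spec <- function(coefficients, norm_min, norm_range,
                       scale_factor = 10, skin_temp_threshold = 35,
                       bands = default_risk_bands()) {
  coefficients <- check_named6(coefficients, "coefficients")
  norm_min <- check_named6(norm_min, "norm_min")
  norm_range <- check_named6(norm_range, "norm_range")
  if (any(!is.finite(norm_range)) || any(norm_range <= 0)) {
    stop("all normalization ranges must be finite and > 0", call. = FALSE)
  }
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            is.numeric(skin_temp_threshold), length(skin_temp_threshold) == 1L)
  bands <- as.data.frame(bands)
  if (!all(c("label", "lower") %in% names(bands))) {
    stop("bands must have columns 'label' and 'lower'", call. = FALSE)
  }
  if (nrow(bands) < 2L || any(diff(bands$lower) <= 0)) {
    stop("band lower bounds must be strictly increasing (>= 2 bands)",
         call. = FALSE)
  }
  structure(
    list(coefficients = coefficients, norm_min = norm_min,
         norm_range = norm_range, scale_factor = scale_factor,
         skin_temp_threshold = skin_temp_threshold,
         bands = bands[, c("label", "lower")]),
    class = "ehsra_spec"
  )
}

check_named6 <- function(x, what) {
  if (is.null(names(x))) names(x) <- ehsra_vars
  if (!setequal(names(x), ehsra_vars) || length(x) != 6L) {
    stop(sprintf("'%s' must be a numeric vector with names %s", what,
                 paste(ehsra_vars, collapse = ", ")), call. = FALSE)
  }
  x <- x[ehsra_vars]
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  }
  x
}

#' Default risk bands
#'
#' Four ordered bands with lower bounds at the published cut-offs 12.02,
#' 15.88 and 17.56 on the index scale.
#'
#' @return Data frame with columns `label` and `lower`.
#' @export
default_risk_bands <- function() {
  data.frame(
    label = c("Low", "Moderate", "High", "Very high"),
    lower = c(-Inf, 12.02, 15.88, 17.56),
    stringsAsFactors = FALSE
  )
}

#' The published EHSRA index specification
#'
#' Weights are the standardized indirect effects of each variable on tympanic
#' temperature from the path model (0.752, 0.686, 0.774, 0.244, 0.491, 0.387);
#' normalization minima and ranges are the calibration-study measurement
#' ranges; the scale factor is 10 and the air-velocity sign switches at a skin
#' temperature of 35 degrees C.
#'
#' Note: the published formula's globe-temperature denominator (39.30) differs
#' slightly from the globe range implied by the summary table (62.43 - 23.40 =
#' 39.03). The formula constants are canonical here.
#'
#' @return An `ehsra_spec`.
#' @export
default_ehsra_spec <- function() {
  ehsra_spec(
    coefficients = c(t_dry = 0.752, t_wet = 0.686, t_globe = 0.774,
                     v_air = 0.244, metabolism = 0.491, clo = 0.387),
    norm_min = c(t_dry = 21.97, t_wet = 12.10, t_globe = 23.40,
                 v_air = 0.0, metabolism = 130, clo = 0.50),
    norm_range = c(t_dry = 26.23, t_wet = 25.47, t_globe = 39.30,
                   v_air = 4.20, metabolism = 360, clo = 0.85),
    scale_factor = 10,
    skin_temp_threshold = 35,
    bands = default_risk_bands()
  )
}

#' Read / write an index specification as JSON
#'
#' The JSON layout mirrors the spec fields one-to-one; the file shipped at
#' `system.file("extdata", "ehsra_spec.json", package = "ehsra")` reproduces
#' [default_ehsra_spec()] exactly.
#'
#' @param path File path.
#' @return `read_ehsra_spec()` returns an `ehsra_spec`; `write_ehsra_spec()`
#'   returns `path` invisibly.
#' @export
read_ehsra_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bands <- as.data.frame(x$bands)
  bands$lower <- as.numeric(ifelse(bands$lower == "-Inf", -Inf, bands$lower))
  num <- function(z) {
    out <- vapply(z, as.numeric, numeric(1))
    names(out) <- names(z)
    out
  }
  ehsra_spec(
    coefficients = num(x$coefficients),
    norm_min = num(x$norm_min),
    norm_range = num(x$norm_range),
    scale_factor = as.numeric(x$scale_factor),
    skin_temp_threshold = as.numeric(x$skin_temp_threshold),
    bands = bands
  )
}

#' @rdname read_ehsra_spec
#' @param spec An `ehsra_spec`.
#' @export
write_ehsra_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ehsra_spec"))
  out <- list(
    coefficients = as.list(spec$coefficients),
    norm_min = as.list(spec$norm_min),
    norm_range = as.list(spec$norm_range),
    scale_factor = spec$scale_factor,
    skin_temp_threshold = spec$skin_temp_threshold,
    bands = data.frame(label = spec$bands$label,
                       lower = ifelse(is.infinite(spec$bands$lower), "-Inf",
                                      as.character(spec$bands$lower)))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.ehsra_spec <- function(x, ...) {
  cat("EHSRA index specification\n")
  tab <- data.frame(coefficient = x$coefficients, min = x$norm_min,
                    range = x$norm_range,
                    unit = ehsra_var_units[ehsra_vars])
  print(tab)
  cat(sprintf("scale factor: %g;  air-velocity sign switch at t_dry = %g degC\n",
              x$scale_factor, x$skin_temp_threshold))
  cat("risk bands (lower bounds): ",
      paste(sprintf("%s >= %.4g", x$bands$label, x$bands$lower),
            collapse = "; "), "\n")
  invisible(x)
}
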