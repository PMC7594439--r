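#' Min-max normalize the six index variables
#'
#' Applies `(x - min) / range` per variable using the spec's calibration
#' constants. Values outside `[0, 1]` are legal (the input lies outside the
#' calibration range) but raise a warning, since the index weights were
#' calibrated on that range and anything beyond it is extrapolation.
#'
#' @param data Data frame (or coercible) with numeric columns `t_dry`,
#'   `t_wet`, `t_globe`, `v_air`, `metabolism`, `clo`; one row per
#'   worker-period.
#' @param spec An [ehsra_spec()]; defaults to the published constants.
#' @param warn_out_of_range Emit a warning when normalized values leave
#'   `[0, 1]` (default `TRUE`).
#' @param check Enforce the physical input invariants (`v_air >= 0`,
#'   `metabolism > 0`, `clo > 0`). Set `FALSE` when scoring raw synthetic
#'   multivariate-normal draws, whose tails can be non-physical by
#'   construction; finiteness is always required.
#' @return Data frame of the six normalized (dimensionless) columns.
#' @export
normalize_thermal <- function(data, spec = default_ehsra_spec(),
                              warn_out_of_range = TRUE, check = TRUE) {
  data <- check_thermal_frame(data, physical = check)
  out <- data[ehsra_vars]
  for (v in ehsra_vars) {
    out[[v]] <- (data[[v]] - spec$norm_min[[v]]) / spec$norm_range[[v]]
  }
  if (warn_out_of_range) {
    tol <- 1e-9  # keep exact range endpoints from flagging via FP rounding
    bad <- vapply(out, function(z) any(z < -tol | z > 1 + tol), logical(1))
    if (any(bad)) {
      warning(sprintf(
        "normalized values outside [0, 1] for: %s (input beyond the index calibration range; score is an extrapolation)",
        paste(ehsra_vars[bad], collapse = ", ")), call. = FALSE)
    }
  }
  out
}

check_thermal_frame <- function(data, physical = TRUE) {
  data <- as.data.frame(data)
  missing <- setdiff(ehsra_vars, names(data))
  if (length(missing)) {
    stop("missing required variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in ehsra_vars) {
    if (!is.numeric(data[[v]])) {
      stop(sprintf("'%s' must be numeric", v), call. = FALSE)
    }
    if (any(!is.finite(data[[v]]))) {
      stop(sprintf("'%s' contains non-finite values (rows %s)", v,
                   paste(utils::head(which(!is.finite(data[[v]])), 5L),
                         collapse = ", ")), call. = FALSE)
    }
  }
  if (physical) {
    if (any(data$v_air < 0)) stop("'v_air' must be >= 0", call. = FALSE)
    if (any(data$metabolism <= 0)) stop("'metabolism' must be > 0", call. = FALSE)
    if (any(data$clo <= 0)) stop("'clo' must be > 0", call. = FALSE)
    if (any(data$t_dry > data$t_globe)) {
      warning("t_dry exceeds t_globe in some rows; physically unusual but accepted",
              call. = FALSE)
    }
  }
  data
}

#' Compute the EHSRA score
#'
#' The index is `scale_factor * sum_i c_i * n_i`, where `n_i` is the min-max
#' normalized value of variable `i`. The air-velocity term enters with sign
#' `-1` whenever dry temperature is below the skin-temperature threshold
#' (35 degrees C by default): when air is cooler than skin, air movement
#' removes heat instead of adding it. Pure and deterministic.
#'
#' @inheritParams normalize_thermal
#' @return Numeric vector of scores, one per row.
#' @examples
#' ehsra_score(data.frame(t_dry = 30, t_wet = 20, t_globe = 40,
#'                        v_air = 1, metabolism = 300, clo = 0.8))
#' @export
ehsra_score <- function(data, spec = default_ehsra_spec(),
                        warn_out_of_range = TRUE, check = TRUE) {
  data <- check_thermal_frame(data, physical = check)
  norm <- normalize_thermal(data, spec, warn_out_of_range = warn_out_of_range,
                            check = FALSE)
  sign_v <- ifelse(data$t_dry < spec$skin_temp_threshold, -1, 1)
  terms <- mapply(function(v, n) spec$coefficients[[v]] * n,
                  ehsra_vars, norm, SIMPLIFY = FALSE)
  terms$v_air <- terms$v_air * sign_v
  spec$scale_factor * Reduce(`+`, terms)
}

#' Map scores to risk bands
#'
#' Band membership uses half-open intervals closed at each lower bound, except
#' that the top band is open at its lower bound: with the default bands,
#' Low `< 12.02`, Moderate `[12.02, 15.88)`, High `[15.88, 17.56]`,
#' Very high `> 17.56`. This makes the published band table (whose printed
#' edges 15.87/15.88 leave a gap for continuous scores) total over the reals.
#'
#' @param score Numeric vector of finite index scores.
#' @param spec An [ehsra_spec()] carrying the bands.
#' @return Ordered factor of band labels.
#' @export
classify_risk <- function(score, spec = default_ehsra_spec()) {
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  lowers <- spec$bands$lower[-1L]  # interior bounds
  m <- length(lowers)
  idx <- rep(1L, length(score))
  for (k in seq_len(m - 1L)) idx <- idx + (score >= lowers[k])
  idx <- idx + (score > lowers[m])
  factor(spec$bands$label[idx], levels = spec$bands$label, ordered = TRUE)
}

#' Age-predicted maximum heart rate and physiological screening
#'
#' `hrmax()` is `208 - 0.7 * age`. `hrmax_screen()` fails a subject whose
#' observed working heart rate strictly exceeds HRmax, or (when tympanic
#' temperature is supplied) whose tympanic temperature exceeds 39 degrees C —
#' the exclusion rules of the calibration study.
#'
#' @param age Age in years (> 0; vectorized).
#' @param heart_rate Observed working heart rate, beats per minute.
#' @param tympanic Optional tympanic temperature, degrees C.
#' @param tympanic_limit Exclusion threshold, degrees C (default 39).
#' @return `hrmax()`: numeric. `hrmax_screen()`: data frame with columns
#'   `hrmax`, `pass_hr`, `pass_tympanic`, `pass`.
#' @examples
#' hrmax(40)                 # 180
#' hrmax_screen(20, 195)     # fails: 195 > 194
#' @export
hrmax <- function(age) {
  stopifnot(is.numeric(age), all(age >= 0))
  208 - 0.7 * age
}

#' @rdname hrmax
#' @export
hrmax_screen <- function(age, heart_rate, tympanic = NULL,
                         tympanic_limit = 39) {
  hm <- hrmax(age)
  pass_hr <- !(heart_rate > hm)
  pass_ty <- if (is.null(tympanic)) rep(TRUE, length(pass_hr)) else
    !(tympanic > tympanic_limit)
  data.frame(hrmax = hm, pass_hr = pass_hr, pass_tympanic = pass_ty,
             pass = pass_hr & pass_ty)
}

#' Collapse repeated measurements into one representative record
#'
#' The calibration protocol recorded each variable three times (30/60/90 min
#' into the shift) and took the arithmetic mean of the thermal variables and
#' the maximum of the physiological variables (tympanic temperature, heart
#' rate) as representative values. Any number of repeats >= 1 is accepted.
#'
#' @param repeats Data frame of repeated measurements for one subject:
#'   thermal columns (any of `t_dry`, `t_wet`, `t_globe`, `v_air`,
#'   `metabolism`, `clo`) and optional physiological columns (`tympanic`,
#'   `heart_rate`). Other columns (e.g. `subject_id`, `site`, `age`) must be
#'   constant within the group and are carried through.
#' @return One-row data frame of representative values.
#' @export
aggregate_repeats <- function(repeats) {
  repeats <- as.data.frame(repeats)
  if (nrow(repeats) == 0L) stop("no repeats to aggregate", call. = FALSE)
  physio <- c("tympanic", "heart_rate")
  out <- repeats[1L, , drop = FALSE]
  for (v in names(repeats)) {
    x <- repeats[[v]]
    if (v %in% ehsra_vars) {
      out[[v]] <- mean(x)
    } else if (v %in% physio) {
      out[[v]] <- max(x)
    } else if (is.numeric(x)) {
      if (length(unique(x)) > 1L && v != "time") {
        warning(sprintf("column '%s' varies within repeats; first value kept", v),
                call. = FALSE)
      }
    } else if (length(unique(x)) > 1L) {
      warning(sprintf("column '%s' varies within repeats; first value kept", v),
              call. = FALSE)
    }
  }
  out$time <- NULL
  rownames(out) <- NULL
  out
}

#' Aggregate a long-format table of repeated measurements by subject
#'
#' Applies [aggregate_repeats()] within each group of `by` columns.
#'
#' @param data Long-format data frame (one row per measurement time).
#' @param by Grouping column names present in `data` (default `subject_id`).
#' @return Data frame with one row per group.
#' @export
aggregate_cohort <- function(data, by = "subject_id") {
  data <- as.data.frame(data)
  missing <- setdiff(by, names(data))
  if (length(missing)) {
    stop("grouping column(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(data[by], drop = TRUE)
  parts <- lapply(split(data, key), aggregate_repeats)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(match(out[[by[1L]]], data[[by[1L]]])), , drop = FALSE]
}
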