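#' Dichotomize tympanic temperature at a risk boundary
#'
#' Positive (higher-risk) class iff temperature strictly exceeds the boundary;
#' the boundary value itself is not "exceeding". The calibration boundaries
#' between the four risk levels are 37.5, 38.0 and 38.5 degrees C.
#'
#' @param tympanic Numeric vector, degrees C.
#' @param boundary Finite scalar, degrees C.
#' @return Integer vector of 0/1 labels.
#' @export
dichotomize <- function(tympanic, boundary) {
  stopifnot(is.numeric(tympanic), length(boundary) == 1L,
            is.finite(boundary))
  as.integer(tympanic > boundary)
}

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop(sprintf("need both classes: %d positive, %d negative", n1, n0),
         call. = FALSE)
  }
  labels
}

#' ROC curve over score thresholds
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus `-Inf`/`+Inf` sentinels; a case is predicted positive iff its
#' score is `>=` the threshold. The sentinels guarantee the curve reaches
#' (sensitivity 1, specificity 0) and (sensitivity 0, specificity 1).
#'
#' @param scores Numeric vector of index scores.
#' @param labels 0/1 vector (1 = positive class), same length.
#' @return Object of class `roc_curve`: data frame-backed list with
#'   `threshold`, `sensitivity`, `specificity` (thresholds increasing).
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- check_two_classes(labels)
  u <- sort(unique(scores))
  U <- length(u)
  thr <- c(-Inf, if (U > 1L) (u[-U] + u[-1L]) / 2, Inf)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  idx <- match(scores, u)
  pos_at <- tabulate(idx[labels == 1L], U)
  neg_at <- tabulate(idx[labels == 0L], U)
  # midpoint between u[i], u[i+1]: predicted positive iff score >= u[i+1]
  pos_ge <- rev(cumsum(rev(pos_at)))   # positives with score >= u[i]
  neg_lt <- cumsum(neg_at)             # negatives with score <= u[i]
  sens <- c(1, if (U > 1L) pos_ge[-1L] / n1, 0)
  spec <- c(0, if (U > 1L) neg_lt[-U] / n0, 1)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' Area under the ROC curve with a 95% confidence interval
#'
#' AUC is the Mann-Whitney pair statistic: the probability that a random
#' positive scores above a random negative, ties counting one half. This
#' equals the trapezoidal area under the ROC curve. The confidence interval
#' uses the Hanley-McNeil normal-approximation standard error.
#'
#' @param scores,labels As in [roc_curve()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci` (length 2, clipped to `[0, 1]`), and
#'   the class counts.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- check_two_classes(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(auc = auc, se = se,
       ci = pmin(pmax(auc + c(-1, 1) * z * se, 0), 1),
       n_pos = n1, n_neg = n0)
}

#' Nearest-to-ideal optimal cut-point
#'
#' Chooses the threshold minimizing the Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to the ideal corner (sensitivity 1,
#' specificity 1). Ties are broken toward higher sensitivity, then toward the
#' lower threshold.
#'
#' @param curve A [roc_curve()], or raw `scores` if `labels` is supplied.
#' @param labels Optional 0/1 labels; when given, `curve` is taken as scores.
#' @param conf_level Confidence level for the accompanying AUC interval.
#' @return Object of class `cutpoint_result`: `threshold`, `sensitivity`,
#'   `specificity`, `distance`, `auc`, `auc_ci`.
#' @export
optimal_cutpoint <- function(curve, labels = NULL, conf_level = 0.95) {
  if (!is.null(labels)) {
    scores <- curve
    curve <- roc_curve(scores, labels)
    a <- roc_auc(scores, labels, conf_level)
  } else {
    a <- list(auc = trapezoid_auc(curve), se = NA_real_,
              ci = c(NA_real_, NA_real_))
  }
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  # lexicographic: min distance, then max sensitivity, then min threshold
  best <- order(d, -pts$sensitivity, pts$threshold)[1L]
  structure(list(threshold = pts$threshold[best],
                 sensitivity = pts$sensitivity[best],
                 specificity = pts$specificity[best],
                 distance = d[best],
                 auc = a$auc, auc_se = a$se, auc_ci = a$ci),
            class = "cutpoint_result")
}

#' Trapezoidal area under a constructed ROC curve
#'
#' @param curve A [roc_curve()].
#' @return Scalar area in `[0, 1]`.
#' @export
trapezoid_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  fpr <- 1 - pts$specificity  # decreasing with threshold
  tpr <- pts$sensitivity
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1L] + tpr[o][-length(tpr)]) / 2)
}

#' Derive the four risk bands from scores and tympanic temperature
#'
#' Runs the nearest-to-ideal cut-point selection at each tympanic boundary
#' (default 37.5 / 38.0 / 38.5 degrees C) and assembles the three cut-offs
#' into a four-band risk specification. Cut-points that do not come out
#' strictly increasing are a calibration failure and raise an error rather
#' than being silently reordered.
#'
#' @param scores Index scores.
#' @param tympanic Tympanic temperatures, degrees C, same length.
#' @param boundaries Three increasing tympanic boundaries, degrees C.
#' @param labels Band labels, length `length(boundaries) + 1`.
#' @param digits Cut-offs are rounded to this many decimals for the band
#'   table (default 2, the published precision); `Inf` keeps full precision.
#' @return List of class `risk_band_calibration`: `cutpoints` (list of
#'   `cutpoint_result`, one per boundary), `bands` (data frame usable in
#'   [ehsra_spec()]).
#' @export
derive_risk_bands <- function(scores, tympanic,
                              boundaries = c(37.5, 38.0, 38.5),
                              labels = c("Low", "Moderate", "High", "Very high"),
                              digits = 2) {
  stopifnot(length(scores) == length(tympanic),
            length(labels) == length(boundaries) + 1L,
            !is.unsorted(boundaries, strictly = TRUE))
  cuts <- lapply(boundaries, function(b) {
    optimal_cutpoint(scores, dichotomize(tympanic, b))
  })
  thr <- vapply(cuts, `[[`, numeric(1), "threshold")
  if (is.finite(digits)) thr <- round(thr, digits)
  if (is.unsorted(thr, strictly = TRUE)) {
    stop(sprintf(
      "derived cut-points are not strictly increasing (%s); calibration failed",
      paste(signif(thr, 6), collapse = ", ")), call. = FALSE)
  }
  names(cuts) <- paste0("boundary_", boundaries)
  structure(list(
    cutpoints = cuts,
    boundaries = boundaries,
    bands = data.frame(label = labels, lower = c(-Inf, thr),
                       stringsAsFactors = FALSE)
  ), class = "risk_band_calibration")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "cut-point %.4g  (sens %.3f, spec %.3f, distance %.3f)  AUC %.3f",
    x$threshold, x$sensitivity, x$specificity, x$distance, x$auc))
  if (all(is.finite(x$auc_ci))) {
    cat(sprintf("  (95%% CI %.3f, %.3f)", x$auc_ci[1], x$auc_ci[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.risk_band_calibration <- function(x, ...) {
  cat("Risk-band calibration (nearest-to-ideal ROC cut-points)\n")
  for (i in seq_along(x$cutpoints)) {
    cat(sprintf("  tympanic > %.1f : ", x$boundaries[i]))
    print(x$cutpoints[[i]])
  }
  print(x$bands)
  invisible(x)
}
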