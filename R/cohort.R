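#' Cohort model for synthetic worker data
#'
#' Describes the joint distribution of the six index variables plus working
#' tympanic temperature as a multivariate normal: means, SDs and a 7x7
#' correlation matrix, with optional hard ranges for rejection truncation,
#' optional two-site overrides and a random seed. An indefinite correlation
#' matrix (e.g. from rounded published values) is repaired to the nearest
#' positive-definite matrix by eigenvalue clipping, with a message reporting
#' the shift.
#'
#' @param mean,sd Named length-7 numeric vectors over
#'   `c(t_dry, t_wet, t_globe, v_air, metabolism, clo, tympanic)`.
#' @param corr 7x7 correlation matrix (same names).
#' @param ranges Optional named list of length-2 numeric ranges used when
#'   sampling with `truncate = TRUE`.
#' @param sites Optional list of per-site overrides; see
#'   [default_cohort_model()].
#' @return Object of class `cohort_model`.
#' @export
cohort_model <- function(mean, sd, corr, ranges = NULL, sites = NULL) {
  vars <- c(ehsra_vars, "tympanic")
  stopifnot(length(mean) == 7L, length(sd) == 7L)
  if (is.null(names(mean))) names(mean) <- vars
  if (is.null(names(sd))) names(sd) <- vars
  mean <- mean[vars]; sd <- sd[vars]
  if (any(!is.finite(sd)) || any(sd <= 0)) stop("sd must be > 0", call. = FALSE)
  corr <- as.matrix(corr)
  if (is.null(rownames(corr))) dimnames(corr) <- list(vars, vars)
  corr <- corr[vars, vars]
  if (max(abs(corr - t(corr))) > 1e-8) stop("corr must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("corr must have unit diagonal", call. = FALSE)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    repaired <- nearest_pd_corr(corr)
    message(sprintf(
      "correlation matrix not positive definite (min eigenvalue %.2e); repaired, max entry shift %.4f",
      min(ev), max(abs(repaired - corr))))
    corr <- repaired
  }
  structure(list(vars = vars, mean = mean, sd = sd, corr = corr,
                 ranges = ranges, sites = sites),
            class = "cohort_model")
}

# eigenvalue clipping + rescale to unit diagonal
nearest_pd_corr <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  M <- e$vectors %*% (lam * t(e$vectors))
  D <- 1 / sqrt(diag(M))
  M <- M * tcrossprod(D)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  (M + t(M)) / 2
}

#' The published-cohort calibration
#'
#' The default synthetic-cohort model, calibrated to the printed summary
#' tables of the calibration study (n = 201 male workers from a hot-dry steel
#' site and a hot-humid petrochemical site): per-variable means and SDs, the
#' 7x7 Pearson correlation matrix, the observed hard ranges, and the two-site
#' climatic overrides (dry/wet/globe temperature means and SDs per site,
#' mixed 111:90).
#'
#' The printed pooled dry-temperature mean (24.78 degC) is inconsistent with
#' the per-site means (33.58, 36.26 degC) — likely a misprint in the source
#' table. The pooled table is used verbatim; correlation-based quantities are
#' unaffected by means.
#'
#' @return A [cohort_model()].
#' @export
default_cohort_model <- function() {
  vars <- c(ehsra_vars, "tympanic")
  means <- c(t_dry = 24.78, t_wet = 22.01, t_globe = 39.89, v_air = 0.58,
             metabolism = 248.47, clo = 0.83, tympanic = 37.7)
  sds <- c(t_dry = 6.01, t_wet = 6.60, t_globe = 9.73, v_air = 0.39,
           metabolism = 103.70, clo = 0.14, tympanic = 0.56)
  R <- diag(7)
  dimnames(R) <- list(vars, vars)
  lower <- c(
    0.626,                                  # wet ~ dry
    0.907, 0.511,                           # globe ~ dry, wet
    0.296, 0.152, 0.347,                    # v_air ~ ...
    0.318, 0.131, 0.332, 0.082,             # metabolism ~ ...
    0.454, 0.054, 0.530, 0.135, 0.321,      # clo ~ ...
    0.751, 0.685, 0.766, 0.258, 0.509, 0.388  # tympanic ~ ...
  )
  k <- 1L
  for (i in 2:7) for (j in 1:(i - 1)) {
    R[i, j] <- R[j, i] <- lower[k]
    k <- k + 1L
  }
  ranges <- list(
    t_dry = c(21.97, 48.20), t_wet = c(12.10, 37.57),
    t_globe = c(23.40, 62.43), v_air = c(0, 4.20),
    metabolism = c(130, 490), clo = c(0.50, 1.35),
    tympanic = c(36.7, 39.1)
  )
  sites <- list(
    steel = list(
      n_weight = 111,
      mean = c(t_dry = 33.58, t_wet = 17.63, t_globe = 39.01),
      sd = c(t_dry = 5.21, t_wet = 2.04, t_globe = 9.63)
    ),
    petrochemical = list(
      n_weight = 90,
      mean = c(t_dry = 36.26, t_wet = 27.43, t_globe = 40.97),
      sd = c(t_dry = 6.61, t_wet = 6.26, t_globe = 9.80)
    )
  )
  cohort_model(means, sds, R, ranges = ranges, sites = sites)
}

# Cholesky-based multivariate normal draw
rmvn <- function(n, mean, cov) {
  L <- chol(cov)
  Z <- matrix(stats::rnorm(n * length(mean)), n)
  sweep(Z %*% L, 2L, mean, `+`)
}

#' Sample a synthetic worker cohort
#'
#' Draws `n` multivariate-normal records with the model's moments. With
#' `two_site = TRUE` the cohort is a mixture of the per-site climatic
#' conditions at the model's site weights (keeping the pooled correlation
#' structure); the returned table then carries a `site` column. With
#' `truncate = TRUE`, draws outside the model's hard ranges are rejected and
#' redrawn — off by default because truncation distorts the calibrated
#' moments. Demographic screening variables (`age`, `heart_rate`) are drawn
#' independently of the thermal block, which carries no published
#' cross-correlations with them.
#'
#' @param model A [cohort_model()].
#' @param n Number of records (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @param two_site Mix the per-site climatic overrides.
#' @param truncate Rejection-truncate to the model's hard ranges.
#' @param demographics Add independent `age` and `heart_rate` columns.
#' @return Data frame with columns `subject_id`, optional `site`, the six
#'   thermal variables, `tympanic`, and optional demographics.
#' @export
sample_cohort <- function(model = default_cohort_model(), n, seed = NULL,
                          two_site = FALSE, truncate = FALSE,
                          demographics = FALSE) {
  stopifnot(inherits(model, "cohort_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(m, mu, sds) {
    cov <- model$corr * tcrossprod(sds)
    out <- rmvn(m, mu, cov)
    colnames(out) <- model$vars
    out
  }
  sample_block <- function(m, mu, sds) {
    if (!truncate) return(draw(m, mu, sds))
    acc <- matrix(numeric(0), 0L, 7L, dimnames = list(NULL, model$vars))
    attempts <- 0L
    while (nrow(acc) < m) {
      batch <- draw(max(m, 1000L), mu, sds)
      keep <- rep(TRUE, nrow(batch))
      for (v in names(model$ranges)) {
        rg <- model$ranges[[v]]
        keep <- keep & batch[, v] >= rg[1L] & batch[, v] <= rg[2L]
      }
      attempts <- attempts + nrow(batch)
      acc <- rbind(acc, batch[keep, , drop = FALSE])
      if (attempts > 100L * m && nrow(acc) < 0.01 * attempts) {
        stop("rejection rate above 99%; ranges incompatible with moments",
             call. = FALSE)
      }
    }
    acc[seq_len(m), , drop = FALSE]
  }
  if (two_site) {
    if (is.null(model$sites)) stop("model has no site overrides", call. = FALSE)
    w <- vapply(model$sites, `[[`, numeric(1), "n_weight")
    n_per <- floor(n * w / sum(w))
    n_per[1L] <- n_per[1L] + (n - sum(n_per))
    blocks <- vector("list", length(model$sites))
    for (i in seq_along(model$sites)) {
      s <- model$sites[[i]]
      mu <- model$mean; sds <- model$sd
      mu[names(s$mean)] <- s$mean
      sds[names(s$sd)] <- s$sd
      blocks[[i]] <- if (n_per[i] > 0L) sample_block(n_per[i], mu, sds)
    }
    out <- as.data.frame(do.call(rbind, blocks))
    out$site <- rep(names(model$sites), n_per)
  } else {
    out <- as.data.frame(sample_block(n, model$mean, model$sd))
  }
  if (demographics) {
    # Demographics table: age 36.62 (8.24), working HR 121.00 (28.45)
    out$age <- round(pmin(pmax(stats::rnorm(n, 36.62, 8.24), 18), 65))
    out$heart_rate <- stats::rnorm(n, 121.00, 28.45)
  }
  out <- cbind(subject_id = sprintf("S%05d", seq_len(n)), out)
  out
}

#' Apply the study's physiological exclusion screens to a cohort
#'
#' Removes rows whose working heart rate exceeds the age-predicted maximum
#' (`208 - 0.7 * age`) or whose tympanic temperature exceeds 39 degrees C,
#' and reports per-rule exclusion counts. Rules whose columns are absent are
#' skipped with a message.
#'
#' @param cohort Data frame with (some of) `age`, `heart_rate`, `tympanic`.
#' @param tympanic_limit Exclusion threshold, degrees C (default 39).
#' @return List with `cohort` (filtered data frame) and `exclusions`
#'   (named counts per rule, plus `total` distinct rows removed).
#' @export
apply_screening <- function(cohort, tympanic_limit = 39) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  fail_hr <- rep(FALSE, n)
  fail_ty <- rep(FALSE, n)
  if (all(c("age", "heart_rate") %in% names(cohort))) {
    fail_hr <- cohort$heart_rate > hrmax(cohort$age)
  } else {
    message("age/heart_rate absent: HRmax screen skipped")
  }
  if ("tympanic" %in% names(cohort)) {
    fail_ty <- cohort$tympanic > tympanic_limit
  } else {
    message("tympanic absent: temperature screen skipped")
  }
  fail_hr[is.na(fail_hr)] <- FALSE
  fail_ty[is.na(fail_ty)] <- FALSE
  keep <- !(fail_hr | fail_ty)
  list(
    cohort = cohort[keep, , drop = FALSE],
    exclusions = c(hrmax = sum(fail_hr), tympanic = sum(fail_ty),
                   total = sum(!keep))
  )
}

#' @export
print.cohort_model <- function(x, ...) {
  cat("Synthetic cohort model (multivariate normal)\n")
  print(data.frame(mean = x$mean, sd = x$sd))
  cat("correlation matrix: 7 x 7",
      if (!is.null(x$sites)) sprintf("; %d site override(s)", length(x$sites)),
      "\n", sep = "")
  invisible(x)
}
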