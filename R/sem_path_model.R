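#' Specify the one-latent-factor path model
#'
#' The measurement/structural model behind the index: six observed
#' environmental and personal variables are indicators of a single latent
#' "heat strain" factor, and the latent factor has one structural path to the
#' observed outcome (tympanic temperature). Identification fixes the latent
#' variance at 1 with all loadings free, matching a report of six standardized
#' loadings plus one structural coefficient. An optional list of indicator
#' error covariances allows richer topologies.
#'
#' @param indicators Character vector of indicator column names (default the
#'   six index variables).
#' @param outcome Outcome column name (default `"tympanic"`).
#' @param latent Label for the latent factor.
#' @param error_cov Optional list of length-2 character vectors naming
#'   indicator pairs whose measurement errors covary.
#' @return An object of class `path_model_spec`.
#' @export
path_model_spec <- function(indicators = ehsra_vars, outcome = "tympanic",
                            latent = "heat_strain", error_cov = list()) {
  indicators <- as.character(indicators)
  stopifnot(length(indicators) >= 2L, length(outcome) == 1L)
  if (outcome %in% indicators) {
    stop("outcome must not be one of the indicators", call. = FALSE)
  }
  for (pr in error_cov) {
    if (length(pr) != 2L || !all(pr %in% indicators)) {
      stop("error_cov entries must be pairs of declared indicators",
           call. = FALSE)
    }
  }
  structure(list(indicators = indicators, outcome = outcome, latent = latent,
                 error_cov = error_cov),
            class = "path_model_spec")
}

#' Convert a correlation matrix plus SD vector to a covariance matrix
#'
#' @param R Correlation matrix (symmetric, unit diagonal) with dimnames.
#' @param sd Named (or positionally matching) vector of standard deviations.
#' @return Covariance matrix.
#' @export
cov_from_corr <- function(R, sd) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have unit diagonal", call. = FALSE)
  if (!is.null(names(sd)) && !is.null(rownames(R))) sd <- sd[rownames(R)]
  if (length(sd) != nrow(R) || any(!is.finite(sd)) || any(sd <= 0)) {
    stop("sd must be positive, one per variable", call. = FALSE)
  }
  S <- R * tcrossprod(sd)
  dimnames(S) <- dimnames(R)
  S
}

# model-implied covariance from the raw parameter blocks
implied_sigma <- function(lambda, gamma, psi, error_cov_idx, ecov) {
  k <- length(lambda)
  p <- k + 1L
  Sigma <- matrix(0, p, p)
  Sigma[1:k, 1:k] <- tcrossprod(lambda)
  diag(Sigma)[1:k] <- diag(Sigma)[1:k] + psi[1:k]
  if (length(ecov)) {
    for (j in seq_along(ecov)) {
      a <- error_cov_idx[j, 1L]; b <- error_cov_idx[j, 2L]
      Sigma[a, b] <- Sigma[a, b] + ecov[j]
      Sigma[b, a] <- Sigma[b, a] + ecov[j]
    }
  }
  Sigma[1:k, p] <- Sigma[p, 1:k] <- lambda * gamma
  Sigma[p, p] <- gamma^2 + psi[p]
  Sigma
}

ml_discrepancy <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% S
  logdet + sum(diag(Sinv_S)) - logdetS - nrow(S)
}

#' Fit the path model by maximum likelihood
#'
#' Minimizes the Wishart ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over loadings, the structural coefficient, error variances
#' (log-parameterized) and any declared error covariances, by BFGS with an
#' analytic gradient from a deterministic start (loadings `0.7 * sd_i`,
#' error variances half the observed variances). The chi-square statistic is
#' `(n - 1) * F` at the optimum.
#'
#' @param S Sample covariance (or correlation) matrix with dimnames covering
#'   the model variables; must be symmetric positive definite.
#' @param n Sample size (`> p`).
#' @param model A [path_model_spec()].
#' @param max_iter Iteration cap for the optimizer (default 500).
#' @param grad_tol Gradient-norm convergence tolerance (default 1e-8).
#' @return An object of class `path_model_fit`: raw and standardized
#'   loadings, structural coefficient `gamma`, error variances, `chisq`,
#'   `df`, discrepancy value, convergence flag, and the inputs.
#' @export
fit_path_model <- function(S, n, model = path_model_spec(),
                           max_iter = 500L, grad_tol = 1e-8) {
  S <- as.matrix(S)
  vars <- c(model$indicators, model$outcome)
  if (is.null(rownames(S))) {
    if (nrow(S) != length(vars)) stop("unnamed S of wrong size", call. = FALSE)
    dimnames(S) <- list(vars, vars)
  }
  missing <- setdiff(vars, rownames(S))
  if (length(missing)) {
    stop("S lacks variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  S <- S[vars, vars]
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric", call. = FALSE)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) stop("S must be positive definite", call. = FALSE)
  k <- length(model$indicators)
  p <- k + 1L
  if (n <= p) stop("n must exceed the number of observed variables",
                   call. = FALSE)
  logdetS <- 2 * sum(log(diag(chS)))
  m <- length(model$error_cov)
  ecov_idx <- if (m) t(vapply(model$error_cov, function(pr)
    match(pr, model$indicators), integer(2L))) else matrix(0L, 0L, 2L)

  unpack <- function(th) {
    th <- unname(th)
    list(lambda = th[1:k], gamma = th[k + 1L],
         psi = exp(th[(k + 2L):(k + 1L + p)]),
         ecov = if (m) th[(k + p + 2L):(k + p + 1L + m)] else numeric(0))
  }
  fn <- function(th) {
    pr <- unpack(th)
    f <- ml_discrepancy(
      implied_sigma(pr$lambda, pr$gamma, pr$psi, ecov_idx, pr$ecov), S, logdetS)
    if (!is.finite(f)) 1e10 else f
  }
  gr <- function(th) {
    pr <- unpack(th)
    Sigma <- implied_sigma(pr$lambda, pr$gamma, pr$psi, ecov_idx, pr$ecov)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(th)))
    Sinv <- chol2inv(ch)
    G <- Sinv - Sinv %*% S %*% Sinv   # dF = tr(G dSigma)
    g <- numeric(length(th))
    lam <- pr$lambda
    for (i in 1:k) {                  # dSigma/dlambda_i
      g[i] <- 2 * sum(G[i, 1:k] * lam) + 2 * G[i, p] * pr$gamma
    }
    g[k + 1L] <- 2 * sum(G[p, 1:k] * lam) + 2 * G[p, p] * pr$gamma
    for (i in 1:p) {                  # log-variance chain rule
      g[k + 1L + i] <- G[i, i] * pr$psi[i]
    }
    if (m) for (j in 1:m) {
      g[k + p + 1L + j] <- 2 * G[ecov_idx[j, 1L], ecov_idx[j, 2L]]
    }
    g
  }

  sds <- sqrt(diag(S))
  start <- c(0.7 * sds[1:k], 0.7 * sds[p], log(0.5 * diag(S)),
             rep(0, m))
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  gnorm <- sqrt(sum(gr(opt$par)^2))
  converged <- is.finite(opt$value) && (gnorm <= grad_tol ||
    (opt$convergence == 0L && gnorm <= 1e-4))
  pr <- unpack(opt$par)
  # sign convention: majority-positive loadings (the factor sign is arbitrary)
  if (sum(pr$lambda < 0) > k / 2) {
    pr$lambda <- -pr$lambda
    pr$gamma <- -pr$gamma
  }
  Sigma <- implied_sigma(pr$lambda, pr$gamma, pr$psi, ecov_idx, pr$ecov)
  dimnames(Sigma) <- dimnames(S)
  isd <- sqrt(diag(Sigma))
  std_lambda <- pr$lambda / isd[1:k]
  std_gamma <- pr$gamma / isd[p]
  names(pr$lambda) <- names(std_lambda) <- model$indicators
  names(pr$psi) <- vars
  n_free <- 2L * k + 2L + m
  df <- p * (p + 1L) / 2L - n_free
  heywood <- any(std_lambda^2 > 1) || std_gamma^2 > 1
  if (heywood) {
    warning("Heywood case: a standardized loading exceeds 1 in magnitude",
            call. = FALSE)
  }
  if (!converged) {
    warning(sprintf("optimizer did not reach gradient tolerance (|g| = %.2e)",
                    gnorm), call. = FALSE)
  }
  structure(list(
    model = model, S = S, n = n,
    loadings = pr$lambda, gamma = pr$gamma, psi = pr$psi,
    error_cov = if (m) stats::setNames(pr$ecov, vapply(model$error_cov,
      paste, "", collapse = "~~")) else numeric(0),
    std_loadings = std_lambda, std_gamma = std_gamma,
    implied = Sigma, discrepancy = max(opt$value, 0),
    chisq = max((n - 1) * opt$value, 0),
    df = df, n_free = n_free,
    converged = converged, grad_norm = gnorm, heywood = heywood
  ), class = "path_model_fit")
}

#' Direct and indirect standardized effects on the outcome
#'
#' The direct effect of each indicator is its standardized loading on the
#' latent strain factor; its indirect effect on the outcome is that loading
#' times the standardized structural coefficient (`indirect = direct * gamma`,
#' an algebraic identity of the single-path topology).
#'
#' @param fit A converged [fit_path_model()] result.
#' @param digits Rounding for the report columns (default 3; use `Inf` for
#'   full precision).
#' @return Data frame with columns `variable`, `direct`, `indirect`, plus one
#'   final row for the structural (strain -> outcome) coefficient.
#' @export
path_effects <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "path_model_fit"))
  if (!fit$converged) {
    warning("effects from a non-converged fit", call. = FALSE)
  }
  direct <- fit$std_loadings
  indirect <- direct * fit$std_gamma
  rnd <- function(x) if (is.finite(digits)) round(x, digits) else x
  data.frame(
    variable = c(names(direct), fit$model$latent),
    direct = rnd(c(direct, fit$std_gamma)),
    indirect = c(rnd(indirect), NA_real_),
    row.names = NULL
  )
}

#' Independence (null) baseline model
#'
#' The baseline for incremental fit indices: all observed variables mutually
#' uncorrelated. Its chi-square has the closed form `-(n - 1) * log|R|` with
#' `R` the sample correlation matrix, on `p(p - 1)/2` degrees of freedom.
#'
#' @param S Sample covariance or correlation matrix (PD).
#' @param n Sample size.
#' @return List with `chisq`, `df`, `n`.
#' @export
independence_null <- function(S, n) {
  S <- as.matrix(S)
  R <- stats::cov2cor(S)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) stop("correlation matrix is singular", call. = FALSE)
  p <- nrow(S)
  list(chisq = -(n - 1) * 2 * sum(log(diag(ch))), df = p * (p - 1L) / 2L,
       n = n)
}

#' Goodness-of-fit indices
#'
#' Standard SEM fit summaries from the fitted and baseline chi-squares:
#' GFI `= 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`, AGFI, NFI, CFI,
#' IFI, RMSEA `= sqrt(max(chisq - df, 0) / (df (n - 1)))`, normed chi-square
#' `chisq / df`, and the chi-square upper-tail p value.
#'
#' @param fit A [fit_path_model()] result.
#' @param null_fit Baseline model as returned by [independence_null()];
#'   computed from the fit's own inputs when omitted.
#' @return List of class `ehsra_fit_indices` with components `gfi`, `agfi`,
#'   `nfi`, `cfi`, `ifi`, `rmsea`, `normed_chisq`, `chisq`, `df`, `p_value`.
#'   With `df = 0`, RMSEA and the normed chi-square are `NaN` with a warning.
#' @export
fit_indices <- function(fit, null_fit = independence_null(fit$S, fit$n)) {
  stopifnot(inherits(fit, "path_model_fit"))
  S <- fit$S
  p <- nrow(S)
  Sinv_S <- solve(fit$implied, S)
  gfi <- 1 - sum(diag(crossprod(Sinv_S - diag(p)))) /
    sum(diag(crossprod(Sinv_S)))
  chisq <- fit$chisq; df <- fit$df
  chisq0 <- null_fit$chisq; df0 <- null_fit$df
  if (df > 0) {
    agfi <- 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)
    rmsea <- sqrt(max(chisq - df, 0) / (df * (fit$n - 1)))
    normed <- chisq / df
    p_value <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    warning("df = 0: RMSEA, AGFI, normed chi-square and p value undefined",
            call. = FALSE)
    agfi <- rmsea <- normed <- p_value <- NaN
  }
  nfi <- (chisq0 - chisq) / chisq0
  cfi <- 1 - max(chisq - df, 0) / max(chisq0 - df0, chisq - df, 0)
  if (!is.finite(cfi)) cfi <- 1  # both discrepancies zero
  ifi <- (chisq0 - chisq) / (chisq0 - df)
  structure(list(gfi = gfi, agfi = agfi, nfi = nfi, cfi = cfi, ifi = ifi,
                 rmsea = rmsea, normed_chisq = normed,
                 chisq = chisq, df = df, p_value = p_value),
            class = "ehsra_fit_indices")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("One-factor path model fit (ML), n = %d, chisq = %.4g on %d df%s\n",
              x$n, x$chisq, x$df,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  eff <- path_effects(x)
  print(eff)
  invisible(x)
}

#' @export
print.ehsra_fit_indices <- function(x, ...) {
  cat("Goodness-of-fit indices\n")
  vals <- c(GFI = x$gfi, AGFI = x$agfi, NFI = x$nfi, CFI = x$cfi,
            IFI = x$ifi, RMSEA = x$rmsea, `chisq/df` = x$normed_chisq,
            `p value` = x$p_value)
  print(round(vals, 3))
  invisible(x)
}
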