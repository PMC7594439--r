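# Independent oracles used across the suite. These deliberately re-derive
# every formula from scratch (literal arithmetic, enumeration, or a second
# optimizer) and share no code with the package internals they check.

# -- index ------------------------------------------------------------------

# literal term-by-term score evaluation from the published constants
oracle_score <- function(row) {
  cf <- c(0.752, 0.686, 0.774, 0.244, 0.491, 0.387)
  mn <- c(21.97, 12.10, 23.40, 0.0, 130, 0.50)
  rg <- c(26.23, 25.47, 39.30, 4.20, 360, 0.85)
  x <- c(row$t_dry, row$t_wet, row$t_globe, row$v_air, row$metabolism,
         row$clo)
  z <- (x - mn) / rg
  s <- cf[1] * z[1] + cf[2] * z[2] + cf[3] * z[3] + cf[5] * z[5] +
    cf[6] * z[6]
  s <- s + (if (row$t_dry < 35) -1 else 1) * cf[4] * z[4]
  10 * s
}

random_thermal <- function(n) {
  t_dry <- runif(n, 20, 50)
  data.frame(
    t_dry = t_dry, t_wet = runif(n, 10, 40),
    t_globe = t_dry + runif(n, 1, 18),  # keep radiant load above air temp
    v_air = runif(n, 0, 4.5),
    metabolism = runif(n, 120, 500), clo = runif(n, 0.45, 1.4)
  )
}

# -- ROC --------------------------------------------------------------------

# AUC by explicit pair counting (ties half) over all pos x neg pairs
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# enumerate every threshold (each distinct score and both infinities),
# classify by score >= t, count the confusion table directly, and pick the
# operating point nearest (1, 1), ties toward higher sensitivity then lower
# threshold
oracle_best_point <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  P <- sum(labels == 1); N <- sum(labels == 0)
  best <- NULL
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    sens <- tp / P; spec <- (N - fp) / N
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 && sens > best$sens + 1e-15)) {
      best <- list(d = d, sens = sens, spec = spec, t = t)
    }
  }
  best
}

# all distinguishable labelled datasets of size n over a score alphabet:
# compositions of n over the (score, label) symbol pairs
enumerate_count_vectors <- function(n, n_symbols) {
  rec <- function(remaining, slots) {
    if (slots == 1L) return(matrix(remaining, 1L, 1L))
    parts <- lapply(0:remaining, function(k) {
      cbind(k, rec(remaining - k, slots - 1L))
    })
    do.call(rbind, parts)
  }
  unname(rec(n, n_symbols))
}

# -- SEM --------------------------------------------------------------------

# implied covariance of the one-factor + outcome model, re-derived
oracle_sem_sigma <- function(lambda, gamma, psi) {
  k <- length(lambda)
  Sxx <- lambda %*% t(lambda) + diag(psi[1:k], k)
  Sxy <- lambda * gamma
  rbind(cbind(Sxx, Sxy), c(Sxy, gamma^2 + psi[k + 1]))
}

# second, independent ML fit: same discrepancy re-derived via determinant()
# and solve(), optimized with nlminb (PORT) from a perturbed start
oracle_fit_sem <- function(S, n, jitter = 0.15) {
  k <- nrow(S) - 1L
  obj <- function(th) {
    lambda <- th[1:k]; gamma <- th[k + 1]
    psi <- exp(th[(k + 2):(2 * k + 2)])
    Sig <- oracle_sem_sigma(lambda, gamma, psi)
    ld <- determinant(Sig, logarithm = TRUE)
    if (ld$sign <= 0) return(1e9)
    v <- as.numeric(ld$modulus) + sum(diag(solve(Sig, S))) -
      as.numeric(determinant(S, logarithm = TRUE)$modulus) - nrow(S)
    if (!is.finite(v)) 1e9 else v
  }
  sds <- sqrt(diag(S))
  start <- c(0.5 * sds[1:k] + jitter, 0.5 * sds[k + 1] - jitter,
             log(0.6 * diag(S)))
  o <- stats::nlminb(start, obj, control = list(iter.max = 2000,
                                                eval.max = 4000))
  lambda <- o$par[1:k]; gamma <- o$par[k + 1]
  if (sum(lambda < 0) > k / 2) {
    lambda <- -lambda; gamma <- -gamma
  }
  list(lambda = lambda, gamma = gamma, value = o$objective,
       chisq = (n - 1) * o$objective)
}

# random one-factor-consistent PD covariance (optionally perturbed but PD)
random_sem_cov <- function(k = 6, perturb = 0) {
  lambda <- runif(k, 0.3, 0.95)
  gamma <- runif(1, 0.4, 0.9)
  psi <- c(runif(k, 0.2, 1), runif(1, 0.2, 1))
  S <- oracle_sem_sigma(lambda, gamma, psi)
  if (perturb > 0) {
    p <- k + 1L
    E <- matrix(rnorm(p * p, sd = perturb), p)
    S <- S + crossprod(E) / p
  }
  vars <- c(paste0("x", 1:k), "tympanic")
  dimnames(S) <- list(vars, vars)
  list(S = S, lambda = lambda, gamma = gamma, psi = psi)
}

# -- misc -------------------------------------------------------------------

# random PD correlation matrix with an outcome column, via a scaled Wishart
random_corr7 <- function() {
  repeat {
    A <- matrix(rnorm(49), 7)
    W <- crossprod(A) + diag(7) * 0.5
    R <- cov2cor(W)
    vars <- c("t_dry", "t_wet", "t_globe", "v_air", "metabolism", "clo",
              "tympanic")
    dimnames(R) <- list(vars, vars)
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > 1e-4) {
      return(R)
    }
  }
}
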