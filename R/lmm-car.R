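# Linear mixed model for paired air-water temperatures:
#
#   Tw_ij = alpha + beta_air * Ta_ij + beta * X_j + catchment_k
#           + b0_j + b1_j * Ta_ij + e_ij
#
# with (b0_j, b1_j) ~ N(0, D) per site and, for the daily timescale, a
# continuous AR(1) within-site error correlation cor(e_s, e_t) = phi^|s-t|.
#
# The marginal likelihood is evaluated per site, never on a stacked N x N
# matrix: each site's CAR(1) correlation is whitened by the exact
# bidiagonal innovations transform (valid for arbitrary gaps), after which
# the covariance is a rank-2 update of sigma^2 * I handled by the
# Woodbury identity with a 2x2 core. beta and sigma^2 are profiled out,
# leaving at most four free parameters: the log-Cholesky factor of
# D / sigma^2 and a logit-transformed phi.

#' Model specification for the air-water temperature LMM
#'
#' @param env_terms character vector of environmental covariates to include
#'   as fixed effects (any subset of [env_covariates()]; may be empty for
#'   the air + catchment baseline).
#' @param timescale `"day"` or `"month"`; decides the units of the CAR time
#'   covariate.
#' @param correlation `"car1"` or `"none"`. The convention mirrored here is
#'   CAR(1) for daily series and independent errors for monthly series.
#' @param method `"REML"` (reported coefficients) or `"ML"` (likelihood
#'   ratio comparisons).
#' @param random if `FALSE`, drop the site random effects entirely
#'   (a GLS/OLS reduction used mostly for checks).
#' @param center_air center the air covariate at its grand mean (off by
#'   default: intercepts are reported on the raw scale).
#' @return object of class `lmm_spec`.
#' @export
lmm_spec <- function(env_terms = env_covariates(),
                     timescale = c("day", "month"),
                     correlation = NULL,
                     method = c("REML", "ML"),
                     random = TRUE,
                     center_air = FALSE) {
  timescale <- match.arg(timescale)
  method <- match.arg(method)
  if (is.null(correlation))
    correlation <- if (timescale == "day") "car1" else "none"
  correlation <- match.arg(correlation, c("car1", "none"))
  if (length(env_terms) && !is.character(env_terms))
    stop("`env_terms` must be a character vector", call. = FALSE)
  structure(list(env_terms = env_terms, timescale = timescale,
                 correlation = correlation, method = method,
                 random = random, center_air = center_air),
            class = "lmm_spec")
}

#' Continuous AR(1) correlation at a time gap
#'
#' Correlation between two residuals separated by `dt` units of time:
#' `phi^dt`, valid for non-integer gaps.
#'
#' @param phi correlation at lag 1, in `[0, 1)`.
#' @param dt non-negative time gap (vectorised).
#' @export
car_correlation <- function(phi, dt) {
  stopifnot_scalar(phi, "phi", lower = 0, upper = 1 - 1e-12)
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  phi^dt
}

#' Build the fixed/random design for the air-water LMM
#'
#' Joins the paired observations with the site covariate table and lays out
#' the stacked design: fixed columns in the order intercept, air
#' temperature, catchment dummies (treatment coding, reference = first
#' level alphabetically), then the requested environmental covariates;
#' random design `Z = [1, Ta]` per site; time covariate in timescale units.
#'
#' @param paired `data.frame(site_id, t, Ta, Tw)` (e.g. from
#'   [pair_observations()] or [simulate_paired_obs()]).
#' @param sites site covariate table from [generate_sites()] (or the same
#'   layout).
#' @param spec an [lmm_spec()].
#' @return an `lmm_design` list with stacked `X`, `Z`, `y`, `t`, integer
#'   site index and term metadata.
#' @export
build_design <- function(paired, sites, spec = lmm_spec()) {
  need <- c("site_id", "t", "Ta", "Tw")
  if (!all(need %in% names(paired)))
    stop("`paired` needs columns site_id, t, Ta, Tw", call. = FALSE)
  missing_sites <- setdiff(unique(paired$site_id), sites$site_id)
  if (length(missing_sites))
    stop("sites without covariates: ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  idx <- match(paired$site_id, sites$site_id)
  ord <- order(paired$site_id, paired$t)
  paired <- paired[ord, , drop = FALSE]
  idx <- idx[ord]
  if (anyDuplicated(paste(paired$site_id, paired$t)))
    stop("duplicated time points within a site", call. = FALSE)

  site_f <- factor(paired$site_id)
  J <- nlevels(site_f)
  N <- nrow(paired)
  Ta <- paired$Ta
  if (spec$center_air) Ta <- Ta - mean(Ta)

  X <- cbind(`(Intercept)` = rep(1, N), air = Ta)
  col_class <- c("within", "within")
  catch <- droplevels(factor(sites$catchment[idx]))
  catchment_cols <- character(0)
  if (nlevels(catch) > 1L) {
    lev <- sort(levels(catch))
    catch <- factor(catch, levels = lev)        # alphabetical reference
    Cm <- stats::model.matrix(~catch)[, -1, drop = FALSE]
    colnames(Cm) <- paste0("catchment", lev[-1])
    X <- cbind(X, Cm)
    catchment_cols <- colnames(Cm)
    col_class <- c(col_class, rep("between", ncol(Cm)))
  } else if (nlevels(catch) == 1L && length(unique(sites$catchment)) > 1L) {
    warning("catchment is constant after subsetting; dropped from the design")
  }
  for (nm in spec$env_terms) {
    if (is.null(sites[[nm]]))
      stop(sprintf("site table lacks covariate `%s`", nm), call. = FALSE)
    X <- cbind(X, sites[[nm]][idx])
    colnames(X)[ncol(X)] <- nm
    col_class <- c(col_class, "between")
  }
  structure(list(
    X = X, Z = cbind(1, Ta), y = paired$Tw, t = as.numeric(paired$t),
    site = as.integer(site_f), site_levels = levels(site_f),
    first = match(seq_len(J), as.integer(site_f)),
    N = N, J = J, p = ncol(X), col_class = col_class,
    catchment_cols = catchment_cols, spec = spec,
    paired = paired
  ), class = "lmm_design")
}

# ---- likelihood core -------------------------------------------------------

# Whiten the stacked columns by the per-site CAR(1) innovations transform.
# Returns the transformed matrix and log|R| summed over sites.
car_whiten <- function(M, d, phi) {
  if (phi <= 0) return(list(M = M, ldR = 0))
  N <- d$N
  r <- c(0, phi^diff(d$t))
  r[d$first] <- 0
  a <- sqrt(1 - r * r)
  lagM <- rbind(0, M[-N, , drop = FALSE])
  list(M = (M - r * lagM) / a, ldR = sum(log1p(-r * r)))
}

# Accumulated per-site quantities needed by the profiled likelihood.
# lam is the lower-triangular factor of D / sigma^2 (2x2); phi the CAR
# parameter (0 for independent errors). Returns A = [X y]' V^-1 [X y]
# * sigma^2 (a (p+1)x(p+1) matrix), plus log-determinant pieces.
lmm_core <- function(d, lam, phi) {
  W <- cbind(d$X, d$y)
  wh <- car_whiten(cbind(W, d$Z), d, phi)
  p1 <- ncol(W)
  Wt <- wh$M[, seq_len(p1), drop = FALSE]
  Zt <- wh$M[, p1 + (1:2), drop = FALSE]
  s <- d$site
  A <- crossprod(Wt)
  ldM <- 0
  if (!(lam[1, 1] == 0 && lam[2, 1] == 0 && lam[2, 2] == 0)) {
    z1 <- Zt[, 1]; z2 <- Zt[, 2]
    s11 <- rowsum(z1 * z1, s); s12 <- rowsum(z1 * z2, s)
    s22 <- rowsum(z2 * z2, s)
    G1 <- rowsum(z1 * Wt, s); G2 <- rowsum(z2 * Wt, s)
    a11 <- lam[1, 1]; a21 <- lam[2, 1]; a22 <- lam[2, 2]
    q11 <- a11^2 * s11 + 2 * a11 * a21 * s12 + a21^2 * s22
    q12 <- a22 * (a11 * s12 + a21 * s22)
    q22 <- a22^2 * s22
    detM <- (1 + q11) * (1 + q22) - q12^2
    m11 <- (1 + q22) / detM
    m22 <- (1 + q11) / detM
    m12 <- -q12 / detM
    k11 <- a11^2 * m11
    k12 <- a11 * (a21 * m11 + a22 * m12)
    k22 <- a21^2 * m11 + 2 * a21 * a22 * m12 + a22^2 * m22
    A <- A - (crossprod(G1, as.vector(k11) * G1) +
              crossprod(G1, as.vector(k12) * G2) +
              crossprod(G2, as.vector(k12) * G1) +
              crossprod(G2, as.vector(k22) * G2))
    ldM <- sum(log(detM))
  }
  list(A = A, ldR = wh$ldR, ldM = ldM)
}

# Profiled negative log-likelihood over theta. theta packs the free
# parameters: log-Cholesky of D/sigma^2 (3 values) when random effects are
# estimated, then qlogis(phi) when the CAR parameter is estimated.
theta_unpack <- function(theta, d, fix_phi = NULL) {
  i <- 0L
  if (d$spec$random) {
    lam <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
    i <- 3L
  } else lam <- matrix(0, 2, 2)
  phi <- if (d$spec$correlation == "car1") {
    if (!is.null(fix_phi)) fix_phi else stats::plogis(theta[i + 1L])
  } else 0
  list(lam = lam, phi = phi)
}

profiled_nll <- function(theta, d, method, fix_phi = NULL) {
  pr <- theta_unpack(theta, d, fix_phi)
  if (!all(is.finite(pr$lam))) return(1e10)
  core <- lmm_core(d, pr$lam, pr$phi)
  p <- d$p; N <- d$N
  Axx <- core$A[seq_len(p), seq_len(p), drop = FALSE]
  Axy <- core$A[seq_len(p), p + 1L]
  Ayy <- core$A[p + 1L, p + 1L]
  ch <- tryCatch(chol(Axx), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), Axy))
  rss <- max(Ayy - sum(Axy * beta), 1e-300)
  if (method == "ML") {
    sig2 <- rss / N
    ll <- -0.5 * (core$ldR + core$ldM + N * log(sig2) + N + N * log(2 * pi))
  } else {
    sig2 <- rss / (N - p)
    ll <- -0.5 * (core$ldR + core$ldM + (N - p) * log(sig2) +
                    2 * sum(log(diag(ch))) + (N - p) +
                    (N - p) * log(2 * pi))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

# GLS estimates and covariance at given variance parameters.
gls_at <- function(d, lam, phi, method) {
  core <- lmm_core(d, lam, phi)
  p <- d$p; N <- d$N
  Axx <- core$A[seq_len(p), seq_len(p), drop = FALSE]
  Axy <- core$A[seq_len(p), p + 1L]
  Ayy <- core$A[p + 1L, p + 1L]
  ch <- chol(Axx)
  beta <- backsolve(ch, forwardsolve(t(ch), Axy))
  rss <- max(Ayy - sum(Axy * beta), 0)
  sig2 <- rss / if (method == "ML") N else N - p
  list(beta = beta, sig2 = sig2,
       beta_cov = sig2 * chol2inv(ch),
       core = core, rss = rss)
}

heuristic_start <- function(d) {
  # per-site OLS of y on [1, Ta] to seed the variance components
  p <- d$p
  res_all <- numeric(d$N)
  b0 <- b1 <- numeric(d$J)
  ok <- rep(FALSE, d$J)
  # global OLS residual scale as fallback
  fit0 <- stats::lm.fit(d$X, d$y)
  sig0 <- max(stats::sd(fit0$residuals), 1e-3)
  for (j in seq_len(d$J)) {
    i <- which(d$site == j)
    if (length(i) >= 3) {
      f <- stats::lm.fit(d$Z[i, , drop = FALSE], d$y[i])
      b0[j] <- f$coefficients[1]; b1[j] <- f$coefficients[2]
      res_all[i] <- f$residuals
      ok[j] <- all(is.finite(f$coefficients))
    }
  }
  if (sum(ok) >= 3) {
    t00 <- max(stats::sd(b0[ok]), 1e-3)
    t11 <- max(stats::sd(b1[ok]), 1e-4)
    sig <- max(stats::sd(res_all[d$site %in% which(ok)]), 1e-3)
  } else {
    t00 <- sig0 / 2; t11 <- 0.05; sig <- sig0
  }
  phi0 <- 0.3
  if (d$spec$correlation == "car1") {
    r <- res_all[-1] * res_all[-d$N]
    same <- d$site[-1] == d$site[-d$N]
    v <- stats::var(res_all)
    if (v > 0 && any(same))
      phi0 <- min(max(mean(r[same]) / v, 0.05), 0.98)
  }
  th <- c(log(t00 / sig), 0, log(t11 / sig))
  if (!d$spec$random) th <- numeric(0)
  if (d$spec$correlation == "car1") th <- c(th, stats::qlogis(phi0))
  th
}

#' Marginal log-likelihood of the air-water LMM at given parameters
#'
#' Evaluates the Gaussian marginal log-likelihood with per-site covariance
#' `V_j = Z_j D Z_j' + sigma^2 R_j(phi)`, `R_j[k,l] = phi^|t_k - t_l|`,
#' computed through per-site factorisations (never a stacked N x N
#' matrix). With `beta = NULL` the fixed effects are profiled out by GLS.
#' `method = "REML"` adds the restricted-likelihood adjustment
#' `-0.5 log|sum_j X_j' V_j^-1 X_j|`.
#'
#' @param design an [build_design()] object.
#' @param D 2x2 random-effects covariance (PSD; intercept first, air slope
#'   second).
#' @param sigma residual SD (> 0).
#' @param phi CAR(1) parameter in `[0, 1)`; ignored unless the design's
#'   spec uses `correlation = "car1"`.
#' @param beta optional fixed-effect vector; profiled out when `NULL`.
#' @param method `"ML"` or `"REML"`.
#' @return scalar log-likelihood.
#' @export
lmm_loglik <- function(design, D, sigma, phi = 0, beta = NULL,
                       method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot_scalar(sigma, "sigma", lower = 1e-12)
  if (phi < 0 || phi >= 1) stop("`phi` must lie in [0, 1)", call. = FALSE)
  use_phi <- if (design$spec$correlation == "car1") phi else 0
  lam <- chol2_lower(D) / sigma
  core <- lmm_core(design, lam, use_phi)
  p <- design$p; N <- design$N
  Axx <- core$A[seq_len(p), seq_len(p), drop = FALSE]
  Axy <- core$A[seq_len(p), p + 1L]
  Ayy <- core$A[p + 1L, p + 1L]
  ch <- if (is.null(beta) || method == "REML") chol(Axx) else NULL
  if (is.null(beta)) {
    beta <- backsolve(ch, forwardsolve(t(ch), Axy))
    quad <- max(Ayy - sum(Axy * beta), 0)
  } else {
    quad <- Ayy - 2 * sum(beta * Axy) + drop(crossprod(beta, Axx %*% beta))
  }
  sig2 <- sigma^2
  if (method == "ML") {
    ll <- -0.5 * (core$ldR + core$ldM + N * log(sig2) + quad / sig2 +
                    N * log(2 * pi))
  } else {
    # restricted likelihood: log|X' V^-1 X| = log|Axx| - p log sig2
    ll <- -0.5 * (core$ldR + core$ldM + N * log(sig2) + quad / sig2 +
                    2 * sum(log(diag(ch))) - p * log(sig2) +
                    (N - p) * log(2 * pi))
  }
  ll
}

#' Fit the air-water temperature mixed model
#'
#' Maximises the profiled REML or ML likelihood over an unconstrained
#' parameterisation (log-Cholesky factor of `D / sigma^2`, logit of `phi`),
#' with `beta` and `sigma^2` profiled out analytically. Runs `n_starts`
#' deterministic starts (a moment-based start from per-site OLS plus fixed
#' jitters) and keeps the best optimum.
#'
#' @param paired paired observations (`site_id, t, Ta, Tw`), or `NULL` when
#'   `design` is given.
#' @param sites site covariate table; ignored when `design` is given.
#' @param spec an [lmm_spec()].
#' @param design optionally a prebuilt [build_design()] object.
#' @param n_starts number of optimiser starts (default 3).
#' @param fix_phi optionally hold the CAR parameter fixed at this value.
#' @param start optional explicit starting theta (used for warm starts).
#' @param control passed to [stats::nlminb()].
#' @return object of class `stlmm`: fixed estimates and covariance, `D`
#'   (with `tau00`, `tau11`, `d_corr`), `sigma`, `phi`, log-likelihood,
#'   convergence flag, and the design (for downstream metrics).
#' @export
fit_lmm <- function(paired = NULL, sites = NULL, spec = lmm_spec(),
                    design = NULL, n_starts = 3, fix_phi = NULL,
                    start = NULL, control = list(iter.max = 500,
                                                 eval.max = 800)) {
  d <- if (is.null(design)) build_design(paired, sites, spec) else design
  spec <- d$spec
  method <- spec$method
  if (d$J < 2 && spec$random)
    stop("at least 2 sites are required", call. = FALSE)
  if (d$N < 2 * d$p)
    warning("fewer than 2 observations per fixed parameter")
  if (qr(d$X)$rank < d$p) {
    qd <- qr(d$X)
    bad <- colnames(d$X)[qd$pivot[seq(qd$rank + 1, d$p)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  npar <- (if (spec$random) 3L else 0L) +
    (if (spec$correlation == "car1" && is.null(fix_phi)) 1L else 0L)
  if (npar == 0L) {
    pr <- theta_unpack(numeric(0), d, fix_phi)
    g <- gls_at(d, pr$lam, pr$phi, method)
    ll <- -profiled_nll(numeric(0), d, method, fix_phi)
    best <- list(par = numeric(0), objective = -ll, convergence = 0L)
  } else {
    th0 <- if (is.null(start)) heuristic_start(d) else start
    if (!is.null(fix_phi) && spec$correlation == "car1" && is.null(start))
      th0 <- th0[seq_len(npar)]
    th0 <- th0[seq_len(npar)]
    jit <- list(rep(0, npar), rep(0.7, npar), rep(-0.9, npar),
                c(1.2, rep(-0.5, npar - 1)), rep(1.5, npar))
    best <- NULL
    for (k in seq_len(max(1L, n_starts))) {
      thk <- th0 + jit[[1 + (k - 1) %% length(jit)]]
      opt <- tryCatch(
        stats::nlminb(thk, profiled_nll, d = d, method = method,
                      fix_phi = fix_phi, control = control),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$objective) &&
          (is.null(best) || opt$objective < best$objective))
        best <- opt
    }
    if (is.null(best))
      return(structure(list(converged = FALSE, diagnostics = "all starts failed",
                            spec = spec, design = d), class = "stlmm"))
    pr <- theta_unpack(best$par, d, fix_phi)
    g <- gls_at(d, pr$lam, pr$phi, method)
    ll <- -best$objective
  }

  sigma <- sqrt(g$sig2)
  D <- g$sig2 * tcrossprod(pr$lam)
  tau00 <- sqrt(D[1, 1]); tau11 <- sqrt(D[2, 2])
  d_corr <- if (tau00 > 0 && tau11 > 0) D[1, 2] / (tau00 * tau11) else 0
  beta <- drop(g$beta); names(beta) <- colnames(d$X)
  beta_cov <- g$beta_cov
  dimnames(beta_cov) <- list(colnames(d$X), colnames(d$X))
  structure(list(
    beta = beta, beta_cov = beta_cov,
    D = D, tau00 = tau00, tau11 = tau11, d_corr = d_corr,
    sigma = sigma, phi = if (spec$correlation == "car1") pr$phi else NA_real_,
    loglik = ll, method = method,
    converged = is.null(best$convergence) || best$convergence %in% c(0L, 1L),
    theta = best$par, n_obs = d$N, n_sites = d$J,
    spec = spec, design = d
  ), class = "stlmm")
}

#' @export
logLik.stlmm <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + length(object$theta) + 1,
            class = "logLik")
}

#' Fixed-effect inference table with between-within degrees of freedom
#'
#' `t = coef / SE`; degrees of freedom by the between-within rule:
#' site-level terms (catchment contrasts and the environmental covariates,
#' constant within site) use `df = n_sites - q_between - 1`;
#' observation-level terms (intercept, air temperature) use
#' `df = N - n_sites - q_within`. Two-sided p from the t distribution.
#'
#' @param fit a converged [fit_lmm()] object.
#' @return `data.frame(term, coef, se, t, df, p)`.
#' @export
fixed_inference <- function(fit) {
  if (!isTRUE(fit$converged))
    stop("fit did not converge; inference refused", call. = FALSE)
  d <- fit$design
  cls <- d$col_class
  q_between <- sum(cls == "between")
  q_within <- sum(cls == "within") - 1L   # air terms, excluding intercept
  df <- ifelse(cls == "between",
               d$J - q_between - 1L,
               d$N - d$J - q_within)
  se <- sqrt(diag(fit$beta_cov))
  tval <- fit$beta / se
  data.frame(term = names(fit$beta), coef = unname(fit$beta),
             se = unname(se), t = unname(tval), df = df,
             p = 2 * stats::pt(-abs(unname(tval)), df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Likelihood-ratio comparison of nested fixed-effect structures
#'
#' Both models are refit with ML if they were estimated by REML (the
#' convention for ANOVA-type comparisons of fixed effects), then
#' `chi2 = 2 (ll_full - ll_reduced)` on `df` = difference in
#' fixed-parameter counts.
#'
#' @param fit_reduced,fit_full fitted models sharing the random and
#'   correlation structure, with nested fixed terms.
#' @return list with `chi2`, `df`, `p`, and the two ML log-likelihoods.
#' @export
lrt_compare <- function(fit_reduced, fit_full) {
  s0 <- fit_reduced$spec; s1 <- fit_full$spec
  if (!identical(s0$correlation, s1$correlation) ||
      !identical(s0$random, s1$random) ||
      !identical(s0$timescale, s1$timescale))
    stop("models must share the random and correlation structure",
         call. = FALSE)
  n0 <- colnames(fit_reduced$design$X); n1 <- colnames(fit_full$design$X)
  if (!all(n0 %in% n1))
    stop("fixed-effect specifications are not nested", call. = FALSE)
  refit_ml <- function(f) {
    if (f$method == "ML") return(f)
    d <- f$design; d$spec$method <- "ML"
    fit_lmm(design = d, start = if (length(f$theta)) f$theta else NULL)
  }
  f0 <- refit_ml(fit_reduced); f1 <- refit_ml(fit_full)
  chi2 <- 2 * (f1$loglik - f0$loglik)
  df <- length(n1) - length(n0)
  p <- if (df == 0) 1 else stats::pchisq(max(chi2, 0), df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p,
       loglik_reduced = f0$loglik, loglik_full = f1$loglik)
}

#' @export
print.stlmm <- function(x, digits = 4, ...) {
  if (!isTRUE(x$converged)) {
    cat("Air-water temperature LMM: NOT CONVERGED\n")
    return(invisible(x))
  }
  cat(sprintf("Air-water temperature LMM (%s, %s timescale, errors: %s)\n",
              x$method, x$spec$timescale, x$spec$correlation))
  cat("\nFixed effects:\n")
  print(fixed_inference(x), digits = digits)
  cat("\nRandom effects:\n")
  cat(sprintf("  Residual standard deviation (sigma)    %.*f\n", 3, x$sigma))
  cat(sprintf("  Site (intercept) standard deviation    %.*f\n", 3, x$tau00))
  cat(sprintf("  Site (air slope) standard deviation    %.*f\n", 3, x$tau11))
  if (x$spec$correlation == "car1")
    cat(sprintf("  Correlation at lag 1 (phi)             %.*f\n", 3, x$phi))
  r2 <- tryCatch(r2_nakagawa(x), error = function(e) NULL)
  if (!is.null(r2)) {
    cat(sprintf("  Intraclass correlation (ICC)           %.*f\n", 3,
                icc_adjusted(x)))
    cat(sprintf("\nObservations: %d sites: %d\n", x$n_obs, x$n_sites))
    cat(sprintf("Marginal / Conditional R2: %.3f / %.3f\n",
                r2[["r2_marginal"]], r2[["r2_conditional"]]))
  }
  invisible(x)
}
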