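# Model-assessment statistics: Nakagawa-Schielzeth marginal/conditional
# R-squared (random-slope extension), adjusted ICC, population-level RMSE,
# and (generalised) variance inflation factors.

variance_components <- function(fit) {
  d <- fit$design
  xb <- drop(d$X %*% fit$beta)
  var_f <- stats::var(xb)
  # random-slope extension: mean over observations of z_i' D z_i
  Z <- d$Z
  var_r <- mean(Z[, 1]^2 * fit$D[1, 1] + 2 * Z[, 1] * Z[, 2] * fit$D[1, 2] +
                  Z[, 2]^2 * fit$D[2, 2])
  list(var_f = var_f, var_r = var_r, var_e = fit$sigma^2, xb = xb)
}

#' Marginal and conditional R-squared for the fitted mixed model
#'
#' Variance-component decomposition: `var_f` is the variance of the
#' fixed-effect predictions over all observations; `var_r` the mean over
#' observations of `z_i' D z_i` (random-slope extension of the
#' between-site variance); `var_e` the residual variance `sigma^2` (the
#' CAR(1) correlation redistributes, not inflates, the stationary residual
#' variance, so it does not enter the partition). Marginal R2 is the fixed
#' share of the total; conditional R2 the fixed-plus-random share.
#'
#' @param fit a converged [fit_lmm()] object.
#' @return named vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_nakagawa <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  vc <- variance_components(fit)
  tot <- vc$var_f + vc$var_r + vc$var_e
  if (tot <= 0) stop("total variance is zero; R2 undefined", call. = FALSE)
  c(r2_marginal = vc$var_f / tot,
    r2_conditional = (vc$var_f + vc$var_r) / tot)
}

#' Adjusted intraclass correlation of the fitted mixed model
#'
#' `var_r / (var_r + var_e)` with the same random-slope `var_r` as
#' [r2_nakagawa()]; algebraically equal to
#' `(R2c - R2m) / (1 - R2m)`.
#'
#' @param fit a converged [fit_lmm()] object.
#' @export
icc_adjusted <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  vc <- variance_components(fit)
  den <- vc$var_r + vc$var_e
  if (den <= 0) stop("no non-fixed variance; ICC undefined", call. = FALSE)
  vc$var_r / den
}

#' Population-level RMSE of the fitted model
#'
#' Root mean squared error of the fixed-effects-only predictions (random
#' effects set to zero), in degC.
#'
#' @param fit a converged [fit_lmm()] object.
#' @export
rmse_population <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  d <- fit$design
  if (d$N == 0) stop("empty data", call. = FALSE)
  sqrt(mean((d$y - drop(d$X %*% fit$beta))^2))
}

# Empirical BLUPs of the site random effects: b_j = D Z_j' V_j^-1 r_j.
#' Predicted site-level random effects (BLUPs)
#' @param fit a converged [fit_lmm()] object.
#' @return matrix `n_sites x 2` (intercept, air slope deviations).
#' @export
ranef_sites <- function(fit) {
  d <- fit$design
  r <- d$y - drop(d$X %*% fit$beta)
  phi <- if (is.na(fit$phi)) 0 else fit$phi
  out <- matrix(0, d$J, 2,
                dimnames = list(d$site_levels, c("intercept", "air")))
  for (j in seq_len(d$J)) {
    i <- which(d$site == j)
    Zj <- d$Z[i, , drop = FALSE]
    tj <- d$t[i]
    R <- phi^abs(outer(tj, tj, `-`))
    V <- Zj %*% fit$D %*% t(Zj) + fit$sigma^2 * R
    out[j, ] <- drop(fit$D %*% crossprod(Zj, solve(V, r[i])))
  }
  out
}

#' Conditional-residual RMSE (random effects included)
#' @param fit a converged [fit_lmm()] object.
#' @export
rmse_conditional <- function(fit) {
  d <- fit$design
  b <- ranef_sites(fit)
  pred <- drop(d$X %*% fit$beta) +
    b[d$site, 1] + b[d$site, 2] * d$Z[, 2]
  sqrt(mean((d$y - pred)^2))
}

#' Variance inflation factors of the fixed design
#'
#' For each non-intercept column, `1 / (1 - R2)` of regressing it on the
#' other non-intercept columns. The multi-column catchment term
#' additionally gets a generalised VIF (determinant ratio of the
#' correlation matrix). Terms whose (G)VIF exceeds `cutoff` are flagged;
#' perfectly collinear columns report `Inf`.
#'
#' @param design an [build_design()] object or an `stlmm` fit.
#' @param cutoff flag threshold (default 10, the conventional cut-off).
#' @return `data.frame(term, vif, df, flagged)`.
#' @export
vif_terms <- function(design, cutoff = 10) {
  d <- if (inherits(design, "stlmm")) design$design else design
  X <- d$X[, colnames(d$X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2)
    stop("VIF needs at least two non-intercept columns", call. = FALSE)
  Rm <- suppressWarnings(stats::cor(X))
  per_col <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(per_col) <- colnames(X)

  terms <- list()
  cc <- d$catchment_cols
  if (length(cc) > 1) {
    oth <- setdiff(colnames(X), cc)
    gvif <- tryCatch({
      det(Rm[cc, cc, drop = FALSE]) * det(Rm[oth, oth, drop = FALSE]) /
        det(Rm)
    }, error = function(e) Inf)
    if (!is.finite(gvif) || gvif < 0) gvif <- Inf
    terms[["catchment"]] <- c(vif = gvif, df = length(cc))
  } else if (length(cc) == 1) {
    terms[["catchment"]] <- c(vif = unname(per_col[cc]), df = 1)
  }
  for (nm in setdiff(colnames(X), cc))
    terms[[nm]] <- c(vif = unname(per_col[nm]), df = 1)
  out <- data.frame(
    term = names(terms),
    vif = vapply(terms, `[[`, numeric(1), "vif"),
    df = vapply(terms, `[[`, numeric(1), "df"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$flagged <- !is.finite(out$vif) | out$vif > cutoff
  out
}

#' Full metrics report for a fitted model
#'
#' @param fit a converged [fit_lmm()] object.
#' @param vif_cutoff threshold above which terms are flagged.
#' @return list with `r2_marginal`, `r2_conditional`, `icc_adjusted`,
#'   `rmse_population`, `vif` table and flagged term names.
#' @export
metrics_report <- function(fit, vif_cutoff = 10) {
  r2 <- r2_nakagawa(fit)
  vif <- if (ncol(fit$design$X) > 2) vif_terms(fit, cutoff = vif_cutoff)
  else NULL
  flagged <- if (!is.null(vif)) vif$term[vif$flagged] else character(0)
  if (length(flagged))
    warning("VIF above cut-off for: ", paste(flagged, collapse = ", "))
  list(r2_marginal = unname(r2[["r2_marginal"]]),
       r2_conditional = unname(r2[["r2_conditional"]]),
       icc_adjusted = icc_adjusted(fit),
       rmse_population = rmse_population(fit),
       vif = vif, flagged = flagged)
}
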