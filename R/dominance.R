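# All-subsets dominance analysis of environmental predictors over an
# air-temperature + catchment baseline, measured as marginal-R2 additional
# contributions (Azen & Budescu's complete / conditional / general
# hierarchy, plus Shapley-type relative importance shares).

subset_key <- function(s) {
  if (!length(s)) "(baseline)" else paste(sort(s), collapse = "+")
}

all_subsets <- function(predictors) {
  p <- length(predictors)
  out <- vector("list", 2^p)
  for (m in 0:(2^p - 1))
    out[[m + 1]] <- predictors[bitwAnd(m, bitwShiftL(1, seq_len(p) - 1)) > 0]
  out
}

#' Fit statistic for every subset of the candidate predictors
#'
#' Evaluates `r2_fun` (a function taking a character vector of predictors
#' and returning the model's fit statistic, typically marginal R2 of the
#' baseline-plus-subset model) on all `2^|P|` subsets, including the empty
#' set (baseline) and the full set.
#'
#' @param r2_fun `function(character()) -> numeric(1)`.
#' @param predictors character vector of candidate predictors (`|P| <= 12`).
#' @return named numeric vector keyed by `subset_key()`; attribute
#'   `predictors` carries the candidate set.
#' @export
enumerate_subsets <- function(r2_fun, predictors) {
  if (length(predictors) > 12)
    stop("at most 12 predictors (2^|P| refits)", call. = FALSE)
  if (anyDuplicated(predictors))
    stop("duplicated predictor names", call. = FALSE)
  subs <- all_subsets(predictors)
  vals <- numeric(length(subs))
  names(vals) <- vapply(subs, subset_key, character(1))
  failures <- character(0)
  for (i in seq_along(subs)) {
    v <- tryCatch(r2_fun(subs[[i]]), error = function(e) {
      failures <<- c(failures, paste0(subset_key(subs[[i]]), ": ",
                                      conditionMessage(e)))
      NA_real_
    })
    vals[i] <- v
  }
  if (length(failures) || anyNA(vals))
    stop("subset model failures:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  attr(vals, "predictors") <- predictors
  vals
}

#' Additional contribution of a predictor to a subset model
#'
#' `R2(S + x) - R2(S)`; may be negative when subset models are refit mixed
#' models (variance components shift between refits), in which case the
#' value is recorded as-is.
#'
#' @param map output of [enumerate_subsets()].
#' @param x a predictor not in `S`.
#' @param S character vector (possibly empty) of other predictors.
#' @export
additional_contribution <- function(map, x, S = character(0)) {
  if (x %in% S) stop("`x` must not be in `S`", call. = FALSE)
  unname(map[subset_key(c(S, x))] - map[subset_key(S)])
}

# Conditional profile: for predictor x, the mean additional contribution
# at each subset size k = 0..|P|-1, averaging over all subsets of the
# other predictors of that size.
conditional_profile <- function(map, x, predictors) {
  others <- setdiff(predictors, x)
  p <- length(predictors)
  sums <- numeric(p); counts <- numeric(p)
  for (S in all_subsets(others)) {
    k <- length(S)
    sums[k + 1] <- sums[k + 1] + additional_contribution(map, x, S)
    counts[k + 1] <- counts[k + 1] + 1
  }
  stats::setNames(sums / counts, paste0("k", 0:(p - 1)))
}

#' General dominance weights (Shapley decomposition of the fit statistic)
#'
#' For each predictor, the mean over subset sizes of the size-wise mean
#' additional contribution. The weights satisfy the efficiency identity
#' `sum(weights) = R2(full) - R2(baseline)` and equal the Shapley values
#' of the R2 game.
#'
#' @param map output of [enumerate_subsets()].
#' @return named numeric vector of weights.
#' @export
general_dominance <- function(map) {
  predictors <- attr(map, "predictors")
  if (is.null(predictors) || length(map) != 2^length(predictors))
    stop("`map` must be a complete enumerate_subsets() result",
         call. = FALSE)
  vapply(predictors, function(x)
    mean(conditional_profile(map, x, predictors)), numeric(1))
}

#' Classify the dominance relation between two predictors
#'
#' Checks, in order of strength: complete dominance (one predictor's
#' additional contribution exceeds the other's over every subset of the
#' remaining predictors), conditional dominance (its size-wise mean
#' contributions are all greater), and general dominance (its overall
#' average is greater). Strict inequality is required at every level;
#' exact ties yield `"none"`.
#'
#' @param map output of [enumerate_subsets()].
#' @param x,y distinct predictors from the candidate set.
#' @return list `(level, dominant, dominated)`; `level` one of
#'   `"complete"`, `"conditional"`, `"general"`, `"none"`.
#' @export
classify_pair <- function(map, x, y) {
  predictors <- attr(map, "predictors")
  if (identical(x, y)) stop("`x` and `y` must differ", call. = FALSE)
  if (!all(c(x, y) %in% predictors))
    stop("`x` and `y` must be candidate predictors", call. = FALSE)
  rest <- setdiff(predictors, c(x, y))
  dx <- dy <- numeric(0)
  for (S in all_subsets(rest)) {
    dx <- c(dx, additional_contribution(map, x, S))
    dy <- c(dy, additional_contribution(map, y, S))
  }
  result <- function(level, who)
    list(level = level, dominant = who, dominated = setdiff(c(x, y), who))
  if (all(dx > dy)) return(result("complete", x))
  if (all(dy > dx)) return(result("complete", y))
  cx <- conditional_profile(map, x, predictors)
  cy <- conditional_profile(map, y, predictors)
  if (all(cx > cy)) return(result("conditional", x))
  if (all(cy > cx)) return(result("conditional", y))
  gx <- mean(cx); gy <- mean(cy)
  if (gx > gy) return(result("general", x))
  if (gy > gx) return(result("general", y))
  list(level = "none", dominant = NA_character_, dominated = NA_character_)
}

#' Relative importance shares from general dominance weights
#'
#' `100 * weight_x / (R2(full) - R2(baseline))`; sums to 100.
#'
#' @param weights output of [general_dominance()].
#' @return named percentages.
#' @export
relative_importance <- function(weights) {
  inc <- sum(weights)
  if (inc <= 0)
    stop("baseline-to-full increment is not positive; shares undefined",
         call. = FALSE)
  100 * weights / inc
}

#' Full dominance analysis over a fit-statistic engine
#'
#' Enumerates all subsets, computes conditional profiles, general
#' dominance weights, pairwise dominance levels and relative importance
#' shares.
#'
#' @param r2_fun `function(character()) -> numeric(1)` returning the fit
#'   statistic of the baseline-plus-subset model.
#' @param predictors candidate predictor names.
#' @return object of class `dominance_result`: `map`, `profiles` (matrix,
#'   predictors x sizes), `general`, `shares` (percent), `pairs`
#'   (data.frame source/target/level), `increment`.
#' @export
dominance_analysis <- function(r2_fun, predictors) {
  map <- enumerate_subsets(r2_fun, predictors)
  profiles <- t(vapply(predictors,
                       function(x) conditional_profile(map, x, predictors),
                       numeric(length(predictors))))
  rownames(profiles) <- predictors
  general <- general_dominance(map)
  pairs <- do.call(rbind, lapply(utils::combn(predictors, 2, simplify = FALSE),
    function(pr) {
      cl <- classify_pair(map, pr[1], pr[2])
      data.frame(source = if (is.na(cl$dominant)) pr[1] else cl$dominant,
                 target = if (is.na(cl$dominant)) pr[2] else cl$dominated,
                 level = cl$level, stringsAsFactors = FALSE)
    }))
  shares <- tryCatch(relative_importance(general), error = function(e) {
    warning("baseline-to-full R2 increment is not positive; ",
            "relative-importance shares are undefined (NA)", call. = FALSE)
    stats::setNames(rep(NA_real_, length(general)), names(general))
  })
  structure(list(
    map = map, profiles = profiles, general = general,
    shares = shares,
    pairs = pairs,
    increment = unname(map[subset_key(predictors)] - map["(baseline)"])
  ), class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, digits = 4, ...) {
  cat("Dominance analysis over", length(x$general), "predictors\n")
  cat(sprintf("Baseline-to-full R2 increment: %.4f\n", x$increment))
  cat("\nGeneral dominance weights (shares %):\n")
  tab <- data.frame(weight = x$general, share = x$shares)
  print(round(tab[order(-tab$weight), ], digits))
  cat("\nPairwise dominance:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' OLS R-squared engine for dominance analysis
#'
#' Classic multiple R2 of an ordinary least-squares fit of `response` on
#' `baseline_terms` plus the subset; the surrogate engine for exact
#' Shapley-value checks.
#'
#' @param data data.frame holding response and predictors.
#' @param response column name of the response.
#' @param baseline_terms columns always included (besides the intercept).
#' @return `function(subset) -> R2`.
#' @export
ols_r2_engine <- function(data, response, baseline_terms = character(0)) {
  y <- data[[response]]
  tss <- sum((y - mean(y))^2)
  function(subset) {
    cols <- c(baseline_terms, subset)
    X <- cbind(1, as.matrix(data[, cols, drop = FALSE]))
    fit <- stats::lm.fit(X, y)
    1 - sum(fit$residuals^2) / tss
  }
}

#' Marginal-R2 LMM engine for dominance analysis
#'
#' Refits the mixed model for each predictor subset over the
#' air + catchment baseline, holding the random and correlation structure
#' (the model form) fixed; variance components are re-estimated in every
#' subset model. Returns the marginal R2. Fits are warm-started from the
#' full model's variance parameters to stabilise and speed up the 2^|P|
#' refits.
#'
#' @param paired,sites data as in [fit_lmm()].
#' @param spec an [lmm_spec()]; its `env_terms` are ignored (the subset
#'   argument replaces them).
#' @param n_starts optimiser starts per subset fit (default 1 on top of
#'   the warm start).
#' @return `function(subset) -> marginal R2`; the environment caches the
#'   fits under `$fits`.
#' @export
lmm_r2m_engine <- function(paired, sites, spec = lmm_spec(),
                           predictors = env_covariates(), n_starts = 2) {
  fits <- new.env(parent = emptyenv())
  full_spec <- spec; full_spec$env_terms <- predictors
  full_fit <- fit_lmm(paired, sites, full_spec)
  if (!isTRUE(full_fit$converged)) stop("full model did not converge")
  warm <- if (length(full_fit$theta)) full_fit$theta else NULL
  attr(full_fit, "r2m") <- unname(r2_nakagawa(full_fit)[["r2_marginal"]])
  fits[[subset_key(predictors)]] <- full_fit
  function(subset) {
    key <- subset_key(subset)
    if (!is.null(fits[[key]])) return(attr(fits[[key]], "r2m"))
    sp <- spec; sp$env_terms <- subset
    f <- fit_lmm(paired, sites, sp, n_starts = n_starts, start = warm)
    if (!isTRUE(f$converged)) stop("subset fit did not converge")
    r2 <- unname(r2_nakagawa(f)[["r2_marginal"]])
    attr(f, "r2m") <- r2
    fits[[key]] <- f
    r2
  }
}
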