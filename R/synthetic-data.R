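# Synthetic paired air-water logger network generator.
#
# Emulates a multi-catchment monitoring design: site tables with catchment
# membership and five environmental covariates, hourly air series
# (seasonal + diel sinusoids + AR(1) noise), water temperatures generated
# from the air-water mixed model truth (random site intercept/slope,
# gap-aware continuous AR(1) residuals), and burst missingness.

#' Environmental covariate names used throughout the package
#'
#' Two catchment-scale land/geology covariates, one geology-age split, and
#' two reach-scale covariates, in the fixed column order the design matrix
#' uses.
#' @export
env_covariates <- function() {
  c("cultivated", "volc_quaternary", "volc_prequaternary",
    "elevation", "riparian_forest")
}

#' True generating parameters for the air-water temperature model
#'
#' Container for the parameters of the generating model: grand intercept
#' `alpha` (degC), air-temperature slope `beta_air`, signed covariate
#' coefficients `beta_env` (degC per covariate unit), catchment offsets
#' relative to the reference catchment, random-effect SDs `tau00`
#' (intercept, degC) and `tau11` (air slope), their correlation `d_corr`,
#' residual SD `sigma` (degC) and the continuous AR(1) parameter `phi`
#' (correlation of residuals one time unit apart).
#'
#' Defaults reproduce the regime of a published 130-station summer
#' monitoring study at each timescale: the daily truth has
#' `alpha = 14.425`, `beta_air = 0.315`, `sigma = 1.518`, `tau00 = 1.081`,
#' `tau11 = 0.09`, `phi = 0.962`; the monthly truth has `alpha = 6.647`,
#' `beta_air = 0.622`, `sigma = 0.826`, `tau00 = 1.323`, `tau11 = 0.135`
#' and independent residuals (`phi = 0`). `d_corr` defaults to 0.
#'
#' @param timescale `"day"` or `"month"`; selects the default parameter set.
#' @param alpha,beta_air,beta_env,catchment_offsets,tau00,tau11,d_corr,sigma,phi
#'   overrides for individual parameters. `beta_env` must be a named vector
#'   over (a subset of) [env_covariates()]; omitted names get coefficient 0.
#' @return An object of class `truth_params` (a named list).
#' @export
truth_params <- function(timescale = c("day", "month"),
                         alpha = NULL, beta_air = NULL, beta_env = NULL,
                         catchment_offsets = NULL,
                         tau00 = NULL, tau11 = NULL, d_corr = 0,
                         sigma = NULL, phi = NULL) {
  timescale <- match.arg(timescale)
  def <- if (timescale == "day") {
    list(alpha = 14.425, beta_air = 0.315,
         beta_env = c(cultivated = 0.033, volc_quaternary = -0.018,
                      volc_prequaternary = -0.002, elevation = -0.044,
                      riparian_forest = -0.013),
         catchment_offsets = c(Kiso = -0.327, Sorachi = -3.922,
                               Teshio = -3.626),
         tau00 = 1.081, tau11 = 0.09, sigma = 1.518, phi = 0.962)
  } else {
    list(alpha = 6.647, beta_air = 0.622,
         beta_env = c(cultivated = 0.043, volc_quaternary = -0.019,
                      volc_prequaternary = -0.008, elevation = -0.022,
                      riparian_forest = -0.006),
         catchment_offsets = c(Kiso = -0.702, Sorachi = -1.987,
                               Teshio = -1.544),
         tau00 = 1.323, tau11 = 0.135, sigma = 0.826, phi = 0)
  }
  env <- def$beta_env
  if (!is.null(beta_env)) {
    if (is.null(names(beta_env)) || !all(names(beta_env) %in% env_covariates()))
      stop("`beta_env` must be named after env_covariates()", call. = FALSE)
    env[] <- 0
    env[names(beta_env)] <- beta_env
  }
  out <- list(
    alpha = if (is.null(alpha)) def$alpha else alpha,
    beta_air = if (is.null(beta_air)) def$beta_air else beta_air,
    beta_env = env,
    catchment_offsets = if (is.null(catchment_offsets)) def$catchment_offsets
    else catchment_offsets,
    tau00 = if (is.null(tau00)) def$tau00 else tau00,
    tau11 = if (is.null(tau11)) def$tau11 else tau11,
    d_corr = d_corr,
    sigma = if (is.null(sigma)) def$sigma else sigma,
    phi = if (is.null(phi)) def$phi else phi,
    timescale = timescale
  )
  stopifnot_scalar(out$sigma, "sigma", lower = 0)
  stopifnot_scalar(out$tau00, "tau00", lower = 0)
  stopifnot_scalar(out$tau11, "tau11", lower = 0)
  if (abs(out$d_corr) >= 1) stop("`d_corr` must lie in (-1, 1)", call. = FALSE)
  if (out$phi < 0 || out$phi >= 1) stop("`phi` must lie in [0, 1)", call. = FALSE)
  class(out) <- "truth_params"
  out
}

# 2x2 random-effect covariance implied by a truth_params object.
truth_D <- function(truth) {
  off <- truth$d_corr * truth$tau00 * truth$tau11
  matrix(c(truth$tau00^2, off, off, truth$tau11^2), 2, 2)
}

#' Generate a site table for a multi-catchment monitoring network
#'
#' Draws `n_sites` monitoring stations allocated over `n_catchments`
#' catchments with bounded environmental covariates: the percentage
#' covariates come from scaled Beta distributions and reach elevation from
#' a truncated log-normal, all configurable through `covariate_config`.
#'
#' @param n_sites number of stations (>= 1).
#' @param n_catchments number of catchments (>= 1, at most 26).
#' @param covariate_config optional named list overriding, per covariate,
#'   `list(shape1=, shape2=)` for the Beta draws (percent covariates) or
#'   `list(meanlog=, sdlog=, min=, max=)` for elevation.
#' @param seed integer master seed.
#' @return `data.frame` with columns `site_id`, `catchment`,
#'   `cultivated`, `volc_quaternary`, `volc_prequaternary`, `elevation`,
#'   `riparian_forest`.
#' @export
generate_sites <- function(n_sites, n_catchments = 4, covariate_config = list(),
                           seed = 1) {
  if (!is.numeric(n_sites) || length(n_sites) != 1L || is.na(n_sites) ||
      n_sites < 1)
    stop("`n_sites` must be a positive count", call. = FALSE)
  if (!is.numeric(n_catchments) || length(n_catchments) != 1L ||
      is.na(n_catchments) || n_catchments < 1)
    stop("`n_catchments` must be a positive count", call. = FALSE)
  n_sites <- as.integer(n_sites); n_catchments <- as.integer(n_catchments)

  # First four catchment labels follow the study naming (Hiji is the
  # alphabetical reference); further ones are generic.
  base_names <- c("Hiji", "Kiso", "Sorachi", "Teshio")
  cat_names <- if (n_catchments <= 4L) base_names[seq_len(n_catchments)]
  else c(base_names, paste0("Catchment", LETTERS[seq_len(n_catchments - 4L)]))

  cfg <- list(
    cultivated = list(shape1 = 1.2, shape2 = 4),
    volc_quaternary = list(shape1 = 0.8, shape2 = 2.5),
    volc_prequaternary = list(shape1 = 0.8, shape2 = 2.5),
    riparian_forest = list(shape1 = 3, shape2 = 1.3),
    # reach elevations of a low/mid-order monitoring network; the range is
    # kept moderate so the elevation effect stays on a physical scale
    elevation = list(meanlog = log(280), sdlog = 0.3, min = 150, max = 450)
  )
  for (nm in names(covariate_config)) cfg[[nm]] <-
      utils::modifyList(cfg[[nm]], covariate_config[[nm]])

  with_seed(seed, {
    # round-robin base allocation keeps every catchment non-empty when
    # n_sites >= n_catchments; the remainder is randomised.
    catchment <- rep(cat_names, length.out = n_sites)
    catchment <- sample(catchment)
    rbeta_pct <- function(nm)
      100 * stats::rbeta(n_sites, cfg[[nm]]$shape1, cfg[[nm]]$shape2)
    el <- cfg$elevation
    elevation <- stats::qlnorm(
      stats::runif(n_sites,
                   stats::plnorm(el$min, el$meanlog, el$sdlog),
                   stats::plnorm(el$max, el$meanlog, el$sdlog)),
      el$meanlog, el$sdlog)
    data.frame(
      site_id = sprintf("S%03d", seq_len(n_sites)),
      catchment = factor(catchment, levels = cat_names),
      cultivated = rbeta_pct("cultivated"),
      volc_quaternary = rbeta_pct("volc_quaternary"),
      volc_prequaternary = rbeta_pct("volc_prequaternary"),
      elevation = elevation,
      riparian_forest = rbeta_pct("riparian_forest"),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate an hourly air-temperature series for one site
#'
#' Site mean (by default a latitudinal catchment offset plus an elevation
#' lapse of -6.5 degC/km on an 18 degC valley-floor baseline) plus an
#' annual sinusoid, a diel sinusoid peaking mid-afternoon, and stationary
#' AR(1) hourly noise.
#'
#' @param site one row of a [generate_sites()] table (list or data.frame).
#' @param start,end first and last calendar day (coercible to `Date`);
#'   hours run from `start 00:00` to `end 23:00` UTC.
#' @param mean_air site mean air temperature; default derived from elevation.
#' @param seasonal_amp,diel_amp sinusoid amplitudes (degC); the diel cycle
#'   has daily range `2 * diel_amp`.
#' @param seasonal_peak_doy day-of-year of the annual maximum.
#' @param ar_coef hourly lag-1 autocorrelation of the noise, in (-1, 1).
#' @param noise_sd stationary SD of the AR(1) noise (degC).
#' @param seed integer seed.
#' @return `data.frame(site_id, timestamp, air, water)` with `water` all `NA`.
#' @export
generate_air_series <- function(site, start, end, mean_air = NULL,
                                seasonal_amp = 8, diel_amp = 3,
                                seasonal_peak_doy = 210,
                                ar_coef = 0.8, noise_sd = 1.2, seed = 1) {
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) stop("`start` must precede `end`", call. = FALSE)
  if (abs(ar_coef) >= 1) stop("`ar_coef` must lie in (-1, 1)", call. = FALSE)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = 3600)
  if (is.null(mean_air)) mean_air <- site_mean_air(site)
  doy <- as.POSIXlt(ts)$yday + 1
  hr <- as.POSIXlt(ts)$hour
  n <- length(ts)
  noise <- with_seed(derive_seed(seed, paste0(site$site_id, "/air")), {
    z <- stats::rnorm(n)
    e <- numeric(n)
    e[1] <- noise_sd * z[1]
    if (n > 1) {
      innov_sd <- noise_sd * sqrt(1 - ar_coef^2)
      for (i in 2:n) e[i] <- ar_coef * e[i - 1] + innov_sd * z[i]
    }
    e
  })
  air <- mean_air +
    seasonal_amp * cos(2 * pi * (doy - seasonal_peak_doy) / 365.25) -
    diel_amp * cos(2 * pi * (hr - 15) / 24) + noise
  data.frame(site_id = site$site_id, timestamp = ts, air = air,
             water = NA_real_, stringsAsFactors = FALSE)
}

# Summer mean air temperature of a site: a latitudinal catchment offset
# (Shikoku/Honshu warmer than Hokkaido) plus an elevation lapse of
# -6.5 degC/km on an 18 degC valley-floor baseline.
default_air_offsets <- c(Hiji = 2, Kiso = 1, Sorachi = -3.5, Teshio = -4.5)

site_mean_air <- function(site) {
  offs <- default_air_offsets[as.character(site$catchment)]
  if (is.na(offs)) offs <- 0
  18 + unname(offs) - 6.5 * site$elevation / 1000
}

# Gap-aware continuous AR(1) residual recursion:
# e_t = phi^dt * e_{t-dt} + sigma * sqrt(1 - phi^(2 dt)) * z, giving exact
# stationary variance sigma^2 and corr(e_t, e_{t+d}) = phi^d for any gap
# pattern.
car1_residuals <- function(t, sigma, phi, z) {
  n <- length(t)
  e <- numeric(n)
  if (n == 0L || sigma == 0) return(e)
  e[1] <- sigma * z[1]
  if (n > 1) {
    r <- phi^diff(t)
    sd_innov <- sigma * sqrt(1 - r^2)
    for (i in 2:n) e[i] <- r[i - 1] * e[i - 1] + sd_innov[i - 1] * z[i]
  }
  e
}

# Per-site random intercept/slope draw, reproducible from (seed, site_id).
site_random_effects <- function(truth, site_id, seed) {
  L <- chol2_lower(truth_D(truth))
  with_seed(derive_seed(seed, paste0(site_id, "/re")),
            drop(L %*% stats::rnorm(2)))
}

#' Generate water-temperature observations from the model truth
#'
#' Applies the generating model at the truth's timescale: linear predictor
#' (grand intercept, catchment offset, covariate effects, air slope) plus a
#' per-site random intercept/slope pair drawn once from the 2x2 covariance
#' built from `tau00`, `tau11`, `d_corr`, plus continuous AR(1) residuals
#' generated by the exact gap-aware recursion, so that
#' `cor(e_t, e_{t+d}) = phi^d` for arbitrary gaps.
#'
#' @param site one row of a site table (needs `site_id`, `catchment` and the
#'   covariates named in `truth$beta_env`).
#' @param air_obs `data.frame` with columns `t` (numeric time, in units of
#'   the truth's timescale, strictly increasing) and `Ta` (degC).
#' @param truth a [truth_params()] object.
#' @param seed integer master seed; the site's random effects derive from
#'   `(seed, site_id)` so a site's draw is independent of the other sites.
#' @return `data.frame(site_id, t, Ta, Tw)`.
#' @export
generate_water_obs <- function(site, air_obs, truth, seed = 1) {
  if (!all(c("t", "Ta") %in% names(air_obs)))
    stop("`air_obs` needs columns `t` and `Ta`", call. = FALSE)
  t <- air_obs$t
  if (is.unsorted(t, strictly = TRUE))
    stop("`air_obs$t` must be strictly increasing", call. = FALSE)
  b <- site_random_effects(truth, site$site_id, seed)
  offs <- 0
  cm <- as.character(site$catchment)
  if (cm %in% names(truth$catchment_offsets))
    offs <- unname(truth$catchment_offsets[cm])
  env <- truth$beta_env
  xenv <- sum(vapply(names(env), function(nm) {
    if (is.null(site[[nm]])) stop(sprintf("site lacks covariate `%s`", nm),
                                  call. = FALSE)
    env[[nm]] * site[[nm]]
  }, numeric(1)))
  lp <- truth$alpha + offs + xenv + b[1] + (truth$beta_air + b[2]) * air_obs$Ta
  e <- if (truth$sigma > 0) {
    z <- with_seed(derive_seed(seed, paste0(site$site_id, "/resid")),
                   stats::rnorm(length(t)))
    car1_residuals(t, truth$sigma, truth$phi, z)
  } else numeric(length(t))
  data.frame(site_id = site$site_id, t = t, Ta = air_obs$Ta, Tw = lp + e,
             stringsAsFactors = FALSE)
}

#' Inject burst missingness into an hourly series
#'
#' Logger failures arrive as episodes, not isolated points: burst start
#' points occur independently with probability `rate / mean_burst` and
#' burst lengths are geometric with mean `mean_burst` hours, so the
#' expected missing fraction is `rate` (up to slight overlap at high
#' rates). Applied independently to the `air` and `water` channels
#' (separate physical loggers). Timestamps are never altered.
#'
#' @param series output of [generate_air_series()] (possibly with water
#'   filled in).
#' @param rate target missing fraction in `[0, 1]`.
#' @param mean_burst mean episode length in hours.
#' @param seed integer seed.
#' @return the series with masked values set to `NA`.
#' @export
inject_missingness <- function(series, rate, mean_burst = 12, seed = 1) {
  stopifnot_scalar(rate, "rate", lower = 0, upper = 1)
  if (rate == 0) return(series)
  n <- nrow(series)
  for (channel in c("air", "water")) {
    if (all(is.na(series[[channel]]))) next
    if (rate >= 1) { series[[channel]] <- NA_real_; next }
    mask <- with_seed(derive_seed(seed, paste0(series$site_id[1], "/miss/",
                                               channel)), {
      starts <- which(stats::runif(n) < rate / mean_burst)
      lens <- 1L + stats::rgeom(length(starts), prob = 1 / mean_burst)
      idx <- unlist(mapply(function(s, l) s:min(s + l - 1L, n), starts, lens,
                           SIMPLIFY = FALSE), use.names = FALSE)
      unique(idx)
    })
    series[[channel]][mask] <- NA_real_
  }
  series
}

#' Simulate a paired air-water dataset directly at the model timescale
#'
#' Convenience generator for recovery studies: draws a site table, builds a
#' per-site air series at daily or monthly resolution (site mean + seasonal
#' sinusoid + white noise), and generates water temperatures from the truth
#' via [generate_water_obs()]. For the monthly timescale the time covariate
#' follows the summer-campaign layout (four consecutive summer months per
#' year, consecutive years), so gaps between years are present just as in a
#' seasonal monitoring design.
#'
#' @param n_sites,n_catchments design size.
#' @param n_obs observations per site.
#' @param truth a [truth_params()] object; its timescale decides the layout.
#' @param seed integer master seed.
#' @param air_sd SD of the site-level white noise on the air series.
#' @param seasonal_amp annual amplitude of the air series (degC).
#' @return list with `sites` (site table) and `paired`
#'   (`data.frame(site_id, t, Ta, Tw)`).
#' @export
simulate_paired_obs <- function(n_sites, n_obs, truth,
                                n_catchments = 4, seed = 1,
                                air_sd = 1.5, seasonal_amp = 8) {
  sites <- generate_sites(n_sites, n_catchments, seed = seed)
  if (truth$timescale == "day") {
    t <- seq_len(n_obs)                       # consecutive days, June onwards
    doy <- 152 + (t - 1) %% 365
  } else {
    yrs <- ceiling(n_obs / 4)
    t <- as.vector(outer(1:4, (seq_len(yrs) - 1) * 12, `+`))[seq_len(n_obs)]
    doy <- 152 + ((t - 1) %% 12) * 30.4
  }
  season <- seasonal_amp * cos(2 * pi * (doy - 210) / 365.25)
  paired <- do.call(rbind, lapply(seq_len(n_sites), function(j) {
    site <- sites[j, ]
    mu <- site_mean_air(site)
    noise <- with_seed(derive_seed(seed, paste0(site$site_id, "/ta")),
                       stats::rnorm(n_obs, sd = air_sd))
    air <- data.frame(t = t, Ta = mu + season + noise)
    generate_water_obs(site, air, truth, seed = seed)
  }))
  rownames(paired) <- NULL
  list(sites = sites, paired = paired)
}

# Variance-reduction factor of the mean of n consecutive unit-spaced CAR(1)
# values: var(mean) = sigma^2 * f(n, phi).
car1_mean_var_factor <- function(n, phi) {
  if (n == 1L) return(1)
  k <- seq_len(n - 1)
  (n + 2 * sum((n - k) * phi^k)) / n^2
}

#' Fill in hourly water temperatures beneath a daily-scale truth
#'
#' Pipeline helper: generates an hourly water channel whose daily means
#' follow the daily-timescale truth. The linear predictor is applied to the
#' hourly air series; the residual process is hourly CAR(1) with
#' `phi_hourly = phi_daily^(1/24)` and its SD scaled up so the 24-hour mean
#' residual has SD `sigma` (the daily truth's residual SD).
#'
#' @param site one site-table row.
#' @param air_series output of [generate_air_series()] for that site.
#' @param truth a daily-timescale [truth_params()] object.
#' @param seed integer master seed.
#' @return the series with the `water` column filled.
#' @export
generate_hourly_water <- function(site, air_series, truth, seed = 1) {
  stopifnot(truth$timescale == "day")
  phi_h <- truth$phi^(1 / 24)
  f <- car1_mean_var_factor(24L, phi_h)
  sigma_h <- truth$sigma / sqrt(f)
  b <- site_random_effects(truth, site$site_id, seed)
  offs <- 0
  cm <- as.character(site$catchment)
  if (cm %in% names(truth$catchment_offsets))
    offs <- unname(truth$catchment_offsets[cm])
  env <- truth$beta_env
  xenv <- sum(vapply(names(env), function(nm) env[[nm]] * site[[nm]],
                     numeric(1)))
  th <- as.numeric(air_series$timestamp) / 3600   # hours
  lp <- truth$alpha + offs + xenv + b[1] +
    (truth$beta_air + b[2]) * air_series$air
  e <- if (sigma_h > 0) {
    z <- with_seed(derive_seed(seed, paste0(site$site_id, "/residh")),
                   stats::rnorm(length(th)))
    car1_residuals(th, sigma_h, phi_h, z)
  } else numeric(length(th))
  air_series$water <- lp + e
  air_series
}
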