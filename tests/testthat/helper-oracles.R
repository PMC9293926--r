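# Independent oracles used across tests. These deliberately avoid the
# package's per-site factorised code paths.

# Dense stacked multivariate-normal log-likelihood: builds the full N x N
# covariance elementwise and evaluates the Gaussian density directly.
dense_loglik <- function(design, D, sigma, phi = 0, beta = NULL,
                         method = "ML") {
  d <- design
  N <- d$N
  V <- matrix(0, N, N)
  for (j in seq_len(d$J)) {
    i <- which(d$site == j)
    Zj <- d$Z[i, , drop = FALSE]
    R <- phi^abs(outer(d$t[i], d$t[i], `-`))
    V[i, i] <- Zj %*% D %*% t(Zj) + sigma^2 * R
  }
  Vi <- solve(V)
  X <- d$X; y <- d$y
  XtVi <- t(X) %*% Vi
  if (is.null(beta)) beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  ll <- -0.5 * (determinant(V)$modulus + drop(t(r) %*% Vi %*% r) +
                  N * log(2 * pi))
  if (method == "REML")
    ll <- ll - 0.5 * determinant(XtVi %*% X)$modulus +
      0.5 * ncol(X) * log(2 * pi)
  as.numeric(ll)
}

# Shapley values of the R2 game by direct enumeration over all predictor
# orderings (independent of the size-wise averaging the package uses).
shapley_permutation <- function(map, predictors) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  key <- function(s) if (!length(s)) "(baseline)" else
    paste(sort(s), collapse = "+")
  phi <- setNames(numeric(length(predictors)), predictors)
  pp <- perms(predictors)
  for (ord in pp) {
    S <- character(0)
    for (x in ord) {
      phi[x] <- phi[x] + map[key(c(S, x))] - map[key(S)]
      S <- c(S, x)
    }
  }
  phi / length(pp)
}

# Small random mixed-model instance for oracle comparisons.
random_small_instance <- function(seed, max_sites = 5, max_obs = 10) {
  set.seed(seed)
  J <- sample(3:max_sites, 1)   # >= 3 sites so site-level columns stay full rank
  truth <- truth_params("day", tau00 = runif(1, 0.2, 1.5),
                        tau11 = runif(1, 0.01, 0.2),
                        d_corr = runif(1, -0.6, 0.6),
                        sigma = runif(1, 0.5, 2),
                        phi = runif(1, 0, 0.95))
  n_obs <- sample(3:max_obs, 1)
  sim <- simulate_paired_obs(J, n_obs, truth, n_catchments = 2,
                             seed = seed + 1000)
  # irregular gaps: drop ~20% of rows
  keep <- runif(nrow(sim$paired)) > 0.2
  paired <- sim$paired[keep, , drop = FALSE]
  # ensure >= 2 obs per site and at least 3 sites (site-level columns must
  # stay identifiable); otherwise keep the full grid
  tab <- table(paired$site_id)
  paired <- paired[paired$site_id %in% names(tab[tab >= 2]), , drop = FALSE]
  if (length(unique(paired$site_id)) < 3) paired <- sim$paired
  list(truth = truth, sites = sim$sites, paired = paired)
}
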