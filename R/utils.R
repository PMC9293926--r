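# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All exported generators funnel their randomness through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Hierarchical seed stream: derive a per-site seed from a master seed and the
# site identifier, so adding or removing sites never perturbs the draws of
# the remaining ones. Plain integer mixing, kept below 2^31.
derive_seed <- function(master, key) {
  ints <- utf8ToInt(as.character(key))
  h <- 0
  for (v in ints) h <- (h * 131 + v) %% 99990001
  as.integer((as.numeric(master) %% 1000003) * 2027 + h * 7 + 1) %% 2147483647L
}

# Days in a calendar month, leap-aware (civil calendar via Date arithmetic).
days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- if (month == 12L) as.Date(sprintf("%04d-01-01", year + 1L))
  else as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  as.integer(nxt - first)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# Lower-triangular factor of a 2x2 PSD matrix (tolerant Cholesky, allows
# zero variances).
chol2_lower <- function(D) {
  d11 <- D[1, 1]; d12 <- D[1, 2]; d22 <- D[2, 2]
  if (d11 < -1e-12 || d22 < -1e-12) stop("D must be positive semi-definite")
  a11 <- sqrt(max(d11, 0))
  a21 <- if (a11 > 0) d12 / a11 else 0
  a22sq <- d22 - a21^2
  if (a22sq < -1e-8 * max(1, d22)) stop("D must be positive semi-definite")
  matrix(c(a11, a21, 0, sqrt(max(a22sq, 0))), 2, 2)
}
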