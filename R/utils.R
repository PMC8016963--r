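#' @importFrom rlang %||% abort warn
#' @importFrom stats cor pt pnorm sd median var predict rnorm runif rbinom setNames
#' @importFrom utils combn head
NULL

# Deterministic 32-bit seed derived from a master seed and a path of labels.
# Polynomial rolling hash mod (2^31 - 1) so adding a drug/stage never perturbs
# the stream of any other drug/stage.
derive_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Exact string matching contract: trim whitespace, fold case.
canonical_id <- function(x) toupper(trimws(x))

# Locale-independent ordering so every run is byte-stable.
sort_c <- function(x) sort(x, method = "radix")

# Pearson r and two-sided p (t transform) over pairwise-complete values.
# Degenerate inputs (constant vector, n < 3) yield r = NA, p = NA.
cor_test_pair <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  r <- max(min(r, 1), -1)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

# Vectorised Pearson correlation of each row of `m` with `y` (complete cells
# assumed). Constant rows get r = 0 per the feature-selection contract.
row_cor <- function(m, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  r <- as.vector(mc %*% yc) / (sm * sy)
  r[!is.finite(r)] <- 0
  r
}

pearson_p <- function(r, n) {
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

# z-score a vector with the population (1/n) SD; constant input returns NULL.
zscore_vec <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mu) / s
}
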