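#' Derive a named random substream seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed from the master seed
#' and a stage label, so inserting or reordering stages never shifts the
#' randomness consumed downstream.
#'
#' @param seed Integer master seed.
#' @param ... Character labels identifying the substream (stage name, set
#'   name, permutation index, ...).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

# Evaluate expr under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Row means / sds without matrixStats.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

# Gene-wise z-scores across samples (rows = genes). Zero-variance rows give 0.
row_zscore <- function(x) {
  m <- rowMeans(x)
  s <- row_sds(x)
  z <- (x - m) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Fit the slope of per-protein SD against the rank of the per-protein mean
#'
#' Diagnostic for the mean-variance relationship that the glog normalisation
#' is designed to remove: on well-stabilised data the slope is near zero.
#'
#' @param values Numeric protein x sample matrix (any scale).
#' @return Slope of `lm(sd ~ rank(mean))`, per rank unit.
#' @export
mean_variance_slope <- function(values) {
  m <- rowMeans(values)
  s <- row_sds(values)
  unname(coef(stats::lm(s ~ rank(m)))[2])
}
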