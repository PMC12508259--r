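#' Variance-stabilising normalisation with affine per-sample calibration
#'
#' Fits the calibrated generalised-log (arcsinh) model
#' \deqn{t_{pi} = \mathrm{arcsinh}\!\left(\frac{x_{pi} - a_i}{b_i}\right)}
#' by minimising the negative profile log-likelihood
#' \deqn{\frac{N}{2}\log \mathrm{SSR}(t) \;-\; \sum_{p,i} \log
#'   \frac{\partial\, \mathrm{arcsinh}((x - a_i)/b_i)}{\partial x}}
#' where SSR is the pooled within-protein sum of squared residuals of `t`
#' and N the number of cells entering it. For robustness, the fraction
#' `trim` of proteins with the largest within-protein residual sum is
#' excluded from the likelihood at each iteration (least-trimmed-squares
#' style). The model is invariant to a common affine change of all samples,
#' so one reference sample is fixed at `a = 0, b = 1`; all other offsets and
#' factors are relative to it. Scale factors are optimised as `log b`, so
#' positivity is structural. Under the additive-multiplicative error model
#' the transform removes the dependence of the within-protein SD on the
#' mean.
#'
#' @param proteins A linear-scale [protein_matrix()].
#' @param trim Fraction of proteins trimmed per iteration (default 0.1).
#' @param reference Index or sample id of the gauge sample (default: first
#'   column).
#' @param tol Relative objective change declaring convergence (default
#'   1e-8).
#' @param maxit Maximum calibration iterations (default 100).
#' @return List with `matrix` (a glog-scale [protein_matrix()], all
#'   proteins, arcsinh units) and `calib` (class `CalibrationParams`: named
#'   vectors `a` and `b`, `iterations`, `objective`, `converged`).
#' @export
vsn_normalize <- function(proteins, trim = 0.1, reference = 1L,
                          tol = 1e-8, maxit = 100L) {
  if (proteins$scale != "linear")
    stop("vsn_normalize expects a linear-scale ProteinMatrix, got ",
         proteins$scale)
  x <- proteins$values
  P <- nrow(x); S <- ncol(x)
  if (S < 2) stop("need at least two samples to calibrate")
  if (is.character(reference)) reference <- match(reference, colnames(x))
  ref <- as.integer(reference)
  free <- setdiff(seq_len(S), ref)

  expand <- function(theta) {
    a <- numeric(S); lb <- numeric(S)
    a[free] <- theta[seq_along(free)]
    lb[free] <- theta[length(free) + seq_along(free)]
    list(a = a, b = exp(lb))
  }
  transform_all <- function(a, b) asinh(sweep(sweep(x, 2, a), 2, b, "/"))

  # negative profile log-likelihood and analytic gradient on kept proteins
  objective <- function(theta, keep) {
    p <- expand(theta)
    xa <- sweep(x[keep, , drop = FALSE], 2, p$a)
    t <- asinh(sweep(xa, 2, p$b, "/"))
    r <- t - rowMeans(t)
    ssr <- sum(r * r)
    n <- length(r)
    denom <- sweep(xa * xa, 2, p$b^2, "+")       # b^2 + (x-a)^2
    (n / 2) * log(max(ssr, 1e-300)) + 0.5 * sum(log(denom))
  }
  gradient <- function(theta, keep) {
    p <- expand(theta)
    xk <- x[keep, , drop = FALSE]
    xa <- sweep(xk, 2, p$a)
    u <- sweep(xa, 2, p$b, "/")
    t <- asinh(u)
    r <- t - rowMeans(t)
    ssr <- max(sum(r * r), 1e-300)
    n <- length(r)
    denom <- sweep(xa * xa, 2, p$b^2, "+")
    D <- 1 / sqrt(denom)                          # dt/dx
    dt_da <- -D
    dt_dlb <- -u / sqrt(1 + u * u)
    g_a <- (n / ssr) * colSums(r * dt_da) - colSums(xa / denom)
    g_lb <- (n / ssr) * colSums(r * dt_dlb) +
      colSums(sweep(1 / denom, 2, p$b^2, "*"))
    c(g_a[free], g_lb[free])
  }
  # Trim the `trim` fraction of proteins with the largest within-protein
  # residual sums, extended to any protein whose residual sum is a robust
  # outlier (beyond median + 5 MAD): differentially regulated proteins
  # violate the calibration model and would otherwise bias the fit, and
  # their share of the proteome can exceed any fixed fraction. At most half
  # the proteins are ever trimmed.
  trim_set <- function(theta) {
    if (trim <= 0 || P < 10) return(seq_len(P))
    p <- expand(theta)
    t <- transform_all(p$a, p$b)
    rss <- rowSums((t - rowMeans(t))^2)
    thr <- stats::median(rss) + 5 * stats::mad(rss)
    n_out <- sum(rss > thr)
    trim_n <- min(floor(P / 2), max(floor(trim * P), n_out))
    keep_n <- max(2L, P - trim_n)
    sort(order(rss)[seq_len(keep_n)])
  }

  # initialise: b from median intensity ratios to the reference, a = 0
  med <- apply(x, 2, stats::median)
  theta <- c(rep(0, length(free)), log(med[free] / med[ref]))

  keep <- trim_set(theta)
  obj <- objective(theta, keep)
  iter <- 0L
  converged <- FALSE
  if (sum((transform_all(expand(theta)$a, expand(theta)$b) -
           rowMeans(transform_all(expand(theta)$a, expand(theta)$b)))^2) <
      1e-10) {
    converged <- TRUE                              # already perfectly aligned
  } else {
    repeat {
      iter <- iter + 1L
      fit <- stats::optim(theta, fn = objective, gr = gradient, keep = keep,
                          method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-12))
      theta <- fit$par
      keep <- trim_set(theta)
      new_obj <- objective(theta, keep)
      if (is.finite(obj) &&
          abs(new_obj - obj) <= tol * (abs(obj) + 1e-12)) {
        obj <- new_obj; converged <- TRUE; break
      }
      obj <- new_obj
      if (iter >= maxit) break
    }
  }

  p <- expand(theta)
  t_full <- transform_all(p$a, p$b)
  dimnames(t_full) <- dimnames(x)
  calib <- structure(list(
    a = stats::setNames(p$a, colnames(x)),
    b = stats::setNames(p$b, colnames(x)),
    reference = colnames(x)[ref],
    iterations = iter,
    objective = obj,
    converged = converged), class = "CalibrationParams")
  list(matrix = protein_matrix(t_full, scale = "glog",
                               n_peptides = proteins$n_peptides),
       calib = calib)
}

#' @export
print.CalibrationParams <- function(x, ...) {
  cat(sprintf(
    "CalibrationParams: %d samples, reference %s, %d iteration(s), %s\n",
    length(x$a), x$reference, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
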