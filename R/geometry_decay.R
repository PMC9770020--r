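# Inter-contact Euclidean distances (MNI mm) and the exponential
# distance-decay model of connectivity strength, s = A * exp(-tau * d).

#' Pairwise Euclidean distance matrix between contacts
#'
#' @param geom data frame with columns `label`, `x_mm`, `y_mm`, `z_mm`
#'   (MNI millimetres, RAS orientation).
#' @return symmetric Nc x Nc distance matrix in mm with zero diagonal,
#'   labeled by contact.
#' @export
distance_matrix <- function(geom) {
  if (nrow(geom) < 2) stop("at least 2 channels are required")
  if (anyDuplicated(geom$label)) stop("duplicate channel labels")
  coords <- as.matrix(geom[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(geom$label, geom$label)
  d
}

#' Fit the exponential distance-decay model of connectivity
#'
#' Least-squares fit of `s = A * exp(-tau * d)` to per-pair connectivity
#' strengths versus inter-contact distances, with `tau` constrained
#' non-negative. Starting values come from a linear fit of `log(s)` on `d`
#' over the positive strengths; the nonlinear fit uses
#' Levenberg-Marquardt least squares on all pairs, unweighted. If the
#' exponential fit cannot beat the best constant model, the constant model
#' (`A = mean(s)`, `tau = 0`) is returned.
#'
#' @param h_values per-pair connectivity strengths (>= 0; `NA` dropped).
#' @param d_values per-pair distances in mm.
#' @param max_A upper bound on the strength at distance zero (default 1.5).
#' @return a `decay_fit`: list with `A`, `tau` (per mm), `n_pairs`, `rmse`,
#'   and `fitted` values.
#' @export
fit_decay <- function(h_values, d_values, max_A = 1.5) {
  if (length(h_values) != length(d_values))
    stop("h and d must have equal length")
  ok <- is.finite(h_values) & is.finite(d_values)
  h <- h_values[ok]; d <- d_values[ok]
  if (length(h) < 5) stop("at least 5 finite (h, d) pairs are required")
  if (any(h < 0)) stop("connectivity strengths must be non-negative")
  if (all(h == 0)) stop("all strengths are zero; decay model undefined")

  pos <- h > 0
  if (sum(pos) >= 2 && stats::sd(d[pos]) > 0) {
    lf <- stats::lm(log(h[pos]) ~ d[pos])
    A0 <- exp(unname(stats::coef(lf)[1]))
    tau0 <- max(0, -unname(stats::coef(lf)[2]))
  } else {
    A0 <- mean(h); tau0 <- 0
  }
  A0 <- min(max(A0, 1e-6), max_A)

  fit <- try(minpack.lm::nlsLM(
    h ~ A * exp(-tau * d),
    data = data.frame(h = h, d = d),
    start = list(A = A0, tau = tau0),
    lower = c(A = 0, tau = 0), upper = c(A = max_A, tau = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  ), silent = TRUE)

  const_rss <- sum((h - mean(h))^2)
  if (inherits(fit, "try-error")) {
    A <- mean(h); tau <- 0; fitted_v <- rep(A, length(h)); rss <- const_rss
  } else {
    cf <- stats::coef(fit)
    A <- unname(cf["A"]); tau <- unname(cf["tau"])
    fitted_v <- A * exp(-tau * d)
    rss <- sum((h - fitted_v)^2)
    if (rss > const_rss) {           # never worse than the constant model
      A <- mean(h); tau <- 0; fitted_v <- rep(A, length(h)); rss <- const_rss
    }
  }
  structure(
    list(A = A, tau = tau, n_pairs = length(h),
         rmse = sqrt(rss / length(h)), fitted = fitted_v),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> s = %.4f * exp(-%.4f * d); n = %d pairs, rmse = %.4g\n",
              x$A, x$tau, x$n_pairs, x$rmse))
  invisible(x)
}

upper_pairs <- function(m) m[upper.tri(m)]
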