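#' Delay-embedding parameters
#'
#' @param tau time delay in samples (integer, >= 1).
#' @param dim embedding dimension (integer, >= 2).
#' @return An `embedding_params` object. The package default, `(1, 3)`, is
#'   the globally applied choice for 200 Hz EEG windows; per-signal scans
#'   are available through [mcpe_select_delay()] and
#'   [gp_select_dimension()].
#' @export
embedding_params <- function(tau = 1L, dim = 3L) {
  tau <- as.integer(tau); dim <- as.integer(dim)
  if (is.na(tau) || tau < 1L) .fail("tau must be an integer >= 1")
  if (is.na(dim) || dim < 2L) .fail("dim must be an integer >= 2")
  structure(list(tau = tau, dim = dim), class = "embedding_params")
}

#' Reconstruct the delay-coordinate phase-space trajectory
#'
#' Point `i` of the trajectory is
#' `(s_i, s_{i+tau}, ..., s_{i+(d-1)tau})`, giving
#' `n - (d-1)*tau` points from a series of length `n`.
#'
#' @param series numeric vector.
#' @param params an [embedding_params()] (or anything with `$tau`, `$dim`).
#' @return A `phase_trajectory`: list with `points`
#'   (count x dim matrix), `source_length`, and `params`.
#' @examples
#' tr <- reconstruct_phase_space(1:6, embedding_params(tau = 2, dim = 2))
#' tr$points  # (1,3),(2,4),(3,5),(4,6)
#' @export
reconstruct_phase_space <- function(series, params = embedding_params()) {
  series <- as.numeric(series)
  tau <- params$tau; d <- params$dim
  n <- length(series)
  count <- n - (d - 1L) * tau
  if (count < 1L)
    .fail("series too short: need length > (dim-1)*tau = %d, got %d",
          (d - 1L) * tau, n)
  pts <- vapply(seq_len(d) - 1L,
                function(j) series[(1L + j * tau):(count + j * tau)],
                numeric(count))
  if (count == 1L) pts <- matrix(pts, nrow = 1L)
  structure(list(points = pts, source_length = n, params = params),
            class = "phase_trajectory")
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf("<phase_trajectory> %d points in %d-D (tau=%d, from n=%d)\n",
              nrow(x$points), ncol(x$points), x$params$tau, x$source_length))
  invisible(x)
}

#' Select the delay by minimum cross prediction error
#'
#' For each candidate delay, the series `T` is regressed on its cyclic shift
#' `Z` with the quadratic model `T = q0 + q1*Z + q2*Z^2` (ordinary least
#' squares), and the mean squared prediction error is recorded. The chosen
#' delay is the MSE argmin, ties broken toward the smallest delay. The shift
#' is `Z_i = T_{((i + tau - 1) mod n) + 1}`, so a shift by a full period of
#' a periodic series is the identity and yields zero error.
#'
#' @param series numeric vector, length >= 10, not constant.
#' @param tau_max largest delay scanned (must be < `length(series)`).
#' @return A `delay_scan`: list with `taus`, `mses`, `coefficients`
#'   (tau_max x 3 matrix of `(q0, q1, q2)`), and `best_tau`.
#' @examples
#' s <- sin(2 * pi * (0:199) / 20)   # integer period 20
#' mcpe_select_delay(s, tau_max = 25)$best_tau
#' @export
mcpe_select_delay <- function(series, tau_max = 10L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 10L) .fail("series too short for the delay scan (need >= 10)")
  if (pop_sd(series) == 0) .fail("constant series: delay scan undefined")
  tau_max <- as.integer(tau_max)
  if (tau_max >= n) .fail("tau_max must be smaller than the series length")
  taus <- seq_len(tau_max)
  coefs <- matrix(NA_real_, tau_max, 3L,
                  dimnames = list(NULL, c("q0", "q1", "q2")))
  mses <- numeric(tau_max)
  for (tau in taus) {
    z <- series[((seq_len(n) + tau - 1L) %% n) + 1L]
    X <- cbind(1, z, z^2)
    fit <- stats::lm.fit(X, series)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coefs[tau, ] <- cf
    mses[tau] <- mean(fit$residuals^2)
  }
  structure(list(taus = taus, mses = mses, coefficients = coefs,
                 best_tau = taus[which.min(mses)]),
            class = "delay_scan")
}

#' @export
print.delay_scan <- function(x, ...) {
  cat(sprintf("<delay_scan> tau in 1..%d, best_tau = %d (MSE %.4g)\n",
              max(x$taus), x$best_tau, min(x$mses)))
  invisible(x)
}

#' Grassberger-Procaccia scale statistic for one dimension
#'
#' The fraction `Cm = Cs / Ct` of unordered phase-point pairs whose
#' Euclidean distance is below the population standard deviation of the
#' original series.
#'
#' @param series numeric vector (not constant).
#' @param tau delay in samples.
#' @param dim embedding dimension.
#' @return A single number in `[0, 1]`.
#' @examples
#' gp_cm(c(0, 1, 0, 1, 0, 1), tau = 1, dim = 2)  # 0.4
#' @export
gp_cm <- function(series, tau, dim) {
  s <- pop_sd(series)
  if (s == 0) .fail("constant series: the distance cutoff is zero")
  tr <- reconstruct_phase_space(series, embedding_params(tau, dim))
  d <- stats::dist(tr$points)
  mean(d < s)
}

#' Select the embedding dimension by the G-P scale statistic
#'
#' Computes [gp_cm()] for each candidate dimension and picks the smallest
#' dimension at which the statistic has stabilised: the first `d` with
#' `|Cm(d+1) - Cm(d)| <= stabilize_tol`. If no dimension satisfies the
#' tolerance, the dimension with the smallest successive change is returned
#' with a warning.
#'
#' @param series numeric vector.
#' @param tau delay in samples.
#' @param dim_range candidate dimensions (default `2:10`).
#' @param stabilize_tol successive-difference threshold (default 0.01).
#' @return A `dimension_scan`: list with `dims`, `cm_values`, `chosen_dim`,
#'   and `threshold_sigma` (the distance cutoff used).
#' @export
gp_select_dimension <- function(series, tau, dim_range = 2:10,
                                stabilize_tol = 0.01) {
  series <- as.numeric(series)
  sig <- pop_sd(series)
  if (sig == 0) .fail("constant series: the distance cutoff is zero")
  dims <- as.integer(dim_range)
  cm <- vapply(dims, function(d) gp_cm(series, tau, d), 0)
  chosen <- NA_integer_
  if (length(dims) > 1L) {
    dif <- abs(diff(cm))
    ok <- which(dif <= stabilize_tol)
    if (length(ok)) {
      chosen <- dims[ok[1L]]
    } else {
      chosen <- dims[which.min(dif)]
      warning(sprintf(
        "Cm never stabilises within %g; falling back to the most stable dimension (%d)",
        stabilize_tol, chosen))
    }
  } else {
    chosen <- dims[1L]
    warning("single-dimension scan: stabilisation cannot be assessed")
  }
  structure(list(dims = dims, cm_values = cm, chosen_dim = chosen,
                 threshold_sigma = sig),
            class = "dimension_scan")
}

#' @export
print.dimension_scan <- function(x, ...) {
  cat(sprintf("<dimension_scan> d in %d..%d, chosen_dim = %d\n",
              min(x$dims), max(x$dims), x$chosen_dim))
  print(stats::setNames(round(x$cm_values, 4), paste0("d", x$dims)))
  invisible(x)
}
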