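## Fits of experimental-style data: normalized pH-dependence curves (Hill
## model) and stopped-flow kinetic traces (offset plus a sum of
## exponentials with an iterative term-count selection rule).

#' Normalize a pH-response table to the (0, 1) scale
#'
#' Min-max normalization oriented so that the acidic plateau maps to 1
#' (fully protonated / inserted) and the basic plateau to 0. Idempotent on
#' already-normalized data.
#'
#' @param tbl data frame with columns `pH` and `response` (>= 4 points).
#' @return data frame with `pH` and normalized `response`.
#' @export
normalize_ph_response <- function(tbl) {
  stopifnot(all(c("pH", "response") %in% names(tbl)))
  if (nrow(tbl) < 4L) stop_invalid("need >= 4 pH points")
  r <- tbl$response
  span <- max(r) - min(r)
  if (span <= .Machine$double.eps * max(abs(r), 1))
    stop_invalid("flat response: no transition to normalize")
  y <- (r - min(r)) / span
  # orient: response must fall with pH (acidic plateau -> 1)
  if (stats::cor(tbl$pH, y) > 0) y <- 1 - y
  data.frame(pH = tbl$pH, response = y)
}

#' Fit the Hill equation to a normalized pH transition
#'
#' Levenberg-Marquardt least squares of
#' `response = 1 / (1 + 10^{n (pH - pK)})`, initialized at the linearly
#' interpolated pH of half-response with n = 1.
#'
#' @param tbl normalized table (`pH`, `response` in (0, 1) trend).
#' @return list of class `hill_fit`: `pK`, `n`, `covariance` (2 x 2 for
#'   (pK, n)), `residual` (RSS), `extrapolated` (TRUE when pK falls more
#'   than 1 pH unit outside the data range).
#' @export
fit_hill_transition <- function(tbl) {
  stopifnot(all(c("pH", "response") %in% names(tbl)))
  o <- order(tbl$pH)
  ph <- tbl$pH[o]; y <- tbl$response[o]
  # initializer: pH at response 0.5 by linear interpolation
  pk0 <- tryCatch(stats::approx(y, ph, xout = 0.5, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(pk0)) pk0 <- mean(ph)
  resid_fn <- function(par) y - hill_protonation(ph, par[1], par[2])
  jac_fn <- function(par) {
    f <- hill_protonation(ph, par[1], par[2])
    g <- log(10) * f * (1 - f)
    cbind(-par[2] * g, (ph - par[1]) * g)
  }
  fit <- minpack.lm::nls.lm(par = c(pK = pk0, n = 1), fn = resid_fn,
                            jac = jac_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  if (!(fit$info %in% 1:4))
    stop_invalid("Hill fit did not converge (nls.lm info = %d)", fit$info)
  rss <- sum(fit$fvec^2)
  dof <- length(y) - 2L
  covm <- tryCatch({
    j <- jac_fn(fit$par)
    s2 <- if (dof > 0) rss / dof else NA_real_
    s2 * solve(crossprod(j))
  }, error = function(e) matrix(NA_real_, 2, 2))
  pk <- unname(fit$par[1])
  structure(list(pK = pk, n = unname(fit$par[2]), covariance = covm,
                 residual = rss,
                 extrapolated = pk < min(ph) - 1 || pk > max(ph) + 1),
            class = "hill_fit")
}

#' Reduced chi-square of a fit
#'
#' Plain residual mean square, `sum((obs - fit)^2) / (n - p)`, on the
#' normalized intensity scale (unit measurement variance after
#' normalization).
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param n_params number of fitted parameters.
#' @return the reduced chi-square value.
#' @export
reduced_chi_square <- function(observed, fitted, n_params) {
  stopifnot(length(observed) == length(fitted))
  dof <- length(observed) - n_params
  if (dof <= 0) stop_invalid("degrees of freedom must be > 0")
  sum((observed - fitted)^2) / dof
}

# Fit offset + sum of N exponentials. Initialization by variable
# projection: candidate taus are enumerated on a log-spaced grid, the
# amplitudes and offset solved linearly for each combination, and the best
# few combinations are polished by Levenberg-Marquardt with taus in log10
# space (keeps them positive).
fit_n_exp <- function(t, y, N, n_polish = 3) {
  model <- function(par) {
    off <- par[1]
    a <- par[2:(N + 1)]
    tau <- 10^par[(N + 2):(2 * N + 1)]
    f <- rep(off, length(t))
    for (i in seq_len(N)) f <- f + a[i] * exp(-t / tau[i])
    f
  }
  resid_fn <- function(par) y - model(par)
  lo <- log10(max(min(t[t > 0]), 1e-12))
  hi <- log10(max(t))
  cand <- 10^seq(lo - 0.3, hi, length.out = 12)
  combos <- utils::combn(length(cand), N)
  basis <- vapply(cand, function(tt) exp(-t / tt), numeric(length(t)))
  starts <- vector("list", ncol(combos))
  rss0 <- rep(Inf, ncol(combos))
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    X <- cbind(1, basis[, idx, drop = FALSE])
    lin <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(lin) || any(!is.finite(lin$coefficients))) next
    rss0[ci] <- sum(lin$residuals^2)
    starts[[ci]] <- c(lin$coefficients[1], lin$coefficients[-1],
                      log10(cand[idx]))
  }
  best <- NULL
  for (ci in order(rss0)[seq_len(min(n_polish, sum(is.finite(rss0))))]) {
    if (!is.finite(rss0[ci])) next
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[ci]], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, info = fit$info)
  }
  if (is.null(best)) return(NULL)
  off <- best$par[1]
  a <- best$par[2:(N + 1)]
  tau <- 10^best$par[(N + 2):(2 * N + 1)]
  o <- order(tau)
  list(offset = unname(off), amplitudes = unname(a[o]),
       taus = unname(tau[o]),
       fitted = model(best$par), rss = best$rss,
       converged = best$info %in% 1:4)
}

#' Fit a multiexponential decay with automatic term-count selection
#'
#' Fits `intensity = offset + sum_i a_i exp(-t / tau_i)` for an increasing
#' number of terms N = 1, 2, ... The loop stops at the first N whose
#' reduced chi-square falls below `chisq_threshold`, or when adding another
#' term would lower the chi-square by less than a factor of
#' `ratio_threshold`; reaching `max_N` without either stop returns the
#' max_N fit flagged unconverged. Amplitude signs are unconstrained (traces
#' may rise before decaying).
#'
#' @param trace data frame with `time` and `intensity` (normalized scale);
#'   any excluded prefix window must already be applied, or use
#'   `exclude_prefix`.
#' @param max_N largest candidate term count.
#' @param chisq_threshold absolute reduced chi-square stop (3e-5 on
#'   (0,1)-normalized traces).
#' @param ratio_threshold minimum chi-square improvement factor that
#'   justifies another term.
#' @param exclude_prefix drop points with `time < exclude_prefix` before
#'   fitting (same units as `time`).
#' @return list of class `exp_fit`: `N`, `amplitudes`, `taus` (ascending),
#'   `offset`, `reduced_chi_square`, `selection_trace` (data frame N,
#'   reduced_chi_square), `converged`.
#' @export
fit_multiexponential <- function(trace, max_N = 4, chisq_threshold = 3e-5,
                                 ratio_threshold = 10, exclude_prefix = 0) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  keep <- trace$time >= exclude_prefix
  t <- trace$time[keep]; y <- trace$intensity[keep]
  if (any(diff(t) <= 0)) stop_invalid("times must be strictly increasing")
  fits <- list(); chis <- numeric()
  selected <- NA_integer_; converged <- FALSE
  for (N in seq_len(max_N)) {
    if (length(y) <= 2 * N + 1) break
    f <- fit_n_exp(t, y, N)
    if (is.null(f)) break
    fits[[N]] <- f
    chis[N] <- reduced_chi_square(y, f$fitted, 2 * N + 1)
    if (chis[N] < chisq_threshold) {
      selected <- N; converged <- TRUE; break
    }
    if (N >= 2 && chis[N - 1] / chis[N] < ratio_threshold) {
      selected <- N - 1L; converged <- TRUE; break
    }
  }
  if (!converged) selected <- length(fits)
  if (selected < 1L) stop_invalid("multiexponential fit failed at N = 1")
  f <- fits[[selected]]
  structure(list(N = as.integer(selected), amplitudes = f$amplitudes,
                 taus = f$taus, offset = f$offset,
                 reduced_chi_square = chis[selected],
                 selection_trace = data.frame(
                   N = seq_along(chis), reduced_chi_square = chis),
                 converged = converged),
            class = "exp_fit")
}

#' Normalize a kinetic trace to a reference intensity
#'
#' Divides the raw signal by the membrane-adsorbed-state (state II)
#' fluorescence so traces from different runs share the scale the
#' chi-square thresholds assume.
#'
#' @param trace data frame with `time` and `intensity`.
#' @param ref_intensity state II reference (> 0).
#' @return the trace with `intensity` rescaled.
#' @export
normalize_kinetic_trace <- function(trace, ref_intensity) {
  if (!is.finite(ref_intensity) || ref_intensity <= 0)
    stop_invalid("normalization reference must be > 0")
  if (any(diff(trace$time) <= 0))
    stop_invalid("times must be strictly increasing")
  trace$intensity <- trace$intensity / ref_intensity
  trace
}
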