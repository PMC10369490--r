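## pKa-versus-depth profiles: insertion-bin slicing, quality-control
## criteria, Hill fits of per-bin titration curves, Bayesian-bootstrap
## errors, and the deep-region summary pKa.

bin_low_of <- function(z, bin_width = 0.5) floor(z / bin_width) * bin_width

#' Slice frame records into insertion bins
#'
#' Bins are half-open intervals `[low, low + width)` anchored at integer
#' multiples of the bin width, so every frame falls in exactly one bin.
#'
#' @param frames frame table carrying `insertion_A`.
#' @param bin_width bin width (Angstrom).
#' @return named list of frame subsets, names `"[low,high)"`, ordered by
#'   depth; each element carries attributes `bin_low` and `bin_high`.
#' @export
slice_by_insertion <- function(frames, bin_width = 0.5) {
  stopifnot("insertion_A" %in% names(frames))
  lows <- bin_low_of(frames$insertion_A, bin_width)
  ulows <- sort(unique(lows))
  out <- lapply(ulows, function(lo) {
    sub <- frames[lows == lo, , drop = FALSE]
    attr(sub, "bin_low") <- lo
    attr(sub, "bin_high") <- lo + bin_width
    sub
  })
  names(out) <- sprintf("[%g,%g)", ulows, ulows + bin_width)
  out
}

#' Per-bin titration curve from frame records
#'
#' Average protonations are computed per (pH, replicate, replica) — the
#' "samples" that all downstream fitting and error estimation consume —
#' then aggregated into replicate means and the pooled curve (mean over
#' sample curves per pH, each pH weighted equally in fits).
#'
#' @param bin_frames frames of one insertion bin with columns `pH`,
#'   `replicate`, `replica` and the protonation column.
#' @param prot_col name of the binary protonation column.
#' @return list of class `titration_curve`: `points` (per pH/replicate/
#'   replica means and counts), `sample_means` (pH x sample matrix, one
#'   column per replicate/replica series), `replicate_means` (pH x
#'   replicate matrix), `pooled` (data frame pH, protonation, n).
#' @export
titration_curve <- function(bin_frames, prot_col = "prot_asp") {
  stopifnot(prot_col %in% names(bin_frames))
  key <- paste(bin_frames$pH, bin_frames$replicate, bin_frames$replica,
               sep = "|")
  agg <- rowsum(cbind(n = rep(1L, nrow(bin_frames)),
                      s = bin_frames[[prot_col]]), key)
  n <- agg[, "n"]; s <- agg[, "s"]
  parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  pts <- data.frame(pH = as.numeric(parts[, 1]),
                    replicate = as.integer(parts[, 2]),
                    replica = as.integer(parts[, 3]),
                    mean_prot = s / n, n = n)
  pts <- pts[order(pts$pH, pts$replicate, pts$replica), ]
  ph_vals <- sort(unique(pts$pH))
  reps <- sort(unique(pts$replicate))
  # sample curves: one column per (replicate, replica) series
  sam <- unique(pts[, c("replicate", "replica")])
  sam <- sam[order(sam$replicate, sam$replica), ]
  sm <- matrix(NA_real_, length(ph_vals), nrow(sam),
               dimnames = list(ph = ph_vals,
                               sample = paste(sam$replicate, sam$replica,
                                              sep = "/")))
  for (j in seq_len(nrow(sam))) {
    sel <- pts$replicate == sam$replicate[j] & pts$replica == sam$replica[j]
    sm[match(pts$pH[sel], ph_vals), j] <- pts$mean_prot[sel]
  }
  # replicate mean at each pH: unweighted mean over its replicas' means
  rm <- matrix(NA_real_, length(ph_vals), length(reps),
               dimnames = list(ph = ph_vals, replicate = reps))
  for (j in seq_along(reps)) {
    cols <- which(sam$replicate == reps[j])
    rm[, j] <- rowMeans(sm[, cols, drop = FALSE], na.rm = TRUE)
  }
  rm[is.nan(rm)] <- NA_real_
  pooled <- data.frame(
    pH = ph_vals,
    protonation = rowMeans(sm, na.rm = TRUE),
    n = vapply(ph_vals, function(p) sum(pts$n[pts$pH == p]), numeric(1)))
  structure(list(points = pts, sample_means = sm, replicate_means = rm,
                 pooled = pooled),
            class = "titration_curve")
}

#' Quality-control criteria for a per-bin pKa estimate
#'
#' Three screens gate every per-bin fit:
#' \enumerate{
#'   \item each replicate present in the bin holds at least `min_points`
#'     frames of \emph{each} protonation state at \emph{every} ladder pH;
#'   \item at least `min_replicates` replicates contribute, each with data
#'     from at least `min_replicas` distinct replicas (counted over the bin
#'     as a whole);
#'   \item the pooled titration curve is monotone: the mean protonation at
#'     a pH may not exceed that of the previous (lower) pH by more than
#'     `mono_tol`.
#' }
#'
#' @param bin_frames frames of one insertion bin.
#' @param ph_ladder the full pH ladder; defaults to the pH values present.
#' @param min_points,min_replicates,min_replicas,mono_tol thresholds.
#' @param prot_col protonation column name.
#' @return list of class `criteria_ledger` with logicals `criterion1`,
#'   `criterion2`, `criterion3`, `pass`, a `violations` character vector,
#'   and `mono_violating_ph` (pH points breaking monotonicity).
#' @export
check_criteria <- function(bin_frames, ph_ladder = NULL, min_points = 10,
                           min_replicates = 3, min_replicas = 2,
                           mono_tol = 0.05, prot_col = "prot_asp") {
  ladder <- sort(ph_ladder %||% unique(bin_frames$pH))
  viol <- character()
  if (nrow(bin_frames) == 0L) {
    return(structure(list(criterion1 = FALSE, criterion2 = FALSE,
                          criterion3 = FALSE, pass = FALSE,
                          violations = "empty bin",
                          mono_violating_ph = numeric()),
                     class = "criteria_ledger"))
  }
  reps <- sort(unique(bin_frames$replicate))
  # criterion 1: per replicate, per ladder pH, >= min_points of each state
  c1 <- TRUE
  for (r in reps) {
    fr <- bin_frames[bin_frames$replicate == r, ]
    for (p in ladder) {
      prot <- fr[[prot_col]][fr$pH == p]
      n1 <- sum(prot == 1L); n0 <- sum(prot == 0L)
      if (n1 < min_points || n0 < min_points) {
        c1 <- FALSE
        viol <- c(viol, sprintf(
          "criterion1: replicate %s at pH %.2f has %d protonated / %d deprotonated points (< %d)",
          r, p, n1, n0, min_points))
      }
    }
  }
  # criterion 2: enough replicates, each spanning enough replicas
  n_replicas_per_rep <- vapply(reps, function(r)
    length(unique(bin_frames$replica[bin_frames$replicate == r])), integer(1))
  ok_reps <- sum(n_replicas_per_rep >= min_replicas)
  c2 <- length(reps) >= min_replicates && ok_reps >= min_replicates &&
    all(n_replicas_per_rep >= min_replicas)
  if (!c2) viol <- c(viol, sprintf(
    "criterion2: %d replicates, replica coverage %s (need >= %d replicates with >= %d replicas)",
    length(reps), paste(n_replicas_per_rep, collapse = ","),
    min_replicates, min_replicas))
  # criterion 3: pooled-curve monotonicity within mono_tol
  curve <- titration_curve(bin_frames, prot_col)
  pooled <- curve$pooled
  mono_viol <- numeric()
  if (nrow(pooled) >= 2L) {
    for (k in 2:nrow(pooled)) {
      if (pooled$protonation[k] > pooled$protonation[k - 1] + mono_tol)
        mono_viol <- c(mono_viol, pooled$pH[k])
    }
  }
  c3 <- length(mono_viol) == 0L
  if (!c3) viol <- c(viol, sprintf(
    "criterion3: protonation rises by > %.2f at pH %s", mono_tol,
    paste(format(mono_viol), collapse = ", ")))
  structure(list(criterion1 = c1, criterion2 = c2, criterion3 = c3,
                 pass = c1 && c2 && c3, violations = viol,
                 mono_violating_ph = mono_viol),
            class = "criteria_ledger")
}

# Fast Hill fit on (ph, y) pairs: Levenberg-Marquardt with analytic
# Jacobian; initialized from a logit-linear regression.
hill_fit_core <- function(ph, y, n_mode = "free", weights = NULL) {
  stopifnot(length(ph) == length(y))
  w <- weights %||% rep(1, length(ph))
  eps <- 1e-4
  yc <- pmin(pmax(y, eps), 1 - eps)
  lg <- log10((1 - yc) / yc)        # = n (ph - pKa)
  init <- tryCatch({
    fit0 <- stats::lm.fit(cbind(1, ph), lg)
    n0 <- fit0$coefficients[2]
    if (!is.finite(n0) || n0 < 0.05) n0 <- 1
    pka0 <- -fit0$coefficients[1] / n0
    if (!is.finite(pka0)) pka0 <- mean(ph)
    c(pka = unname(pka0), n = unname(n0))
  }, error = function(e) c(pka = mean(ph), n = 1))
  if (n_mode == "fixed") {
    resid_fn <- function(par) sqrt(w) * (y - hill_protonation(ph, par[1], 1))
    jac_fn <- function(par) {
      f <- hill_protonation(ph, par[1], 1)
      matrix(-sqrt(w) * (log(10) * 1 * f * (1 - f)), ncol = 1)
    }
    fit <- minpack.lm::nls.lm(par = init[1], fn = resid_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100))
    pka <- fit$par[1]; n <- 1
  } else {
    resid_fn <- function(par)
      sqrt(w) * (y - hill_protonation(ph, par[1], par[2]))
    jac_fn <- function(par) {
      f <- hill_protonation(ph, par[1], par[2])
      g <- log(10) * f * (1 - f)
      cbind(-sqrt(w) * par[2] * g, sqrt(w) * (ph - par[1]) * g)
    }
    fit <- minpack.lm::nls.lm(par = init, fn = resid_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100))
    pka <- fit$par[1]; n <- fit$par[2]
  }
  list(pka = unname(pka), hill_n = unname(n),
       converged = fit$info %in% 1:4,
       rss = sum(fit$fvec^2), info = fit$info)
}

#' Fit the Hill equation to a titration curve
#'
#' Least-squares fit of `protonation(pH) = 1 / (1 + 10^{n (pH - pKa)})` to
#' the pooled per-pH average protonations, each pH point weighted equally.
#'
#' @param curve a [titration_curve()], or a data frame with columns `pH`
#'   and `protonation`.
#' @param n_mode `"free"` fits the cooperativity, `"fixed"` pins n = 1.
#' @return list of class `pka_fit`: `pka`, `hill_n`, `converged`, `rss`.
#' @export
fit_pka <- function(curve, n_mode = c("free", "fixed")) {
  n_mode <- match.arg(n_mode)
  pooled <- if (inherits(curve, "titration_curve")) curve$pooled else curve
  if (nrow(pooled) < 3L)
    stop_invalid("need >= 3 pH points to fit (got %d)", nrow(pooled))
  fit <- hill_fit_core(pooled$pH, pooled$protonation, n_mode)
  structure(fit, class = "pka_fit")
}

#' Bayesian-bootstrap standard deviation of a per-bin pKa
#'
#' Each bootstrap draws Dirichlet(1, ..., 1) weights over the
#' average-protonation samples (columns), forms the weighted pooled
#' titration curve, re-applies the monotonicity screen, and refits the
#' Hill model. Resamples whose weighted curve fails the screen are
#' discarded and redrawn (their number is reported); the spread of the
#' resulting pKa distribution is the error estimate. The profile builder
#' passes the replica-level sample curves of [titration_curve()] (20
#' columns for a 5-replicate, 4-replica run), which keeps the sd estimate
#' well conditioned; a pH x replicate matrix of replicate means works the
#' same way.
#'
#' @param replicate_means pH x sample matrix of average protonations
#'   (e.g. `sample_means` or `replicate_means` of [titration_curve()]).
#' @param ph pH values of the rows; defaults to the row names.
#' @param n_boot number of retained bootstrap fits.
#' @param seed integer seed.
#' @param mono_tol monotonicity tolerance applied to each weighted curve.
#' @param n_mode Hill cooperativity mode, as in [fit_pka()].
#' @param max_attempts total draw budget before giving up.
#' @return list of class `bootstrap_sd`: `sd`, `mean`, `pkas`,
#'   `n_discarded`, `ok` (FALSE when the draw budget was exhausted: the
#'   bin should be dropped).
#' @export
bayesian_bootstrap_sd <- function(replicate_means,
                                  ph = as.numeric(rownames(replicate_means)),
                                  n_boot = 1000, seed = 1L,
                                  mono_tol = 0.05, n_mode = "free",
                                  max_attempts = 20 * n_boot) {
  m <- as.matrix(replicate_means)
  if (ncol(m) < 2L) stop_invalid("need >= 2 samples to bootstrap")
  if (any(!is.finite(m)))
    stop_invalid("replicate_means must be complete (no missing cells)")
  stopifnot(length(ph) == nrow(m))
  pkas <- numeric(n_boot)
  n_disc <- 0L; got <- 0L; attempts <- 0L
  with_rng(substream_seed(seed, "bayes-boot"), {
    while (got < n_boot && attempts < max_attempts) {
      attempts <- attempts + 1L
      g <- stats::rexp(ncol(m))
      w <- g / sum(g)
      y <- as.vector(m %*% w)
      if (any(diff(y) > mono_tol)) { n_disc <- n_disc + 1L; next }
      fit <- hill_fit_core(ph, y, n_mode)
      if (!fit$converged) { n_disc <- n_disc + 1L; next }
      got <- got + 1L
      pkas[got] <- fit$pka
    }
  })
  ok <- got == n_boot
  structure(list(sd = if (ok) stats::sd(pkas) else NA_real_,
                 mean = if (ok) mean(pkas) else NA_real_,
                 pkas = pkas[seq_len(got)], n_discarded = n_disc, ok = ok),
            class = "bootstrap_sd")
}

#' Build a pKa-versus-depth profile from pHRE frame records
#'
#' The full per-bin pipeline: equilibration discard (a per-replicate
#' frame-time filter), 0.5 Angstrom insertion slicing, the three
#' quality-control criteria, monotonicity remedy, Hill fit and
#' Bayesian-bootstrap error. Bins failing any criterion are reported with
#' flags but carry no estimate.
#'
#' @param frames frame table (`replicate`, `replica`, `pH`, `time_ps`,
#'   `insertion_A`, protonation column).
#' @param bin_width insertion bin width (Angstrom).
#' @param ph_ladder pH ladder; defaults to the pH values present.
#' @param equil_frac fraction of each replicate's time span discarded as
#'   equilibration (0.3 mirrors dropping the first 30 of 100 ns).
#' @param min_points,min_replicates,min_replicas,mono_tol criteria
#'   thresholds (see [check_criteria()]).
#' @param mono_remedy `"drop_ph"` removes monotonicity-violating pH points
#'   from the fit; `"drop_bin"` discards the whole bin.
#' @param n_mode Hill cooperativity mode.
#' @param n_boot bootstrap resamples per bin.
#' @param seed integer seed.
#' @param prot_col protonation column name.
#' @return data frame of class `pka_profile`: one row per sampled bin with
#'   `bin_low`, `bin_high`, `bin_mid`, `n_frames`, criteria flags, `pass`,
#'   `pka`, `hill_n`, `bootstrap_sd`, `n_dropped_ph`.
#' @export
build_profile <- function(frames, bin_width = 0.5, ph_ladder = NULL,
                          equil_frac = 0.3, min_points = 10,
                          min_replicates = 3, min_replicas = 2,
                          mono_tol = 0.05,
                          mono_remedy = c("drop_ph", "drop_bin"),
                          n_mode = "free", n_boot = 1000, seed = 1L,
                          prot_col = "prot_asp") {
  mono_remedy <- match.arg(mono_remedy)
  ladder <- sort(ph_ladder %||% unique(frames$pH))
  if (equil_frac > 0) {
    keep <- rep(TRUE, nrow(frames))
    for (r in unique(frames$replicate)) {
      sel <- frames$replicate == r
      keep[sel] <- frames$time_ps[sel] > equil_frac * max(frames$time_ps[sel])
    }
    frames <- frames[keep, , drop = FALSE]
  }
  bins <- slice_by_insertion(frames, bin_width)
  rows <- vector("list", length(bins))
  for (b in seq_along(bins)) {
    bf <- bins[[b]]
    lo <- attr(bf, "bin_low"); hi <- attr(bf, "bin_high")
    led <- check_criteria(bf, ladder, min_points, min_replicates,
                          min_replicas, mono_tol, prot_col)
    row <- data.frame(bin_low = lo, bin_high = hi, bin_mid = (lo + hi) / 2,
                      n_frames = nrow(bf), criterion1 = led$criterion1,
                      criterion2 = led$criterion2,
                      criterion3 = led$criterion3, pass = led$pass,
                      pka = NA_real_, hill_n = NA_real_,
                      bootstrap_sd = NA_real_, n_dropped_ph = 0L)
    c3_ok <- led$criterion3 ||
      (mono_remedy == "drop_ph" &&
         length(ladder) - length(led$mono_violating_ph) >= 3L)
    if (led$criterion1 && led$criterion2 && c3_ok) {
      curve <- titration_curve(bf, prot_col)
      pooled <- curve$pooled
      sm <- curve$sample_means
      if (!led$criterion3 && mono_remedy == "drop_ph") {
        drop <- pooled$pH %in% led$mono_violating_ph
        pooled <- pooled[!drop, , drop = FALSE]
        sm <- sm[!(as.numeric(rownames(sm)) %in% led$mono_violating_ph), ,
                 drop = FALSE]
        row$n_dropped_ph <- sum(drop)
        row$pass <- led$criterion1 && led$criterion2
      }
      # sample curves with a missing pH cell cannot be reweighted
      sm <- sm[, colSums(is.na(sm)) == 0L, drop = FALSE]
      fit <- hill_fit_core(pooled$pH, pooled$protonation, n_mode)
      if (fit$converged && ncol(sm) >= 2L) {
        bs <- bayesian_bootstrap_sd(sm, as.numeric(rownames(sm)),
                                    n_boot = n_boot,
                                    seed = substream_seed(seed,
                                      sprintf("bin/%g", lo)),
                                    mono_tol = mono_tol, n_mode = n_mode)
        if (bs$ok) {
          row$pka <- fit$pka; row$hill_n <- fit$hill_n
          row$bootstrap_sd <- bs$sd
        } else row$pass <- FALSE
      } else row$pass <- FALSE
    }
    rows[[b]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$bin_low), ]
  rownames(out) <- NULL
  class(out) <- c("pka_profile", "data.frame")
  out
}

#' Deep-region summary pKa of a profile
#'
#' Frame-count-weighted mean of the criteria-passing bin pKa values whose
#' bins lie inside the deep-membrane window. Undefined (with an explicit
#' status) when no passing bin falls in the window, mirroring incomplete
#' profiles at depth.
#'
#' @param profile a [build_profile()] result.
#' @param deep_window depth window (Angstrom), default `c(-6, -5)`.
#' @return list of class `pka_ins`: `value` (NA when undefined), `status`
#'   (`"ok"` or `"undefined"`), `n_bins`, `window`.
#' @export
pka_ins <- function(profile, deep_window = c(-6, -5)) {
  sel <- profile$pass & !is.na(profile$pka) &
    profile$bin_low >= deep_window[1] - 1e-9 &
    profile$bin_high <= deep_window[2] + 1e-9
  if (!any(sel)) {
    return(structure(list(value = NA_real_, status = "undefined",
                          n_bins = 0L, window = deep_window),
                     class = "pka_ins"))
  }
  w <- profile$n_frames[sel]
  structure(list(value = sum(profile$pka[sel] * w) / sum(w), status = "ok",
                 n_bins = sum(sel), window = deep_window),
            class = "pka_ins")
}

#' Write a pKa profile as TSV
#' @param profile a `pka_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
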