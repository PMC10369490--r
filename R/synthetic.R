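## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with known ground truth, so each downstream stage is
## testable by parameter recovery rather than against external trajectories.

#' Protonated fraction under the Hill model
#'
#' The logistic titration model used package-wide: the equilibrium fraction
#' of the protonated state at a given pH for a site with midpoint `pka` and
#' cooperativity `n`,
#' \deqn{f(pH) = 1 / (1 + 10^{n (pH - pKa)}).}
#'
#' @param ph pH value(s).
#' @param pka midpoint (pH units).
#' @param n Hill cooperativity coefficient (> 0 for a titrating site).
#' @return protonated fraction in (0, 1).
#' @export
hill_protonation <- function(ph, pka, n = 1) 1 / (1 + 10^(n * (ph - pka)))

#' Ground-truth depth-dependent pKa profile
#'
#' Defines the "true" pKa (and cooperativity) of the tracked residue as a
#' function of signed insertion depth, in Angstrom, negative below the outer
#' phosphate surface. Values between bin centers are linearly interpolated;
#' outside the covered range the terminal values are held.
#'
#' @param bin_centers strictly increasing signed depths (Angstrom).
#' @param pka_values pKa per bin center (finite).
#' @param hill_n cooperativity per bin center (recycled if scalar).
#' @return an object of class `ground_truth_profile`.
#' @export
ground_truth_profile <- function(bin_centers, pka_values, hill_n = 1) {
  if (any(diff(bin_centers) <= 0))
    stop_invalid("bin_centers must be strictly increasing")
  if (length(pka_values) != length(bin_centers) || any(!is.finite(pka_values)))
    stop_invalid("pka_values must be finite and match bin_centers")
  hill_n <- rep_len(hill_n, length(bin_centers))
  structure(list(bin_centers = as.numeric(bin_centers),
                 pka_values = as.numeric(pka_values),
                 hill_n = as.numeric(hill_n)),
            class = "ground_truth_profile")
}

#' Evaluate a ground-truth profile at arbitrary depths
#' @param profile a [ground_truth_profile()].
#' @param z signed depths (Angstrom).
#' @return list with `pka` and `hill_n` vectors.
#' @export
profile_at_depth <- function(profile, z) {
  stopifnot(inherits(profile, "ground_truth_profile"))
  list(
    pka = stats::approx(profile$bin_centers, profile$pka_values, z,
                        rule = 2)$y,
    hill_n = stats::approx(profile$bin_centers, profile$hill_n, z,
                           rule = 2)$y
  )
}

#' Configuration for synthetic pHRE frame generation
#'
#' Defaults mirror the production pHRE setup these analyses are designed
#' for: five independent replicates, four pH replicas spanning pH 5.00-7.25
#' in 0.75 steps, 5000 stored frames per replica (100 ns at one frame per
#' 20 ps exchange period).
#'
#' @param n_replicates number of independent replicates (>= 1).
#' @param ph_ladder ascending pH values, one per replica.
#' @param n_frames stored frames per replica.
#' @param seed master seed; substreams are derived per channel.
#' @param frame_dt_ps time between stored frames (ps).
#' @param depth_bounds sampled insertion range (Angstrom, low < high).
#' @param walk_sd per-frame step s.d. of the reflected depth walk (Angstrom).
#' @param noise list of per-channel noise levels (all >= 0).
#' @param deformation_field optional [gaussian_deformation()] used when a
#'   bilayer is generated alongside the frames.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_replicates = 5,
                             ph_ladder = seq(5.00, 7.25, by = 0.75),
                             n_frames = 5000,
                             seed = 1L,
                             frame_dt_ps = 20,
                             depth_bounds = c(-6.25, 0.25),
                             walk_sd = 0.35,
                             noise = list(),
                             deformation_field = NULL) {
  if (n_replicates < 1) stop_invalid("n_replicates must be >= 1")
  if (length(ph_ladder) && any(diff(ph_ladder) < 0))
    stop_invalid("ph_ladder must be sorted ascending")
  noise_vals <- unlist(noise)
  if (length(noise_vals) && any(noise_vals < 0))
    stop_invalid("all noise levels must be >= 0")
  stopifnot(length(depth_bounds) == 2L, depth_bounds[1] < depth_bounds[2])
  structure(list(n_replicates = as.integer(n_replicates),
                 ph_ladder = as.numeric(ph_ladder),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 frame_dt_ps = frame_dt_ps, depth_bounds = depth_bounds,
                 walk_sd = walk_sd, noise = noise,
                 deformation_field = deformation_field),
            class = "synthetic_config")
}

#' Parametric Gaussian leaflet deformation field
#'
#' A radially symmetric Gaussian perturbation of leaflet height,
#' `amplitude * exp(-r^2 / (2 width^2))` with `r` the xy distance from
#' `center`. Negative amplitude pinches both leaflets toward the midplane
#' (local thinning), as under an inserted peptide.
#'
#' @param amplitude peak height change (Angstrom; negative = thinning).
#' @param width Gaussian width (Angstrom).
#' @param center xy center (Angstrom).
#' @return function of (x, y) returning the height perturbation.
#' @export
gaussian_deformation <- function(amplitude, width, center = c(0, 0)) {
  force(amplitude); force(width); force(center)
  stopifnot(width > 0)
  function(x, y) {
    r2 <- (x - center[1])^2 + (y - center[2])^2
    amplitude * exp(-r2 / (2 * width^2))
  }
}

#' Generate a two-leaflet phosphate lattice
#'
#' Places `n_lipids_per_leaflet` phosphate reference points per leaflet on a
#' jittered square lattice at z = +/- `half_thickness`, then applies the
#' deformation field additively: the upper leaflet gains `f(x, y)` and the
#' lower loses it, so both local half-thicknesses deviate by the field value.
#'
#' @param n_lipids_per_leaflet lipids per leaflet (>= 16).
#' @param half_thickness unperturbed half-thickness (Angstrom, > 0).
#' @param deformation_field a function of (x, y) in Angstrom, or `NULL`.
#' @param seed integer seed.
#' @param box_xy lateral box edge lengths (Angstrom).
#' @param jitter_sd lateral and vertical lattice jitter s.d. (Angstrom).
#' @return list with `upper`, `lower` (n x 3 coordinate matrices) and
#'   `box_xy`.
#' @export
generate_bilayer <- function(n_lipids_per_leaflet, half_thickness,
                             deformation_field = NULL, seed = 1L,
                             box_xy = NULL, jitter_sd = 0.4) {
  if (half_thickness <= 0) stop_invalid("half_thickness must be > 0")
  if (n_lipids_per_leaflet < 16)
    stop_invalid("n_lipids_per_leaflet must be >= 16")
  n_side <- ceiling(sqrt(n_lipids_per_leaflet))
  spacing <- 8  # ~64 A^2 area per lipid
  L <- box_xy %||% rep(n_side * spacing, 2)
  with_rng(substream_seed(seed, "bilayer"), {
    one_leaflet <- function(sign_z) {
      g <- expand.grid(x = (seq_len(n_side) - 0.5) * L[1] / n_side,
                       y = (seq_len(n_side) - 0.5) * L[2] / n_side)
      g <- g[seq_len(n_lipids_per_leaflet), , drop = FALSE]
      x <- g$x + stats::rnorm(nrow(g), 0, jitter_sd)
      y <- g$y + stats::rnorm(nrow(g), 0, jitter_sd)
      z <- sign_z * half_thickness + stats::rnorm(nrow(g), 0, jitter_sd)
      # upper leaflet gains f(x, y), lower loses it: local half-thickness
      # on each side deviates by the field value
      if (!is.null(deformation_field))
        z <- z + sign_z * deformation_field(x, y)
      cbind(x = x, y = y, z = z)
    }
    list(upper = one_leaflet(+1), lower = one_leaflet(-1), box_xy = L)
  })
}

#' Generate synthetic pHRE frame records
#'
#' Each (replicate, replica) pair runs an independent reflected Gaussian
#' random walk in insertion depth within `cfg$depth_bounds`; at every stored
#' frame the binary protonation state of the tracked site is drawn as a
#' Bernoulli variable with success probability given by the Hill model at
#' the replica's current pH and the local ground-truth pKa. With
#' `mix = "exchange"` (the default) the replicas of a replicate then
#' attempt neighbor pH swaps through the package's Metropolis rule
#' ([exchange_probability()]), so each replica visits the whole ladder over
#' time exactly as in production pHRE; `mix = "none"` pins replica k to
#' ladder pH k. Either way the marginal protonation at a given (depth, pH)
#' is the Hill value, but only the mixed mode gives every replica a full
#' titration curve.
#'
#' @param profile a [ground_truth_profile()] covering `cfg$depth_bounds`.
#' @param cfg a [synthetic_config()].
#' @param mix `"exchange"` or `"none"`.
#' @return data frame with columns `replicate`, `replica`, `pH` (the pH the
#'   replica held at that frame), `time_ps`, `insertion_A`, `prot_asp`.
#' @export
generate_phre_frames <- function(profile, cfg,
                                 mix = c("exchange", "none")) {
  mix <- match.arg(mix)
  stopifnot(inherits(profile, "ground_truth_profile"),
            inherits(cfg, "synthetic_config"))
  if (length(cfg$ph_ladder) == 0L) stop_invalid("ph_ladder must be non-empty")
  rng_cover <- range(profile$bin_centers)
  if (cfg$depth_bounds[1] < rng_cover[1] - 1e-9 ||
      cfg$depth_bounds[2] > rng_cover[2] + 1e-9)
    stop_invalid("profile must cover the sampled depth range %s..%s",
                 cfg$depth_bounds[1], cfg$depth_bounds[2])
  if (cfg$n_frames == 0L)
    return(data.frame(replicate = integer(), replica = integer(),
                      pH = numeric(), time_ps = numeric(),
                      insertion_A = numeric(), prot_asp = integer()))
  lo <- cfg$depth_bounds[1]; hi <- cfg$depth_bounds[2]
  reflect <- function(z) {
    # fold into [lo, hi] by reflection at the walls
    w <- hi - lo
    z <- (z - lo) %% (2 * w)
    lo + ifelse(z > w, 2 * w - z, z)
  }
  n_rep <- length(cfg$ph_ladder)
  nf <- cfg$n_frames
  out <- vector("list", cfg$n_replicates)
  for (rep_i in seq_len(cfg$n_replicates)) {
    # depth walks, one per replica, independent of the pH dynamics
    z <- matrix(0, nf, n_rep)
    for (k in seq_len(n_rep)) {
      zseed <- substream_seed(cfg$seed, sprintf("depth/%d/%d", rep_i, k))
      z[, k] <- with_rng(zseed, {
        steps <- stats::rnorm(nf, 0, cfg$walk_sd)
        reflect(stats::runif(1, lo, hi) + cumsum(steps))
      })
    }
    # Hill protonation probability of each replica at every ladder pH
    truth <- profile_at_depth(profile, as.vector(z))
    pmat <- array(0, c(nf, n_rep, n_rep))  # frame x replica x pH index
    for (j in seq_len(n_rep))
      pmat[, , j] <- matrix(hill_protonation(cfg$ph_ladder[j], truth$pka,
                                             truth$hill_n), nf, n_rep)
    ph_idx <- matrix(0L, nf, n_rep)   # ladder rung held by each replica
    prot <- matrix(0L, nf, n_rep)
    mseed <- substream_seed(cfg$seed, sprintf("mix/%d", rep_i))
    with_rng(mseed, {
      u_prot <- matrix(stats::runif(nf * n_rep), nf, n_rep)
      u_swap <- matrix(stats::runif(nf * n_rep), nf, n_rep)
      cur <- seq_len(n_rep)           # replica k holds rung cur[k]
      for (f in seq_len(nf)) {
        for (k in seq_len(n_rep)) {
          prot[f, k] <- as.integer(u_prot[f, k] < pmat[f, k, cur[k]])
        }
        ph_idx[f, ] <- cur
        if (mix == "exchange" && n_rep >= 2L) {
          first <- if (f %% 2L == 0L && n_rep > 2L) 2L else 1L
          holder <- order(cur)        # holder[d]: replica at rung d
          for (d in seq(first, n_rep - 1L, by = 2L)) {
            i <- holder[d]; j <- holder[d + 1L]
            p <- min(1, 10^((cfg$ph_ladder[cur[i]] - cfg$ph_ladder[cur[j]]) *
                              (prot[f, i] - prot[f, j])))
            if (u_swap[f, d] < p) {
              tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
            }
          }
        }
      }
    })
    out[[rep_i]] <- data.frame(
      replicate = rep_i,
      replica = rep(seq_len(n_rep), each = nf),
      pH = cfg$ph_ladder[as.vector(ph_idx)],
      time_ps = rep(seq_len(nf) * cfg$frame_dt_ps, n_rep),
      insertion_A = as.vector(z),
      prot_asp = as.vector(prot))
  }
  do.call(rbind, out)
}

#' Generate per-frame interaction-shell counts along a depth series
#'
#' Emulates depth-dependent partner abundances: for each channel a mean
#' function of depth is evaluated along the series and counts are drawn
#' Poisson around it (`dispersion = 1`), scaled-Poisson-like for other
#' positive dispersions, or set to the rounded mean when `dispersion = 0`.
#'
#' @param depth depth series (Angstrom).
#' @param mean_funs named list of functions of depth returning channel means
#'   (must be defined, i.e. finite, over the sampled depths).
#' @param dispersion >= 0; 0 gives deterministic rounded means.
#' @param seed integer seed.
#' @return data frame with one integer column per channel.
#' @export
generate_contact_profiles <- function(depth, mean_funs, dispersion = 1,
                                      seed = 1L) {
  if (dispersion < 0) stop_invalid("dispersion must be >= 0")
  stopifnot(is.list(mean_funs), length(names(mean_funs)) == length(mean_funs))
  out <- lapply(names(mean_funs), function(ch) {
    mu <- mean_funs[[ch]](depth)
    if (any(!is.finite(mu)))
      stop_invalid("mean function '%s' undefined at a sampled depth", ch)
    if (any(mu < 0)) stop_invalid("mean function '%s' gives negative means", ch)
    if (dispersion == 0) return(as.integer(round(mu)))
    with_rng(substream_seed(seed, paste0("contacts/", ch)), {
      if (dispersion == 1) stats::rpois(length(mu), mu)
      else {
        # over/under-dispersed counts via a gamma-mixed Poisson with
        # variance = dispersion * mean
        if (dispersion > 1) {
          shape <- mu / (dispersion - 1)
          stats::rpois(length(mu), stats::rgamma(length(mu), shape,
                                                 rate = shape / pmax(mu, 1e-12)))
        } else {
          as.integer(pmax(0, round(mu + stats::rnorm(length(mu), 0,
                                      sqrt(dispersion * pmax(mu, 0))))))
        }
      }
    })
  })
  names(out) <- names(mean_funs)
  as.data.frame(out)
}

#' Default depth-dependent shell-partner mean functions
#'
#' Smooth logistic shapes qualitatively matching a membrane-inserting
#' acidic residue: phosphate contacts grow with insertion, cholines and
#' water hydrogen bonds fall (desolvation), and the arginine-contact channel
#' is preset-dependent.
#'
#' @param arg_mode one of "none", "shallow", "deep".
#' @return named list of mean functions of depth (Angstrom, signed).
#' @export
default_contact_means <- function(arg_mode = c("none", "shallow", "deep")) {
  arg_mode <- match.arg(arg_mode)
  list(
    n_phos = function(z) 1 + 3 / (1 + exp((z + 3) / 1.2)),
    n_chol = function(z) 0.5 + 2.5 / (1 + exp(-(z + 3) / 1.2)),
    n_hbond = function(z) 6 / (1 + exp(-(z + 4) / 1.5)),
    arg_contact = switch(arg_mode,
      none = function(z) rep(0.05, length(z)),
      shallow = function(z) 1.5 / (1 + exp(-(z + 2) / 1.0)),
      deep = function(z) 1.5 / (1 + exp((z + 3) / 1.0)))
  )
}

#' Generate a synthetic pH-titration experiment
#'
#' Response = `baseline + span * f(pH) + noise`, with `f` the Hill
#' protonated fraction, emulating a normalized spectroscopic readout of a
#' pH-driven membrane-insertion transition.
#'
#' @param pk transition midpoint.
#' @param n cooperativity.
#' @param baseline,span affine scale of the raw readout (`span != 0`).
#' @param noise_sd Gaussian noise s.d.
#' @param ph_grid non-empty pH values.
#' @param seed integer seed.
#' @return data frame with `pH` and `response`.
#' @export
generate_titration_experiment <- function(pk, n, baseline = 0, span = 1,
                                          noise_sd = 0,
                                          ph_grid = seq(4, 8, by = 0.25),
                                          seed = 1L) {
  if (length(ph_grid) == 0L) stop_invalid("ph_grid must be non-empty")
  if (span == 0) stop_invalid("span must be nonzero")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  resp <- baseline + span * hill_protonation(ph_grid, pk, n)
  if (noise_sd > 0)
    resp <- resp + with_rng(substream_seed(seed, "titration"),
                            stats::rnorm(length(ph_grid), 0, noise_sd))
  data.frame(pH = ph_grid, response = resp)
}

#' Generate a synthetic stopped-flow kinetic trace
#'
#' Intensity = `offset + sum_i a_i exp(-t / tau_i) + noise` on the supplied
#' time grid, emulating normalized fluorescence during peptide
#' insertion/exit.
#'
#' @param amplitudes exponential amplitudes (same length as `taus`).
#' @param taus characteristic times, all > 0, in the units of `t_grid`.
#' @param offset additive plateau.
#' @param noise_sd Gaussian noise s.d.
#' @param t_grid strictly increasing times.
#' @param seed integer seed.
#' @return data frame with `time` and `intensity`.
#' @export
generate_kinetic_trace <- function(amplitudes, taus, offset = 0,
                                   noise_sd = 0, t_grid, seed = 1L) {
  if (length(amplitudes) != length(taus) || length(taus) < 1L)
    stop_invalid("amplitudes and taus must have equal length >= 1")
  if (any(taus <= 0)) stop_invalid("all taus must be > 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  y <- rep(offset, length(t_grid))
  for (i in seq_along(taus)) y <- y + amplitudes[i] * exp(-t_grid / taus[i])
  if (noise_sd > 0)
    y <- y + with_rng(substream_seed(seed, "kinetics"),
                      stats::rnorm(length(t_grid), 0, noise_sd))
  data.frame(time = t_grid, intensity = y)
}
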