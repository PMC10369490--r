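# Shared fixture builders. Everything is generated in code; no data files.

# Deterministic one-bin frame table with exact per-cell protonated counts:
# `spec` is a data.frame with columns pH, replicate, replica, n, n_prot.
make_bin_frames <- function(spec) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    data.frame(replicate = s$replicate, replica = s$replica, pH = s$pH,
               time_ps = seq_len(s$n) * 20,
               insertion_A = -2.1,
               prot_asp = c(rep(1L, s$n_prot), rep(0L, s$n - s$n_prot)))
  })
  do.call(rbind, rows)
}

# Full-factorial bin fixture: every (pH, replicate, replica) cell gets n
# frames with protonated fraction frac(pH).
make_balanced_bin <- function(ph_ladder, n_replicates = 3, n_replicas = 2,
                              n = 30, frac = function(p)
                                phrex::hill_protonation(p, 6.0, 1)) {
  spec <- expand.grid(pH = ph_ladder, replicate = seq_len(n_replicates),
                      replica = seq_len(n_replicas))
  spec$n <- n
  spec$n_prot <- round(vapply(spec$pH, frac, numeric(1)) * n)
  make_bin_frames(spec)
}

# Expand one reference point per lipid into a small phosphate-group atom
# cloud (P + 4 O), matching the atom density the 6 A / 10-atom surface
# support rule assumes.
expand_group_atoms <- function(pts, k = 5, sd = 0.8, seed = 1) {
  set.seed(seed)
  out <- pts[rep(seq_len(nrow(pts)), each = k), , drop = FALSE]
  out + matrix(rnorm(nrow(out) * 3, 0, sd), ncol = 3)
}

# Brute-force group-level shell count (independent oracle; plain loops).
brute_count_in_shell <- function(centers, partners, groups, cutoff, box) {
  centers <- rbind(centers); partners <- rbind(partners)
  hit <- logical(length(unique(groups)))
  ug <- unique(groups)
  for (gi in seq_along(ug)) {
    atoms <- which(groups == ug[gi])
    found <- FALSE
    for (a in atoms) {
      for (c in seq_len(nrow(centers))) {
        d2 <- 0
        for (k in 1:3) {
          dd <- partners[a, k] - centers[c, k]
          if (is.finite(box[k])) dd <- dd - box[k] * round(dd / box[k])
          d2 <- d2 + dd^2
        }
        if (sqrt(d2) <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    hit[gi] <- found
  }
  sum(hit)
}

brute_min_distance <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d2 <- 0
    for (k in 1:3) {
      dd <- a[i, k] - b[j, k]
      if (is.finite(box[k])) dd <- dd - box[k] * round(dd / box[k])
      d2 <- d2 + dd^2
    }
    best <- min(best, sqrt(d2))
  }
  best
}

# Independent Hill fit used as an oracle (never calls package fitting code):
# plain SSE minimization with stats::optim.
oracle_hill_fit <- function(ph, y) {
  sse <- function(par)
    sum((y - 1 / (1 + 10^(par[2] * (ph - par[1]))))^2)
  fit <- stats::optim(c(mean(ph), 1), sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  fit$par[1]
}
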