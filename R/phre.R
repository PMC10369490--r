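## pH replica exchange: Metropolis acceptance rule, attempt bookkeeping,
## and a toy ladder simulator for exchange-efficiency studies.

#' pH replica-exchange acceptance probability
#'
#' Metropolis criterion for swapping two constant-pH replicas,
#' \deqn{p = \min\{1, 10^{(pH_m - pH_l)(x_i - x_j)}\},}
#' where `ph_m`, `ph_l` are the exchanging pH values and `x_i`, `x_j` the
#' numbers of protonated groups of the replica currently at `ph_m` and at
#' `ph_l` respectively. Symmetric under the simultaneous swap of both pairs,
#' and satisfies detailed balance:
#' `p(a -> b) / p(b -> a) = 10^{(dpH)(dx)}`.
#'
#' @param ph_m,ph_l the two pH values.
#' @param x_i,x_j protonated-group counts (x_i belongs to the ph_m replica).
#' @return acceptance probability in [0, 1].
#' @export
exchange_probability <- function(ph_m, ph_l, x_i, x_j) {
  stopifnot(is.finite(ph_m), is.finite(ph_l), is.finite(x_i), is.finite(x_j))
  min(1, 10^((ph_m - ph_l) * (x_i - x_j)))
}

#' Attempt one replica exchange
#'
#' Draws a uniform variate and swaps the two states' pH labels iff it falls
#' below [exchange_probability()]; conformations and protonation counts
#' stay with their replicas while the pH values trade places.
#'
#' @param state_a,state_b lists with fields `ph` (pH value) and `x`
#'   (protonated-group count); pH labels must differ.
#' @param cycle_index attempt cycle, recorded in the ledger row.
#' @return list with `accepted`, updated `state_a`, `state_b`, and
#'   `attempt` (a one-row data frame ledger record). Uses the current RNG
#'   stream; seed externally for reproducibility.
#' @export
attempt_exchange <- function(state_a, state_b, cycle_index = NA_integer_) {
  if (isTRUE(all.equal(state_a$ph, state_b$ph)))
    stop_invalid("exchange attempted between identical pH labels")
  if (state_a$x < 0 || state_b$x < 0) stop_invalid("x counts must be >= 0")
  p <- exchange_probability(state_a$ph, state_b$ph, state_a$x, state_b$x)
  accepted <- stats::runif(1) < p
  rec <- data.frame(cycle = cycle_index, ph_m = state_a$ph,
                    ph_l = state_b$ph, x_i = state_a$x, x_j = state_b$x,
                    prob = p, accepted = accepted)
  if (accepted) {
    tmp <- state_a$ph; state_a$ph <- state_b$ph; state_b$ph <- tmp
  }
  list(accepted = accepted, state_a = state_a, state_b = state_b,
       attempt = rec)
}

#' Toy pH-replica-exchange ladder simulator
#'
#' One replica per ladder rung. Each cycle, every replica redraws the
#' protonation state of each titrable site independently from the Hill
#' model at its current pH (the toy decouples conformational dynamics from
#' protonation, which is all that the exchange criterion sees); then
#' adjacent-pH pairs attempt exchanges, even pairs on even cycles and odd
#' pairs on odd cycles.
#'
#' @param site_pkas pKa values of the titrable sites (may be empty: then
#'   every attempt is accepted).
#' @param ph_ladder sorted ascending pH values, length >= 2.
#' @param n_cycles number of exchange cycles (>= 1).
#' @param seed integer seed.
#' @param tau_re_ps exchange attempt period (metadata only), ps.
#' @return list of class `exchange_ledger` with `attempts` (data frame:
#'   cycle, pair, ph_m, ph_l, x_i, x_j, prob, accepted) and `tau_re_ps`.
#' @export
simulate_ladder <- function(site_pkas, ph_ladder, n_cycles, seed = 1L,
                            tau_re_ps = 20) {
  if (length(ph_ladder) < 2L) stop_invalid("ladder needs at least 2 rungs")
  if (is.unsorted(ph_ladder)) stop_invalid("ladder must be sorted ascending")
  if (n_cycles < 1L) stop_invalid("n_cycles must be >= 1")
  n_rep <- length(ph_ladder)
  n_sites <- length(site_pkas)
  # pre-size the ledger columns (at most ceiling((n_rep-1)/2) per cycle)
  max_att <- n_cycles * (n_rep - 1L)
  a_cyc <- integer(max_att); a_pair <- integer(max_att)
  a_phm <- numeric(max_att); a_phl <- numeric(max_att)
  a_xi <- integer(max_att); a_xj <- integer(max_att)
  a_p <- numeric(max_att); a_acc <- logical(max_att)
  n_att <- 0L
  # rung[k]: ladder rung currently held by replica k
  rung <- seq_len(n_rep)
  with_rng(substream_seed(seed, "ladder"), {
    for (cyc in seq_len(n_cycles)) {
      # redraw protonation counts at each replica's current pH
      x <- if (n_sites == 0L) rep(0L, n_rep) else {
        vapply(ph_ladder[rung], function(ph)
          sum(stats::runif(n_sites) < hill_protonation(ph, site_pkas, 1)),
          numeric(1))
      }
      holder <- order(rung)        # holder[d]: replica at rung d
      first <- if (cyc %% 2L == 0L && n_rep > 2L) 2L else 1L
      for (d in seq(first, n_rep - 1L, by = 2L)) {
        i <- holder[d]; j <- holder[d + 1L]
        p <- min(1, 10^((ph_ladder[d] - ph_ladder[d + 1L]) * (x[i] - x[j])))
        acc <- stats::runif(1) < p
        n_att <- n_att + 1L
        a_cyc[n_att] <- cyc; a_pair[n_att] <- d
        a_phm[n_att] <- ph_ladder[d]; a_phl[n_att] <- ph_ladder[d + 1L]
        a_xi[n_att] <- x[i]; a_xj[n_att] <- x[j]
        a_p[n_att] <- p; a_acc[n_att] <- acc
        if (acc) {
          tmp <- rung[i]; rung[i] <- rung[j]; rung[j] <- tmp
        }
      }
    }
  })
  keep <- seq_len(n_att)
  attempts <- data.frame(cycle = a_cyc[keep], pair = a_pair[keep],
                         ph_m = a_phm[keep], ph_l = a_phl[keep],
                         x_i = a_xi[keep], x_j = a_xj[keep],
                         prob = a_p[keep], accepted = a_acc[keep])
  structure(list(attempts = attempts, tau_re_ps = tau_re_ps,
                 ph_ladder = ph_ladder),
            class = "exchange_ledger")
}

#' Exchange efficiency of a ledger
#'
#' Accepted over attempted, overall and per neighbor pair.
#'
#' @param ledger an `exchange_ledger` (or its `attempts` data frame).
#' @return list with `overall` (fraction) and `per_pair` (data frame:
#'   pair, attempted, accepted, efficiency).
#' @export
exchange_efficiency <- function(ledger) {
  att <- if (inherits(ledger, "exchange_ledger")) ledger$attempts else ledger
  if (!is.data.frame(att) || nrow(att) == 0L)
    stop_invalid("ledger has no attempts")
  per <- do.call(rbind, lapply(split(att, att$pair), function(d) {
    data.frame(pair = d$pair[1], attempted = nrow(d),
               accepted = sum(d$accepted),
               efficiency = mean(d$accepted))
  }))
  rownames(per) <- NULL
  list(overall = mean(att$accepted), per_pair = per)
}

#' Serialize an exchange ledger to TSV
#' @param ledger an `exchange_ledger`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exchange_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "exchange_ledger"))
  utils::write.table(ledger$attempts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
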