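## First-interaction-shell census of the key carboxylate: phosphate and
## choline contacts, Asp-Arg salt bridges, water hydrogen bonds. The 5.2 A
## shell cutoff is taken as given (from RDF minima of prior simulations of
## the same membrane), not recomputed here.

#' Count partner groups in the first interaction shell
#'
#' Group-level counting: a partner group counts once if any of its atoms is
#' within `cutoff` of any center atom (minimum image), however many of its
#' atoms are inside the shell.
#'
#' @param center_coords m x 3 coordinates of the probe moiety (e.g. the
#'   carboxylate oxygens).
#' @param partner_coords n x 3 coordinates of partner atoms.
#' @param group_id length-n group labels for the partner atoms; by default
#'   each atom is its own group.
#' @param cutoff shell radius (Angstrom); default 5.2 (0.52 nm).
#' @param box periodic box lengths (3-vector; `Inf` = non-periodic).
#' @return integer count of groups with at least one atom in the shell.
#' @export
count_in_shell <- function(center_coords, partner_coords, group_id = NULL,
                           cutoff = 5.2, box = c(Inf, Inf, Inf)) {
  center_coords <- rbind(center_coords)
  if (nrow(center_coords) == 0L) stop_invalid("center selection is empty")
  partner_coords <- rbind(partner_coords)
  if (nrow(partner_coords) == 0L) return(0L)
  group_id <- group_id %||% seq_len(nrow(partner_coords))
  stopifnot(length(group_id) == nrow(partner_coords))
  d <- min_image_cross_dist(center_coords, partner_coords, box)
  atom_in <- apply(d <= cutoff, 2, any)
  length(unique(group_id[atom_in]))
}

#' Minimum side-chain distance between two atom selections
#'
#' Minimum over all atom pairs under the minimum-image convention; used for
#' the Asp carboxylate / Arg guanidinium salt-bridge distance series.
#'
#' @param asp_coords,arg_coords non-empty coordinate matrices (n x 3).
#' @param box periodic box lengths.
#' @return minimum pair distance (Angstrom).
#' @export
min_sidechain_distance <- function(asp_coords, arg_coords,
                                   box = c(Inf, Inf, Inf)) {
  asp_coords <- rbind(asp_coords); arg_coords <- rbind(arg_coords)
  if (nrow(asp_coords) == 0L || nrow(arg_coords) == 0L)
    stop_invalid("both selections must be non-empty")
  min(min_image_cross_dist(asp_coords, arg_coords, box))
}

#' Salt-bridge occupancy of a minimum-distance series
#'
#' @param min_distances per-frame minimum Asp-Arg distances (Angstrom).
#' @param bridge_cutoff contact criterion (Angstrom); 4.0 is the
#'   conventional carboxylate-guanidinium heavy-atom threshold.
#' @return fraction of frames at or under the cutoff, in [0, 1].
#' @export
salt_bridge_occupancy <- function(min_distances, bridge_cutoff = 4.0) {
  if (length(min_distances) == 0L) stop_invalid("distance series is empty")
  mean(min_distances <= bridge_cutoff)
}

#' Count water molecules hydrogen-bonded to an acceptor moiety
#'
#' Geometric criterion with water as the donor (the ionized carboxylate
#' only accepts): a water counts if its oxygen lies within `d_cutoff` of
#' any acceptor atom and, for at least one of its hydrogens, the
#' acceptor-donor-hydrogen angle at the water oxygen is at most
#' `angle_cutoff` (i.e. the O-H bond points at the acceptor to within the
#' tolerance).
#'
#' @param acceptor_coords m x 3 acceptor atoms (carboxylate oxygens).
#' @param water_o n x 3 water oxygen coordinates.
#' @param water_h (2n) x 3 water hydrogen coordinates, hydrogens `2i - 1`
#'   and `2i` belonging to water `i`.
#' @param d_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff angular tolerance (degrees).
#' @param box periodic box lengths.
#' @return integer count of hydrogen-bonded waters.
#' @export
count_water_hbonds <- function(acceptor_coords, water_o, water_h,
                               d_cutoff = 3.5, angle_cutoff = 30,
                               box = c(Inf, Inf, Inf)) {
  acceptor_coords <- rbind(acceptor_coords)
  water_o <- rbind(water_o); water_h <- rbind(water_h)
  if (nrow(acceptor_coords) == 0L) stop_invalid("acceptor selection is empty")
  if (nrow(water_h) != 2L * nrow(water_o))
    stop_invalid("malformed water topology: need 2 hydrogens per oxygen")
  if (nrow(water_o) == 0L) return(0L)
  n_bonded <- 0L
  cos_tol <- cos(angle_cutoff * pi / 180)
  for (i in seq_len(nrow(water_o))) {
    o <- water_o[i, ]
    doa <- min_image_cross_dist(o, acceptor_coords, box)[1, ]
    close <- which(doa <= d_cutoff)
    if (length(close) == 0L) next
    hs <- water_h[c(2L * i - 1L, 2L * i), , drop = FALSE]
    bonded <- FALSE
    for (a in close) {
      v_oa <- min_image(acceptor_coords[a, ] - o, box)
      for (hrow in 1:2) {
        v_oh <- min_image(hs[hrow, ] - o, box)
        ca <- sum(v_oa * v_oh) /
          (sqrt(sum(v_oa^2)) * sqrt(sum(v_oh^2)))
        if (ca >= cos_tol) { bonded <- TRUE; break }
      }
      if (bonded) break
    }
    if (bonded) n_bonded <- n_bonded + 1L
  }
  n_bonded
}

#' Per-frame shell census record
#'
#' Convenience constructor bundling the four census channels for one frame.
#'
#' @param n_phosphate,n_choline,n_water_hbond non-negative counts.
#' @param arg_in_shell logical.
#' @param frame_time ps.
#' @return list of class `shell_counts`.
#' @export
shell_counts <- function(n_phosphate, n_choline, n_water_hbond,
                         arg_in_shell, frame_time = NA_real_) {
  if (any(c(n_phosphate, n_choline, n_water_hbond) < 0))
    stop_invalid("counts must be >= 0")
  structure(list(n_phosphate = as.integer(n_phosphate),
                 n_choline = as.integer(n_choline),
                 n_water_hbond = as.integer(n_water_hbond),
                 arg_in_shell = as.logical(arg_in_shell),
                 frame_time = frame_time),
            class = "shell_counts")
}
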