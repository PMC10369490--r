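## Membrane geometry: local surface reference, signed insertion depth,
## half-thickness deformation scans, TM tilt.

#' Local phosphate-surface reference height
#'
#' Mean z of the phosphate atoms of one leaflet lying within `radius_xy` of
#' the residue in the xy plane (minimum image). If fewer than `min_atoms`
#' qualify, the radius is widened in `expand_step` increments up to
#' `radius_cap`; if support is still insufficient the call errors rather
#' than silently referencing distant lipids.
#'
#' @param residue_xy length-2 xy position of the residue (Angstrom).
#' @param phosphate_coords n x 3 phosphate coordinates of a single leaflet.
#' @param box_xy periodic xy box lengths (use `Inf` for non-periodic).
#' @param radius_xy initial search radius (Angstrom).
#' @param min_atoms minimum number of supporting atoms.
#' @param expand_step,radius_cap widening policy when support is short.
#' @return list of class `surface_reference` with `mean_z`,
#'   `n_support_atoms`, `radius_xy` (the radius actually used).
#' @export
local_surface_z <- function(residue_xy, phosphate_coords,
                            box_xy = c(Inf, Inf), radius_xy = 6,
                            min_atoms = 10, expand_step = 1,
                            radius_cap = 12) {
  phosphate_coords <- rbind(phosphate_coords)
  if (nrow(phosphate_coords) == 0L)
    stop_invalid("phosphate coordinate set is empty")
  stopifnot(radius_xy > 0)
  d <- min_image_dist_xy(residue_xy, phosphate_coords, box_xy)
  r <- radius_xy
  repeat {
    sel <- d <= r
    if (sum(sel) >= min_atoms) break
    r <- r + expand_step
    if (r > radius_cap + 1e-9)
      stop_invalid(
        "only %d support atoms within the %.1f A radius cap (need %d)",
        sum(d <= radius_cap), radius_cap, min_atoms)
  }
  structure(list(mean_z = mean(phosphate_coords[sel, 3]),
                 n_support_atoms = sum(sel), radius_xy = r),
            class = "surface_reference")
}

#' Signed membrane-insertion depth
#'
#' Difference between the residue z coordinate and the local phosphate
#' surface reference of the outer leaflet. Negative values mean the residue
#' sits below the phosphate plane (inserted); the sign convention is fixed
#' package-wide.
#'
#' @param residue_z residue z coordinate (Angstrom).
#' @param surface a `surface_reference` from [local_surface_z()] (or a bare
#'   numeric surface z).
#' @param frame_time optional frame time (ps), carried through.
#' @return list of class `insertion_depth` with `value` and `frame_time`.
#' @export
insertion_depth <- function(residue_z, surface, frame_time = NA_real_) {
  sz <- if (inherits(surface, "surface_reference")) surface$mean_z
        else as.numeric(surface)
  structure(list(value = residue_z - sz, frame_time = frame_time),
            class = "insertion_depth")
}

#' Radial half-thickness deformation scan
#'
#' Scans concentric xy annuli of width `annulus_width` centered on the
#' peptide and reports, per leaflet, the local half-thickness deviation from
#' the bulk value. Half-thickness is measured against the instantaneous
#' bilayer midplane (mean z of all phosphates, robust to box drift); the
#' bulk pools all atoms beyond `bulk_min`. Empty annuli are flagged with
#' `NA`, never interpolated.
#'
#' @param upper,lower n x 3 phosphate coordinates per leaflet.
#' @param center_xy xy scan center (peptide position).
#' @param box_xy periodic xy box lengths.
#' @param annulus_width annulus width (Angstrom).
#' @param r_max outer scan radius (Angstrom).
#' @param bulk_min inner radius of the bulk region (Angstrom).
#' @return data frame of class `deformation_profile` with columns `radius`
#'   (annulus midpoint), `upper_dev`, `lower_dev`, `n_upper`, `n_lower`,
#'   plus attributes `bulk_half_thickness` (per-leaflet mean) and
#'   `midplane_z`.
#' @export
half_thickness_scan <- function(upper, lower, center_xy,
                                box_xy = c(Inf, Inf), annulus_width = 0.5,
                                r_max = 25, bulk_min = 15) {
  upper <- rbind(upper); lower <- rbind(lower)
  if (nrow(upper) == 0L || nrow(lower) == 0L)
    stop_invalid("both leaflets must be non-empty")
  midplane <- mean(c(upper[, 3], lower[, 3]))
  du <- min_image_dist_xy(center_xy, upper, box_xy)
  dl <- min_image_dist_xy(center_xy, lower, box_xy)
  bulk_u_sel <- du > bulk_min
  bulk_l_sel <- dl > bulk_min
  if (!any(bulk_u_sel) || !any(bulk_l_sel))
    stop_invalid("no atoms beyond bulk_min = %.1f A; bulk undefined",
                 bulk_min)
  bulk_u <- abs(mean(upper[bulk_u_sel, 3]) - midplane)
  bulk_l <- abs(mean(lower[bulk_l_sel, 3]) - midplane)
  edges <- seq(0, r_max, by = annulus_width)
  n_ann <- length(edges) - 1L
  res <- data.frame(radius = edges[-length(edges)] + annulus_width / 2,
                    upper_dev = NA_real_, lower_dev = NA_real_,
                    n_upper = 0L, n_lower = 0L)
  for (i in seq_len(n_ann)) {
    su <- du >= edges[i] & du < edges[i + 1]
    sl <- dl >= edges[i] & dl < edges[i + 1]
    res$n_upper[i] <- sum(su); res$n_lower[i] <- sum(sl)
    if (any(su))
      res$upper_dev[i] <- abs(mean(upper[su, 3]) - midplane) - bulk_u
    if (any(sl))
      res$lower_dev[i] <- abs(mean(lower[sl, 3]) - midplane) - bulk_l
  }
  attr(res, "bulk_half_thickness") <- mean(c(bulk_u, bulk_l))
  attr(res, "bulk_half_thickness_upper") <- bulk_u
  attr(res, "bulk_half_thickness_lower") <- bulk_l
  attr(res, "midplane_z") <- midplane
  class(res) <- c("deformation_profile", "data.frame")
  res
}

#' Tilt angle of the transmembrane segment
#'
#' Angle between the segment axis (start -> end) and the membrane normal,
#' folded into [0, 90] degrees (a membrane normal has no preferred sign).
#'
#' @param tm_start_coord,tm_end_coord 3-vectors, distinct.
#' @param membrane_normal 3-vector (default z axis).
#' @return angle in degrees in [0, 90].
#' @export
tilt_angle <- function(tm_start_coord, tm_end_coord,
                       membrane_normal = c(0, 0, 1)) {
  axis <- tm_end_coord - tm_start_coord
  na <- sqrt(sum(axis^2)); nn <- sqrt(sum(membrane_normal^2))
  if (na == 0) stop_invalid("TM segment has zero length")
  if (nn == 0) stop_invalid("membrane normal has zero length")
  cosang <- abs(sum(axis * membrane_normal)) / (na * nn)
  acos(pmin(1, pmax(0, cosang))) * 180 / pi
}
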