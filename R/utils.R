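#' @keywords internal
"_PACKAGE"

## Shared helpers: seeded substreams, periodic geometry, frame-table I/O.

#' Derive a reproducible substream seed from a master seed and a channel name
#'
#' Each stochastic channel (depth walk, protonation draws, contact counts,
#' noise, ...) consumes its own substream so that adding or reordering
#' channels never perturbs the draws of the others.
#'
#' @param seed master integer seed.
#' @param channel character scalar naming the substream.
#' @return an integer seed < 2^31.
#' @export
substream_seed <- function(seed, channel) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(channel))
  codes <- utf8ToInt(channel)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched, so generators are pure functions of (args, seed).
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Minimum-image displacement components under a rectangular periodic box
#'
#' @param d numeric vector (or matrix) of raw coordinate differences.
#' @param box periodic box edge length(s) matching the columns of `d`;
#'   use `Inf` for a non-periodic direction.
#' @return wrapped displacements with each component in (-L/2, L/2].
#' @export
min_image <- function(d, box) {
  if (is.matrix(d)) {
    stopifnot(length(box) == ncol(d))
    for (j in seq_len(ncol(d))) {
      if (is.finite(box[j])) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
    }
    d
  } else {
    ifelse(is.finite(box), d - box * round(d / box), d)
  }
}

# xy minimum-image distances from one point to the rows of `coords` (n x >=2)
min_image_dist_xy <- function(point_xy, coords, box_xy) {
  d <- cbind(coords[, 1] - point_xy[1], coords[, 2] - point_xy[2])
  d <- min_image(d, box_xy)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

# full 3D minimum-image distance matrix between two coordinate sets
min_image_cross_dist <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L, length(box) == 3L)
  out <- matrix(0, nrow(a), nrow(b))
  for (j in 1:3) {
    dj <- outer(a[, j], b[, j], "-")
    if (is.finite(box[j])) dj <- dj - box[j] * round(dj / box[j])
    out <- out + dj^2
  }
  sqrt(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a frame table in the package's TSV dialect
#'
#' The inter-stage contract of the pipeline: one row per stored simulation
#' frame with columns `replicate`, `replica`, `pH`, `time_ps`, `insertion_A`,
#' one `prot_<site>` column per titrable site, and the shell-census channels
#' `n_phos`, `n_chol`, `n_hbond`, `arg_contact` when present.
#'
#' @param frames data frame of frame records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  utils::write.table(frames, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a frame table written by [write_frames()]
#' @param path TSV file path.
#' @return data frame of frame records.
#' @export
read_frames <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export point coordinates as a minimal GRO-dialect file
#'
#' Fixed-width GRO records, nm units (coordinates supplied in Angstrom are
#' divided by 10). Intended for quick visual inspection of synthetic
#' bilayers in standard viewers, not as a full topology.
#'
#' @param coords n x 3 matrix, Angstrom.
#' @param path output path.
#' @param box box edge lengths in Angstrom (3-vector).
#' @param atom_name,res_name atom/residue labels (recycled).
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(coords, path, box = c(100, 100, 100),
                      atom_name = "P", res_name = "LIP",
                      title = "synthetic bilayer") {
  coords <- rbind(coords)
  n <- nrow(coords)
  atom_name <- rep_len(atom_name, n)
  res_name <- rep_len(res_name, n)
  lines <- c(title, sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              i %% 100000L, res_name[i], atom_name[i],
                              i %% 100000L,
                              coords[i, 1] / 10, coords[i, 2] / 10,
                              coords[i, 3] / 10))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f",
                            box[1] / 10, box[2] / 10, box[3] / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read coordinates from a GRO-dialect file
#' @param path GRO file.
#' @return list with `coords` (n x 3 matrix, Angstrom) and `box` (Angstrom).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  xyz <- t(vapply(body, function(l) {
    c(as.numeric(substr(l, 21, 28)), as.numeric(substr(l, 29, 36)),
      as.numeric(substr(l, 37, 44)))
  }, numeric(3), USE.NAMES = FALSE)) * 10
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3] * 10
  list(coords = xyz, box = box)
}
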