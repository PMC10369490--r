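## Attribution of pKa shifts to electrostatic shell partners: property
## insertion profiles, interpolation at the per-bin pKa, feature-matrix
## assembly, and random-forest importance ranking.

#' Per-bin, per-pH mean of one shell property
#'
#' @param frames frame table carrying the named count channel plus
#'   `insertion_A` and `pH`.
#' @param property_name one of the census channels (e.g. `"n_phos"`,
#'   `"n_chol"`, `"n_hbond"`, `"arg_contact"`).
#' @param bin_width insertion bin width (Angstrom).
#' @param min_occupancy bins x pH cells with fewer frames are dropped
#'   (absent, not zero).
#' @return data frame of class `property_profile`: `bin_low`, `bin_mid`,
#'   `pH`, `value` (mean), `n`.
#' @export
property_profile <- function(frames, property_name, bin_width = 0.5,
                             min_occupancy = 10) {
  if (!property_name %in% names(frames))
    stop_invalid("unknown property '%s'", property_name)
  lows <- bin_low_of(frames$insertion_A, bin_width)
  key <- paste(lows, frames$pH, sep = "|")
  agg <- rowsum(cbind(n = rep(1L, nrow(frames)),
                      s = frames[[property_name]]), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  out <- data.frame(bin_low = as.numeric(parts[, 1]),
                    pH = as.numeric(parts[, 2]),
                    value = agg[, "s"] / agg[, "n"], n = agg[, "n"])
  out$bin_mid <- out$bin_low + bin_width / 2
  out <- out[out$n >= min_occupancy,
             c("bin_low", "bin_mid", "pH", "value", "n")]
  out <- out[order(out$bin_low, out$pH), ]
  rownames(out) <- NULL
  class(out) <- c("property_profile", "data.frame")
  out
}

#' Interpolate a property profile at each bin's pKa
#'
#' For every insertion bin with at least two pH points, the pH-dependent
#' property is linearly interpolated at that bin's fitted pKa, yielding the
#' property value "seen" at the titration midpoint.
#'
#' @param profile a [property_profile()].
#' @param bin_pka data frame with `bin_low` and `pka` (e.g. a
#'   [build_profile()] result restricted to passing bins).
#' @param out_of_range policy when a bin pKa lies outside the pH grid:
#'   `"flag"` extrapolates the terminal value and marks the row,
#'   `"clamp"` does the same silently, `"drop"` removes the row.
#' @return data frame: `bin_low`, `pka`, `value`, `extrapolated`.
#' @export
interpolate_at_pka <- function(profile, bin_pka,
                               out_of_range = c("flag", "clamp", "drop")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(all(c("bin_low", "pka") %in% names(bin_pka)))
  rows <- lapply(seq_len(nrow(bin_pka)), function(i) {
    lo <- bin_pka$bin_low[i]; pk <- bin_pka$pka[i]
    sub <- profile[profile$bin_low == lo, ]
    if (nrow(sub) < 2L || !is.finite(pk)) return(NULL)
    extra <- pk < min(sub$pH) || pk > max(sub$pH)
    if (extra && out_of_range == "drop") return(NULL)
    v <- stats::approx(sub$pH, sub$value, xout = pk, rule = 2)$y
    data.frame(bin_low = lo, pka = pk, value = v,
               extrapolated = extra && out_of_range == "flag")
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(bin_low = numeric(), pka = numeric(),
                      value = numeric(), extrapolated = logical())
}

#' Assemble the cross-variant feature matrix
#'
#' One row per (variant, criteria-passing bin): the four shell-partner
#' features interpolated at the bin pKa, with that pKa as the response.
#' Rows with any missing cell are dropped; the retained dimensions and the
#' per-variant row provenance are attached as attributes.
#'
#' @param variant_data named list (one entry per peptide variant) of lists
#'   with `frames` (census-carrying frame table) and `profile` (a
#'   [build_profile()] result).
#' @param channels census channel names mapped to feature columns.
#' @param bin_width insertion bin width (Angstrom).
#' @param min_occupancy per-cell occupancy floor for property means.
#' @return data frame of class `feature_matrix` with columns `variant`,
#'   `bin_low`, `phosphate`, `arginine`, `choline`, `hbond`, `pka`.
#' @export
assemble_feature_matrix <- function(variant_data,
                                    channels = c(phosphate = "n_phos",
                                                 arginine = "arg_contact",
                                                 choline = "n_chol",
                                                 hbond = "n_hbond"),
                                    bin_width = 0.5, min_occupancy = 10) {
  stopifnot(length(names(variant_data)) == length(variant_data))
  rows <- lapply(names(variant_data), function(v) {
    fr <- variant_data[[v]]$frames
    pr <- variant_data[[v]]$profile
    ok <- pr[pr$pass & !is.na(pr$pka), c("bin_low", "pka")]
    if (nrow(ok) == 0L) return(NULL)
    feats <- lapply(channels, function(ch) {
      pp <- property_profile(fr, ch, bin_width, min_occupancy)
      interpolate_at_pka(pp, ok, out_of_range = "clamp")
    })
    base <- ok
    for (f in names(channels)) {
      m <- feats[[f]][, c("bin_low", "value")]
      names(m)[2] <- f
      base <- merge(base, m, by = "bin_low", all = FALSE)
    }
    if (nrow(base) == 0L) return(NULL)
    cbind(variant = v, base[, c("bin_low", names(channels), "pka")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_invalid("no complete (variant, bin) rows")
  out <- out[stats::complete.cases(out), ]
  rownames(out) <- NULL
  attr(out, "dimensions") <- dim(out)
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Random-forest importance ranking of the electrostatic features
#'
#' Regresses the per-bin pKa on the four shell features with a
#' random-forest ensemble (2500 trees, depth cap 20) and reports
#' impurity-based importances normalized to sum to 1, alongside the
#' in-sample coefficient of determination (headline) and the out-of-bag
#' one. Permutation importance is available as a cross-check mode.
#'
#' @param matrix a [assemble_feature_matrix()] result, or any data frame
#'   with the feature columns and a `pka` response.
#' @param features feature column names.
#' @param n_trees,max_depth forest hyperparameters.
#' @param seed integer seed (forest growth is stochastic).
#' @param mode `"impurity"` or `"permutation"` importance.
#' @return list of class `feature_importance`: `importances` (named,
#'   summing to 1), `r_squared` (in-sample), `r_squared_oob`, `n_rows`.
#' @export
feature_importance <- function(matrix,
                               features = c("phosphate", "arginine",
                                            "choline", "hbond"),
                               n_trees = 2500, max_depth = 20, seed = 1L,
                               mode = c("impurity", "permutation")) {
  mode <- match.arg(mode)
  stopifnot(all(c(features, "pka") %in% names(matrix)))
  df <- as.data.frame(matrix)[, c(features, "pka")]
  if (nrow(df) < 20L) stop_invalid("need >= 20 rows (got %d)", nrow(df))
  if (stats::var(df$pka) == 0)
    stop_invalid("degenerate constant response")
  fit <- ranger::ranger(
    dependent.variable.name = "pka", data = df,
    num.trees = n_trees, max.depth = max_depth,
    importance = mode, seed = substream_seed(seed, "forest"),
    num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  pred <- stats::predict(fit, df)$predictions
  r2_in <- 1 - sum((df$pka - pred)^2) / sum((df$pka - mean(df$pka))^2)
  structure(list(importances = imp[features], r_squared = r2_in,
                 r_squared_oob = fit$r.squared, n_rows = nrow(df)),
            class = "feature_importance")
}
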