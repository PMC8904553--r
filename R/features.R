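#' Threshold filtering of an interferogram
#'
#' Flags the noisy low-amplitude part of a spectrum: samples whose power
#' falls below `threshold` times the global maximum are excluded from the
#' subsequent local-maxima analysis (the default 0.05 corresponds to 5% of
#' the global maximum). Power values are retained; only an inclusion mask is
#' attached, and the global maximum is unchanged.
#'
#' @param spectrum An [interferogram()].
#' @param threshold Fraction of the global maximum in `[0, 1)`.
#' @return The spectrum with a logical `included` field added.
#' @export
filter_by_threshold <- function(spectrum, threshold = 0.05) {
  if (!inherits(spectrum, "interferogram")) {
    stop("`spectrum` must be an interferogram", call. = FALSE)
  }
  stopifnot_scalar(threshold, "threshold")
  if (threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  global_max <- max(spectrum$power)
  if (global_max <= 0) {
    stop("degenerate spectrum: non-positive global maximum", call. = FALSE)
  }
  spectrum$included <- spectrum$power >= threshold * global_max
  spectrum$threshold <- threshold
  spectrum
}

#' Local maxima of an interferogram
#'
#' Finds interior samples strictly greater than both neighbours among the
#' samples retained by [filter_by_threshold()] (all samples if the spectrum
#' was not filtered). Plateaus count once, at their leftmost point. With
#' fewer than three retained samples the list is empty.
#'
#' @param spectrum An [interferogram()], usually threshold-filtered.
#' @return A data frame with columns `wavelength` and `power`, sorted by
#'   wavelength.
#' @export
find_local_maxima <- function(spectrum) {
  if (!inherits(spectrum, "interferogram")) {
    stop("`spectrum` must be an interferogram", call. = FALSE)
  }
  keep <- if (is.null(spectrum$included)) {
    rep(TRUE, length(spectrum$power))
  } else {
    spectrum$included
  }
  w <- spectrum$wavelength[keep]
  p <- spectrum$power[keep]
  empty <- data.frame(wavelength = numeric(0), power = numeric(0))
  if (length(p) < 3L) return(empty)
  # collapse equal-value runs so each plateau is judged once (leftmost point)
  r <- rle(p)
  vals <- r$values
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  if (length(vals) < 3L) return(empty)
  interior <- 2:(length(vals) - 1L)
  is_max <- vals[interior] > vals[interior - 1L] &
    vals[interior] > vals[interior + 1L]
  hit <- starts[interior][is_max]
  data.frame(wavelength = w[hit], power = p[hit])
}

#' Spacing statistics of consecutive fringe maxima
#'
#' Average, maximum, minimum and median wavelength distance between
#' consecutive local maxima (the empirical free spectral range). With fewer
#' than two maxima all four statistics are reported as the sentinel 0.
#'
#' @param maxima A data frame from [find_local_maxima()] (sorted by
#'   wavelength).
#' @return Named numeric vector `c(average, maximum, minimum, median)` in nm.
#' @export
maxima_distance_stats <- function(maxima) {
  if (nrow(maxima) < 2L) {
    return(c(average = 0, maximum = 0, minimum = 0, median = 0))
  }
  d <- diff(maxima$wavelength)
  c(average = mean(d), maximum = max(d), minimum = min(d),
    median = stats::median(d))
}

#' Amplitude normalisation factor
#'
#' Rescales the experimental spectrum onto the simulation's amplitude range:
#' `f = ssmax / global max`, where `ssmax` is the maximum of the simulated
#' signal and `global max` the maximum of the measured one.
#'
#' @param experimental,simulated [interferogram()] objects.
#' @return The scalar factor `f`.
#' @export
amplitude_factor <- function(experimental, simulated) {
  gmax <- max(experimental$power)
  if (gmax <= 0) {
    stop("degenerate input: experimental global maximum is not positive",
         call. = FALSE)
  }
  max(simulated$power) / gmax
}

# Put two spectra on a shared uniform grid by linear resampling. With
# `force_odd` the grid gets an odd point count (an even number of panels),
# as composite Simpson requires. Spectra already sharing a uniform grid of
# acceptable parity pass through unchanged.
resample_to_common_grid <- function(experimental, simulated, n = NULL,
                                    force_odd = TRUE) {
  we <- experimental$wavelength
  ws <- simulated$wavelength
  if (length(we) == length(ws) && all(we == ws)) {
    h <- diff(we)
    uniform <- all(abs(h - h[1L]) <= 1e-9 * abs(h[1L]))
    if (uniform && (!force_odd || length(we) %% 2L == 1L)) {
      return(list(wavelength = we, experimental = experimental$power,
                  simulated = simulated$power))
    }
  }
  lo <- max(we[1L], ws[1L])
  hi <- min(we[length(we)], ws[length(ws)])
  if (lo >= hi) {
    stop("incompatible domains: wavelength ranges do not overlap",
         call. = FALSE)
  }
  if (is.null(n)) n <- max(length(we), length(ws))
  if (force_odd && n %% 2L == 0L) n <- n + 1L
  grid <- seq(lo, hi, length.out = n)
  list(
    wavelength = grid,
    experimental = stats::approx(we, experimental$power, grid)$y,
    simulated = stats::approx(ws, simulated$power, grid)$y
  )
}

#' Distortion of a measured interferogram
#'
#' Quantifies how far a measured fringe pattern departs from its theoretical
#' reference through the areas under both curves:
#' `D = |(1 - area_exp * f) / area_sym|`, with both areas computed by
#' composite Simpson integration over the shared wavelength window and `f`
#' the amplitude factor of [amplitude_factor()]. The formula is applied
#' literally in this asymmetric form.
#'
#' @param experimental,simulated [interferogram()] objects with overlapping
#'   wavelength ranges.
#' @param f Amplitude normalisation factor.
#' @return The scalar distortion `D >= 0`.
#' @export
distortion <- function(experimental, simulated, f) {
  rs <- resample_to_common_grid(experimental, simulated)
  area_exp <- simpson_integral(rs$wavelength, rs$experimental)
  area_sym <- simpson_integral(rs$wavelength, rs$simulated)
  abs((1 - area_exp * f) / area_sym)
}

#' Axial shift between measured and simulated fringe patterns
#'
#' Signed wavelength offset of the experimental global maximum relative to
#' the simulated one, in nm. Ties for the global maximum are broken towards
#' the lowest wavelength.
#'
#' @param experimental,simulated [interferogram()] objects.
#' @return Signed shift in nm.
#' @export
axial_shift <- function(experimental, simulated) {
  experimental$wavelength[which.max(experimental$power)] -
    simulated$wavelength[which.max(simulated$power)]
}

#' RMSE between normalised experimental and simulated spectra
#'
#' Root-mean-square pointwise difference between the amplitude-normalised
#' experimental signal (`f * power`) and the simulated signal, evaluated on
#' a shared uniform grid. Scaling the experimental signal by `f` first puts
#' the error in simulation units and makes it invariant under rescaling of
#' the measured power.
#'
#' @param experimental,simulated [interferogram()] objects with overlapping
#'   wavelength ranges.
#' @param f Amplitude normalisation factor.
#' @return The RMSE as a scalar.
#' @export
signal_rmse <- function(experimental, simulated, f) {
  rs <- resample_to_common_grid(experimental, simulated, force_odd = FALSE)
  sqrt(mean((f * rs$experimental - rs$simulated)^2))
}

#' Map one interferogram to its 18-slot feature row
#'
#' Computes the feature vector describing one measured (or synthetic)
#' spectrum against the theoretical two-beam reference generated from
#' `model`:
#'
#' * `F1` number of local maxima after threshold filtering
#' * `F2` global maximum power
#' * `F3` the threshold fraction used
#' * `F4` amplitude normalisation factor `f`
#' * `F5`-`F8` average / maximum / minimum / median wavelength distance
#'   between consecutive local maxima (nm)
#' * `F9` Simpson-rule distortion `D`
#' * `F10` axial shift of the global maximum (nm, signed)
#' * `F11` RMSE between normalised experimental and simulated signal
#' * `F12` cavity length (um)
#' * `F13`, `F14` minimum and maximum wavelength of the spectrum (nm)
#' * `F15` power amplitude (max - min)
#' * `F16` wavelength of maximum power (nm)
#' * `F17` wavelength of maximum power of the theoretical signal (nm)
#' * `F18` class target, left `NA` here and filled by [build_dataset()]
#'
#' @param experimental An [interferogram()].
#' @param model The [cavity_model()] describing the acquisition (its
#'   refractive index must be the one for this spectrum).
#' @param threshold Fraction of the global maximum used to exclude the noisy
#'   part of the signal; default 0.05.
#' @return A one-row data frame with columns `F1`..`F18`.
#' @export
extract_features <- function(experimental, model, threshold = 0.05) {
  simulated <- theoretical_interferogram(model)
  filtered <- filter_by_threshold(experimental, threshold)
  maxima <- find_local_maxima(filtered)
  dist_stats <- maxima_distance_stats(maxima)
  f <- amplitude_factor(experimental, simulated)
  row <- data.frame(
    F1 = nrow(maxima),
    F2 = max(experimental$power),
    F3 = threshold,
    F4 = f,
    F5 = unname(dist_stats["average"]),
    F6 = unname(dist_stats["maximum"]),
    F7 = unname(dist_stats["minimum"]),
    F8 = unname(dist_stats["median"]),
    F9 = distortion(experimental, simulated, f),
    F10 = axial_shift(experimental, simulated),
    F11 = signal_rmse(experimental, simulated, f),
    F12 = model$cavity_length,
    F13 = experimental$wavelength[1L],
    F14 = experimental$wavelength[length(experimental$wavelength)],
    F15 = max(experimental$power) - min(experimental$power),
    F16 = experimental$wavelength[which.max(experimental$power)],
    F17 = simulated$wavelength[which.max(simulated$power)],
    F18 = NA_integer_
  )
  if (!all(is.finite(unlist(row[paste0("F", 1:17)])))) {
    stop("feature extraction produced non-finite values; row rejected",
         call. = FALSE)
  }
  row
}

#' Feature table for a collection of spectra
#'
#' Applies [extract_features()] to every spectrum, taking each spectrum's
#' refractive index from its metadata (`operating_index`), and prepends the
#' provenance columns `label_index`, `operating_index`, `replicate`, `seed`
#' and `source` where available.
#'
#' @param spectra List of [interferogram()] objects (e.g. from
#'   [generate_study_design()] or [read_study_design()]).
#' @param base_model The shared [cavity_model()]; per spectrum its
#'   refractive index is replaced by the spectrum's `operating_index`
#'   metadata when present.
#' @param threshold Threshold fraction passed to [extract_features()].
#' @return A data frame with provenance columns followed by `F1`..`F18`.
#' @export
extract_feature_table <- function(spectra, base_model, threshold = 0.05) {
  rows <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    model_i <- base_model
    if (!is.null(sp$metadata$operating_index)) {
      model_i$refractive_index <- sp$metadata$operating_index
    }
    feats <- extract_features(sp, model_i, threshold)
    meta <- sp$metadata
    prov <- data.frame(
      source = if (is.null(meta$source)) sprintf("spectrum_%03d", i) else meta$source,
      label_index = if (is.null(meta$label_index)) NA_real_ else meta$label_index,
      operating_index = if (is.null(meta$operating_index)) NA_real_ else meta$operating_index,
      replicate = if (is.null(meta$replicate)) NA_integer_ else meta$replicate,
      seed = if (is.null(meta$seed)) NA_integer_ else meta$seed
    )
    cbind(prov, feats)
  })
  do.call(rbind, rows)
}

feature_columns <- function() paste0("F", 1:18)
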