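#' Fabry-Perot cavity model
#'
#' Describes the optical configuration that generates an interferogram: a
#' two-beam Fabry-Perot cavity of geometric length `cavity_length` filled
#' with a medium of refractive index `refractive_index`, illuminated by a
#' broadband source with a Gaussian envelope centred at `center_wavelength`
#' whose full width at half maximum is `spectral_width`. The recorded fringe
#' pattern has contrast `visibility`; `noise_sd` is the standard deviation of
#' additive amplitude noise relative to the peak power.
#'
#' Lengths are handled in nanometres internally; `cavity_length` is given in
#' micrometres as cavity geometry is usually quoted and converted at this
#' boundary.
#'
#' @param refractive_index Refractive index of the cavity medium at the
#'   operating wavelength (>= 1).
#' @param cavity_length Geometric cavity length in micrometres (> 0).
#' @param center_wavelength Source centre wavelength in nm.
#' @param spectral_width Source envelope FWHM in nm.
#' @param visibility Fringe contrast in `[0, 1]`.
#' @param noise_sd Additive noise standard deviation relative to peak power
#'   (>= 0).
#' @param wavelength_grid Strictly increasing wavelengths (nm) on which
#'   spectra are sampled; must cover `center_wavelength`.
#' @return An object of class `cavity_model`.
#' @examples
#' m <- cavity_model(refractive_index = 1.30)
#' theoretical_interferogram(m)
#' @export
cavity_model <- function(refractive_index = 1.30,
                         cavity_length = 280,
                         center_wavelength = 1550,
                         spectral_width = 35,
                         visibility = 0.9956,
                         noise_sd = 0.01,
                         wavelength_grid = default_wavelength_grid()) {
  stopifnot_scalar(refractive_index, "refractive_index")
  stopifnot_scalar(cavity_length, "cavity_length")
  stopifnot_scalar(center_wavelength, "center_wavelength")
  stopifnot_scalar(spectral_width, "spectral_width")
  stopifnot_scalar(visibility, "visibility")
  stopifnot_scalar(noise_sd, "noise_sd")
  if (refractive_index < 1) {
    stop("`refractive_index` must be >= 1", call. = FALSE)
  }
  if (cavity_length <= 0) stop("`cavity_length` must be > 0", call. = FALSE)
  if (spectral_width <= 0) stop("`spectral_width` must be > 0", call. = FALSE)
  if (visibility < 0 || visibility > 1) {
    stop("`visibility` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(wavelength_grid) < 2L || any(diff(wavelength_grid) <= 0)) {
    stop("`wavelength_grid` must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (center_wavelength < wavelength_grid[1L] ||
      center_wavelength > wavelength_grid[length(wavelength_grid)]) {
    stop("`wavelength_grid` must cover `center_wavelength`", call. = FALSE)
  }
  structure(
    list(
      refractive_index = refractive_index,
      cavity_length = cavity_length,
      center_wavelength = center_wavelength,
      spectral_width = spectral_width,
      visibility = visibility,
      noise_sd = noise_sd,
      wavelength_grid = as.numeric(wavelength_grid)
    ),
    class = "cavity_model"
  )
}

#' Default wavelength sampling grid
#'
#' 2001 uniform points over 1530-1570 nm, covering a 1550 nm source with
#' +/- 20 nm of usable bandwidth.
#'
#' @param from,to Window bounds in nm.
#' @param n Number of grid points.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_wavelength_grid <- function(from = 1530, to = 1570, n = 2001L) {
  seq(from, to, length.out = n)
}

#' @export
print.cavity_model <- function(x, ...) {
  cat("Fabry-Perot cavity model\n")
  cat(sprintf("  n = %.4f, l = %g um, source %g nm (FWHM %g nm)\n",
              x$refractive_index, x$cavity_length, x$center_wavelength,
              x$spectral_width))
  cat(sprintf("  visibility = %.4f, noise sd = %g, grid %g-%g nm (%d pts)\n",
              x$visibility, x$noise_sd, x$wavelength_grid[1L],
              x$wavelength_grid[length(x$wavelength_grid)],
              length(x$wavelength_grid)))
  invisible(x)
}

#' Interferogram container
#'
#' A sampled optical spectrum: paired wavelength (nm) and optical power
#' sequences, plus free-form metadata (sample label, replicate, true
#' refractive index for synthetic spectra).
#'
#' @param wavelength Strictly increasing wavelengths in nm.
#' @param power Finite power values, same length as `wavelength`.
#' @param metadata Named list of provenance fields.
#' @return An object of class `interferogram`.
#' @export
interferogram <- function(wavelength, power, metadata = list()) {
  wavelength <- as.numeric(wavelength)
  power <- as.numeric(power)
  if (length(wavelength) != length(power)) {
    stop("`wavelength` and `power` must have equal length", call. = FALSE)
  }
  if (length(wavelength) == 0L) stop("empty spectrum", call. = FALSE)
  if (any(diff(wavelength) <= 0)) {
    stop("`wavelength` must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(power))) stop("`power` must be finite", call. = FALSE)
  structure(
    list(wavelength = wavelength, power = power, metadata = metadata),
    class = "interferogram"
  )
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("Interferogram: %d samples, %g-%g nm, power [%.4g, %.4g]\n",
              length(x$wavelength), x$wavelength[1L],
              x$wavelength[length(x$wavelength)],
              min(x$power), max(x$power)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, format, ""),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.interferogram <- function(x, ...) {
  plot(x$wavelength, x$power, type = "l",
       xlab = "Wavelength [nm]", ylab = "Optical power [a.u.]", ...)
  invisible(x)
}

# Two-beam interference phase 4*pi*n*l/lambda; l in um, lambda in nm.
cavity_phase <- function(n, cavity_length_um, wavelength_nm) {
  4 * pi * n * (cavity_length_um * 1000) / wavelength_nm
}

#' Theoretical two-beam interferogram
#'
#' The noiseless reference fringe pattern `T = 1 + cos(4 pi n l / lambda)`
#' of a two-beam Fabry-Perot cavity, sampled on the model's wavelength grid.
#' Values lie in `[0, 2]`; maxima sit at wavelengths `2 n l / m` for integer
#' fringe order `m`.
#'
#' @param model A [cavity_model()].
#' @return An [interferogram()] with metadata recording `n` and `l`.
#' @export
theoretical_interferogram <- function(model) {
  if (!inherits(model, "cavity_model")) {
    stop("`model` must be a cavity_model", call. = FALSE)
  }
  phase <- cavity_phase(model$refractive_index, model$cavity_length,
                        model$wavelength_grid)
  interferogram(
    wavelength = model$wavelength_grid,
    power = 1 + cos(phase),
    metadata = list(kind = "theoretical",
                    refractive_index = model$refractive_index,
                    cavity_length = model$cavity_length)
  )
}

#' Synthetic measured interferogram
#'
#' Emulates one optical-spectrum-analyzer acquisition:
#' `power = envelope(lambda) * (1 + V cos(4 pi n l / lambda)) + noise`,
#' where the envelope is a Gaussian source spectrum (FWHM =
#' `spectral_width`), `V` is the fringe visibility and the additive noise is
#' zero-mean Gaussian with standard deviation `noise_sd` relative to the peak
#' power. Identical `(model, seed)` pairs give bitwise-identical spectra.
#'
#' @param model A [cavity_model()].
#' @param seed Integer seed for the noise realisation.
#' @param flat_envelope If `TRUE`, replace the Gaussian source envelope by a
#'   constant 1 (useful for analytic checks).
#' @return An [interferogram()].
#' @export
synthetic_interferogram <- function(model, seed, flat_envelope = FALSE) {
  if (!inherits(model, "cavity_model")) {
    stop("`model` must be a cavity_model", call. = FALSE)
  }
  lambda <- model$wavelength_grid
  envelope <- if (flat_envelope) {
    rep(1, length(lambda))
  } else {
    exp(-4 * log(2) * ((lambda - model$center_wavelength) /
                         model$spectral_width)^2)
  }
  phase <- cavity_phase(model$refractive_index, model$cavity_length, lambda)
  clean <- envelope * (1 + model$visibility * cos(phase))
  peak <- max(clean)
  noise <- if (model$noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(lambda), 0, model$noise_sd * peak))
  } else {
    numeric(length(lambda))
  }
  interferogram(
    wavelength = lambda,
    power = clean + noise,
    metadata = list(kind = "synthetic",
                    refractive_index = model$refractive_index,
                    cavity_length = model$cavity_length,
                    visibility = model$visibility,
                    noise_sd = model$noise_sd,
                    seed = seed)
  )
}

#' Certified refractive-index liquid panel
#'
#' The calibration design: a set of liquids, each identified by the label
#' refractive index printed on its datasheet (measured at 589.3 nm) and the
#' operating refractive index at the 1550 nm source wavelength, measured a
#' fixed number of replicate times. The default panel spans 1.30-1.50 in
#' 0.01 steps (21 liquids, 10 replicates each). Because the paper-level
#' datasheet dispersion values are not portable, the operating index defaults
#' to the label index; pass `operating_indices` to override per liquid.
#'
#' @param label_indices Label (589.3 nm) refractive indices.
#' @param operating_indices Operating (1550 nm) refractive indices, same
#'   length; defaults to `label_indices`.
#' @param replicates Spectra per liquid (>= 1).
#' @return An object of class `liquid_panel`.
#' @export
liquid_panel <- function(label_indices = seq(1.30, 1.50, by = 0.01),
                         operating_indices = label_indices,
                         replicates = 10L) {
  label_indices <- as.numeric(label_indices)
  operating_indices <- as.numeric(operating_indices)
  if (length(label_indices) == 0L) stop("empty panel", call. = FALSE)
  if (length(label_indices) != length(operating_indices)) {
    stop("label and operating indices must have equal length", call. = FALSE)
  }
  if (!all(is.finite(label_indices)) || !all(is.finite(operating_indices))) {
    stop("panel indices must be finite", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L) {
    stop("`replicates` must be a positive integer", call. = FALSE)
  }
  structure(
    list(label_indices = label_indices,
         operating_indices = operating_indices,
         replicates = replicates),
    class = "liquid_panel"
  )
}

#' @export
print.liquid_panel <- function(x, ...) {
  cat(sprintf("Liquid panel: %d liquids (%.2f-%.2f) x %d replicates\n",
              length(x$label_indices), min(x$label_indices),
              max(x$label_indices), x$replicates))
  invisible(x)
}

#' Generate the full synthetic study design
#'
#' Simulates the complete acquisition campaign: for every liquid in the panel
#' and every replicate, one synthetic interferogram from the base cavity
#' model with the liquid's operating refractive index substituted. Per-
#' spectrum noise seeds are derived deterministically from `seed`, so a
#' single master seed reproduces all spectra. The default panel yields
#' 21 x 10 = 210 spectra.
#'
#' @param panel A [liquid_panel()].
#' @param base_model A [cavity_model()] providing geometry, source, and noise
#'   settings shared by all acquisitions.
#' @param seed Master integer seed.
#' @return A list of [interferogram()] objects, each with metadata fields
#'   `label_index`, `operating_index`, `replicate`, `seed`.
#' @export
generate_study_design <- function(panel = liquid_panel(),
                                  base_model = cavity_model(),
                                  seed = 1L) {
  if (!inherits(panel, "liquid_panel")) {
    stop("`panel` must be a liquid_panel", call. = FALSE)
  }
  if (!inherits(base_model, "cavity_model")) {
    stop("`base_model` must be a cavity_model", call. = FALSE)
  }
  n_liquids <- length(panel$label_indices)
  n_total <- n_liquids * panel$replicates
  seeds <- derive_seeds(seed, n_total)
  spectra <- vector("list", n_total)
  idx <- 0L
  for (i in seq_len(n_liquids)) {
    model_i <- base_model
    model_i$refractive_index <- panel$operating_indices[i]
    for (r in seq_len(panel$replicates)) {
      idx <- idx + 1L
      sp <- synthetic_interferogram(model_i, seeds[idx])
      sp$metadata$label_index <- panel$label_indices[i]
      sp$metadata$operating_index <- panel$operating_indices[i]
      sp$metadata$replicate <- r
      spectra[[idx]] <- sp
    }
  }
  spectra
}
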