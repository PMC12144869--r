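# Seeded generators for synthetic HRMS peak lists, 1H NMR spectra and assay
# plates with known ground truth, so every analysis stage can be exercised
# without instrument data. Each generator takes a mandatory seed and is
# bit-reproducible for a given seed.

#' Synthetic HRMS peak list with planted ion envelopes
#'
#' Builds a centroided peak list as the union of the isotope envelopes of the
#' planted ion hypotheses (scaled to the requested species intensities), with
#' optional multiplicative intensity noise and uniform m/z jitter, plus decoy
#' peaks. Decoys are drawn uniform in m/z with log-uniform intensities below
#' the planted base peak, and are kept away from every planted peak by an
#' exclusion window of `3 * jitter_ppm`, floored at `min_exclusion_ppm` so the
#' generator remains adversarial-but-fair to a ppm-tolerance matcher even at
#' zero jitter.
#'
#' @param planted_ions List of `ion_hypothesis` objects ([enumerate_ions()]).
#' @param intensities Base-peak intensity per planted species (recycled).
#' @param n_decoys Number of decoy peaks.
#' @param jitter_ppm Half-width of the uniform m/z jitter, ppm.
#' @param intensity_noise Relative s.d. of multiplicative intensity noise.
#' @param seed Integer RNG seed (mandatory).
#' @param mz_range m/z window for decoys (default spans the planted envelopes
#'   with a 10% margin).
#' @param min_rel_intensity Planted isotopologue peaks below this % of their
#'   envelope base are not emitted (default 0.5).
#' @param min_exclusion_ppm Floor of the decoy exclusion window, ppm.
#' @return A list: `peaklist` ([peak_list()]) and `truth` (list with the
#'   planted formulas, charges, intensities, the seed and all settings).
#' @export
synth_ms <- function(planted_ions, intensities = 100, n_decoys = 0,
                     jitter_ppm = 0, intensity_noise = 0, seed,
                     mz_range = NULL, min_rel_intensity = 0.5,
                     min_exclusion_ppm = 20) {
  stopifnot(jitter_ppm >= 0, intensity_noise >= 0, !missing(seed))
  withr_seed <- .seed_scope(seed)
  on.exit(withr_seed())
  intensities <- rep_len(intensities, length(planted_ions))
  planted <- do.call(rbind, lapply(seq_along(planted_ions), function(i) {
    h <- planted_ions[[i]]
    pk <- h$pattern$peaks
    pk <- pk[pk$rel_intensity >= min_rel_intensity, , drop = FALSE]
    data.frame(mz = pk$mz,
               intensity = pk$rel_intensity / 100 * intensities[i],
               formula = h$formula, z = h$z_pred, stringsAsFactors = FALSE)
  }))
  mz <- planted$mz * (1 + stats::runif(nrow(planted), -jitter_ppm,
                                       jitter_ppm) * 1e-6)
  intensity <- planted$intensity *
    (1 + stats::rnorm(nrow(planted), 0, intensity_noise))
  intensity <- pmax(intensity, 0)
  if (is.null(mz_range)) {
    span <- range(planted$mz)
    pad <- 0.1 * diff(span) + 1
    mz_range <- c(max(span[1] - pad, 1), span[2] + pad)
  }
  if (n_decoys > 0) {
    excl_ppm <- max(3 * jitter_ppm, min_exclusion_ppm)
    decoy_mz <- numeric(0)
    tries <- 0L
    while (length(decoy_mz) < n_decoys) {
      tries <- tries + 1L
      if (tries > 200L * n_decoys) {
        stop("decoy placement impossible in the given m/z range", call. = FALSE)
      }
      cand <- stats::runif(1, mz_range[1], mz_range[2])
      if (all(abs(cand - planted$mz) > cand * excl_ppm * 1e-6)) {
        decoy_mz <- c(decoy_mz, cand)
      }
    }
    base_int <- max(planted$intensity)
    decoy_int <- exp(stats::runif(n_decoys, log(base_int * 1e-3),
                                  log(base_int * 0.99)))
    mz <- c(mz, decoy_mz)
    intensity <- c(intensity, decoy_int)
  }
  truth <- list(
    formulas = vapply(planted_ions, `[[`, "", "formula"),
    charges = vapply(planted_ions, function(h) h$z_pred, integer(1)),
    intensities = intensities, n_decoys = n_decoys,
    jitter_ppm = jitter_ppm, intensity_noise = intensity_noise, seed = seed
  )
  list(peaklist = peak_list(mz, intensity), truth = truth)
}

#' Synthetic 1D 1H NMR spectrum from planted Lorentzian peaks
#'
#' Sums Lorentzian lines with the requested integrals on a uniform ppm grid
#' and adds Gaussian baseline noise. The Lorentzian half-width at half-maximum
#' is `linewidth_hz / 2 / field_mhz` ppm.
#'
#' @param peaks_spec Data frame with columns `ppm` and `integral` (relative
#'   areas).
#' @param linewidth_hz Full width at half maximum, Hz (> 0).
#' @param noise_sd Gaussian baseline noise s.d., in amplitude units.
#' @param seed Integer RNG seed (mandatory).
#' @param field_mhz Spectrometer frequency, MHz (default 400).
#' @param ppm_range,resolution Grid window (default 0--12 ppm) and step
#'   (default 0.001 ppm).
#' @return A list: `spectrum` (data frame `ppm`, `amplitude`) and `truth`
#'   (the peak spec, linewidth, noise and seed).
#' @export
synth_nmr <- function(peaks_spec, linewidth_hz = 2, noise_sd = 0, seed,
                      field_mhz = 400, ppm_range = c(0, 12),
                      resolution = 0.001) {
  stopifnot(linewidth_hz > 0, noise_sd >= 0, !missing(seed),
            all(c("ppm", "integral") %in% names(peaks_spec)))
  if (any(peaks_spec$ppm < ppm_range[1] | peaks_spec$ppm > ppm_range[2])) {
    stop("planted peaks fall outside the ppm grid", call. = FALSE)
  }
  withr_seed <- .seed_scope(seed)
  on.exit(withr_seed())
  grid <- seq(ppm_range[1], ppm_range[2], by = resolution)
  hwhm <- linewidth_hz / 2 / field_mhz  # ppm
  amp <- rep(0, length(grid))
  for (i in seq_len(nrow(peaks_spec))) {
    x0 <- peaks_spec$ppm[i]
    A <- peaks_spec$integral[i]
    amp <- amp + A / pi * hwhm / ((grid - x0)^2 + hwhm^2)
  }
  if (noise_sd > 0) amp <- amp + stats::rnorm(length(grid), 0, noise_sd)
  list(spectrum = data.frame(ppm = grid, amplitude = amp),
       truth = list(peaks = peaks_spec, linewidth_hz = linewidth_hz,
                    noise_sd = noise_sd, field_mhz = field_mhz, seed = seed))
}

#' Synthetic host-guest assay plate with planted association constants
#'
#' Solves the 1:1 mass balance for the bound fraction of each planted Ka at
#' the given dispense design and emits the integrals the NMR readout would
#' give in slow exchange (`I_HG = f`, `I_H = 1 - f`, per-proton normalized),
#' with optional Gaussian integral noise.
#'
#' @param Ka_grid Data frame with columns `host`, `guest`, `timepoint`, `Ka`
#'   (planted, 1/M; 0 means no binding).
#' @param V_host,C_host,V_guest,C_guest Plate dispense design (defaults: the
#'   screen's 500 uL of 0.0008 M host + 75 uL of 0.0214 M guest).
#' @param integral_noise_sd Gaussian noise s.d. added to each integral.
#' @param seed Integer RNG seed (mandatory).
#' @return A list: `plate` (data frame ready for [analyze_plate()]) and
#'   `truth` (the planted grid plus the seed).
#' @export
synth_assay <- function(Ka_grid, V_host = 500, C_host = 8e-4,
                        V_guest = 75, C_guest = 0.0214,
                        integral_noise_sd = 0, seed) {
  stopifnot(all(c("host", "guest", "timepoint", "Ka") %in% names(Ka_grid)),
            all(Ka_grid$Ka >= 0), !missing(seed))
  withr_seed <- .seed_scope(seed)
  on.exit(withr_seed())
  mix <- plate_mix(V_host, C_host, V_guest, C_guest)
  f <- vapply(Ka_grid$Ka, bound_fraction_from_ka, 0,
              H_tot = mix$H_tot, G_tot = mix$G_tot)
  I_HG <- f
  I_H <- 1 - f
  if (integral_noise_sd > 0) {
    I_HG <- pmax(I_HG + stats::rnorm(length(f), 0, integral_noise_sd), 0)
    I_H <- pmax(I_H + stats::rnorm(length(f), 0, integral_noise_sd), 0)
  }
  plate <- data.frame(
    host = Ka_grid$host, guest = Ka_grid$guest,
    V_host = V_host, C_host = C_host, V_guest = V_guest, C_guest = C_guest,
    timepoint = Ka_grid$timepoint, I_H = I_H, I_HG = I_HG,
    stringsAsFactors = FALSE
  )
  list(plate = plate,
       truth = list(Ka_grid = Ka_grid, bound_fraction = f, seed = seed))
}

# set the RNG seed locally; returns a restore function for on.exit
.seed_scope <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
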