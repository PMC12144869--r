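# Enumeration of candidate assembly ions per reaction and matching against
# experimental HRMS peak lists with charge-state verification.
#
# Topology conventions: M_N L_N cages (tetrahedron M4L4, pseudo-icosahedron
# M12L12) and triple-stranded M2X3 helicates (X = tritopic ligand L and/or
# ditopic intermediate I), plus the free ligand and free intermediate, which
# show up protonated in ESI spectra.

.MOC_TOPOLOGIES <- c("M4L4", "M12L12", "M2L3", "M2IL2", "M2I2L", "M2I3",
                     "free_L", "free_I")

# mass difference between adjacent isotopologues (~ one extra neutron)
.ISOTOPE_SPACING <- 1.00335

#' Class of a topology label
#'
#' Groups topologies into the screen's target classes: `"MNLN"` for the
#' M4L4/M12L12 cages, `"M2X3"` for the helicates, `"free"` for uncomplexed
#' linkers.
#'
#' @param topology Character vector of topology labels.
#' @return Character vector of class labels.
#' @export
topology_class <- function(topology) {
  ifelse(topology %in% c("M4L4", "M12L12"), "MNLN",
         ifelse(topology %in% c("M2L3", "M2IL2", "M2I2L", "M2I3"), "M2X3",
                ifelse(topology %in% c("free_L", "free_I"), "free", "other")))
}

#' Enumerate screen reactions from precursor lists
#'
#' Full Cartesian product of triamines, aldehydes and metal salts; the screen
#' runs every combination under identical conditions.
#'
#' @param triamines,aldehydes,metal_salts Lists of [precursor] objects with the
#'   matching roles (each may be empty, giving an empty reaction list).
#' @return A data frame with one row per reaction: `reaction_id`, `triamine`,
#'   `aldehyde`, `metal_salt`, `counterion`.
#' @examples
#' p <- example_precursors()
#' rx <- enumerate_reactions(p[c("A", "B")], p[c("1", "2", "3", "4")],
#'                           p[c("ZnNTf2", "ZnOTf", "ZnBF4")])
#' nrow(rx)  # 24
#' @export
enumerate_reactions <- function(triamines, aldehydes, metal_salts) {
  check_role <- function(lst, role) {
    ok <- vapply(lst, function(p) inherits(p, "precursor") && p$role == role,
                 logical(1))
    if (!all(ok)) stop("expected only precursors with role ", role,
                       call. = FALSE)
  }
  check_role(triamines, "triamine")
  check_role(aldehydes, "aldehyde")
  check_role(metal_salts, "metal_salt")
  if (!length(triamines) || !length(aldehydes) || !length(metal_salts)) {
    return(data.frame(reaction_id = character(), triamine = character(),
                      aldehyde = character(), metal_salt = character(),
                      counterion = character(), stringsAsFactors = FALSE))
  }
  grid <- expand.grid(
    metal_salt = vapply(metal_salts, `[[`, "", "id"),
    aldehyde = vapply(aldehydes, `[[`, "", "id"),
    triamine = vapply(triamines, `[[`, "", "id"),
    stringsAsFactors = FALSE
  )[, c("triamine", "aldehyde", "metal_salt")]
  counterion <- vapply(metal_salts, function(p) p$counterion_id, "")
  names(counterion) <- vapply(metal_salts, `[[`, "", "id")
  data.frame(
    reaction_id = sprintf("%s%s/%s", grid$triamine, grid$aldehyde,
                          grid$metal_salt),
    grid,
    counterion = unname(counterion[grid$metal_salt]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Candidate assemblies for one reaction
#'
#' Builds one assembly species per topology from the reaction's precursors:
#' compositions are `m` metal ions plus the linker multiset, with total cation
#' charge `2m` for a divalent metal. The ditopic intermediate I is the
#' two-fold condensation product (one free amine remaining); the tritopic
#' ligand L is the full three-fold condensation.
#'
#' @param triamine,aldehyde,metal [precursor] objects (`metal` may be a
#'   metal_salt precursor; only its ion composition is used).
#' @param topologies Subset of supported topologies (default: all eight).
#' @return A list of `assembly_species` objects (fields `topology`, `n_metal`,
#'   `linkers`, `composition`, `total_cation_charge`, `label`).
#' @examples
#' p <- example_precursors()
#' sp <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2)
#' length(sp)  # 8
#' @export
candidate_assemblies <- function(triamine, aldehyde, metal,
                                 topologies = .MOC_TOPOLOGIES) {
  stopifnot(all(topologies %in% .MOC_TOPOLOGIES))
  L <- condense(triamine, aldehyde, triamine$site_count)
  I <- condense(triamine, aldehyde, triamine$site_count - 1L)
  m_comp <- metal$composition
  m_charge <- metal$charge
  build <- function(topology) {
    spec <- switch(topology,
      M4L4   = list(m = 4L,  L = 4L,  I = 0L),
      M12L12 = list(m = 12L, L = 12L, I = 0L),
      M2L3   = list(m = 2L,  L = 3L,  I = 0L),
      M2IL2  = list(m = 2L,  L = 2L,  I = 1L),
      M2I2L  = list(m = 2L,  L = 1L,  I = 2L),
      M2I3   = list(m = 2L,  L = 0L,  I = 3L),
      free_L = list(m = 0L,  L = 1L,  I = 0L),
      free_I = list(m = 0L,  L = 0L,  I = 1L)
    )
    comp <- spec$m * m_comp + spec$L * L$composition + spec$I * I$composition
    linkers <- c(rep(list(L), spec$L), rep(list(I), spec$I))
    structure(
      list(topology = topology, n_metal = spec$m, linkers = linkers,
           composition = comp,
           total_cation_charge = spec$m * m_charge,
           label = sprintf("%s[%s]", topology, L$label)),
      class = "assembly_species"
    )
  }
  lapply(topologies, build)
}

#' @export
print.assembly_species <- function(x, ...) {
  cat(sprintf("<assembly %s> %s charge %+d\n", x$label,
              render_formula(x$composition), x$total_cation_charge))
  invisible(x)
}

#' Enumerate observable ions for an assembly species
#'
#' For a metal-containing species with total cation charge `2m`, ESI produces a
#' counterion-retention ladder `[M_m L_n . (anion)_k]^(2m-k)+` for
#' `k = 0 .. 2m-1` (the neutral `k = 2m` ion is unobservable). For the free
#' ligand and intermediate, protonated ions `[X + pH]^p+` are generated up to
#' `max_protonation`. Hypotheses are filtered to those whose predicted
#' base-peak m/z falls in `mz_range`.
#'
#' @param species An `assembly_species` from [candidate_assemblies()].
#' @param counterion A [precursor] with role counterion (charge -1).
#' @param mz_range Length-2 numeric, the instrument m/z window (default
#'   `c(0, Inf)`, no filtering).
#' @param max_protonation Highest proton count for metal-free species
#'   (default 1, i.e. `[L+H]+` only).
#' @param prune,resolution Passed to [isotope_pattern()].
#' @return A list of `ion_hypothesis` objects: fields `species`,
#'   `k_counterions`, `z_pred`, `protonation`, `composition`, `formula`,
#'   `pattern`.
#' @export
enumerate_ions <- function(species, counterion, mz_range = c(0, Inf),
                           max_protonation = 1L, prune = 1e-4,
                           resolution = 0.01) {
  stopifnot(inherits(species, "assembly_species"))
  hyps <- list()
  if (species$n_metal > 0L) {
    if (counterion$charge != -1L) {
      stop("counterion must carry charge -1", call. = FALSE)
    }
    q <- species$total_cation_charge
    for (k in 0:(q - 1L)) {
      comp <- species$composition + k * counterion$composition
      hyps[[length(hyps) + 1L]] <- list(
        species = species, k_counterions = k, protonation = 0L,
        z_pred = q - k, composition = comp
      )
    }
  } else {
    for (p in seq_len(max_protonation)) {
      comp <- species$composition + composition(H = p)
      hyps[[length(hyps) + 1L]] <- list(
        species = species, k_counterions = 0L, protonation = p,
        z_pred = p, composition = comp
      )
    }
  }
  hyps <- lapply(hyps, function(h) {
    h$formula <- render_formula(h$composition)
    h$pattern <- isotope_pattern(h$composition, z = h$z_pred,
                                 prune = prune, resolution = resolution)
    h$base_mz <- base_peak_mz(h$pattern)
    class(h) <- "ion_hypothesis"
    h
  })
  keep <- vapply(hyps, function(h)
    h$base_mz >= mz_range[1] && h$base_mz <= mz_range[2], logical(1))
  hyps[keep]
}

#' @export
print.ion_hypothesis <- function(x, ...) {
  cat(sprintf("<ion> %s k=%d z=%+d base m/z %.4f (%s)\n", x$formula,
              x$k_counterions, x$z_pred, x$base_mz, x$species$label))
  invisible(x)
}

#' Read an HRMS peak list from CSV
#'
#' @param path CSV with columns `mz`, `intensity` (centroided data).
#' @return A `peak_list`: data frame sorted ascending in `mz`, with attribute
#'   `base_peak_intensity`.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  peak_list(df$mz, df$intensity)
}

#' Construct a peak list
#'
#' @param mz,intensity Numeric vectors of equal length; intensities must be
#'   non-negative.
#' @return A `peak_list` data frame (columns `mz`, `intensity`, ascending in
#'   `mz`) with attribute `base_peak_intensity`.
#' @export
peak_list <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  out <- data.frame(mz = mz[o], intensity = intensity[o])
  attr(out, "base_peak_intensity") <- if (nrow(out)) max(out$intensity) else 0
  class(out) <- c("peak_list", "data.frame")
  out
}

# index of nearest experimental peak within tol_ppm, or NA
.match_peak <- function(mz_pred, peaks_mz, tol_ppm) {
  if (!length(peaks_mz)) return(NA_integer_)
  i <- findInterval(mz_pred, peaks_mz)
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), length(peaks_mz)))
  d <- abs(peaks_mz[cand] - mz_pred)
  best <- cand[which.min(d)]
  if (min(d) <= mz_pred * tol_ppm * 1e-6) best else NA_integer_
}

#' Assign a charge state from matched isotopologue peak spacing
#'
#' The observed charge is `round(1.00335 / median adjacent spacing)`; if the
#' spacings are irregular (any deviating from the median by more than
#' `max_dev_frac`) or fewer than two peaks are supplied, the charge is
#' unassignable and `NA` is returned.
#'
#' @param mz Numeric vector of matched isotopologue m/z values (one envelope).
#' @param max_dev_frac Maximum tolerated deviation of any adjacent spacing from
#'   the median spacing, as a fraction of the median (default 0.2).
#' @return Integer charge, or `NA_integer_` if unassignable.
#' @examples
#' assign_charge(c(500.0, 500.5017, 501.0034))  # 2
#' @export
assign_charge <- function(mz, max_dev_frac = 0.2) {
  mz <- sort(mz)
  if (length(mz) < 2L) return(NA_integer_)
  sp <- diff(mz)
  med <- stats::median(sp)
  if (med <= 0) return(NA_integer_)
  if (max(abs(sp - med)) > max_dev_frac * med) return(NA_integer_)
  as.integer(round(.ISOTOPE_SPACING / med))
}

#' Match ion hypotheses against an experimental peak list
#'
#' A hypothesis matches when at least `min_isotope_peaks` of its predicted
#' isotopologue peaks each find an experimental peak within `tol_ppm`. Each
#' matched hypothesis yields one record built from its most intense matched
#' peak, with the observed charge assigned from the m/z splitting of the
#' matched peaks and compared with the predicted charge.
#'
#' @param peaklist A [peak_list()].
#' @param hypotheses List of `ion_hypothesis` objects from [enumerate_ions()].
#' @param tol_ppm Match tolerance in ppm (default 5).
#' @param min_isotope_peaks Minimum matched isotopologue peaks (default 3).
#' @param min_rel_intensity Predicted peaks below this relative intensity (%
#'   of envelope base peak) are not required to match (default 1).
#' @return A data frame of match records with the result columns `formula`,
#'   `found_mz`, `found_intensity`, `predicted_mz`, `predicted_intensity`,
#'   `predicted_charge`, plus `observed_charge`, `charge_consistent`,
#'   `topology`, `n_matched_peaks`. Zero rows when nothing matches.
#' @export
match_spectrum <- function(peaklist, hypotheses, tol_ppm = 5,
                           min_isotope_peaks = 3L, min_rel_intensity = 1) {
  stopifnot(tol_ppm > 0, nrow(peaklist) > 0)
  rows <- lapply(hypotheses, function(h) {
    pk <- h$pattern$peaks
    pk <- pk[pk$rel_intensity >= min_rel_intensity, , drop = FALSE]
    idx <- vapply(pk$mz, .match_peak, integer(1),
                  peaks_mz = peaklist$mz, tol_ppm = tol_ppm)
    hit <- !is.na(idx)
    if (sum(hit) < min_isotope_peaks) return(NULL)
    matched_pred <- pk[hit, , drop = FALSE]
    matched_exp <- peaklist[idx[hit], , drop = FALSE]
    best <- which.max(matched_exp$intensity)
    z_obs <- assign_charge(matched_exp$mz)
    data.frame(
      formula = h$formula,
      found_mz = matched_exp$mz[best],
      found_intensity = matched_exp$intensity[best],
      predicted_mz = matched_pred$mz[best],
      predicted_intensity = matched_pred$rel_intensity[best],
      predicted_charge = h$z_pred,
      observed_charge = z_obs,
      charge_consistent = !is.na(z_obs) && z_obs == h$z_pred,
      topology = h$species$topology,
      n_matched_peaks = sum(hit),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(
      formula = character(), found_mz = numeric(), found_intensity = numeric(),
      predicted_mz = numeric(), predicted_intensity = numeric(),
      predicted_charge = integer(), observed_charge = integer(),
      charge_consistent = logical(), topology = character(),
      n_matched_peaks = integer(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$formula, out$predicted_charge), , drop = FALSE]
}

#' Keep only charge-consistent match records
#'
#' Retains records whose observed charge (from isotopologue spacing) equals the
#' predicted charge, ordered by formula then predicted charge — the filtering
#' step that turns raw envelope matches into the screen's speciation table.
#'
#' @param records Data frame from [match_spectrum()].
#' @return The filtered, reordered data frame.
#' @export
filter_charge_consistent <- function(records) {
  out <- records[which(records$charge_consistent), , drop = FALSE]
  out <- out[order(out$formula, out$predicted_charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a reaction's MS outcome per topology class
#'
#' Each target class (`MNLN`, `M2X3`, `free`) is `"major"` if any of its
#' matched ions reaches `major_fraction` of the spectrum base peak, `"minor"`
#' if matched below that, `"absent"` if unmatched.
#'
#' @param records Charge-filtered match records ([filter_charge_consistent()]).
#' @param peaklist The [peak_list()] that was searched (for its base peak).
#' @param major_fraction Fraction of base-peak intensity separating major from
#'   minor (default 0.5).
#' @return Named character vector over classes `MNLN`, `M2X3`, `free`.
#' @export
classify_reaction_ms <- function(records, peaklist, major_fraction = 0.5) {
  base <- attr(peaklist, "base_peak_intensity")
  if (is.null(base) || !length(base) || base <= 0) {
    stop("empty peak list", call. = FALSE)
  }
  classes <- c("MNLN", "M2X3", "free")
  status <- stats::setNames(rep("absent", length(classes)), classes)
  if (nrow(records)) {
    cls <- topology_class(records$topology)
    for (cl in classes) {
      ints <- records$found_intensity[cls == cl]
      if (!length(ints)) next
      status[cl] <- if (max(ints) >= major_fraction * base) "major" else "minor"
    }
  }
  status
}

#' Write match records as the screen's HRMS results CSV
#'
#' Emits the six result fields (formula, found m/z, found intensity, predicted
#' m/z, predicted intensity, predicted charge).
#'
#' @param records Data frame from [match_spectrum()] /
#'   [filter_charge_consistent()].
#' @param path Output CSV path.
#' @export
write_match_csv <- function(records, path) {
  cols <- c("formula", "found_mz", "found_intensity", "predicted_mz",
            "predicted_intensity", "predicted_charge")
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
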