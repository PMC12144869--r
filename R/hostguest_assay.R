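# Plate-based single-point NMR host-guest assay: dilution arithmetic, slow
# exchange bound fraction, 1:1 association constant, affinity classes, and the
# host x guest heatmap table.

#' Mixed concentrations and guest equivalents for an assay well
#'
#' @param V_host,V_guest Dispensed volumes, uL.
#' @param C_host,C_guest Stock concentrations, mol/L.
#' @return A list: `H_tot`, `G_tot` (dilution-corrected totals, mol/L) and
#'   `equivalents` (moles guest per mole host).
#' @examples
#' plate_mix(V_host = 500, C_host = 8e-4, V_guest = 75, C_guest = 0.0214)
#' @export
plate_mix <- function(V_host, C_host, V_guest, C_guest) {
  if (any(c(V_host, C_host, V_guest, C_guest) <= 0)) {
    stop("volumes and concentrations must be positive", call. = FALSE)
  }
  V <- V_host + V_guest
  list(H_tot = C_host * V_host / V,
       G_tot = C_guest * V_guest / V,
       equivalents = (C_guest * V_guest) / (C_host * V_host))
}

#' Affinity class from an association constant
#'
#' Operationalizes "much stronger / comparable / much weaker than K_ref" as
#' decade cutoffs around the reference (default 10^3 1/M, the assay's design
#' point): strong at or above `10 * K_ref`, weak at or below `K_ref / 10`,
#' intermediate between, none at exactly zero.
#'
#' @param Ka Association constant, 1/M (>= 0; `Inf` allowed, classed strong).
#' @param K_ref Reference constant, 1/M.
#' @return One of `"none"`, `"weak"`, `"intermediate"`, `"strong"`.
#' @export
classify_affinity <- function(Ka, K_ref = 1e3) {
  stopifnot(Ka >= 0, K_ref > 0)
  if (Ka == 0) return("none")
  if (Ka >= 10 * K_ref) return("strong")
  if (Ka <= K_ref / 10) return("weak")
  "intermediate"
}

#' Single-point association constant from slow-exchange integrals
#'
#' In slow exchange, free host and host-guest complex give separate resonance
#' sets; with per-proton-normalized integrals `I_H` (free host) and `I_HG`
#' (complex), the bound fraction is `f = I_HG / (I_H + I_HG)`. Assuming a
#' single guest per host (1:1):
#' `[HG] = f * H_tot`, `[H] = (1 - f) * H_tot`, `[G]free = G_tot - [HG]`,
#' and `Ka = [HG] / ([H] * [G]free)`.
#'
#' @param I_H,I_HG Per-proton-normalized integrals, >= 0, not both zero.
#' @param H_tot,G_tot Total (mixed) host and guest concentrations, mol/L.
#' @param K_ref Passed to [classify_affinity()].
#' @return A list: `bound_fraction`, `HG_conc`, `Hfree_conc`, `Gfree_conc`,
#'   `Ka` (1/M; `Inf` when no free host remains), `affinity_class`,
#'   `feasible` (FALSE when f = 1 or the implied [HG] exceeds the available
#'   guest, which signals inconsistent integrals).
#' @examples
#' ka_single_point(I_H = 1, I_HG = 1, H_tot = 6.96e-4, G_tot = 2.79e-3)
#' @export
ka_single_point <- function(I_H, I_HG, H_tot, G_tot, K_ref = 1e3) {
  stopifnot(I_H >= 0, I_HG >= 0, H_tot > 0, G_tot >= 0)
  if (I_H + I_HG <= 0) stop("I_H + I_HG must be positive", call. = FALSE)
  f <- I_HG / (I_H + I_HG)
  HG <- f * H_tot
  Hfree <- (1 - f) * H_tot
  Gfree <- G_tot - HG
  if (f >= 1) {
    return(list(bound_fraction = f, HG_conc = HG, Hfree_conc = 0,
                Gfree_conc = Gfree, Ka = Inf, affinity_class = "strong",
                feasible = FALSE))
  }
  if (Gfree <= 0) {
    # more complex than guest delivered: integrals inconsistent with totals
    return(list(bound_fraction = f, HG_conc = HG, Hfree_conc = Hfree,
                Gfree_conc = Gfree, Ka = NA_real_,
                affinity_class = NA_character_, feasible = FALSE))
  }
  Ka <- HG / (Hfree * Gfree)
  list(bound_fraction = f, HG_conc = HG, Hfree_conc = Hfree,
       Gfree_conc = Gfree, Ka = Ka,
       affinity_class = classify_affinity(Ka, K_ref), feasible = TRUE)
}

#' Bound fraction implied by a known Ka (1:1 mass balance)
#'
#' Solves the quadratic mass balance
#' `Ka * x^2 - (Ka * (H + G) + 1) * x + Ka * H * G = 0` for the complex
#' concentration `x = [HG]` and returns `f = x / H_tot`. This is the forward
#' model the single-point assay inverts; it also drives the synthetic assay
#' generator.
#'
#' @param Ka Association constant, 1/M (>= 0).
#' @param H_tot,G_tot Total concentrations, mol/L.
#' @return Bound fraction in `[0, 1)`.
#' @export
bound_fraction_from_ka <- function(Ka, H_tot, G_tot) {
  stopifnot(Ka >= 0, H_tot > 0, G_tot >= 0)
  if (Ka == 0 || G_tot == 0) return(0)
  b <- Ka * (H_tot + G_tot) + 1
  x <- (b - sqrt(b^2 - 4 * Ka^2 * H_tot * G_tot)) / (2 * Ka)
  x / H_tot
}

#' Analyze a host-guest assay plate
#'
#' @param plate Data frame with columns `host`, `guest`, `V_host`, `C_host`,
#'   `V_guest`, `C_guest`, `timepoint`, `I_H`, `I_HG`.
#' @param K_ref Passed to [classify_affinity()].
#' @return The plate with added columns `H_tot`, `G_tot`, `equivalents`,
#'   `bound_fraction`, `Ka`, `affinity_class`, `feasible`.
#' @export
analyze_plate <- function(plate, K_ref = 1e3) {
  need <- c("host", "guest", "V_host", "C_host", "V_guest", "C_guest",
            "timepoint", "I_H", "I_HG")
  stopifnot(all(need %in% names(plate)))
  res <- lapply(seq_len(nrow(plate)), function(i) {
    w <- plate[i, ]
    mix <- plate_mix(w$V_host, w$C_host, w$V_guest, w$C_guest)
    ka <- ka_single_point(w$I_H, w$I_HG, mix$H_tot, mix$G_tot, K_ref = K_ref)
    data.frame(H_tot = mix$H_tot, G_tot = mix$G_tot,
               equivalents = mix$equivalents,
               bound_fraction = ka$bound_fraction, Ka = ka$Ka,
               affinity_class = ka$affinity_class, feasible = ka$feasible,
               stringsAsFactors = FALSE)
  })
  cbind(plate, do.call(rbind, res))
}

#' Host x guest heatmap table of association constants
#'
#' For each host-guest combination the largest Ka across timepoints is
#' reported (binding is often slower than the first measurement); cells with
#' no binding at any timepoint are `NA`.
#'
#' @param results Data frame with columns `host`, `guest`, `timepoint`, `Ka`
#'   (e.g. from [analyze_plate()]).
#' @return A hosts x guests numeric matrix.
#' @export
heatmap_table <- function(results) {
  stopifnot(all(c("host", "guest", "timepoint", "Ka") %in% names(results)))
  key <- paste(results$host, results$guest, results$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate well for the same (host, guest, timepoint)", call. = FALSE)
  }
  hosts <- unique(results$host)
  guests <- unique(results$guest)
  m <- matrix(NA_real_, length(hosts), length(guests),
              dimnames = list(hosts, guests))
  for (h in hosts) for (g in guests) {
    ka <- results$Ka[results$host == h & results$guest == g]
    ka <- ka[!is.na(ka)]
    if (length(ka) && max(ka) > 0) m[h, g] <- max(ka)
  }
  m
}
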