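# Screen-level reporting: combine per-reaction MS and NMR triage into the
# outcome grid, replicate agreement, and liquid-handler transfer plans for the
# stoichiometry screen.

#' Combine MS and NMR triage into the screen outcome grid
#'
#' A reaction is a hit — the "fully red box" — when a target topology class
#' (MNLN or M2X3) is the major MS assembly and the NMR conversion category is
#' the best bin (default `"minor"`, i.e. <1% residual aldehyde).
#'
#' @param ms_results Data frame with columns `reaction_id`, `MNLN`, `M2X3`
#'   (statuses from [classify_reaction_ms()]).
#' @param nmr_results Data frame with columns `reaction_id`, `category`.
#' @param best_bin The NMR category that qualifies for a hit.
#' @return Data frame `reaction_id`, `MNLN`, `M2X3`, `nmr_category`, `hit`.
#' @export
combine_outcomes <- function(ms_results, nmr_results, best_bin = "minor") {
  stopifnot(all(c("reaction_id", "MNLN", "M2X3") %in% names(ms_results)),
            all(c("reaction_id", "category") %in% names(nmr_results)))
  if (!setequal(ms_results$reaction_id, nmr_results$reaction_id)) {
    stop("MS and NMR results cover different reaction ids", call. = FALSE)
  }
  nmr <- nmr_results[match(ms_results$reaction_id, nmr_results$reaction_id), ]
  out <- data.frame(
    reaction_id = ms_results$reaction_id,
    MNLN = ms_results$MNLN,
    M2X3 = ms_results$M2X3,
    nmr_category = nmr$category,
    stringsAsFactors = FALSE
  )
  out$hit <- (out$MNLN == "major" | out$M2X3 == "major") &
    out$nmr_category == best_bin
  out
}

#' Replicate agreement between two screen runs
#'
#' @param outcomes_run1,outcomes_run2 Outcome grids from [combine_outcomes()]
#'   over the same reactions (paired by `reaction_id`).
#' @param nmr_adjacent_ok If `TRUE`, NMR categories one bin apart still count
#'   as agreeing (`bin_order` gives the ordering). Default `FALSE`.
#' @param bin_order Ordered category labels, best first.
#' @return A list: `ms_agreement`, `nmr_agreement` (fractions), `n`,
#'   `ms_agree_n`, `nmr_agree_n`.
#' @export
replicate_agreement <- function(outcomes_run1, outcomes_run2,
                                nmr_adjacent_ok = FALSE,
                                bin_order = conversion_bins()$labels) {
  if (nrow(outcomes_run1) != nrow(outcomes_run2)) {
    stop("replicate runs differ in length", call. = FALSE)
  }
  o2 <- outcomes_run2[match(outcomes_run1$reaction_id,
                            outcomes_run2$reaction_id), ]
  if (anyNA(o2$reaction_id)) stop("reaction ids do not pair up", call. = FALSE)
  ms_agree <- outcomes_run1$MNLN == o2$MNLN & outcomes_run1$M2X3 == o2$M2X3
  b1 <- match(outcomes_run1$nmr_category, bin_order)
  b2 <- match(o2$nmr_category, bin_order)
  nmr_agree <- if (nmr_adjacent_ok) abs(b1 - b2) <= 1L else b1 == b2
  n <- nrow(outcomes_run1)
  list(ms_agreement = sum(ms_agree) / n,
       nmr_agreement = sum(nmr_agree) / n,
       n = n, ms_agree_n = sum(ms_agree), nmr_agree_n = sum(nmr_agree))
}

#' Liquid-handler transfer plan for one well
#'
#' Converts a triamine:aldehyde:metal equivalence (e.g. 4:12:4, or 6:12:n for
#' the helicate-targeting stoichiometry) into dispense volumes at the given
#' stock concentrations, topping up with solvent to the working volume. The
#' scale is set by the moles of triamine per well (`scale_basis`, the default
#' basis for "overall concentration").
#'
#' @param equivalents Numeric length-3, triamine:aldehyde:metal mole ratio
#'   (metal may be 0 for the no-metal control).
#' @param stock_concs Numeric length-3, stock concentrations mol/L in the same
#'   order.
#' @param V_total Working volume per well, uL.
#' @param scale_basis Moles of triamine per well (mol).
#' @return A list: `volumes` (named uL vector for triamine/aldehyde/metal),
#'   `solvent_topup` (uL), `equivalents`.
#' @examples
#' compute_transfers(c(4, 12, 4), c(0.05, 0.15, 0.05), V_total = 1000,
#'                   scale_basis = 9.2e-6)
#' @export
compute_transfers <- function(equivalents, stock_concs, V_total, scale_basis) {
  stopifnot(length(equivalents) == 3L, length(stock_concs) == 3L,
            all(stock_concs > 0), all(equivalents >= 0),
            equivalents[1] > 0, V_total > 0, scale_basis > 0)
  moles <- scale_basis * equivalents / equivalents[1]
  vol_uL <- moles / stock_concs * 1e6
  names(vol_uL) <- c("triamine", "aldehyde", "metal")
  used <- sum(vol_uL)
  if (used > V_total + 1e-9) {
    stop(sprintf("infeasible plan: stocks require %.1f uL > %.1f uL well volume",
                 used, V_total), call. = FALSE)
  }
  list(volumes = vol_uL, solvent_topup = V_total - used,
       equivalents = equivalents)
}

#' Write an outcome grid to CSV and JSON
#'
#' @param outcomes Grid from [combine_outcomes()].
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @export
write_outcome_grid <- function(outcomes, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(outcomes, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(outcomes, path_json, dataframe = "rows",
                         auto_unbox = TRUE)
  }
  invisible(outcomes)
}
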