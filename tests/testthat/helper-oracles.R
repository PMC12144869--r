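# Independent oracles and shared fixture builders.

# Brute-force isotopologue distribution: enumerate every per-atom isotope
# assignment (feasible only for a handful of atoms), then aggregate peaks
# closer than `resolution` into intensity-weighted centroids with a plain
# loop. Kept deliberately independent of the package's convolution engine.
bf_isotopologues <- function(counts, z, resolution = 0.01) {
  iso <- list(
    H  = cbind(c(1.00782503207, 2.01410177785), c(0.999885, 0.000115)),
    C  = cbind(c(12.0, 13.00335483507), c(0.9893, 0.0107)),
    N  = cbind(c(14.00307400443, 15.00010889888), c(0.99636, 0.00364)),
    O  = cbind(c(15.99491461957, 16.99913175650, 17.99915961286),
               c(0.99757, 0.00038, 0.00205)),
    F  = cbind(18.99840316273, 1),
    S  = cbind(c(31.97207117441, 32.97145890985, 33.96786700, 35.96708071),
               c(0.9499, 0.0075, 0.0425, 0.0001)),
    B  = cbind(c(10.01293695, 11.00930536), c(0.199, 0.801)),
    Cl = cbind(c(34.96885268, 36.96590259), c(0.7576, 0.2424)),
    Zn = cbind(c(63.92914201, 65.92603381, 66.92712775, 67.92484455,
                 69.9253192),
               c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061))
  )
  atoms <- rep(names(counts), counts)
  choices <- lapply(atoms, function(el) seq_len(nrow(iso[[el]])))
  grid <- do.call(expand.grid, choices)
  mass <- numeric(nrow(grid))
  prob <- rep(1, nrow(grid))
  for (j in seq_along(atoms)) {
    tab <- iso[[atoms[j]]]
    mass <- mass + tab[grid[[j]], 1]
    prob <- prob * tab[grid[[j]], 2]
  }
  o <- order(mass)
  mass <- mass[o]; prob <- prob[o]
  # aggregate: walk the sorted masses, new centroid when the gap >= resolution
  agg_m <- c(); agg_p <- c()
  cur_m <- mass[1] * prob[1]; cur_p <- prob[1]; last <- mass[1]
  for (i in seq_along(mass)[-1]) {
    if (mass[i] - last >= resolution) {
      agg_m <- c(agg_m, cur_m / cur_p); agg_p <- c(agg_p, cur_p)
      cur_m <- 0; cur_p <- 0
    }
    cur_m <- cur_m + mass[i] * prob[i]
    cur_p <- cur_p + prob[i]
    last <- mass[i]
  }
  agg_m <- c(agg_m, cur_m / cur_p); agg_p <- c(agg_p, cur_p)
  data.frame(mz = (agg_m - z * 0.000548579909) / z,
             rel_intensity = 100 * agg_p / max(agg_p))
}

# default screen precursor sets, used across fixtures
screen_sets <- function() {
  p <- example_precursors()
  list(triamines = p[c("A", "B")],
       aldehydes = p[c("1", "2", "3", "4")],
       salts = p[c("ZnNTf2", "ZnOTf", "ZnBF4")],
       all = p)
}

# ion ladder for the A1/Zn(NTf2)2 tetrahedron reaction, cached per session
a1_tetrahedron_ions <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- example_precursors()
      sp <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2,
                                 topologies = "M4L4")[[1]]
      cache <<- enumerate_ions(sp, p$NTf2)
    }
    cache
  }
})

# every ion hypothesis for the A1/Zn(NTf2)2 reaction (all 8 topologies)
a1_full_hypotheses <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- example_precursors()
      sp <- candidate_assemblies(p$A, p$`1`, p$ZnNTf2)
      cache <<- unlist(lapply(sp, enumerate_ions, counterion = p$NTf2),
                       recursive = FALSE)
    }
    cache
  }
})
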