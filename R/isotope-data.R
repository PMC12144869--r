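# Static isotope table (IUPAC/NIST atomic masses and representative natural
# abundances). Abundances are fractions summing to 1 per element; masses in Da.
# Covers the elements occurring in the screen's precursors (organic linkers,
# Zn(II), and the NTf2-/OTf-/BF4- counterion family) plus a few common extras.

.isotope_table <- local({
  tab <- list(
    H  = list(mass = c(1.00782503207, 2.01410177785),
              abundance = c(0.999885, 0.000115)),
    C  = list(mass = c(12.0, 13.00335483507),
              abundance = c(0.9893, 0.0107)),
    N  = list(mass = c(14.00307400443, 15.00010889888),
              abundance = c(0.99636, 0.00364)),
    O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
              abundance = c(0.99757, 0.00038, 0.00205)),
    F  = list(mass = 18.99840316273, abundance = 1),
    Na = list(mass = 22.98976928, abundance = 1),
    P  = list(mass = 30.97376199842, abundance = 1),
    S  = list(mass = c(31.97207117441, 32.97145890985, 33.96786700,
                       35.96708071),
              abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
    B  = list(mass = c(10.01293695, 11.00930536),
              abundance = c(0.199, 0.801)),
    Cl = list(mass = c(34.96885268, 36.96590259),
              abundance = c(0.7576, 0.2424)),
    Fe = list(mass = c(53.93960899, 55.93493633, 56.93539284, 57.93327443),
              abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
    Zn = list(mass = c(63.92914201, 65.92603381, 66.92712775, 67.92484455,
                       69.9253192),
              abundance = c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061)),
    Br = list(mass = c(78.9183376, 80.9162906),
              abundance = c(0.5069, 0.4931))
  )
  # order isotopes by descending abundance so [1] is the principal isotope
  lapply(tab, function(e) {
    o <- order(e$abundance, decreasing = TRUE)
    list(mass = e$mass[o], abundance = e$abundance[o])
  })
})

# CODATA electron mass in Da; subtracted once per positive charge when
# converting neutral-fragment mass to cation m/z.
.electron_mass <- 0.000548579909

#' Elements with embedded isotope data
#'
#' @return Character vector of element symbols for which isotope masses and
#'   natural abundances are available.
#' @export
isotope_elements <- function() names(.isotope_table)

.isotopes_for <- function(element) {
  iso <- .isotope_table[[element]]
  if (is.null(iso)) {
    stop("no isotope data for element '", element, "'", call. = FALSE)
  }
  iso
}
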