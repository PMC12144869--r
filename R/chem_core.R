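# Molecular-formula arithmetic for precursors, imine condensation products and
# assemblies. An elemental composition is a named integer vector (element
# symbol -> count) with class "composition"; all higher modules build on it.

#' Create an elemental composition
#'
#' An elemental composition maps element symbols to non-negative atom counts.
#' Compositions support `+`, `-` and scalar `*` elementwise; subtraction that
#' would drive any count negative is an error (the operation is chemically
#' impossible).
#'
#' @param ... Named counts, e.g. `composition(C = 6, H = 5, N = 1, O = 1)`, or
#'   a single named numeric vector.
#' @return An object of class `composition`.
#' @examples
#' composition(H = 2, O = 1)
#' composition(C = 42, H = 30, N = 6) + composition(Zn = 1)
#' @export
composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) {
    return(structure(integer(0), class = "composition"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("all counts must be named by element symbol", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative atom count", call. = FALSE)
  if (any(counts != round(counts))) stop("atom counts must be integers", call. = FALSE)
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0L]
  structure(as.integer(counts), names = names(counts), class = "composition")
}

.as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) return(composition(x))
  stop("cannot interpret as an elemental composition", call. = FALSE)
}

#' @export
Ops.composition <- function(e1, e2) {
  if (.Generic %in% c("+", "-")) {
    a <- .as_composition(e1)
    b <- .as_composition(e2)
    els <- union(names(a), names(b))
    av <- ifelse(els %in% names(a), a[els], 0L)
    bv <- ifelse(els %in% names(b), b[els], 0L)
    out <- if (.Generic == "+") av + bv else av - bv
    if (any(out < 0)) {
      stop("composition subtraction underflow: more atoms removed than present",
           call. = FALSE)
    }
    names(out) <- els
    return(composition(out))
  }
  if (.Generic == "*") {
    if (is.numeric(e1)) { k <- e1; c <- e2 } else { k <- e2; c <- e1 }
    if (length(k) != 1L || k < 0 || k != round(k)) {
      stop("composition can only be multiplied by a non-negative integer",
           call. = FALSE)
    }
    v <- unclass(c) * as.integer(k)
    return(composition(v))
  }
  if (.Generic == "==") {
    return(identical(composition(unclass(.as_composition(e1))),
                     composition(unclass(.as_composition(e2)))))
  }
  stop("operation '", .Generic, "' not defined for compositions", call. = FALSE)
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition>", render_formula(x), "\n")
  invisible(x)
}

#' @export
format.composition <- function(x, ...) render_formula(x)

#' Render a composition as a Hill-order formula string
#'
#' Hill order: carbon first, then hydrogen, then all other elements
#' alphabetically (if no carbon is present, all elements are alphabetical).
#'
#' @param comp A [composition].
#' @return A single formula string; `parse_formula()` round-trips it.
#' @examples
#' render_formula(composition(O = 1, H = 2))   # "H2O"
#' render_formula(composition(N = 6, C = 42, H = 30))
#' @export
render_formula <- function(comp) {
  comp <- .as_composition(comp)
  if (length(comp) == 0L) return("")
  els <- names(comp)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  n <- comp[ord]
  paste0(ord, ifelse(n == 1L, "", n), collapse = "")
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas with multi-letter element symbols and optional
#' counts, e.g. `"C2F6NO4S2"` for the triflimide anion.
#'
#' @param text A formula string.
#' @return A [composition].
#' @examples
#' parse_formula("H2O")
#' parse_formula("C6H5NO")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (text == "") return(composition())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt)) stop("malformed count in formula '", text, "'", call. = FALSE)
  known <- isotope_elements()
  bad <- setdiff(unique(els), known)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  composition(stats::setNames(cnt, els))
}

#' Elemental composition from a SMILES string
#'
#' Uses the Open Babel backend (via the ChemmineOB package) to perceive the
#' molecular formula, including implicit hydrogens. Formula strings remain the
#' canonical internal representation; this is a convenience entry point for
#' precursor libraries stored as SMILES.
#'
#' @param smiles A SMILES string.
#' @return A [composition].
#' @examples
#' \dontrun{
#' composition_from_smiles("O")                  # water -> H2O
#' composition_from_smiles("O=Cc1ccccn1")        # 2-formylpyridine -> C6H5NO
#' }
#' @export
composition_from_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("composition_from_smiles() requires the ChemmineOB package; ",
         "supply a formula string instead", call. = FALSE)
  }
  props <- tryCatch(
    ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  if (is.null(props) || !nzchar(props$formula[1])) {
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  # Open Babel renders ionic formulas with trailing charge signs; strip them
  parse_formula(gsub("[+-]+$", "", props$formula[1]))
}

#' Define a screen precursor
#'
#' Precursors are the building blocks of the subcomponent self-assembly screen:
#' tritopic triamines, monoaldehydes, metal salts and their counterions.
#'
#' @param id Short label (e.g. `"A"`, `"1"`, `"NTf2"`).
#' @param role One of `"triamine"`, `"aldehyde"`, `"metal_salt"`, `"counterion"`.
#' @param formula Formula string for the species (for a metal salt, the bare
#'   metal ion, e.g. `"Zn"`).
#' @param smiles Optional SMILES; used to derive the composition when `formula`
#'   is missing (requires ChemmineOB).
#' @param charge Integer formal charge: `+2` for a divalent metal ion, `-1` for
#'   a counterion anion, `0` for neutral organics.
#' @param site_count Number of reactive sites: 3 for a triamine (primary
#'   amines), 1 for an aldehyde.
#' @param counterion_id For `role = "metal_salt"`, the id of its counterion.
#' @return An object of class `precursor`.
#' @examples
#' precursor("A", "triamine", "C24H21N3")
#' precursor("1", "aldehyde", "C6H5NO")
#' precursor("NTf2", "counterion", "C2F6NO4S2", charge = -1)
#' @export
precursor <- function(id, role, formula = NULL, smiles = NULL,
                      charge = 0L, site_count = NULL, counterion_id = NULL) {
  role <- match.arg(role, c("triamine", "aldehyde", "metal_salt", "counterion"))
  if (is.null(formula) && is.null(smiles)) {
    stop("precursor needs a formula or a SMILES string", call. = FALSE)
  }
  comp <- if (!is.null(formula)) parse_formula(formula) else
    composition_from_smiles(smiles)
  if (is.null(site_count)) {
    site_count <- switch(role, triamine = 3L, aldehyde = 1L, 0L)
  }
  if (role == "triamine" && site_count < 3L) {
    stop("a triamine must declare at least 3 amine sites", call. = FALSE)
  }
  if (role == "aldehyde" && site_count != 1L) {
    stop("an aldehyde carries exactly one aldehyde site", call. = FALSE)
  }
  if (role == "metal_salt") {
    if (charge != 2L) stop("metal_salt precursors model a divalent metal ion",
                           call. = FALSE)
    if (is.null(counterion_id)) {
      stop("metal_salt needs counterion_id", call. = FALSE)
    }
  }
  if (role == "counterion" && charge != -1L) {
    stop("counterions are modelled as singly charged anions", call. = FALSE)
  }
  structure(
    list(id = as.character(id), role = role, composition = comp,
         smiles = smiles, charge = as.integer(charge),
         site_count = as.integer(site_count),
         counterion_id = counterion_id),
    class = "precursor"
  )
}

#' @export
print.precursor <- function(x, ...) {
  cat(sprintf("<precursor %s> %s %s charge %+d\n", x$id, x$role,
              render_formula(x$composition), x$charge))
  invisible(x)
}

#' Imine condensation between a triamine and a monoaldehyde
#'
#' Each condensation forms one imine bond and releases one water:
#' `composition = triamine + n * aldehyde - n * H2O`. With `n` equal to the
#' triamine's site count (3) the product is the tritopic ligand L; with
#' `n = site_count - 1` it is the ditopic intermediate I, which retains one
#' free amine.
#'
#' @param triamine,aldehyde [precursor] objects with the matching roles.
#' @param n Number of condensations, `0 <= n <= site_count`.
#' @return An object of class `linker` with fields `kind` (`"ligand_L"`,
#'   `"intermediate_I"` or `"partial"`), `composition`, `n_condensations` and
#'   the two precursor ids.
#' @examples
#' A <- precursor("A", "triamine", "C24H21N3")
#' ald <- precursor("1", "aldehyde", "C6H5NO")
#' condense(A, ald, 3)  # ligand A1, C42H30N6
#' @export
condense <- function(triamine, aldehyde, n) {
  stopifnot(inherits(triamine, "precursor"), inherits(aldehyde, "precursor"))
  if (triamine$role != "triamine" || aldehyde$role != "aldehyde") {
    stop("condense() expects a triamine and an aldehyde", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 0L || n > triamine$site_count) {
    stop("n must lie in 0..site_count", call. = FALSE)
  }
  water <- composition(H = 2, O = 1)
  comp <- triamine$composition + n * aldehyde$composition - n * water
  kind <- if (n == triamine$site_count) "ligand_L" else
    if (n == triamine$site_count - 1L) "intermediate_I" else "partial"
  structure(
    list(kind = kind, triamine_id = triamine$id, aldehyde_id = aldehyde$id,
         n_condensations = n, composition = comp,
         label = paste0(triamine$id, aldehyde$id)),
    class = "linker"
  )
}

#' @export
print.linker <- function(x, ...) {
  cat(sprintf("<linker %s> %s (%d condensations) %s\n", x$label, x$kind,
              x$n_condensations, render_formula(x$composition)))
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of count times the exact mass of the most abundant
#' isotope (e.g. 12C, 1H, 64Zn).
#'
#' @param comp A [composition] (or formula string).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C")        # 12 exactly
#' monoisotopic_mass("H2O")      # 18.0106
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_composition(comp)
  if (length(comp) == 0L) return(0)
  sum(vapply(names(comp), function(el) .isotopes_for(el)$mass[1], 0) * unclass(comp))
}

#' Average (abundance-weighted) mass of a composition
#'
#' @param comp A [composition] (or formula string).
#' @return Mass in Da.
#' @export
average_mass <- function(comp) {
  comp <- .as_composition(comp)
  if (length(comp) == 0L) return(0)
  sum(vapply(names(comp), function(el) {
    iso <- .isotopes_for(el)
    sum(iso$mass * iso$abundance)
  }, 0) * unclass(comp))
}

#' Built-in example precursor library
#'
#' The screen's demonstration library: two tritopic triamines (A:
#' 1,3,5-tris(4-aminophenyl)benzene; B: tris(4-aminophenyl)amine), four
#' 2-formylpyridine aldehydes (1 and its o/m/p ring-methylated isomers 2-4),
#' and three Zn(II) salts with triflimide, triflate and tetrafluoroborate
#' counterions.
#'
#' @return A named list of [precursor] objects.
#' @export
example_precursors <- function() {
  list(
    A    = precursor("A", "triamine", "C24H21N3",
                     smiles = "Nc1ccc(cc1)-c1cc(-c2ccc(N)cc2)cc(-c2ccc(N)cc2)c1"),
    B    = precursor("B", "triamine", "C18H18N4",
                     smiles = "Nc1ccc(cc1)N(c1ccc(N)cc1)c1ccc(N)cc1"),
    `1`  = precursor("1", "aldehyde", "C6H5NO", smiles = "O=Cc1ccccn1"),
    `2`  = precursor("2", "aldehyde", "C7H7NO", smiles = "Cc1cccc(C=O)n1"),
    `3`  = precursor("3", "aldehyde", "C7H7NO", smiles = "Cc1ccc(C=O)nc1"),
    `4`  = precursor("4", "aldehyde", "C7H7NO", smiles = "Cc1ccnc(C=O)c1"),
    NTf2 = precursor("NTf2", "counterion", "C2F6NO4S2", charge = -1),
    OTf  = precursor("OTf", "counterion", "CF3O3S", charge = -1),
    BF4  = precursor("BF4", "counterion", "BF4", charge = -1),
    ZnNTf2 = precursor("Zn(NTf2)2", "metal_salt", "Zn", charge = 2,
                       counterion_id = "NTf2"),
    ZnOTf  = precursor("Zn(OTf)2", "metal_salt", "Zn", charge = 2,
                       counterion_id = "OTf"),
    ZnBF4  = precursor("Zn(BF4)2", "metal_salt", "Zn", charge = 2,
                       counterion_id = "BF4")
  )
}

#' Read a precursor library from CSV or JSON
#'
#' Expected columns/fields: `id`, `role`, `formula` and/or `smiles`, `charge`,
#' `site_count` (optional), `counterion_id` (metal salts only).
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A named list of [precursor] objects.
#' @export
read_precursor_library <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "role")
  if (!all(need %in% names(df))) {
    stop("precursor library needs at least columns id, role", call. = FALSE)
  }
  get_chr <- function(row, col) {
    if (!col %in% names(df)) return(NULL)
    v <- row[[col]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NULL else
      as.character(v)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    precursor(
      id = row$id, role = row$role,
      formula = get_chr(row, "formula"), smiles = get_chr(row, "smiles"),
      charge = if ("charge" %in% names(df) && !is.na(row$charge))
        row$charge else 0L,
      site_count = if ("site_count" %in% names(df) && !is.na(row$site_count))
        row$site_count else NULL,
      counterion_id = get_chr(row, "counterion_id")
    )
  })
  stats::setNames(out, df$id)
}
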