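# Monoisotopic element masses in Da, most abundant isotope.
# Source: IUPAC/CODATA atomic mass evaluation (AME2020), truncated to
# the precision needed for 4-decimal m/z targets at m/z < 1000.
.element_masses <- c(
  H  = 1.00782503223,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.9984031627,
  Na = 22.9897692820,
  Si = 27.9769265347,
  P  = 30.9737619986,
  S  = 31.9720711744,
  Cl = 34.9688526820,
  K  = 38.9637064864,
  Se = 79.9165218,
  I  = 126.9044719
)

# Proton (not hydrogen-atom) mass: protonation adds H and removes an
# electron. Using the H atom mass instead misses the printed T3 target
# in the 4th decimal.
.proton_mass <- 1.007276466879
.electron_mass <- 0.000548579909

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formulas with one- or two-letter element symbols and
#' optional integer counts, e.g. `"C15H12I3NO4"`. Repeated symbols are
#' summed. Parenthesised groups are not supported.
#'
#' @param formula A single character string.
#' @return A named integer vector of class `element_counts`, one entry per
#'   element, every count >= 1, ordered in Hill convention (C, H, then
#'   alphabetical).
#' @examples
#' parse_formula("H2O")
#' parse_formula("C15H12I3NO4")  # T3
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) {
    return(structure(integer(0), class = "element_counts"))
  }
  pattern <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (paste(tokens, collapse = "") != formula) {
    bad <- sub(paste0("^(", paste(tokens, collapse = "|"), ")*"), "", formula)
    stop("malformed formula token near: '", substr(bad, 1, 8), "' in '",
         formula, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  unknown <- setdiff(syms, names(.element_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " in '", formula, "'", call. = FALSE)
  }
  if (any(counts < 1L | is.na(counts))) {
    stop("element counts must be positive integers in '", formula, "'",
         call. = FALSE)
  }
  out <- tapply(counts, syms, sum)
  out <- structure(as.integer(out), names = names(out))
  # Hill order: C first, then H, then the rest alphabetically
  ord <- c(intersect(c("C", "H"), names(out)),
           sort(setdiff(names(out), c("C", "H"))))
  structure(out[ord], class = "element_counts")
}

#' Canonical Hill-order formula string for element counts
#'
#' @param counts An `element_counts` vector from [parse_formula()].
#' @return A single string; `parse_formula(formula_string(x))` round-trips.
#' @export
formula_string <- function(counts) {
  if (!length(counts)) return("")
  paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Monoisotopic mass of an elemental composition
#'
#' Sums per-element monoisotopic masses times counts. Accurate to well
#' under 0.0005 Da for compositions within the embedded mass table.
#'
#' @param counts An `element_counts` vector, or a formula string which is
#'   parsed first.
#' @return Neutral monoisotopic mass in Da (0 for an empty composition).
#' @examples
#' monoisotopic_mass("H2O")          # 18.010565
#' monoisotopic_mass("C15H12I3NO4")  # T3, 650.7900
#' @export
monoisotopic_mass <- function(counts) {
  if (is.character(counts)) counts <- parse_formula(counts)
  if (!length(counts)) return(0)
  missing <- setdiff(names(counts), names(.element_masses))
  if (length(missing)) {
    stop("element(s) missing from mass table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(.element_masses[names(counts)] * as.numeric(counts))
}

#' Define an ionization adduct
#'
#' @param name Adduct label, e.g. `"[M+H]+"`.
#' @param delta Mass delta in Da added to the neutral mass.
#' @param charge Signed integer charge; must be non-zero.
#' @return An `adduct_spec` object.
#' @export
adduct_spec <- function(name, delta, charge) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(charge), length(charge) == 1L,
            charge == as.integer(charge), charge != 0)
  structure(list(name = name, delta = delta, charge = as.integer(charge)),
            class = "adduct_spec")
}

#' Built-in single-charge adducts
#'
#' Deltas are computed as the mass of the added/removed atoms corrected by
#' the electron mass, so `[M+H]+` adds exactly one proton (1.007276 Da).
#'
#' @return Named list of `adduct_spec` objects.
#' @export
builtin_adducts <- function() {
  list(
    "[M+H]+"   = adduct_spec("[M+H]+",   .proton_mass, 1L),
    "[M-H]-"   = adduct_spec("[M-H]-",  -.proton_mass, -1L),
    "[M+Na]+"  = adduct_spec("[M+Na]+",
                             .element_masses[["Na"]] - .electron_mass, 1L),
    "[M+K]+"   = adduct_spec("[M+K]+",
                             .element_masses[["K"]] - .electron_mass, 1L),
    "[M+Cl]-"  = adduct_spec("[M+Cl]-",
                             .element_masses[["Cl"]] + .electron_mass, -1L),
    "[M+NH4]+" = adduct_spec("[M+NH4]+",
                             monoisotopic_mass("NH4") - .electron_mass, 1L)
  )
}

.resolve_adduct <- function(adduct) {
  if (inherits(adduct, "adduct_spec")) return(adduct)
  stopifnot(is.character(adduct), length(adduct) == 1L)
  # tolerate the typographic minus found in some library exports
  key <- gsub("−", "-", adduct)
  reg <- builtin_adducts()
  if (!key %in% names(reg)) {
    stop("unknown adduct '", adduct, "'; known: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[key]]
}

#' m/z of an adduct ion from a neutral monoisotopic mass
#'
#' @param mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct An `adduct_spec` or the name of a built-in adduct.
#' @return `(mass + delta) / |charge|`.
#' @examples
#' adduct_mz(monoisotopic_mass("C15H12I3NO4"), "[M+H]+")  # 651.7973 (T3)
#' adduct_mz(monoisotopic_mass("C15H11I4NO4"), "[M+H]+")  # 777.6940 (T4)
#' @export
adduct_mz <- function(mass, adduct) {
  stopifnot(is.numeric(mass), length(mass) == 1L, is.finite(mass), mass > 0)
  a <- .resolve_adduct(adduct)
  (mass + a$delta) / abs(a$charge)
}
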