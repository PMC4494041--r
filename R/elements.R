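# Periodic-table bookkeeping shared by the parser (query-atom detection),
# the SMARTS abbreviation expander and the valence model.

# Elements 1..103 in atomic-number order.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr"
)

#' Atomic number for an element symbol
#'
#' @param symbol character vector of element symbols.
#' @return integer vector of atomic numbers (`NA` for non-elements).
#' @keywords internal
atomic_number <- function(symbol) {
  match(symbol, .element_symbols)
}

#' Is a molfile atom symbol a query placeholder?
#'
#' Anything that is not a periodic-table element symbol counts as a query
#' atom: the generic placeholders "A", "Q", "*", "X", "L" (atom lists),
#' R-group labels ("R", "R#", "R1", ...), lone pairs ("LP") and deuterium /
#' tritium shorthands are all non-elements.
#'
#' @param symbol character vector of atom-block symbols.
#' @return logical vector.
#' @keywords internal
is_query_symbol <- function(symbol) {
  is.na(atomic_number(symbol))
}
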