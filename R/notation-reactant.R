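#' Reactant notation
#'
#' The reactant is the additional compound involved in the reaction.
#' Hydrolases use water (`"H2O"`), LPMOs hydrogen peroxide (`"H2O2"`),
#' lyases none (`"none"` or the empty string).  Phosphorylases use
#' inorganic phosphate written `"aPi"` or `"ePi"` for its axial or
#' equatorial orientation with respect to the sugar ring.  For
#' transglycosylases and mutases the field holds the leaving part of the
#' donor molecule together with the anomer and linkage of the cleaved
#' bond: amylosucrase, which uses sucrose as donor, has reactant
#' `"a-1,2-bDFruf]"`.
#'
#' @param text A single reactant string, possibly empty.
#' @return `parse_reactant()` returns a `cazac_reactant` object;
#'   `render_reactant()` its canonical string (`"none"` for the absent
#'   reactant).
#' @examples
#' parse_reactant("aPi")
#' parse_reactant("a-1,4-aDGlcp")
#' @export
parse_reactant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  cache_get("reactant", text, parse_reactant_impl)
}

parse_reactant_impl <- function(text) {
  if (text == "" || text == "none") return(new_reactant("none"))
  if (text == "H2O") return(new_reactant("water"))
  if (text == "H2O2") return(new_reactant("peroxide"))
  if (grepl("^[ae]Pi$", text)) {
    return(new_reactant("phosphate", phosphate_orientation = substr(text, 1L, 1L)))
  }
  if (text == "Pi") {
    parse_error("phosphate requires an orientation prefix: \"aPi\" or \"ePi\"", text)
  }
  m <- regmatches(text, regexec("^([ae])-([0-9,/]+)-(.+)$", text))[[1]]
  if (length(m) == 0L) {
    parse_error(paste0("unrecognized reactant; expected H2O, H2O2, none, ",
                       "a/ePi, or a leaving group \"a|e-<bond>-<residue>\""), text)
  }
  bond <- tryCatch(parse_bond(m[[3]]), cazac_parse_error = function(e) {
    parse_error(paste0("invalid leaving-group bond \"", m[[3]], "\""), text)
  })
  if (is_wild(bond$donor) || any(is_wild(bond$acceptors))) {
    parse_error("leaving-group bonds must be fully numeric", text)
  }
  residue <- parse_residue(m[[4]])
  if (!is_saccharide(residue)) {
    parse_error(paste0("leaving-group residue \"", m[[4]], "\" must be a saccharide"),
                text)
  }
  new_reactant("leaving_group", lg_anomer = m[[2]], lg_bond = bond,
               lg_residue = residue)
}

new_reactant <- function(variant, phosphate_orientation = NA_character_,
                         lg_anomer = NA_character_, lg_bond = NULL,
                         lg_residue = NULL) {
  structure(
    list(
      variant = variant,
      phosphate_orientation = phosphate_orientation,
      lg_anomer = lg_anomer,
      lg_bond = lg_bond,
      lg_residue = lg_residue
    ),
    class = "cazac_reactant"
  )
}

#' @param r A `cazac_reactant` object.
#' @rdname parse_reactant
#' @export
render_reactant <- function(r) {
  if (!inherits(r, "cazac_reactant")) {
    cazac_error("`r` must be a cazac_reactant object", "cazac_render_error")
  }
  switch(r$variant,
    none = "none",
    water = "H2O",
    peroxide = "H2O2",
    phosphate = paste0(r$phosphate_orientation, "Pi"),
    leaving_group = paste0(r$lg_anomer, "-", render_bond(r$lg_bond), "-",
                           render_residue(r$lg_residue)),
    cazac_error("invalid reactant variant", "cazac_render_error")
  )
}

#' @export
print.cazac_reactant <- function(x, ...) {
  cat("<cazac_reactant> ", render_reactant(x), "\n", sep = "")
  invisible(x)
}
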