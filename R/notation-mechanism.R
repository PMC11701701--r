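#' Mechanism notation
#'
#' Each sequence-based family carries a catalytic mechanism and the
#' orientation of the glycosidic bond undergoing catalysis.  Classical
#' Koshland mechanisms either retain or invert the anomeric configuration;
#' family GH97 harbors both; NAD-dependent and unsaturated-substrate
#' families fall under "other", which always pairs with both bond
#' orientations; "unknown" covers families whose mechanism is not yet
#' established.  Polysaccharide lyases cleave by beta-elimination and
#' LPMOs act as peroxygenases; neither carries a bond orientation.
#' Orientation is written `a` (axial) or `e` (equatorial) rather than
#' alpha/beta so that it is independent of D/L stereochemistry.
#'
#' Input is case-insensitive and accepts `"b-elimination"` and
#' `"beta-elimination"` as ASCII aliases; canonical output follows the
#' table spellings: `"Retaining a"`, `"Inverting (inferred) a"`,
#' `"Inverting and retaining a"`, `"Other a,e"`, `"Unknown a"`,
#' `"\u03b2-elimination"`, `"peroxygenase"`.  `"(inferred)"` marks a
#' mechanism assigned by analogy rather than experiment.
#'
#' @param text A single mechanism phrase.
#' @return `parse_mechanism()` returns a `cazac_mechanism` object with
#'   fields `category`, `orientation` and `inferred`;
#'   `render_mechanism()` its canonical phrase.
#' @examples
#' parse_mechanism("Retaining a")
#' parse_mechanism("inverting (inferred) a")
#' render_mechanism(parse_mechanism("b-elimination"))
#' @export
parse_mechanism <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(gsub("[[:space:]]+", " ", text))
  cache_get("mechanism", text, parse_mechanism_impl)
}

mechanism_vocabulary <- c(
  "Retaining a", "Retaining e", "Inverting a", "Inverting e",
  "Inverting and retaining a", "Inverting and retaining e",
  "Other a,e", "Unknown a", "Unknown e", "Unknown a,e",
  "\u03b2-elimination", "peroxygenase"
)

parse_mechanism_impl <- function(text) {
  lowered <- tolower(text)
  if (lowered %in% c("\u03b2-elimination", "b-elimination", "beta-elimination")) {
    return(new_mechanism("beta_elimination", "not_applicable"))
  }
  if (lowered == "peroxygenase") {
    return(new_mechanism("peroxygenase", "not_applicable"))
  }
  m <- regmatches(lowered, regexec(
    "^(retaining|inverting|inverting and retaining|retaining and inverting|other|unknown)( \\(inferred\\))? (a|e|a,e)$",
    lowered))[[1]]
  if (length(m) == 0L) {
    parse_error(paste0("unknown mechanism; expected one of: ",
                       paste(mechanism_vocabulary, collapse = ", "),
                       ", optionally with \"(inferred)\""), text)
  }
  category <- switch(m[[2]],
    retaining = "retaining",
    inverting = "inverting",
    "inverting and retaining" = ,
    "retaining and inverting" = "retaining_and_inverting",
    other = "other",
    unknown = "unknown"
  )
  orientation <- switch(m[[4]],
    a = "axial", e = "equatorial", "a,e" = "axial_and_equatorial"
  )
  if (category == "other" && orientation != "axial_and_equatorial") {
    parse_error("mechanism \"other\" always pairs with orientation a,e", text)
  }
  if (category %in% c("retaining", "inverting", "retaining_and_inverting") &&
      orientation == "axial_and_equatorial") {
    parse_error("Koshland mechanisms carry a single bond orientation (a or e)", text)
  }
  new_mechanism(category, orientation, inferred = m[[3]] != "")
}

new_mechanism <- function(category, orientation, inferred = FALSE) {
  structure(
    list(category = category, orientation = orientation,
         inferred = isTRUE(inferred)),
    class = "cazac_mechanism"
  )
}

orientation_letter <- function(orientation) {
  switch(orientation,
    axial = "a", equatorial = "e", axial_and_equatorial = "a,e",
    not_applicable = ""
  )
}

#' @param m A `cazac_mechanism` object.
#' @rdname parse_mechanism
#' @export
render_mechanism <- function(m) {
  if (!inherits(m, "cazac_mechanism")) {
    cazac_error("`m` must be a cazac_mechanism object", "cazac_render_error")
  }
  if (m$category == "beta_elimination") return("\u03b2-elimination")
  if (m$category == "peroxygenase") return("peroxygenase")
  head <- switch(m$category,
    retaining = "Retaining",
    inverting = "Inverting",
    retaining_and_inverting = "Inverting and retaining",
    other = "Other",
    unknown = "Unknown"
  )
  paste0(head, if (m$inferred) " (inferred)" else "", " ",
         orientation_letter(m$orientation))
}

#' @export
print.cazac_mechanism <- function(x, ...) {
  cat("<cazac_mechanism> ", render_mechanism(x), "\n", sep = "")
  invisible(x)
}
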