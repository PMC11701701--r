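#' Glycosidic bond notation
#'
#' A bond names the carbons joined by a glycosidic linkage, donor first:
#' `"1,4"` joins C1 to C4.  Alternative acceptor carbons are separated by a
#' slash (`"1,3/4"`, C3 or C4); `X` stands for an unspecified position, as
#' when the +1 subsite holds a non-carbohydrate aglycon (`"1,X"`).  An `o`
#' after a carbon marks the carbon oxidized during lytic polysaccharide
#' monooxygenase (LPMO) cleavage: `"1o,4"` for C1 oxidation, `"1,4o"` for
#' C4.  The empty string denotes an absent bond (no neighboring residue).
#'
#' @param text A single bond string, possibly empty.
#' @return `parse_bond()` returns a `cazac_bond` object; `render_bond()`
#'   the canonical string, with acceptor alternatives in ascending order.
#' @examples
#' parse_bond("1,3/4")
#' render_bond(parse_bond("1,4/3"))
#' @export
parse_bond <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  cache_get("bond", text, parse_bond_impl)
}

parse_bond_impl <- function(text) {
  if (text == "") return(new_bond_absent())
  m <- regmatches(text, regexec(
    "^(X|[0-9]+)(o?),((?:X|[0-9]+)(?:/(?:X|[0-9]+))*)(o?)$", text))[[1]]
  if (length(m) == 0L) {
    parse_error("bond must be \"<donor>[o],<acceptor>[/<acceptor>...][o]\"", text)
  }
  donor <- m[[2]]
  donor_ox <- m[[3]] == "o"
  acceptors <- strsplit(m[[4]], "/", fixed = TRUE)[[1]]
  acceptor_ox <- m[[5]] == "o"
  if ("X" %in% acceptors && length(acceptors) > 1L) {
    parse_error("wildcard X cannot be combined with other acceptor positions", text)
  }
  if (donor_ox && acceptor_ox) {
    parse_error("at most one carbon of a bond can carry an oxidation mark", text)
  }
  acceptors <- unique(acceptors)
  if (!"X" %in% acceptors) {
    acceptors <- acceptors[order(as.integer(acceptors))]
    if (any(as.integer(acceptors) < 1L)) {
      parse_error("carbon positions must be positive", text)
    }
  }
  if (donor != "X" && as.integer(donor) < 1L) {
    parse_error("carbon positions must be positive", text)
  }
  new_bond(donor, donor_ox, acceptors, acceptor_ox)
}

new_bond <- function(donor, donor_oxidized, acceptors, acceptor_oxidized) {
  structure(
    list(
      present = TRUE,
      donor = donor,
      donor_oxidized = isTRUE(donor_oxidized),
      acceptors = as.character(acceptors),
      acceptor_oxidized = isTRUE(acceptor_oxidized)
    ),
    class = "cazac_bond"
  )
}

new_bond_absent <- function() {
  structure(
    list(
      present = FALSE,
      donor = NA_character_,
      donor_oxidized = FALSE,
      acceptors = character(),
      acceptor_oxidized = FALSE
    ),
    class = "cazac_bond"
  )
}

is_wild <- function(pos) !is.na(pos) & pos == "X"

#' @param b A `cazac_bond` object.
#' @rdname parse_bond
#' @export
render_bond <- function(b) {
  if (!inherits(b, "cazac_bond")) {
    cazac_error("`b` must be a cazac_bond object", "cazac_render_error")
  }
  if (!b$present) return("")
  paste0(
    b$donor, if (b$donor_oxidized) "o" else "", ",",
    paste0(b$acceptors, collapse = "/"),
    if (b$acceptor_oxidized) "o" else ""
  )
}

#' @export
print.cazac_bond <- function(x, ...) {
  cat("<cazac_bond> ", if (x$present) render_bond(x) else "(absent)", "\n", sep = "")
  invisible(x)
}
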