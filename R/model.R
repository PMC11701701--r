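#' EC numbers
#'
#' Four-level Enzyme Commission identifiers, e.g. `"3.2.1.1"`.  The
#' incomplete form `"3.2.1.-"` denotes an activity without an assigned
#' fourth digit; it is a distinct value, never a wildcard over `3.2.1.x`.
#'
#' @param text A single EC string.
#' @return `parse_ec()` returns a `cazac_ec` object; `render_ec()` the
#'   `"c1.c2.c3.c4"` string, with `-` for an incomplete fourth level.
#' @examples
#' parse_ec("3.2.1.22")
#' render_ec(parse_ec("4.2.2.-"))
#' @export
parse_ec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  m <- regmatches(text, regexec("^([0-9]+)\\.([0-9]+)\\.([0-9]+)\\.([0-9]+|-)$",
                                text))[[1]]
  if (length(m) == 0L) {
    parse_error("EC number must have four dot-separated levels, e.g. 3.2.1.1 or 3.2.1.-",
                text)
  }
  new_ec(as.integer(m[[2]]), as.integer(m[[3]]), as.integer(m[[4]]),
         if (m[[5]] == "-") NA_integer_ else as.integer(m[[5]]))
}

new_ec <- function(c1, c2, c3, c4) {
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4), class = "cazac_ec")
}

#' @param ec A `cazac_ec` object.
#' @rdname parse_ec
#' @export
render_ec <- function(ec) {
  stopifnot(inherits(ec, "cazac_ec"))
  paste(ec$c1, ec$c2, ec$c3, if (is.na(ec$c4)) "-" else ec$c4, sep = ".")
}

#' @export
print.cazac_ec <- function(x, ...) {
  cat("<cazac_ec> ", render_ec(x), "\n", sep = "")
  invisible(x)
}

#' Map an EC number to its activity class letter
#'
#' The activity-ID letter encodes the class of catalysis: `H` hydrolysis,
#' `T` transfer (phosphorylases and transglycosylases), `L` lyase, `M`
#' mutase, `O` oxidase.  The first three EC levels determine the letter:
#' 3.2.1 maps to H; 2.4.1, 2.4.2, 2.4.3 and 2.4.99 to T; 4.2.2 to L;
#' 5.4.99 to M; 1.14.99 to O.
#'
#' @param ec A `cazac_ec` object or EC string.
#' @return A single letter among `"H"`, `"T"`, `"L"`, `"M"`, `"O"`.
#' @examples
#' class_letter_for_ec("3.2.1.1")
#' class_letter_for_ec("2.4.99.16")
#' @export
class_letter_for_ec <- function(ec) {
  if (is.character(ec)) ec <- parse_ec(ec)
  stopifnot(inherits(ec, "cazac_ec"))
  prefix <- paste(ec$c1, ec$c2, ec$c3, sep = ".")
  letter <- unname(c(
    "3.2.1" = "H",
    "2.4.1" = "T", "2.4.2" = "T", "2.4.3" = "T", "2.4.99" = "T",
    "4.2.2" = "L",
    "5.4.99" = "M",
    "1.14.99" = "O"
  )[prefix])
  if (is.na(letter)) {
    cazac_error(sprintf("unmapped EC class: no activity class letter for EC %s",
                        render_ec(ec)),
                "cazac_unmapped_ec_error")
  }
  letter
}

#' Activity identifiers
#'
#' A class letter (`H`, `L`, `T`, `M`, `O`) immediately followed by a
#' curator-assigned number, e.g. `H1`, `T292`, `L345`.  The numbers are
#' opaque identifiers; this package never invents or renumbers them.
#'
#' @param text A single activity-ID string.
#' @return `parse_activity_id()` returns a `cazac_activity_id`;
#'   `render_activity_id()` the string form.
#' @examples
#' parse_activity_id("T292")
#' @export
parse_activity_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  m <- regmatches(text, regexec("^([HLTMO])([0-9]+)$", text))[[1]]
  if (length(m) == 0L) {
    parse_error("activity ID must be a class letter (H/L/T/M/O) followed by a number",
                text)
  }
  structure(list(letter = m[[2]], number = as.integer(m[[3]])),
            class = "cazac_activity_id")
}

#' @param id A `cazac_activity_id` object.
#' @rdname parse_activity_id
#' @export
render_activity_id <- function(id) {
  stopifnot(inherits(id, "cazac_activity_id"))
  paste0(id$letter, id$number)
}

#' @export
print.cazac_activity_id <- function(x, ...) {
  cat("<cazac_activity_id> ", render_activity_id(x), "\n", sep = "")
  invisible(x)
}

# The four difructose-dianhydride lyase activities are deliberately not
# representable: those reactions proceed by cleavage followed by
# condensation to a cyclic disaccharide, not by a single describable step.
excluded_ecs <- c("4.2.1.179", "4.2.2.16", "4.2.2.17", "4.2.2.18")

activity_table_columns <- c(
  "activity_id", "ec", "name", "mechanism",
  "res_m2", "bond_m1", "res_m1", "reac_bond", "res_p1", "bond_p1", "res_p2",
  "reactant", "families", "cazy_class"
)

split_families <- function(families) {
  if (is.na(families) || families == "") return(character())
  trimws(strsplit(families, ",", fixed = TRUE)[[1]])
}
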