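#' Residue notation
#'
#' The residue grammar describes the content of one enzyme subsite.  A
#' subsite holds either a monosaccharide (possibly decorated, repeated, or
#' carrying a carbohydrate side chain), a free-text aglycon such as
#' `"alcohol"` or `"Mandelonitrile"`, or nothing at all.
#'
#' A monosaccharide is written as anomer (`a`/`b`, lowercase), `D`/`L`
#' stereochemistry, a three-letter title-case sugar code, and the ring type
#' (`p` pyranose / `f` furanose): `bDGlcp` is beta-D-glucopyranose.  Common
#' modifications such as N-acetylation are appended (`bDGlcpNAc`); other
#' modifications name the modified carbon after an underscore
#' (`bDGalpNAc_4S`).  A carbohydrate side chain and its linkage precede the
#' backbone in parentheses (`(aDXylp-1,6)bDGlcp`); parentheses with a
#' trailing count denote repeated units extending beyond the outer subsites
#' (`(aDGlcp)3`); `(cyclic)` marks a cyclic glycan.  A leading `[` or
#' trailing `]` marks the last occupiable subsite toward the non-reducing
#' or reducing end, the typography used for exolytic activities.  An
#' anomer-less unit (`DGlcp`) denotes an unresolved anomeric state, as for
#' a free reducing sugar.
#'
#' Text that cannot open a monosaccharide (no `[`, `(`, or anomer/stereo
#' prefix) is kept verbatim as an aglycon label; text that starts like a
#' monosaccharide but breaks the grammar is a parse error reporting the
#' offending character position.
#'
#' @param text A single notation string.  The empty string denotes an
#'   empty subsite.
#' @return `parse_residue()` returns a `cazac_residue` object;
#'   `render_residue()` returns the canonical notation string.
#' @examples
#' parse_residue("bDGalpNAc_4S")
#' parse_residue("(aDXylp-1,6)bDGlcp")
#' render_residue(parse_residue("(aDGlcp)_3_"))  # canonical form "(aDGlcp)3"
#' @export
parse_residue <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  cache_get("residue", text, parse_residue_impl)
}

parse_residue_impl <- function(text) {
  if (text == "") {
    return(new_residue_empty())
  }
  if (saccharide_like(text)) {
    s <- new_scanner(text)
    r <- scan_residue(s)
    if (s$pos <= s$n) {
      parse_error("unexpected trailing characters", text, s$pos)
    }
    return(r)
  }
  new_residue_aglycon(text)
}

# An aglycon label never begins with "[", "(" or an anomer/stereo pair;
# anything with such a prefix must parse fully as a saccharide.
saccharide_like <- function(text) {
  grepl("^[\\[(]", text) || grepl("^[ab]?[DL][A-Z]", text)
}

# ---- constructors ---------------------------------------------------------

new_monosaccharide <- function(anomer, stereo, sugar, ring,
                               common_mods = character(),
                               mod_carbons = integer(),
                               mod_codes = character(),
                               cyclic = FALSE) {
  ord <- order(mod_carbons)
  structure(
    list(
      anomer = anomer, stereo = stereo, sugar = sugar, ring = ring,
      common_mods = as.character(common_mods),
      mod_carbons = as.integer(mod_carbons[ord]),
      mod_codes = as.character(mod_codes[ord]),
      cyclic = isTRUE(cyclic)
    ),
    class = "cazac_monosaccharide"
  )
}

new_residue_saccharide <- function(backbone, side_chains = list(),
                                   repeat_count = 1L,
                                   open_boundary = FALSE,
                                   close_boundary = FALSE) {
  structure(
    list(
      variant = "saccharide",
      backbone = backbone,
      side_chains = side_chains,
      repeat_count = as.integer(repeat_count),
      open_boundary = isTRUE(open_boundary),
      close_boundary = isTRUE(close_boundary),
      label = NA_character_
    ),
    class = "cazac_residue"
  )
}

new_residue_aglycon <- function(label) {
  structure(
    list(
      variant = "aglycon", backbone = NULL, side_chains = list(),
      repeat_count = 1L, open_boundary = FALSE, close_boundary = FALSE,
      label = label
    ),
    class = "cazac_residue"
  )
}

new_residue_empty <- function() {
  structure(
    list(
      variant = "empty", backbone = NULL, side_chains = list(),
      repeat_count = 1L, open_boundary = FALSE, close_boundary = FALSE,
      label = NA_character_
    ),
    class = "cazac_residue"
  )
}

#' @export
print.cazac_residue <- function(x, ...) {
  cat("<cazac_residue> ", switch(x$variant,
    empty = "(empty subsite)",
    aglycon = paste0("aglycon \"", x$label, "\""),
    saccharide = render_residue(x)
  ), "\n", sep = "")
  invisible(x)
}

# ---- scanner --------------------------------------------------------------

new_scanner <- function(text) {
  s <- new.env(parent = emptyenv())
  s$text <- text
  s$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  s$n <- nchar(text)
  s$pos <- 1L
  s
}

s_peek <- function(s) if (s$pos <= s$n) s$chars[[s$pos]] else ""

s_take <- function(s) {
  ch <- s_peek(s)
  s$pos <- s$pos + 1L
  ch
}

s_match <- function(s, literal) {
  k <- nchar(literal)
  if (s$pos + k - 1L <= s$n &&
      substr(s$text, s$pos, s$pos + k - 1L) == literal) {
    s$pos <- s$pos + k
    TRUE
  } else {
    FALSE
  }
}

s_digits <- function(s) {
  start <- s$pos
  while (s$pos <= s$n && grepl("^[0-9]$", s$chars[[s$pos]])) {
    s$pos <- s$pos + 1L
  }
  if (s$pos == start) return(NA_integer_)
  as.integer(substr(s$text, start, s$pos - 1L))
}

s_fail <- function(s, message) parse_error(message, s$text, s$pos)

# Appendable "common" modification tokens, longest first so that NAc is
# never read as N followed by stray text.  The set is configurable, not
# authoritative: the nomenclature names N-acetylation as the archetype but
# gives no exhaustive list.
common_mod_tokens <- function() getOption("cazac.common_mods", c("NAc", "N", "A"))

scan_residue <- function(s, depth = 0L) {
  open_boundary <- depth == 0L && s_match(s, "[")
  side_chains <- list()
  repeat_count <- 1L
  backbone <- NULL

  while (s_peek(s) == "(") {
    if (s_match(s, "(cyclic)")) s_fail(s, "\"(cyclic)\" must follow a monosaccharide")
    if (depth >= 2L) s_fail(s, "side chains nested too deeply")
    s_take(s) # "("
    inner <- scan_residue(s, depth = depth + 1L)
    if (s_peek(s) == "-") {
      s_take(s)
      bond_start <- s$pos
      while (s$pos <= s$n && grepl("^[0-9,/Xo]$", s$chars[[s$pos]])) {
        s$pos <- s$pos + 1L
      }
      bond_text <- substr(s$text, bond_start, s$pos - 1L)
      bond <- tryCatch(parse_bond(bond_text), cazac_parse_error = function(e) {
        parse_error(paste0("invalid side-chain bond \"", bond_text, "\""),
                    s$text, bond_start)
      })
      if (!bond$present || is_wild(bond$donor) || any(is_wild(bond$acceptors))) {
        parse_error("side-chain bonds must be fully specified", s$text, bond_start)
      }
      if (!s_match(s, ")")) s_fail(s, "expected \")\" after side-chain bond")
      side_chains[[length(side_chains) + 1L]] <- list(residue = inner, bond = bond)
    } else if (s_peek(s) == ")") {
      s_take(s)
      # repeated unit: "(aDGlcp)3" in tables, "(aDGlcp)_3_" in running text
      underscored <- s_match(s, "_")
      count <- s_digits(s)
      if (is.na(count)) s_fail(s, "expected repeat count after \")\"")
      if (underscored && !s_match(s, "_")) s_fail(s, "expected closing \"_\" after repeat count")
      if (count < 1L) s_fail(s, "repeat count must be positive")
      if (length(side_chains) > 0L || length(inner$side_chains) > 0L) {
        s_fail(s, "repeated units must be plain monosaccharides")
      }
      backbone <- inner$backbone
      repeat_count <- count
      break
    } else {
      s_fail(s, "expected \"-\" or \")\" in parenthesized group")
    }
  }

  if (is.null(backbone)) {
    backbone <- scan_unit(s)
  }
  close_boundary <- depth == 0L && s_match(s, "]")
  new_residue_saccharide(backbone, side_chains, repeat_count,
                         open_boundary, close_boundary)
}

scan_unit <- function(s) {
  anomer <- NA_character_
  ch1 <- s_peek(s)
  if (ch1 %in% c("a", "b")) {
    nxt <- if (s$pos + 1L <= s$n) s$chars[[s$pos + 1L]] else ""
    if (nxt %in% c("D", "L")) {
      anomer <- s_take(s)
    } else {
      s_fail(s, "expected stereochemistry D or L after anomer")
    }
  }
  stereo <- s_peek(s)
  if (!stereo %in% c("D", "L")) s_fail(s, "expected stereochemistry D or L")
  s_take(s)
  if (s$pos + 2L > s$n ||
      !grepl("^[A-Z][a-z][a-z]$", substr(s$text, s$pos, s$pos + 2L))) {
    s_fail(s, "sugar code must be three letters, title-case")
  }
  sugar <- substr(s$text, s$pos, s$pos + 2L)
  s$pos <- s$pos + 3L
  ring <- s_peek(s)
  if (!ring %in% c("p", "f")) s_fail(s, "expected ring type p or f")
  s_take(s)

  common_mods <- character()
  repeat {
    matched <- FALSE
    for (tok in common_mod_tokens()) {
      if (s_match(s, tok)) {
        common_mods <- c(common_mods, tok)
        matched <- TRUE
        break
      }
    }
    if (!matched) break
  }

  mod_carbons <- integer()
  mod_codes <- character()
  while (s_peek(s) == "_") {
    s_take(s)
    carbon <- s_digits(s)
    if (is.na(carbon) || carbon < 1L) s_fail(s, "expected carbon number after \"_\"")
    code_start <- s$pos
    while (s$pos <= s$n && grepl("^[A-Za-z]$", s$chars[[s$pos]])) {
      s$pos <- s$pos + 1L
    }
    if (s$pos == code_start ||
        !grepl("^[A-Z]", substr(s$text, code_start, code_start))) {
      parse_error("expected uppercase modification code", s$text, code_start)
    }
    code <- substr(s$text, code_start, s$pos - 1L)
    if (carbon %in% mod_carbons) {
      parse_error(sprintf("duplicate modification on carbon %d", carbon),
                  s$text, code_start)
    }
    mod_carbons <- c(mod_carbons, carbon)
    mod_codes <- c(mod_codes, code)
  }

  cyclic <- s_match(s, "(cyclic)")
  new_monosaccharide(anomer, stereo, sugar, ring, common_mods,
                     mod_carbons, mod_codes, cyclic)
}

# ---- renderer -------------------------------------------------------------

render_unit <- function(m) {
  paste0(
    if (!is.na(m$anomer)) m$anomer else "",
    m$stereo, m$sugar, m$ring,
    paste0(m$common_mods, collapse = ""),
    paste0(vapply(seq_along(m$mod_carbons), function(i) {
      paste0("_", m$mod_carbons[[i]], m$mod_codes[[i]])
    }, character(1)), collapse = ""),
    if (m$cyclic) "(cyclic)" else ""
  )
}

#' @param r A `cazac_residue` object.
#' @rdname parse_residue
#' @export
render_residue <- function(r) {
  if (!inherits(r, "cazac_residue")) {
    cazac_error("`r` must be a cazac_residue object", "cazac_render_error")
  }
  switch(r$variant,
    empty = "",
    aglycon = r$label,
    saccharide = {
      chains <- paste0(vapply(r$side_chains, function(sc) {
        paste0("(", render_residue(sc$residue), "-", render_bond(sc$bond), ")")
      }, character(1)), collapse = "")
      core <- render_unit(r$backbone)
      if (r$repeat_count > 1L) core <- paste0("(", core, ")", r$repeat_count)
      paste0(
        if (r$open_boundary) "[" else "",
        chains, core,
        if (r$close_boundary) "]" else ""
      )
    },
    cazac_error("invalid residue variant", "cazac_render_error")
  )
}

#' Test residue variants
#'
#' @param r A `cazac_residue` object.
#' @return A logical scalar.
#' @export
is_saccharide <- function(r) {
  inherits(r, "cazac_residue") && r$variant == "saccharide"
}

#' @rdname is_saccharide
#' @export
is_empty_residue <- function(r) {
  inherits(r, "cazac_residue") && r$variant == "empty"
}
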