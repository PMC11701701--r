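#' Match a query residue against a recorded subsite
#'
#' Non-strict matching compares only the monosaccharide core — anomer,
#' D/L stereochemistry, sugar code and ring type — so a query `"bDGalp"`
#' retrieves activities on beta-D-galactopyranose and all its variants
#' (N-acetylated, sulfated, decorated with side chains, repeated, cyclic,
#' or at a chain end).  A query with unspecified anomer (`"DGlcp"`)
#' non-strictly matches any anomer of the same sugar.
#'
#' Strict matching requires structural equality of the full residue,
#' including modifications, side chains, repeat counts, the cyclic flag
#' and the `[`/`]` boundary markers: strict `"aDGlcp"` does not match an
#' exolytic record `"[aDGlcp"`, and strict `"[bDGlcpNAc"` gives direct
#' access to exolytic families.
#'
#' @param query,record `cazac_residue` objects or notation strings.  The
#'   query must be a saccharide.
#' @param strict Logical; use strict matching.
#' @return A logical scalar.
#' @examples
#' match_residue("bDGalp", "bDGalpNAc")                 # TRUE
#' match_residue("bDGalp", "bDGalpNAc", strict = TRUE)  # FALSE
#' @export
match_residue <- function(query, record, strict = FALSE) {
  if (is.character(query)) query <- parse_residue(query)
  if (is.character(record)) record <- parse_residue(record)
  if (!is_saccharide(query)) {
    cazac_error("the query residue must be a saccharide", "cazac_query_error")
  }
  if (!is_saccharide(record)) return(FALSE)
  if (strict) {
    return(identical(render_residue(query), render_residue(record)))
  }
  q <- query$backbone
  r <- record$backbone
  q$stereo == r$stereo && q$sugar == r$sugar && q$ring == r$ring &&
    (is.na(q$anomer) || (!is.na(r$anomer) && q$anomer == r$anomer))
}

#' Match a query bond against a recorded bond
#'
#' Donor positions must agree, with the wildcard `X` on either side
#' matching any position.  A record's acceptor alternatives are
#' disjunctive: the match succeeds if any alternative equals a query
#' alternative (again with `X` matching anything).  Oxidation marks are
#' ignored unless the query carries one, in which case the marks on both
#' carbons must agree exactly.
#'
#' @param query,record `cazac_bond` objects or bond strings; both must be
#'   present (non-empty).
#' @return A logical scalar.
#' @examples
#' match_bond("1,4", "1,3/4")  # TRUE
#' match_bond("1o,4", "1,4o")  # FALSE
#' @export
match_bond <- function(query, record) {
  if (is.character(query)) query <- parse_bond(query)
  if (is.character(record)) record <- parse_bond(record)
  if (!query$present || !record$present) return(FALSE)
  donor_ok <- is_wild(query$donor) || is_wild(record$donor) ||
    query$donor == record$donor
  if (!donor_ok) return(FALSE)
  acceptor_ok <- any(is_wild(query$acceptors)) || any(is_wild(record$acceptors)) ||
    length(intersect(query$acceptors, record$acceptors)) > 0L
  if (!acceptor_ok) return(FALSE)
  if (query$donor_oxidized || query$acceptor_oxidized) {
    return(query$donor_oxidized == record$donor_oxidized &&
             query$acceptor_oxidized == record$acceptor_oxidized)
  }
  TRUE
}

#' Build a search query
#'
#' All fields are optional and additive — each additional field can only
#' restrict the result — but at least one of `residue`, `ec` or `family`
#' must be given.  `residue` is matched against the reacting subsite of
#' each line: subsite -1 for GH and AA records, +1 for PL records (the
#' residue that undergoes catalysis in a lyase sits at +1).
#'
#' @param cazy_class Optional CAZy class, one of `"GH"`, `"PL"`, `"AA"`.
#' @param residue Optional residue notation string or `cazac_residue`.
#' @param strict Logical; strict residue matching (see [match_residue()]).
#' @param activity_class Optional activity class letter
#'   (`"H"`, `"L"`, `"T"`, `"M"`, `"O"`).
#' @param mechanism Optional mechanism phrase or `cazac_mechanism`;
#'   matching compares category and orientation and ignores the inferred
#'   flag.
#' @param reac_bond Optional reacting-bond string or `cazac_bond`.
#' @param ec Optional EC number; incomplete ECs (`"3.2.1.-"`) are
#'   distinct values, not prefixes.
#' @param family Optional family label, e.g. `"GH13"`.
#' @return A `cazac_query` object.
#' @examples
#' cazac_query(cazy_class = "GH", residue = "aDGlcp", strict = TRUE,
#'             reac_bond = "1,4")
#' @export
cazac_query <- function(cazy_class = NULL, residue = NULL, strict = FALSE,
                        activity_class = NULL, mechanism = NULL,
                        reac_bond = NULL, ec = NULL, family = NULL) {
  if (is.null(residue) && is.null(ec) && is.null(family)) {
    cazac_error(paste0("the minimum requirement for a search is a residue, ",
                       "an EC number or a family"),
                "cazac_query_error")
  }
  if (!is.null(cazy_class) && !cazy_class %in% c("GH", "PL", "AA")) {
    cazac_error("cazy_class must be GH, PL or AA", "cazac_query_error")
  }
  if (!is.null(residue)) {
    if (is.character(residue)) residue <- parse_residue(residue)
    if (!is_saccharide(residue)) {
      cazac_error("the query residue must be a saccharide", "cazac_query_error")
    }
  }
  if (!is.null(activity_class) && !activity_class %in% c("H", "L", "T", "M", "O")) {
    cazac_error("activity_class must be one of H, L, T, M, O", "cazac_query_error")
  }
  if (!is.null(mechanism) && is.character(mechanism)) {
    mechanism <- parse_mechanism(mechanism)
  }
  if (!is.null(reac_bond)) {
    if (is.character(reac_bond)) reac_bond <- parse_bond(reac_bond)
    if (!reac_bond$present) {
      cazac_error("the query reacting bond must be non-empty", "cazac_query_error")
    }
  }
  if (!is.null(ec) && is.character(ec)) ec <- parse_ec(ec)
  structure(
    list(cazy_class = cazy_class, residue = residue, strict = isTRUE(strict),
         activity_class = activity_class, mechanism = mechanism,
         reac_bond = reac_bond, ec = ec, family = family),
    class = "cazac_query"
  )
}

#' @export
print.cazac_query <- function(x, ...) {
  cat("<cazac_query>\n")
  if (!is.null(x$cazy_class)) cat("  class:     ", x$cazy_class, "\n", sep = "")
  if (!is.null(x$residue)) {
    cat("  residue:   ", render_residue(x$residue),
        if (x$strict) " (strict)" else "", "\n", sep = "")
  }
  if (!is.null(x$activity_class)) cat("  activity:  ", x$activity_class, "\n", sep = "")
  if (!is.null(x$mechanism)) cat("  mechanism: ", render_mechanism(x$mechanism), "\n", sep = "")
  if (!is.null(x$reac_bond)) cat("  reac bond: ", render_bond(x$reac_bond), "\n", sep = "")
  if (!is.null(x$ec)) cat("  ec:        ", render_ec(x$ec), "\n", sep = "")
  if (!is.null(x$family)) cat("  family:    ", x$family, "\n", sep = "")
  invisible(x)
}

# subsite consulted by a residue query, by CAZy class of the record
reacting_subsite <- function(cazy_class) {
  ifelse(cazy_class == "PL", "res_p1", "res_m1")
}

#' Run a query against an activity table
#'
#' Filters the table line by line: a line is kept iff it satisfies every
#' field set in the query.  The residue is matched against the line's
#' reacting-side subsite (-1 for GH/AA, +1 for PL); when the query names
#' a `cazy_class`, only lines of that class are considered.  Result rows
#' keep their dataset order, so identical inputs always give identical
#' output.
#'
#' @param ds An activity table.
#' @param query A `cazac_query` object.
#' @return The matching lines as a `cazac_tbl` tibble.
#' @examples
#' endo <- run_query(load_fixture(),
#'                   cazac_query(cazy_class = "GH", residue = "aDGlcp",
#'                               strict = TRUE, reac_bond = "1,4"))
#' length(distinct_activity_ids(endo))
#' @export
run_query <- function(ds, query) {
  stopifnot(inherits(query, "cazac_query"))
  tb <- as_tibble(ds)
  keep <- rep(TRUE, nrow(tb))

  if (!is.null(query$cazy_class)) {
    keep <- keep & tb$cazy_class == query$cazy_class
  }
  if (!is.null(query$activity_class)) {
    keep <- keep & substr(tb$activity_id, 1L, 1L) == query$activity_class
  }
  if (!is.null(query$mechanism)) {
    keep <- keep & map_lgl(tb$mechanism, function(s) {
      m <- parse_mechanism(s)
      m$category == query$mechanism$category &&
        m$orientation == query$mechanism$orientation
    })
  }
  if (!is.null(query$ec)) {
    keep <- keep & tb$ec == render_ec(query$ec)
  }
  if (!is.null(query$family)) {
    keep <- keep & map_lgl(tb$families, function(s) query$family %in% split_families(s))
  }
  if (!is.null(query$reac_bond)) {
    keep <- keep & map_lgl(tb$reac_bond, function(s) {
      b <- parse_bond(s)
      b$present && match_bond(query$reac_bond, b)
    })
  }
  if (!is.null(query$residue)) {
    subsite <- reacting_subsite(tb$cazy_class)
    keep <- keep & map_lgl(seq_len(nrow(tb)), function(i) {
      match_residue(query$residue, parse_residue(tb[[subsite[[i]]]][[i]]),
                    strict = query$strict)
    })
  }

  out <- tb[keep, ]
  class(out) <- c("cazac_tbl", class(as_tibble(out)))
  out
}
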