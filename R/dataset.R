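#' Activity tables
#'
#' An activity table is a tibble with one row per activity ID and
#' mechanism, holding the eight descriptor fields as notation strings
#' together with the EC number, activity name, family list and CAZy
#' class.  Column order is fixed:
#' `activity_id, ec, name, mechanism, res_m2, bond_m1, res_m1, reac_bond,
#' res_p1, bond_p1, res_p2, reactant, families, cazy_class`.
#' Families are comma-separated within their cell; empty cells are empty
#' strings.  On disk the table is UTF-8, tab-separated, with a header row.
#'
#' `as_activity_table()` checks the column set, canonicalizes every
#' notation cell through the grammar parsers, and verifies that the
#' (activity_id, mechanism, families) triples are unique.
#'
#' @param x A data frame with the fourteen activity-table columns.
#' @param mode `"strict"` aborts on the first malformed cell;
#'   `"lenient"` drops malformed rows and records them in the
#'   `"problems"` attribute of the result.
#' @return A tibble of class `cazac_tbl`.
#' @export
as_activity_table <- function(x, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  x <- as_tibble(x)
  missing_cols <- setdiff(activity_table_columns, names(x))
  if (length(missing_cols) > 0L) {
    cazac_error(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
                "cazac_table_error")
  }
  unknown <- setdiff(names(x), activity_table_columns)
  if (length(unknown) > 0L) {
    cazac_error(paste0("unknown column(s): ", paste(unknown, collapse = ", ")),
                "cazac_table_error")
  }
  x <- x[, activity_table_columns]
  x[] <- lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })

  canon <- list(
    activity_id = function(s) render_activity_id(parse_activity_id(s)),
    ec = function(s) if (s == "") "" else render_ec(parse_ec(s)),
    name = identity,
    mechanism = function(s) render_mechanism(parse_mechanism(s)),
    res_m2 = function(s) render_residue(parse_residue(s)),
    bond_m1 = function(s) render_bond(parse_bond(s)),
    res_m1 = function(s) render_residue(parse_residue(s)),
    reac_bond = function(s) render_bond(parse_bond(s)),
    res_p1 = function(s) render_residue(parse_residue(s)),
    bond_p1 = function(s) render_bond(parse_bond(s)),
    res_p2 = function(s) render_residue(parse_residue(s)),
    reactant = function(s) render_reactant(parse_reactant(s)),
    families = function(s) {
      fams <- split_families(s)
      if (any(fams == "")) {
        parse_error("families must be non-empty, comma-separated labels", s)
      }
      paste(fams, collapse = ",")
    },
    cazy_class = function(s) {
      if (!s %in% c("GH", "PL", "AA")) {
        parse_error("cazy_class must be GH, PL or AA", s)
      }
      s
    }
  )

  problems <- list()
  bad_rows <- logical(nrow(x))
  for (col in activity_table_columns) {
    fn <- canon[[col]]
    for (i in seq_len(nrow(x))) {
      value <- tryCatch(fn(x[[col]][[i]]), cazac_parse_error = function(e) e)
      if (inherits(value, "cazac_parse_error")) {
        if (mode == "strict") {
          cazac_error(sprintf("row %d, column %s: %s", i, col,
                              conditionMessage(value)),
                      "cazac_table_error", row = i, column = col)
        }
        problems[[length(problems) + 1L]] <-
          tibble(row = i, column = col, message = conditionMessage(value))
        bad_rows[[i]] <- TRUE
      } else {
        x[[col]][[i]] <- value
      }
    }
  }
  if (any(bad_rows)) x <- x[!bad_rows, ]

  key <- paste(x$activity_id, x$mechanism, x$families, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x$activity_id[duplicated(key)][[1]]
    cazac_error(sprintf("duplicate (activity_id, mechanism, families) triple for %s", dup),
                "cazac_table_error")
  }

  structure(x, class = c("cazac_tbl", class(as_tibble(x))),
            problems = if (length(problems) > 0L) bind_rows(problems) else NULL)
}

#' Read and write activity tables
#'
#' `read_activity_table()` reads the tab-separated dialect described in
#' [as_activity_table()], parsing and canonicalizing every cell;
#' `write_activity_table()` writes it back.  Reading a written table
#' reproduces it exactly; reading an arbitrary well-formed file and
#' writing it performs one canonicalization pass (e.g. `(aDGlcp)_3_`
#' becomes `(aDGlcp)3`) and is idempotent thereafter.
#'
#' @param path A file path.
#' @inheritParams as_activity_table
#' @return `read_activity_table()` returns a `cazac_tbl` tibble.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' write_activity_table(load_fixture(), path)
#' identical(read_activity_table(path), load_fixture())
#' @export
read_activity_table <- function(path, mode = c("strict", "lenient")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  as_activity_table(raw, mode = match.arg(mode))
}

#' @param ds An activity table.
#' @rdname read_activity_table
#' @export
write_activity_table <- function(ds, path) {
  ds <- as_tibble(ds)[, activity_table_columns]
  readr::write_tsv(ds, path, na = "", progress = FALSE)
  invisible(path)
}

#' Export an activity table as JSON
#'
#' Mirrors the table one-to-one: one object per line, the model field
#' names as keys, and the family list as a JSON array.
#'
#' @param ds An activity table.
#' @return A JSON string (class `json`).
#' @export
activity_table_json <- function(ds) {
  ds <- as_tibble(ds)
  rows <- purrr::map(seq_len(nrow(ds)), function(i) {
    row <- as.list(ds[i, ])
    row$families <- split_families(row$families)
    row
  })
  jsonlite::toJSON(rows, auto_unbox = TRUE, pretty = TRUE)
}

#' The bundled starch-degradation activity table
#'
#' A 29-line activity table covering alpha-1,4-glucan (starch and
#' malto-oligosaccharide) chemistry: the 18 endo-acting lines on
#' `aDGlcp-1,4` (17 activity IDs, one of which carries two mechanism
#' lines), the 8 exo-acting lines (7 activity IDs, one duplicated), and
#' the three mechanism lines of the alpha-galactosidase function
#' EC 3.2.1.22.  For the alpha-galactosidase lines only the mechanisms
#' and family sets are curated; the subsite fields and the activity-ID
#' number are synthetic placeholders (see the package vignette).
#'
#' @return A `cazac_tbl` tibble with 29 rows.
#' @examples
#' load_fixture()
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "starch_activities.tsv", package = "cazac",
                      mustWork = TRUE)
  checksum <- unname(tools::md5sum(path))
  if (!identical(checksum, fixture_md5)) {
    cazac_error(sprintf("bundled dataset checksum mismatch (%s)", checksum),
                "cazac_checksum_error")
  }
  read_activity_table(path)
}

#' Count distinct activity identifiers and families
#'
#' @param ds An activity table.
#' @return `distinct_activity_ids()` returns the distinct activity-ID
#'   strings in table order; `families_of()` the union of family labels
#'   in table order.
#' @examples
#' length(distinct_activity_ids(load_fixture()))
#' @export
distinct_activity_ids <- function(ds) {
  unique(as.character(as_tibble(ds)$activity_id))
}

#' @rdname distinct_activity_ids
#' @export
families_of <- function(ds) {
  unique(unlist(lapply(as_tibble(ds)$families, split_families), use.names = FALSE))
}
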