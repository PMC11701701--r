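#' Validate activity lines
#'
#' Checks one activity line, or every line of an activity table, against
#' the structural rules of the descriptor model.  Violations are data,
#' not conditions: the validator never raises on a syntactically parsed
#' line, and returns a tibble with zero rows when the line is clean.
#'
#' Rules enforced as violations:
#' * `res-m1-must-be-saccharide` — the -1 subsite carries strictly
#'   carbohydrate information.
#' * `reac-bond-required` — the bond between subsites -1 and +1 (the
#'   reacting bond) is never absent.
#' * class-letter/reactant correspondence — hydrolases (H) use water,
#'   lyases (L) none, transferases (T) phosphate or a leaving group,
#'   mutases (M) a leaving group, oxidases (O) hydrogen peroxide.
#' * `lpmo-bond-needs-oxidation-mark` — an O line must mark exactly one
#'   oxidized carbon (`o`) on the reacting bond.
#' * `ec-class-letter-mismatch` — when an EC number is present and
#'   mapped, its class letter must equal the activity-ID letter.
#' * `excluded-difructose-dianhydride` — EC 4.2.1.179, 4.2.2.16,
#'   4.2.2.17 and 4.2.2.18 describe two-step cleavage/condensation
#'   reactions that the descriptor cannot represent.
#' * `families-required` — every line names at least one family.
#'
#' Advisory checks reported with `severity = "warning"`:
#' * `unverified-side-chain-depth` — a side chain that itself carries a
#'   side chain; the grammar permits one level of nesting but no curated
#'   record exercises it.
#' * `phosphorylase-orientation-lint` — for phosphorylases the phosphate
#'   orientation is expected to equal the -1 anomer orientation under a
#'   retaining mechanism and be opposite under an inverting one.
#'
#' @param line A named list or one-row data frame with the fourteen
#'   activity-table fields as notation strings.
#' @return A tibble with columns `rule`, `severity` (`"violation"` or
#'   `"warning"`) and `message`.
#' @examples
#' line <- list(
#'   activity_id = "H1", ec = "3.2.1.1", name = "amylase",
#'   mechanism = "Retaining a", res_m2 = "aDGlcp", bond_m1 = "1,4",
#'   res_m1 = "aDGlcp", reac_bond = "1,4", res_p1 = "aDGlcp",
#'   bond_p1 = "1,4", res_p2 = "aDGlcp", reactant = "H2O",
#'   families = "GH13", cazy_class = "GH"
#' )
#' validate_line(line)
#' @export
validate_line <- function(line) {
  line <- as.list(line)
  findings <- list()
  flag <- function(rule, message, severity = "violation") {
    findings[[length(findings) + 1L]] <<-
      tibble(rule = rule, severity = severity, message = message)
  }
  cell <- function(col) as.character(line[[col]] %||% "")

  safe <- function(fn, col) {
    tryCatch(fn(cell(col)), cazac_parse_error = function(e) {
      flag("unparsable-cell", sprintf("column %s: %s", col, conditionMessage(e)))
      NULL
    })
  }

  id <- safe(parse_activity_id, "activity_id")
  mech <- safe(parse_mechanism, "mechanism")
  res_m1 <- safe(parse_residue, "res_m1")
  reac_bond <- safe(parse_bond, "reac_bond")
  reactant <- safe(parse_reactant, "reactant")
  for (col in c("res_m2", "res_p1", "res_p2")) safe(parse_residue, col)
  for (col in c("bond_m1", "bond_p1")) safe(parse_bond, col)
  ec <- if (cell("ec") == "") NULL else safe(parse_ec, "ec")

  if (!is.null(res_m1) && !is_saccharide(res_m1)) {
    flag("res-m1-must-be-saccharide",
         "the -1 subsite must contain a monosaccharide, not an aglycon or empty field")
  }
  if (!is.null(reac_bond) && !reac_bond$present) {
    flag("reac-bond-required", "the reacting bond between -1 and +1 must be present")
  }

  if (!is.null(id) && !is.null(reactant)) {
    letter <- id$letter
    v <- reactant$variant
    if (letter == "H" && v != "water") {
      flag("hydrolase-reactant-must-be-water",
           sprintf("class H requires reactant H2O, found \"%s\"", cell("reactant")))
    }
    if (letter == "L" && v != "none") {
      flag("lyase-reactant-must-be-none",
           sprintf("class L requires no reactant, found \"%s\"", cell("reactant")))
    }
    if (letter == "O" && v != "peroxide") {
      flag("lpmo-reactant-must-be-peroxide",
           sprintf("class O requires reactant H2O2, found \"%s\"", cell("reactant")))
    }
    if (letter == "T" && !v %in% c("phosphate", "leaving_group")) {
      flag("transferase-reactant-must-be-phosphate-or-leaving-group",
           sprintf("class T requires a/ePi or a leaving group, found \"%s\"",
                   cell("reactant")))
    }
    if (letter == "M" && v != "leaving_group") {
      flag("mutase-reactant-must-be-leaving-group",
           sprintf("class M requires a leaving group, found \"%s\"", cell("reactant")))
    }
    if (letter == "O" && !is.null(reac_bond) && reac_bond$present) {
      n_marks <- sum(reac_bond$donor_oxidized, reac_bond$acceptor_oxidized)
      if (n_marks != 1L) {
        flag("lpmo-bond-needs-oxidation-mark",
             "an oxidase line must mark exactly one oxidized carbon on the reacting bond")
      }
    }
  }

  if (!is.null(ec)) {
    if (render_ec(ec) %in% excluded_ecs) {
      flag("excluded-difructose-dianhydride",
           sprintf("EC %s (difructose dianhydride metabolism) is outside the descriptor system",
                   render_ec(ec)))
    } else if (!is.null(id)) {
      expected <- tryCatch(class_letter_for_ec(ec),
                           cazac_unmapped_ec_error = function(e) NA_character_)
      if (!is.na(expected) && expected != id$letter) {
        flag("ec-class-letter-mismatch",
             sprintf("EC %s maps to class letter %s but activity ID is %s",
                     render_ec(ec), expected, render_activity_id(id)))
      }
    }
  }

  if (length(split_families(cell("families"))) == 0L) {
    flag("families-required", "every line must name at least one family")
  }
  if (!cell("cazy_class") %in% c("GH", "PL", "AA")) {
    flag("invalid-cazy-class",
         sprintf("cazy_class must be GH, PL or AA, found \"%s\"", cell("cazy_class")))
  }

  if (!is.null(res_m1) && is_saccharide(res_m1)) {
    nested <- any(vapply(res_m1$side_chains,
                         function(sc) length(sc$residue$side_chains) > 0L,
                         logical(1)))
    if (nested) {
      flag("unverified-side-chain-depth",
           "nested side chains parse but no curated record exercises them",
           severity = "warning")
    }
  }

  if (!is.null(id) && !is.null(reactant) && !is.null(mech) &&
      id$letter == "T" && reactant$variant == "phosphate" &&
      !is.null(res_m1) && is_saccharide(res_m1) &&
      !is.na(res_m1$backbone$anomer) &&
      mech$category %in% c("retaining", "inverting")) {
    # anomer a is axial, b equatorial; phosphate keeps the -1 orientation
    # under retention and flips it under inversion
    anomer_orient <- if (res_m1$backbone$anomer == "a") "a" else "e"
    expected <- if (mech$category == "retaining") {
      anomer_orient
    } else {
      setdiff(c("a", "e"), anomer_orient)
    }
    if (reactant$phosphate_orientation != expected) {
      flag("phosphorylase-orientation-lint",
           sprintf("phosphate orientation %s unexpected for a %s mechanism on an anomer-%s sugar",
                   reactant$phosphate_orientation, mech$category,
                   res_m1$backbone$anomer),
           severity = "warning")
    }
  }

  if (length(findings) == 0L) {
    tibble(rule = character(), severity = character(), message = character())
  } else {
    bind_rows(findings)
  }
}

#' @param ds An activity table, as returned by [read_activity_table()] or
#'   [load_fixture()].
#' @rdname validate_line
#' @return `validate_activities()` returns a tibble with columns `row`,
#'   `activity_id`, `rule`, `severity` and `message`, one row per finding
#'   across the whole table.
#' @export
validate_activities <- function(ds) {
  ds <- as_tibble(ds)
  out <- purrr::map(seq_len(nrow(ds)), function(i) {
    found <- validate_line(ds[i, ])
    if (nrow(found) > 0L) {
      found$row <- i
      found$activity_id <- as.character(ds$activity_id[[i]])
    }
    found
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    tibble(row = integer(), activity_id = character(), rule = character(),
           severity = character(), message = character())
  } else {
    out[, c("row", "activity_id", "rule", "severity", "message")]
  }
}
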