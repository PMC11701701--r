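#' Generator parameters
#'
#' Bundles the knobs of the random generators.  The defaults give every
#' grammar feature a nonzero probability — boundary markers, repeats,
#' cyclic glycans, common and positioned modifications, side chains,
#' anomer-less reducing units — so that fuzzing exercises the full
#' grammar.
#'
#' @param seed Integer seed; identical parameters give identical output.
#' @param max_side_chains Maximum number of side chains per residue.
#' @param p_modification,p_boundary,p_repeat,p_cyclic Probabilities in
#'   `[0, 1]` of decorating a residue with modifications, boundary
#'   markers, a repeat count, or the cyclic flag.
#' @param sugar_pool Three-letter sugar codes to draw from.
#' @param n_lines Number of activity lines for [gen_dataset()].
#' @return A list of class `cazac_gen_params`.
#' @export
gen_params <- function(seed, max_side_chains = 1L, p_modification = 0.3,
                       p_boundary = 0.25, p_repeat = 0.15, p_cyclic = 0.1,
                       sugar_pool = c("Glc", "Gal", "Man", "Xyl", "Ara",
                                      "Fru", "Fuc", "Rha"),
                       n_lines = 50L) {
  probs <- c(p_modification, p_boundary, p_repeat, p_cyclic)
  stopifnot(
    is.numeric(seed), length(seed) == 1L,
    all(probs >= 0 & probs <= 1),
    length(sugar_pool) > 0L, all(grepl("^[A-Z][a-z][a-z]$", sugar_pool)),
    max_side_chains >= 0L, n_lines >= 0L
  )
  structure(
    list(seed = as.integer(seed), max_side_chains = as.integer(max_side_chains),
         p_modification = p_modification, p_boundary = p_boundary,
         p_repeat = p_repeat, p_cyclic = p_cyclic,
         sugar_pool = sugar_pool, n_lines = as.integer(n_lines)),
    class = "cazac_gen_params"
  )
}

chance <- function(p) stats::runif(1) < p

pick <- function(x, prob = NULL) {
  i <- if (length(x) == 1L) 1L else sample.int(length(x), 1L, prob = prob)
  x[[i]]
}

gen_unit_impl <- function(params, allow_unspecified = TRUE) {
  anomer <- if (allow_unspecified && chance(0.07)) {
    NA_character_
  } else {
    pick(c("a", "b"))
  }
  common_mods <- character()
  mod_carbons <- integer()
  mod_codes <- character()
  if (chance(params$p_modification)) {
    if (chance(0.6)) {
      common_mods <- pick(common_mod_tokens())
    } else {
      k <- pick(1:2)
      mod_carbons <- sample(2:6, k)
      mod_codes <- sample(c("S", "P", "Me"), k, replace = TRUE)
    }
  }
  new_monosaccharide(
    anomer = anomer,
    stereo = pick(c("D", "L"), prob = c(0.85, 0.15)),
    sugar = pick(params$sugar_pool),
    ring = pick(c("p", "f"), prob = c(0.8, 0.2)),
    common_mods = common_mods,
    mod_carbons = mod_carbons,
    mod_codes = mod_codes,
    cyclic = chance(params$p_cyclic)
  )
}

gen_numeric_bond_impl <- function(oxidized = FALSE) {
  donor <- pick(c("1", "2"), prob = c(0.9, 0.1))
  n_alt <- pick(1:2, prob = c(0.85, 0.15))
  acceptors <- as.character(sort(sample(setdiff(1:6, as.integer(donor)), n_alt)))
  donor_ox <- FALSE
  acceptor_ox <- FALSE
  if (oxidized) {
    if (chance(0.5)) donor_ox <- TRUE else acceptor_ox <- TRUE
  }
  new_bond(donor, donor_ox, acceptors, acceptor_ox)
}

gen_bond_impl <- function(wildcard_ok = TRUE) {
  if (wildcard_ok && chance(0.15)) {
    if (chance(0.5)) {
      new_bond("X", FALSE, as.character(pick(1:6)), FALSE)
    } else {
      new_bond(pick(c("1", "2")), FALSE, "X", FALSE)
    }
  } else {
    gen_numeric_bond_impl()
  }
}

gen_residue_impl <- function(params, depth = 0L, plain = FALSE) {
  backbone <- gen_unit_impl(params, allow_unspecified = !plain)
  side_chains <- list()
  repeat_count <- 1L
  open_boundary <- FALSE
  close_boundary <- FALSE

  if (!plain && depth == 0L) {
    n_sc <- if (params$max_side_chains > 0L && chance(0.25)) {
      pick(seq_len(params$max_side_chains))
    } else {
      0L
    }
    if (n_sc > 0L) {
      side_chains <- lapply(seq_len(n_sc), function(i) {
        list(residue = gen_residue_impl(params, depth = depth + 1L, plain = TRUE),
             bond = gen_numeric_bond_impl())
      })
    }
    can_repeat <- length(side_chains) == 0L &&
      length(backbone$common_mods) == 0L && length(backbone$mod_carbons) == 0L &&
      !backbone$cyclic
    if (can_repeat && chance(params$p_repeat)) repeat_count <- pick(2:5)
    if (chance(params$p_boundary)) {
      if (chance(0.5)) open_boundary <- TRUE else close_boundary <- TRUE
    }
    if (is.na(backbone$anomer)) close_boundary <- TRUE
  }
  if (plain && is.na(backbone$anomer)) {
    backbone$anomer <- pick(c("a", "b"))
  }
  new_residue_saccharide(backbone, side_chains, repeat_count,
                         open_boundary, close_boundary)
}

#' Generate a random residue
#'
#' Draws a structurally valid saccharide residue.  Output is
#' deterministic for a fixed seed and always survives the
#' render/parse round trip.
#'
#' @param params A [gen_params()] object.
#' @return A `cazac_residue` object.
#' @examples
#' render_residue(gen_residue(gen_params(seed = 1)))
#' @export
gen_residue <- function(params) {
  stopifnot(inherits(params, "cazac_gen_params"))
  withr::with_seed(params$seed, gen_residue_impl(params))
}

# one activity line as a named list of canonical notation strings; the
# class letter, EC prefix, reactant and oxidation marks are drawn jointly
# so the class/reactant correspondences hold by construction
gen_line_impl <- function(params, number) {
  role <- pick(c("hydrolase", "phosphorylase", "transglycosylase",
                 "mutase", "pl_lyase", "gh_lyase", "oxidase"),
               prob = c(0.40, 0.12, 0.13, 0.05, 0.10, 0.05, 0.15))

  koshland <- function() {
    new_mechanism(pick(c("retaining", "inverting"), prob = c(0.6, 0.4)),
                  pick(c("axial", "equatorial")),
                  inferred = chance(0.1))
  }
  gh_mechanism <- function() {
    r <- stats::runif(1)
    if (r < 0.70) {
      koshland()
    } else if (r < 0.80) {
      new_mechanism("unknown", pick(c("axial", "equatorial")))
    } else if (r < 0.90) {
      new_mechanism("other", "axial_and_equatorial")
    } else {
      new_mechanism("retaining_and_inverting", pick(c("axial", "equatorial")))
    }
  }
  ec4 <- function() if (chance(0.15)) "-" else as.character(pick(1:250))
  gh_families <- function() {
    paste0("GH", sort(sample(1:200, pick(1:3, prob = c(0.6, 0.3, 0.1)))),
           collapse = ",")
  }

  res_m1 <- gen_residue_impl(params)
  res_p1 <- if (chance(0.75)) {
    gen_residue_impl(params)
  } else {
    new_residue_aglycon(pick(c("alcohol", "Mandelonitrile", "glycerol")))
  }
  outer <- function() {
    r <- stats::runif(1)
    if (r < 0.4) new_residue_empty()
    else if (r < 0.9) gen_residue_impl(params)
    else new_residue_aglycon("alcohol")
  }
  res_m2 <- outer()
  res_p2 <- outer()
  bond_m1 <- if (is_empty_residue(res_m2)) new_bond_absent() else gen_numeric_bond_impl()
  bond_p1 <- if (is_empty_residue(res_p2)) new_bond_absent() else gen_numeric_bond_impl()
  reac_wild_ok <- !is_saccharide(res_p1)
  reac_bond <- if (reac_wild_ok && chance(0.5)) {
    new_bond(pick(c("1", "2")), FALSE, "X", FALSE)
  } else {
    gen_numeric_bond_impl()
  }

  cazy_class <- "GH"
  if (role == "hydrolase") {
    letter <- "H"
    e4 <- ec4()
    ec <- new_ec(3L, 2L, 1L, if (e4 == "-") NA_integer_ else as.integer(e4))
    mechanism <- gh_mechanism()
    reactant <- new_reactant("water")
    families <- gh_families()
  } else if (role == "phosphorylase") {
    letter <- "T"
    prefix <- pick(list(c(2L, 4L, 1L), c(2L, 4L, 99L)))
    ec <- new_ec(prefix[[1]], prefix[[2]], prefix[[3]], pick(1:250))
    mechanism <- koshland()
    # keep the orientation lint clean: retention preserves the -1
    # orientation in the phosphate, inversion flips it
    if (is.na(res_m1$backbone$anomer)) {
      res_m1$backbone$anomer <- pick(c("a", "b"))
      res_m1$close_boundary <- res_m1$close_boundary || FALSE
    }
    anomer_orient <- if (res_m1$backbone$anomer == "a") "a" else "e"
    orient <- if (mechanism$category == "retaining") {
      anomer_orient
    } else {
      setdiff(c("a", "e"), anomer_orient)
    }
    reactant <- new_reactant("phosphate", phosphate_orientation = orient)
    families <- gh_families()
  } else if (role %in% c("transglycosylase", "mutase")) {
    letter <- if (role == "mutase") "M" else "T"
    ec <- if (role == "mutase") {
      new_ec(5L, 4L, 99L, pick(c(11L, 15L, 16L)))
    } else {
      prefix <- pick(list(c(2L, 4L, 1L), c(2L, 4L, 2L)))
      new_ec(prefix[[1]], prefix[[2]], prefix[[3]],
             if (chance(0.15)) NA_integer_ else pick(1:250))
    }
    mechanism <- koshland()
    lg_res <- gen_residue_impl(params, depth = 1L, plain = TRUE)
    lg_res$close_boundary <- chance(0.3)
    reactant <- new_reactant("leaving_group", lg_anomer = pick(c("a", "e")),
                             lg_bond = gen_numeric_bond_impl(),
                             lg_residue = lg_res)
    families <- gh_families()
  } else if (role %in% c("pl_lyase", "gh_lyase")) {
    letter <- "L"
    ec <- new_ec(4L, 2L, 2L, pick(setdiff(1:30, c(16L, 17L, 18L))))
    if (role == "pl_lyase") {
      cazy_class <- "PL"
      mechanism <- new_mechanism("beta_elimination", "not_applicable")
      families <- paste0("PL", sort(sample(1:40, pick(1:2))), collapse = ",")
      if (!is_saccharide(res_p1)) res_p1 <- gen_residue_impl(params)
    } else {
      mechanism <- koshland()
      families <- gh_families()
    }
    reactant <- new_reactant("none")
  } else { # oxidase
    letter <- "O"
    cazy_class <- "AA"
    ec <- new_ec(1L, 14L, 99L, if (chance(0.3)) NA_integer_ else pick(1:60))
    mechanism <- new_mechanism("peroxygenase", "not_applicable")
    reactant <- new_reactant("peroxide")
    reac_bond <- gen_numeric_bond_impl(oxidized = TRUE)
    families <- paste0("AA", sort(sample(1:17, pick(1:2))), collapse = ",")
  }

  list(
    activity_id = paste0(letter, number),
    ec = render_ec(ec),
    name = paste0("synthetic ", sub("^(pl|gh)_", "", role), " ", number),
    mechanism = render_mechanism(mechanism),
    res_m2 = render_residue(res_m2),
    bond_m1 = render_bond(bond_m1),
    res_m1 = render_residue(res_m1),
    reac_bond = render_bond(reac_bond),
    res_p1 = render_residue(res_p1),
    bond_p1 = render_bond(bond_p1),
    res_p2 = render_residue(res_p2),
    reactant = render_reactant(reactant),
    families = families,
    cazy_class = cazy_class
  )
}

#' Generate a random activity table
#'
#' Draws `n_lines` activity lines whose class letters, EC prefixes,
#' reactants and oxidation marks are generated jointly, so every line
#' passes [validate_line()] with zero violations by construction.
#' Activity-ID numbers are assigned sequentially, which keeps the
#' (activity_id, mechanism, families) triples unique.  Generated lines
#' are syntactically valid, not biochemically meaningful.
#'
#' @param params A [gen_params()] object.
#' @return A `cazac_tbl` tibble with `params$n_lines` rows.
#' @examples
#' gen_dataset(gen_params(seed = 7, n_lines = 5))
#' @export
gen_dataset <- function(params) {
  stopifnot(inherits(params, "cazac_gen_params"))
  withr::with_seed(params$seed, {
    rows <- lapply(seq_len(params$n_lines), function(i) {
      tibble(!!!gen_line_impl(params, number = i))
    })
    empty <- tibble(!!!stats::setNames(
      rep(list(character()), length(activity_table_columns)),
      activity_table_columns))
    as_activity_table(bind_rows(c(list(empty), rows)))
  })
}

#' Generate a random query for a dataset
#'
#' Anchors the query on a randomly chosen line of `ds` (its reacting
#' residue, EC number or a family) so that matches exist with useful
#' probability, then adds the optional fields at random.  Used for
#' property testing of the search engine.
#'
#' @param params A [gen_params()] object.
#' @param ds An activity table with at least one row.
#' @return A `cazac_query` object.
#' @export
gen_query <- function(params, ds) {
  stopifnot(inherits(params, "cazac_gen_params"))
  tb <- as_tibble(ds)
  stopifnot(nrow(tb) > 0L)
  withr::with_seed(params$seed, gen_query_impl(params, tb))
}

gen_query_impl <- function(params, tb) {
  i <- pick(seq_len(nrow(tb)))
  line <- tb[i, ]
  subsite <- reacting_subsite(line$cazy_class)
  res <- parse_residue(line[[subsite]])
  anchors <- list()
  if (is_saccharide(res)) {
    residue <- if (chance(0.4)) {
      # generic form: backbone core only, as a broad search would type it
      new_residue_saccharide(new_monosaccharide(
        res$backbone$anomer, res$backbone$stereo, res$backbone$sugar,
        res$backbone$ring))
    } else {
      res
    }
    anchors$residue <- list(residue = residue, strict = chance(0.5))
  }
  if (line$ec != "") anchors$ec <- line$ec
  anchors$family <- pick(split_families(line$families))

  chosen <- pick(names(anchors))
  args <- list()
  if (chosen == "residue" || (!is.null(anchors$residue) && chance(0.3))) {
    args$residue <- anchors$residue$residue
    args$strict <- anchors$residue$strict
  }
  if (chosen == "ec" || (!is.null(anchors$ec) && chance(0.2))) {
    args$ec <- anchors$ec
  }
  if (chosen == "family" || chance(0.2)) args$family <- anchors$family
  if (chance(0.35)) args$cazy_class <- line$cazy_class
  if (chance(0.25)) args$activity_class <- substr(line$activity_id, 1L, 1L)
  if (chance(0.25)) args$mechanism <- line$mechanism
  if (chance(0.35)) {
    args$reac_bond <- if (chance(0.8)) line$reac_bond else "1,X"
  }
  do.call(cazac_query, args)
}
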