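# Brute-force reference for the search engine: a plain row-by-row scan
# applying each match predicate independently, kept deliberately separate
# from the run_query() implementation.
oracle_query <- function(ds, q) {
  tb <- tibble::as_tibble(ds)
  keep <- logical(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    line <- tb[i, ]
    ok <- TRUE
    if (!is.null(q$cazy_class)) ok <- ok && line$cazy_class == q$cazy_class
    if (ok && !is.null(q$activity_class)) {
      ok <- substr(line$activity_id, 1, 1) == q$activity_class
    }
    if (ok && !is.null(q$mechanism)) {
      m <- parse_mechanism(line$mechanism)
      ok <- m$category == q$mechanism$category &&
        m$orientation == q$mechanism$orientation
    }
    if (ok && !is.null(q$ec)) ok <- line$ec == render_ec(q$ec)
    if (ok && !is.null(q$family)) {
      ok <- q$family %in% trimws(strsplit(line$families, ",")[[1]])
    }
    if (ok && !is.null(q$reac_bond)) {
      b <- parse_bond(line$reac_bond)
      ok <- b$present && match_bond(q$reac_bond, b)
    }
    if (ok && !is.null(q$residue)) {
      col <- if (line$cazy_class == "PL") "res_p1" else "res_m1"
      ok <- match_residue(q$residue, parse_residue(line[[col]]),
                          strict = q$strict)
    }
    keep[i] <- isTRUE(ok)
  }
  tb[keep, ]
}

# comparable plain data frame (drops tibble subclasses and attributes)
as_plain_df <- function(x) {
  x <- as.data.frame(tibble::as_tibble(x))
  attr(x, "problems") <- NULL
  rownames(x) <- NULL
  x
}

fixture_strings <- function(ds = load_fixture()) {
  list(
    residues = unique(c(ds$res_m2, ds$res_m1, ds$res_p1, ds$res_p2)),
    bonds = unique(c(ds$bond_m1, ds$reac_bond, ds$bond_p1)),
    reactants = unique(ds$reactant),
    mechanisms = unique(ds$mechanism)
  )
}

activity_table_cols_for_test <- function() {
  c("activity_id", "ec", "name", "mechanism", "res_m2", "bond_m1", "res_m1",
    "reac_bond", "res_p1", "bond_p1", "res_p2", "reactant", "families",
    "cazy_class")
}
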