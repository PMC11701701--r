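test_that("non-strict residue matching retrieves all variants of a core", {
  expect_true(match_residue("bDGalp", "bDGalpNAc"))
  expect_true(match_residue("bDGalp", "bDGalpNAc_4S"))
  expect_true(match_residue("bDGalp", "[bDGalp"))
  expect_true(match_residue("bDGalp", "(aDXylp-1,6)bDGalp"))
  expect_true(match_residue("aDGlcp", "(aDGlcp)3"))
  expect_true(match_residue("aDGlcp", "aDGlcp(cyclic)"))
  expect_false(match_residue("bDGalp", "bDGlcp"))
  expect_false(match_residue("bDGalp", "bLGalp"))
  expect_false(match_residue("bDGalp", "bDGalf"))
  expect_false(match_residue("bDGalp", "aDGalp"))
  # unspecified anomer in the query relaxes the anomer, nothing else
  expect_true(match_residue("DGlcp", "aDGlcp"))
  expect_true(match_residue("DGlcp", "bDGlcpNAc"))
  expect_false(match_residue("DGlcp", "DGalp"))
  # a record with unspecified anomer does not satisfy an anomeric query
  expect_false(match_residue("aDGlcp", "DGlcp]"))
})

test_that("strict residue matching is full structural equality", {
  expect_false(match_residue("bDGalp", "bDGalpNAc", strict = TRUE))
  expect_false(match_residue("[bDGlcpNAc", "bDGlcpNAc", strict = TRUE))
  expect_true(match_residue("[bDGlcpNAc", "[bDGlcpNAc", strict = TRUE))
  expect_false(match_residue("aDGlcp", "[aDGlcp", strict = TRUE))
  expect_false(match_residue("aDGlcp", "DGlcp", strict = TRUE))
  expect_false(match_residue("aDGlcp", "(aDGlcp)3", strict = TRUE))
  expect_false(match_residue("aDGlcp", "aDGlcp(cyclic)", strict = TRUE))
  for (s in c("aDGlcp", "[aDGlcp", "(aDXylp-1,6)bDGlcp", "bDGalpNAc_4S",
              "(aDGlcp)3", "DGlcp]")) {
    expect_true(match_residue(s, s, strict = TRUE), label = s)
  }
})

test_that("aglycon and empty query residues are invalid", {
  expect_error(match_residue("alcohol", "aDGlcp"), class = "cazac_query_error")
  expect_error(match_residue("", "aDGlcp"), class = "cazac_query_error")
  expect_false(match_residue("aDGlcp", "alcohol"))
  expect_false(match_residue("aDGlcp", ""))
})

test_that("bond matching: wildcards, disjunctive alternatives, oxidation", {
  expect_true(match_bond("1,4", "1,4"))
  expect_true(match_bond("1,4", "1,3/4"))
  expect_false(match_bond("1,2", "1,3/4"))
  expect_true(match_bond("1,3/2", "1,2/6"))
  expect_true(match_bond("1,X", "1,6"))
  expect_true(match_bond("1,4", "1,X"))
  expect_true(match_bond("X,4", "2,4"))
  expect_false(match_bond("2,4", "1,4"))
  # oxidation marks are ignored unless the query carries one
  expect_true(match_bond("1,4", "1o,4"))
  expect_true(match_bond("1,4", "1,4o"))
  expect_false(match_bond("1o,4", "1,4o"))
  expect_false(match_bond("1o,4", "1,4"))
  expect_true(match_bond("1o,4", "1o,4"))
})

test_that("queries require a residue, EC number or family", {
  expect_error(cazac_query(mechanism = "Retaining a"),
               class = "cazac_query_error")
  expect_error(cazac_query(), class = "cazac_query_error")
  expect_error(cazac_query(residue = "alcohol"), class = "cazac_query_error")
  expect_s3_class(cazac_query(family = "GH13"), "cazac_query")
})

test_that("the worked starch searches reproduce their published counts", {
  ds <- load_fixture()
  endo <- run_query(ds, cazac_query(cazy_class = "GH", residue = "aDGlcp",
                                    strict = TRUE, reac_bond = "1,4"))
  expect_length(distinct_activity_ids(endo), 17)
  expect_length(families_of(endo), 8)

  exo <- run_query(ds, cazac_query(cazy_class = "GH", residue = "[aDGlcp",
                                   strict = TRUE, reac_bond = "1,4"))
  expect_length(distinct_activity_ids(exo), 7)

  ag <- run_query(ds, cazac_query(ec = "3.2.1.22"))
  expect_equal(nrow(ag), 3L)

  # incomplete ECs are values, not prefixes
  inc <- run_query(ds, cazac_query(ec = "3.2.1.-"))
  expect_setequal(unique(inc$ec), "3.2.1.-")
  expect_equal(nrow(run_query(ds, cazac_query(ec = "2.4.1.-"))), 2L)

  # mechanism matching ignores the inferred flag
  inv <- run_query(ds, cazac_query(family = "GH126",
                                   mechanism = "Inverting a"))
  expect_equal(inv$activity_id, "H1")
})

test_that("summaries count activities by class letter, role and family", {
  ds <- load_fixture()
  endo <- run_query(ds, cazac_query(cazy_class = "GH", residue = "aDGlcp",
                                    strict = TRUE, reac_bond = "1,4"))
  s <- summarize_results(endo)
  expect_equal(s$n_lines, 18L)
  expect_equal(s$n_activities, 17L)
  expect_equal(s$by_class[["H"]], 13L)
  expect_equal(s$by_class[["T"]], 4L)
  expect_equal(s$by_role[["phosphorylase"]], 1L)
  expect_equal(s$by_role[["transglycosylase"]], 3L)
  expect_equal(
    s$by_family$n_activities[s$by_family$family == "GH13"], 13L)

  td <- tidy(s)
  expect_equal(td$family[[1]], "GH13")
  g <- glance(s)
  expect_equal(g$n_activities, 17L)
  expect_equal(g$n_families, 8L)

  empty <- summarize_results(ds[0, ])
  expect_equal(empty$n_lines, 0L)
  expect_equal(sum(empty$by_class), 0L)
  expect_equal(sum(empty$by_role), 0L)
  expect_length(empty$families, 0)
})

test_that("adding query fields never enlarges the result (additivity)", {
  ds <- load_fixture()
  base <- cazac_query(residue = "aDGlcp")
  base_ids <- run_query(ds, base)$activity_id
  richer <- list(
    cazac_query(residue = "aDGlcp", cazy_class = "GH"),
    cazac_query(residue = "aDGlcp", strict = TRUE),
    cazac_query(residue = "aDGlcp", activity_class = "T"),
    cazac_query(residue = "aDGlcp", mechanism = "Retaining a"),
    cazac_query(residue = "aDGlcp", reac_bond = "1,4"),
    cazac_query(residue = "aDGlcp", ec = "3.2.1.1"),
    cazac_query(residue = "aDGlcp", family = "GH13")
  )
  for (q in richer) {
    expect_true(all(run_query(ds, q)$activity_id %in% base_ids))
  }
})

test_that("strict results are a subset of non-strict results", {
  ds <- load_fixture()
  for (res in c("aDGlcp", "[aDGlcp", "bDFruf", "DGlcp")) {
    strict <- run_query(ds, cazac_query(residue = res, strict = TRUE))
    loose <- run_query(ds, cazac_query(residue = res))
    key <- function(x) paste(x$activity_id, x$mechanism, x$families)
    expect_true(all(key(strict) %in% key(loose)), label = res)
  }
})

test_that("results preserve dataset order and are deterministic", {
  ds <- load_fixture()
  q <- cazac_query(family = "GH13")
  a <- run_query(ds, q)
  b <- run_query(ds, q)
  expect_identical(a, b)
  pos <- match(paste(a$activity_id, a$mechanism),
               paste(ds$activity_id, ds$mechanism))
  expect_true(all(diff(pos) > 0))
})

test_that("run_query agrees with the brute-force oracle on the fixture", {
  ds <- load_fixture()
  queries <- list(
    cazac_query(residue = "aDGlcp"),
    cazac_query(residue = "aDGlcp", strict = TRUE),
    cazac_query(residue = "[aDGlcp", strict = TRUE, reac_bond = "1,4"),
    cazac_query(ec = "3.2.1.22"),
    cazac_query(family = "GH57", mechanism = "Retaining a"),
    cazac_query(residue = "aDGalp", activity_class = "H"),
    cazac_query(residue = "bDFruf", cazy_class = "GH")
  )
  for (q in queries) {
    expect_identical(as_plain_df(run_query(ds, q)),
                     as_plain_df(oracle_query(ds, q)))
  }
})
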