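test_that("EC numbers parse, render and reject malformed input", {
  ec <- parse_ec("3.2.1.1")
  expect_equal(unlist(ec[c("c1", "c2", "c3", "c4")]),
               c(c1 = 3L, c2 = 2L, c3 = 1L, c4 = 1L))
  expect_true(is.na(parse_ec("3.2.1.-")$c4))
  expect_identical(render_ec(parse_ec("3.2.1.-")), "3.2.1.-")
  expect_error(parse_ec("3.2"), class = "cazac_parse_error")
  expect_error(parse_ec("3.2.1.1.4"), class = "cazac_parse_error")
  expect_error(parse_ec("3.2.-.1"), class = "cazac_parse_error")
})

test_that("EC prefixes map to activity class letters", {
  expect_equal(class_letter_for_ec("3.2.1.1"), "H")
  expect_equal(class_letter_for_ec("2.4.1.19"), "T")
  expect_equal(class_letter_for_ec("2.4.2.1"), "T")
  expect_equal(class_letter_for_ec("2.4.3.1"), "T")
  expect_equal(class_letter_for_ec("2.4.99.16"), "T")
  expect_equal(class_letter_for_ec("4.2.2.13"), "L")
  expect_equal(class_letter_for_ec("5.4.99.11"), "M")
  expect_equal(class_letter_for_ec("1.14.99.-"), "O")
  expect_error(class_letter_for_ec("1.1.1.1"), class = "cazac_unmapped_ec_error")
  expect_error(class_letter_for_ec("3.2.2.1"), class = "cazac_unmapped_ec_error")
})

test_that("activity IDs parse and render", {
  id <- parse_activity_id("T292")
  expect_equal(id$letter, "T")
  expect_equal(id$number, 292L)
  expect_identical(render_activity_id(id), "T292")
  expect_error(parse_activity_id("X1"), class = "cazac_parse_error")
  expect_error(parse_activity_id("H"), class = "cazac_parse_error")
  expect_error(parse_activity_id("12"), class = "cazac_parse_error")
})

base_line <- function(...) {
  line <- list(
    activity_id = "H1", ec = "3.2.1.1", name = "test hydrolase",
    mechanism = "Retaining a", res_m2 = "aDGlcp", bond_m1 = "1,4",
    res_m1 = "aDGlcp", reac_bond = "1,4", res_p1 = "aDGlcp",
    bond_p1 = "1,4", res_p2 = "aDGlcp", reactant = "H2O",
    families = "GH13", cazy_class = "GH"
  )
  utils::modifyList(line, list(...))
}

test_that("class-letter/reactant correspondences are validated", {
  expect_equal(nrow(validate_line(base_line())), 0L)

  v <- validate_line(base_line(activity_id = "L345", ec = "4.2.2.13",
                               reactant = "H2O"))
  expect_true("lyase-reactant-must-be-none" %in% v$rule)

  v <- validate_line(base_line(activity_id = "O1", ec = "1.14.99.54",
                               reactant = "H2O2", cazy_class = "AA",
                               families = "AA9", reac_bond = "1,4"))
  expect_true("lpmo-bond-needs-oxidation-mark" %in% v$rule)
  v <- validate_line(base_line(activity_id = "O1", ec = "1.14.99.54",
                               reactant = "H2O2", cazy_class = "AA",
                               families = "AA9", reac_bond = "1o,4"))
  expect_equal(nrow(v), 0L)

  v <- validate_line(base_line(activity_id = "T1", ec = "2.4.1.19"))
  expect_true("transferase-reactant-must-be-phosphate-or-leaving-group" %in% v$rule)

  v <- validate_line(base_line(activity_id = "M1", ec = "5.4.99.11",
                               reactant = "aPi"))
  expect_true("mutase-reactant-must-be-leaving-group" %in% v$rule)
})

test_that("structural rules and EC consistency are validated", {
  v <- validate_line(base_line(res_m1 = "alcohol"))
  expect_true("res-m1-must-be-saccharide" %in% v$rule)

  v <- validate_line(base_line(reac_bond = ""))
  expect_true("reac-bond-required" %in% v$rule)

  v <- validate_line(base_line(ec = "2.4.1.19"))
  expect_true("ec-class-letter-mismatch" %in% v$rule)

  v <- validate_line(base_line(families = ""))
  expect_true("families-required" %in% v$rule)

  for (ec in c("4.2.1.179", "4.2.2.16", "4.2.2.17", "4.2.2.18")) {
    v <- validate_line(base_line(activity_id = "L1", ec = ec,
                                 reactant = "none"))
    expect_true("excluded-difructose-dianhydride" %in% v$rule, label = ec)
  }
})

test_that("the validator is total: bad cells become violations, not errors", {
  v <- validate_line(base_line(res_m1 = "bDGl", mechanism = "sideways a"))
  expect_true(all(c("unparsable-cell") %in% v$rule))
  expect_gte(sum(v$rule == "unparsable-cell"), 2)
})

test_that("advisory findings are warnings, not violations", {
  v <- validate_line(base_line(res_m1 = "((aDGlcp-1,2)aDXylp-1,6)bDGlcp"))
  expect_true("unverified-side-chain-depth" %in% v$rule)
  expect_equal(v$severity[v$rule == "unverified-side-chain-depth"], "warning")

  # maltose phosphorylase inverts anomer a, so the phosphate is equatorial
  ok <- base_line(activity_id = "T265", ec = "2.4.1.8",
                  mechanism = "Inverting a", res_m1 = "[aDGlcp",
                  res_p1 = "DGlcp]", bond_p1 = "", res_p2 = "",
                  reactant = "ePi", families = "GH65")
  expect_equal(nrow(validate_line(ok)), 0L)
  v <- validate_line(utils::modifyList(ok, list(reactant = "aPi")))
  expect_equal(v$rule, "phosphorylase-orientation-lint")
  expect_equal(v$severity, "warning")
})

test_that("counting helpers use set semantics", {
  ds <- load_fixture()
  expect_lte(length(distinct_activity_ids(ds)), nrow(ds))
  empty <- ds[0, ]
  expect_length(distinct_activity_ids(empty), 0)
  expect_length(families_of(empty), 0)
})
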