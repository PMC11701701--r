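test_that("the bundled starch table loads with the expected content", {
  ds <- load_fixture()
  expect_s3_class(ds, "cazac_tbl")
  expect_equal(nrow(ds), 29L)
  expect_equal(names(ds),
               c("activity_id", "ec", "name", "mechanism", "res_m2", "bond_m1",
                 "res_m1", "reac_bond", "res_p1", "bond_p1", "res_p2",
                 "reactant", "families", "cazy_class"))

  # landmark lines
  expect_equal(sum(ds$activity_id == "H1"), 2L)
  expect_equal(ds$reactant[ds$activity_id == "T292"], "aPi")
  expect_equal(ds$reactant[ds$activity_id == "T304"], "a-1,2-bDFruf]")
  l345 <- ds[ds$activity_id == "L345", ]
  expect_equal(l345$reactant, "none")
  expect_equal(l345$cazy_class, "GH")
  expect_equal(sum(ds$ec == "3.2.1.22"), 3L)

  # maltose phosphorylase: free reducing glucose in +1
  t265 <- parse_residue(ds$res_p1[ds$activity_id == "T265"])
  expect_true(is.na(t265$backbone$anomer))
  expect_true(t265$close_boundary)

  # the whole table is clean
  report <- validate_activities(ds)
  expect_equal(sum(report$severity == "violation"), 0L)
  expect_equal(nrow(report), 0L)
})

test_that("every fixture notation string round-trips through its grammar", {
  strs <- fixture_strings()
  for (s in strs$residues) {
    expect_identical(render_residue(parse_residue(s)), s, label = s)
  }
  for (s in strs$bonds) {
    expect_identical(render_bond(parse_bond(s)), s, label = s)
  }
  for (s in strs$reactants) {
    expect_identical(render_reactant(parse_reactant(s)), s, label = s)
  }
  for (s in strs$mechanisms) {
    expect_identical(render_mechanism(parse_mechanism(s)), s, label = s)
  }
})

test_that("write/read is the identity on canonical tables", {
  ds <- load_fixture()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(ds, tmp)
  expect_identical(as_plain_df(read_activity_table(tmp)), as_plain_df(ds))
  # byte stability after one pass
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(read_activity_table(tmp), tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("reading canonicalizes non-canonical but well-formed cells", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  header <- paste(c("activity_id", "ec", "name", "mechanism", "res_m2",
                    "bond_m1", "res_m1", "reac_bond", "res_p1", "bond_p1",
                    "res_p2", "reactant", "families", "cazy_class"),
                  collapse = "\t")
  row <- paste(c("H45", "3.2.1.60", "glucotetraohydrolase", "retaining A",
                 "[(aDGlcp)_3_", "1,4", "aDGlcp", "1,4", "aDGlcp", "1,4",
                 "aDGlcp", "H2O", "GH13", "GH"), collapse = "\t")
  writeLines(c(header, row), tmp)
  ds <- read_activity_table(tmp)
  expect_equal(ds$res_m2, "[(aDGlcp)3")
  expect_equal(ds$mechanism, "Retaining a")
})

test_that("header and structure errors are reported by name", {
  tmp <- withr::local_tempfile(fileext = ".tsv")

  writeLines(paste(activity_table_cols_for_test(), collapse = "\t"), tmp)
  expect_equal(nrow(read_activity_table(tmp)), 0L)

  writeLines(paste(c(activity_table_cols_for_test(), "bonus"), collapse = "\t"),
             tmp)
  expect_error(read_activity_table(tmp), "bonus")

  writeLines(paste(setdiff(activity_table_cols_for_test(), "reactant"),
                   collapse = "\t"), tmp)
  expect_error(read_activity_table(tmp), "reactant")
})

test_that("duplicate (activity_id, mechanism, families) triples are rejected", {
  ds <- load_fixture()
  dup <- rbind(as.data.frame(ds), as.data.frame(ds[1, ]))
  expect_error(as_activity_table(dup), "duplicate")
})

test_that("strict mode aborts with coordinates, lenient mode collects", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  good <- paste(c("H1", "3.2.1.1", "ok", "Retaining a", "", "", "aDGlcp",
                  "1,4", "aDGlcp", "", "", "H2O", "GH13", "GH"),
                collapse = "\t")
  bad <- paste(c("H2", "3.2.1.2", "bad", "Retaining a", "", "", "bDGl",
                 "1,4", "aDGlcp", "", "", "H2O", "GH14", "GH"),
               collapse = "\t")
  writeLines(c(paste(activity_table_cols_for_test(), collapse = "\t"),
               good, bad), tmp)

  err <- tryCatch(read_activity_table(tmp, mode = "strict"),
                  error = function(e) e)
  expect_s3_class(err, "cazac_table_error")
  expect_match(conditionMessage(err), "row 2, column res_m1")

  ds <- read_activity_table(tmp, mode = "lenient")
  expect_equal(nrow(ds), 1L)
  problems <- attr(ds, "problems")
  expect_equal(problems$row, 2L)
  expect_equal(problems$column, "res_m1")
})

test_that("JSON export mirrors the model fields one-to-one", {
  ds <- load_fixture()
  parsed <- jsonlite::fromJSON(activity_table_json(ds), simplifyVector = FALSE)
  expect_length(parsed, nrow(ds))
  expect_equal(parsed[[1]]$activity_id, "H1")
  expect_equal(unlist(parsed[[1]]$families), c("GH119", "GH13", "GH57"))
  expect_setequal(names(parsed[[1]]), names(ds))
})
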