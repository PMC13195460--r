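test_that("compound reader parses rows, skips unparseable CIDs, keeps extras", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "CID,SMILES,ExactMass,Custom",
    "101, CCO ,46.0419,a",
    "102,c1ccccc1,78.04695,b",
    ",CC,NA,c",
    "104,CO,32.0262,d",
    "105,C,16.0313,e"
  ), f)
  comp <- read_compound_table(f)
  expect_equal(nrow(comp), 4L)
  expect_equal(comp$cid, c(101L, 102L, 104L, 105L))
  expect_equal(comp$smiles[1], "CCO")  # whitespace trimmed
  expect_equal(attr(comp, "skipped")$row, 3L)
  expect_true("Custom" %in% names(comp))
  expect_equal(comp$Custom, c("a", "b", "d", "e"))

  # header-only file: empty result, no skips
  writeLines("CID,SMILES", f)
  empty <- read_compound_table(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(attr(empty, "skipped")), 0L)

  # missing CID column is a schema error naming the headers
  writeLines(c("foo,bar", "1,2"), f)
  expect_error(read_compound_table(f), "schema error.*foo", ignore.case = TRUE)
  # ...unless a column_map bridges it
  remapped <- read_compound_table(f, column_map = list(cid = "foo"))
  expect_equal(remapped$cid, 1L)
  expect_error(read_compound_table(tempfile()), "not found")
})

test_that("reaction reader retains duplicates and matches the fixture ledger", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "predecessorcid,successorcid,predecessor,successor,datasetref",
    "1,2,a,b,DS01",
    "1,2,a,b,DS02",
    "3,x,c,d,DS01",
    "4,5,e,f,DS01"
  ), f)
  reac <- read_reaction_table(f)
  expect_equal(nrow(reac), 3L)  # duplicate pair retained, bad CID skipped
  expect_equal(sum(reac$predecessor_cid == 1L & reac$successor_cid == 2L), 2L)
  expect_equal(attr(reac, "skipped")$row, 3L)

  writeLines(c("predecessorcid,foo", "1,2"), f)
  expect_error(read_reaction_table(f), "successor_cid")

  # round-trip a generated fixture: counts and endpoint multisets survive
  fx <- generate_fixture(fixture_spec(seed = 11, n_compounds = 20,
                                      n_reactions = 30))
  paths <- write_fixture_csvs(fx)
  back <- read_reaction_table(paths[["reactions"]])
  expect_equal(nrow(back), nrow(fx$reactions))
  expect_equal(sort(back$predecessor_cid), sort(fx$reactions$predecessor_cid))
  expect_equal(sort(back$successor_cid), sort(fx$reactions$successor_cid))
  comp_back <- read_compound_table(paths[["compounds"]])
  expect_equal(comp_back$cid, fx$compounds$cid)
  expect_equal(comp_back$exact_mass, fx$compounds$exact_mass)
})

test_that("contribution template maps endpoints and passes conditions through", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "predecessor,predecessorsmiles,successor,successorsmiles,biosystem",
    "atrazine,CCNc1nc(NC(C)C)nc(Cl)n1,ammelide,O=c1[nH]c(=O)c(N)[nH]1,soil"
  ), f)
  rec <- read_contribution_template(f)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$predecessor_name, "atrazine")
  expect_equal(rec$successor_name, "ammelide")
  expect_equal(rec$biosystem, "soil")
  expect_true(is.na(rec$predecessor_cid))
  expect_false(attr(rec, "cid_resolved"))

  # empty template
  writeLines("predecessor,predecessorsmiles,successor,successorsmiles,biosystem", f)
  expect_equal(nrow(read_contribution_template(f)), 0L)

  # template with many extra condition fields: accepted, passed through
  writeLines(c(
    "predecessor,predecessorsmiles,successor,successorsmiles,pH,temperature_C,sludge_type",
    "p1,CCO,t1,CC=O,7.2,20,activated",
    "p2,CO,t2,C=O,6.8,25,digested",
    ",,t3,CC,7.0,22,raw"
  ), f)
  rec <- read_contribution_template(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$pH, c("7.2", "6.8"))
  expect_equal(rec$sludge_type, c("activated", "digested"))
  rej <- attr(rec, "rejected")
  expect_equal(rej$row, 3L)
  expect_match(rej$reason, "predecessor")
})

test_that("exports carry the canonical columns and round-trip via generic CSV", {
  fx <- generate_fixture(fixture_spec(seed = 3, n_compounds = 14,
                                      n_reactions = 10))
  comp <- normalize_compounds(fx$compounds, fx$reactions)

  ex <- write_export(comp[1:2, ], "metfrag")
  expect_identical(names(ex$table),
                   c("Identifier", "Name", "InChIKey", "InChI", "SMILES",
                     "MolecularFormula", "MonoisotopicMass"))
  expect_equal(nrow(ex$table), 2L)
  expect_equal(ex$table$Identifier, comp$cid[1:2])
  expect_equal(ex$table$Name, comp$display_name[1:2])
  expect_equal(ex$table$SMILES, comp$smiles[1:2])

  pat <- write_export(comp[1:3, ], "patroon")
  expect_identical(names(pat$table),
                   c("Name", "InChI", "SMILES", "Formula", "ExactMass"))
  expect_equal(pat$table$ExactMass, comp$exact_mass[1:3])

  # empty selection yields a header-only file
  f <- tempfile(fileext = ".csv")
  write_export(comp[0, ], "metfrag", f)
  expect_equal(readLines(f),
               "\"Identifier\",\"Name\",\"InChIKey\",\"InChI\",\"SMILES\",\"MolecularFormula\",\"MonoisotopicMass\"")

  # generic_csv round-trip is the identity on all schema fields
  f2 <- tempfile(fileext = ".csv")
  write_export(comp, "generic_csv", f2)
  back <- read_export_csv(f2)
  for (col in c("cid", "smiles", "inchi", "inchikey", "ikfb", "formula",
                "exact_mass", "xlogp", "iupac_name", "title")) {
    expect_equal(back[[col]], comp[[col]], info = col)
  }
  expect_equal(back$display_name, comp$display_name)

  expect_error(write_export(comp, "sdf"), "unknown export format")
  expect_error(write_export(comp[c(1, 1), ], "metfrag"), "duplicated CID")
})

test_that("xlsx export writes a workbook with the canonical header", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_compounds = 14,
                                      n_reactions = 8))
  comp <- normalize_compounds(fx$compounds, fx$reactions)
  f <- tempfile(fileext = ".xlsx")
  write_export(comp[1:3, ], "xlsx", f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # read the header row back through openpyxl
  py <- Sys.which("python")
  out <- system2(py, c("-c", shQuote(paste0(
    "from openpyxl import load_workbook;",
    "ws = load_workbook('", f, "').active;",
    "print(','.join(c.value for c in ws[1]))"))), stdout = TRUE)
  expect_equal(out, paste(export_header("xlsx"), collapse = ","))
})
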