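test_that("activity fixture loads with explicit missingness", {
  acts <- bundled_fixture("activities")
  expect_equal(nrow(acts), 24)
  expect_equal(sum(!is.na(acts$ic50_uM)), 14)
  # per-compound present counts
  present <- tapply(!is.na(acts$ic50_uM), acts$compound, sum)
  expect_equal(as.vector(present[c("2H", "6H", "7H", "9H")]), c(1, 1, 6, 6))
  # missing is NA, never zero
  expect_false(any(acts$ic50_uM == 0, na.rm = TRUE))
})

test_that("quantum fixtures load 2 phases x 4 compounds; suspect row is skipped", {
  en <- bundled_fixture("energies_dipoles")
  expect_equal(nrow(en), 8)
  expect_setequal(unique(en$phase), c("gas", "aqueous"))
  expect_setequal(unique(en$compound), c("2H", "6H", "7H", "9H"))

  q <- bundled_fixture("reactivity_inputs")
  expect_equal(nrow(q), 7)                    # duplicate 9H row dropped
  expect_false("9H" %in% q$compound[q$phase == "gas"])
  q_all <- bundled_fixture("reactivity_inputs", skip_suspect = FALSE)
  expect_equal(nrow(q_all), 8)
  expect_true(sum(q_all$suspect) == 1)
})

test_that("bundled fixtures match spot-checked printed cells", {
  bl <- bundled_fixture("bondlengths_tu")
  expect_equal(bl$experimental[bl$parameter == "R(C2,S8)"], 1.683)
  db <- bundled_fixture("docking_beta")
  r6 <- db[db$compound == "6H", ]
  expect_equal(r6$target, "topo2b")
  expect_equal(r6$dg_kcalmol, -10.07)
  expect_equal(r6$ki_nM, 41.62)
  expect_equal(r6$n_hbonds, 4)
  pc <- bundled_fixture("physchem")
  expect_equal(pc$mw_da[pc$compound == "Etoposide"], 588.56)
  sar <- bundled_fixture("sar_properties")
  expect_equal(sar$vol_A3[sar$compound == "9H"], 1070.91)
})

test_that("fixture checksums have not drifted", {
  expect_equal(
    fixture_checksums(),
    c(bondlengths_tu    = "75d56987d493d413000f9d6b6dd0a39e",
      energies_dipoles  = "ac641062adafc8f06e6fceab22ea7f86",
      reactivity_inputs = "b3cbb84d050bea941236c1b187fe25bd",
      physchem          = "b151d6d067d703cbca4e77ed61f4b96c",
      sar_properties    = "185457fcefd09a008334c4fda2bd04e7",
      activities        = "997d382c9827f963e4e3a37285ed55c2",
      docking_alpha     = "ae13ff8be56c3f2e1e7a8a12ac7cf4d8",
      docking_beta      = "4793e187001b6e4633fdd2f5ba17bf5b"))
})

test_that("write/load round-trips every fixture", {
  schemas <- c(bondlengths_tu = "bondlengths", energies_dipoles = "quantum",
               reactivity_inputs = "quantum", physchem = "physchem",
               sar_properties = "sar", activities = "activity",
               docking_alpha = "docking", docking_beta = "docking")
  for (nm in names(schemas)) {
    x <- bundled_fixture(nm, skip_suspect = FALSE)
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_report(x, tmp, "csv")
    y <- load_table(tmp, schemas[[nm]], skip_suspect = FALSE)
    expect_equal(y, x, ignore_attr = TRUE)
  }
})

test_that("writing an empty collection produces a header-only loadable file", {
  acts <- bundled_fixture("activities")[0, ]
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_report(acts, tmp, "csv")
  back <- load_table(tmp, "activity")
  expect_equal(nrow(back), 0)
  expect_equal(names(back), c("compound", "cell_line", "ic50_uM"))
})

test_that("json reports carry field names as keys", {
  db <- bundled_fixture("docking_beta")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(db, tmp, "json")
  parsed <- jsonlite::read_json(tmp)
  expect_equal(length(parsed), nrow(db))
  expect_setequal(names(parsed[[1]]), names(db))
})

test_that("malformed input is rejected with informative classed errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound,cell_line\nX,HCT", tmp)
  expect_error(load_table(tmp, "activity"), "ic50_uM",
               class = "deskqsar_schema_error")

  writeLines("compound,cell_line,ic50_uM\nX,HCT,abc", tmp)
  expect_error(load_table(tmp, "activity"), "row 1",
               class = "deskqsar_parse_error")

  writeLines("compound,cell_line,ic50_uM\nX,HCT,-2", tmp)
  expect_error(load_table(tmp, "activity"), class = "deskqsar_validation_error")

  # e_homo above e_lumo violates the orbital ordering invariant
  writeLines("compound,phase,e_total_au,dipole_D,e_homo_au,e_lumo_au\nX,gas,,,-0.1,-0.2",
             tmp)
  expect_error(load_table(tmp, "quantum"), class = "deskqsar_validation_error")

  expect_error(bundled_fixture("nope"), "valid names",
               class = "deskqsar_lookup_error")
})

test_that("typeset minus and --- cells are normalized on read", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,cell_line,ic50_uM",
               "X,HCT,−2", "Y,HCT,---"), tmp)
  # U+2212 normalizes to ASCII minus, then fails the positivity invariant:
  expect_error(load_table(tmp, "activity"), class = "deskqsar_validation_error")
  writeLines(c("compound,cell_line,ic50_uM", "X,HCT,2.5", "Y,HCT,---"), tmp)
  out <- load_table(tmp, "activity")
  expect_equal(out$ic50_uM, c(2.5, NA))
})
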