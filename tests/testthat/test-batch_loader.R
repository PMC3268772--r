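# Batch migration: config parsing, code resolution with similar-key
# detection, atomic loads with rollback, loader-vs-interactive equivalence.

write_config <- function(lines) {
  f <- tempfile(fileext = ".conf")
  writeLines(lines, f)
  f
}

test_that("parse_loader_config validates modes, keys and paths", {
  sheet <- tempfile(fileext = ".csv")
  write.csv(data.frame(external_id = "A", species = "BOS",
                       material_type = "BLOOD", amount = 1, unit = "ml"),
            sheet, row.names = FALSE)
  cfg <- parse_loader_config(write_config(c(
    "mode = samples_and_final", "project = P1",
    paste0("samples = ", sheet))))
  expect_s3_class(cfg, "genolims_loader_config")
  expect_equal(cfg$mode, "samples_and_final")
  expect_equal(cfg$id_system, "default")

  expect_error(parse_loader_config(write_config("project = P1")),
               class = "genolims_config_error")      # missing mode
  expect_error(parse_loader_config(write_config("mode = everything")),
               class = "genolims_config_error")      # invalid mode
  expect_error(parse_loader_config(write_config(c(
    "mode = samples_and_final", "project = P1", "samples = /nope.csv"))),
    class = "genolims_config_error")                 # dangling path

  # duplicate key: last wins, warning recorded; unknown keys warn
  cfg2 <- parse_loader_config(write_config(c(
    "mode = individuals_only", "mode = final_only", "project = P1",
    paste0("microsats = ", sheet), "markers = MK01", "colour = blue")))
  expect_equal(cfg2$mode, "final_only")
  warns <- attr(cfg2, "warnings")
  expect_true(any(grepl("duplicate key 'mode'", warns)))
  expect_true(any(grepl("unknown key 'colour'", warns)))
})

test_that("resolve_code folds case, warns on similar keys, never merges them", {
  db <- tmp_db()
  add_code(db, "SPECIES", "BOS TAURUS", "cattle")
  add_code(db, "BREED", "Holstein")
  rep <- genolims:::new_load_report()
  # exact case-insensitive match: existing code, no warning
  id <- resolve_code(db, "SPECIES", "Bos taurus", rep)
  expect_equal(id, get_code(db, "SPECIES", "BOS TAURUS")$code_id)
  expect_equal(nrow(rep$similar_keys), 0L)
  # distance 1: new code plus a warning
  id2 <- resolve_code(db, "BREED", "Holstien", rep)
  expect_false(id2 == get_code(db, "BREED", "Holstein")$code_id)
  expect_equal(rep$similar_keys$candidate, "Holstein")
  expect_equal(rep$similar_keys$distance, 1L)
  # brute-force edit-distance oracle over all codes of the class
  for (cand in list_codes(db, "BREED")$short_name)
    expect_equal(oracle_edit_distance(tolower(cand), tolower("Holstien")) <= 1L,
                 cand %in% rep$similar_keys$candidate ||
                   identical(cand, "Holstien"))
  expect_error(resolve_code(db, "SPECIES", ""), class = "genolims_invalid_value")
})

loader_fixture <- function(n = 20L, corrupt_row = NULL) {
  sheet <- data.frame(
    id_system = "farm", external_id = sprintf("ANI%03d", seq_len(n)),
    species = "Bos taurus", breed = c("Holstein", "Angus"),
    sex = c("F", "M"), material_type = "blood", vessel_type = "vial",
    amount = 5, unit = "ml", stringsAsFactors = FALSE)
  if (!is.null(corrupt_row)) sheet$amount[corrupt_row] <- -3
  mat <- data.frame(sample = sheet$external_id,
                    MK01_1 = "120", MK01_2 = "122",
                    stringsAsFactors = FALSE)
  mat$MK01_1[seq(1L, n, by = 5L)] <- "0"
  mat$MK01_2[seq(1L, n, by = 5L)] <- "0"
  dir <- tempfile(); dir.create(dir)
  write.csv(sheet, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(mat, file.path(dir, "genotypes.csv"), row.names = FALSE)
  writeLines(c("mode = samples_and_final", "project = Legacy",
               "purpose = genotyping", "id_system = farm",
               "samples = samples.csv", "microsats = genotypes.csv",
               "markers = MK01", "software = GeneMapper"),
             file.path(dir, "load.conf"))
  list(dir = dir, sheet = sheet, mat = mat,
       config = file.path(dir, "load.conf"))
}

test_that("run_load persists all sheet rows through the rule-checked paths", {
  fx <- loader_fixture(20L)
  db <- tmp_db()
  rep <- run_load(db, fx$config)
  expect_false(rep$rolled_back)
  expect_equal(rep$rows_processed, 20L)
  expect_equal(unname(rep$inserted["samples"]), 20L)
  expect_equal(unname(rep$inserted["organisms"]), 20L)
  expect_equal(unname(rep$inserted["microsatellites"]),
               sum(fx$mat$MK01_1 != "0"))
  # loaded data is fully traceable
  smp <- search_records(db, "samples")
  tr <- trace_sample(db, smp$sample_id[[1L]])
  expect_equal(nrow(tr$dna), 1L)
})

test_that("any row error rolls the whole load back bit-identically", {
  fx <- loader_fixture(20L, corrupt_row = 13L)
  db <- tmp_db()
  d0 <- lims_digest(db)
  rep <- run_load(db, fx$config)
  expect_true(rep$rolled_back)
  expect_match(rep$errors, "row 13")
  expect_identical(lims_digest(db), d0)
  expect_equal(length(rep$inserted), 0L)
})

test_that("atomicity holds under fault injection at random rows (property)", {
  set.seed(11)
  for (row in sample(20L, 3L)) {
    fx <- loader_fixture(20L, corrupt_row = row)
    db <- tmp_db()
    d0 <- lims_digest(db)
    rep <- run_load(db, fx$config)
    expect_true(rep$rolled_back)
    expect_identical(lims_digest(db), d0)
    lims_close(db)
  }
})

test_that("dry_run produces the full report but leaves the database unchanged", {
  fx <- loader_fixture(12L)
  db <- tmp_db()
  d0 <- lims_digest(db)
  cfg <- parse_loader_config(fx$config)
  cfg$dry_run <- TRUE
  dry <- run_load(db, cfg)
  expect_true(dry$rolled_back)
  expect_identical(lims_digest(db), d0)
  # a real run inserts exactly what the dry run reported
  cfg$dry_run <- FALSE
  real <- run_load(db, cfg)
  expect_identical(dry$inserted, real$inserted)
})

test_that("individuals_only loads are idempotent", {
  sheet <- tempfile(fileext = ".csv")
  write.csv(data.frame(external_id = c("A1", "A2"), species = "Bos taurus",
                       breed = "Holstein", sex = "F"),
            sheet, row.names = FALSE)
  cfgf <- write_config(c("mode = individuals_only",
                         paste0("individuals = ", sheet)))
  db <- tmp_db()
  run_load(db, cfgf)
  d1 <- lims_digest(db)
  rep2 <- run_load(db, cfgf)
  expect_false(rep2$rolled_back)
  expect_identical(lims_digest(db), d1)
  expect_equal(nrow(search_records(db, "organisms")), 2L)
})

test_that("batch load equals the interactive replay of the same sheets", {
  spec <- demo_spec(seed = 3L, n_samples = 80L, n_individuals = 50L,
                    n_sequences = 15L, n_microsats = 60L)
  mA <- generate_demo(spec, tempfile(fileext = ".db"), loader_compat = TRUE)
  withr::defer(lims_close(mA$db))
  configs <- demo_loader_bundle(spec, tempfile())
  dbB <- tmp_db()
  for (cf in configs) {
    rep <- run_load(dbB, cf)
    expect_false(rep$rolled_back)
  }
  expect_identical(canonical_content(mA$db), canonical_content(dbB))
  expect_identical(lims_content_signature(mA$db), lims_content_signature(dbB))
})

test_that("loader templates emit importable empty sheets", {
  dir <- tempfile()
  paths <- loader_template("samples_and_final", dir)
  sheet <- read.csv(file.path(dir, "samples.csv"))
  expect_true(all(c("external_id", "species", "material_type") %in%
                    names(sheet)))
  expect_equal(nrow(sheet), 0L)
  expect_error(loader_template("everything", tempfile()),
               class = "genolims_config_error")
})
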