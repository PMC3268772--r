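# Workflow capture: extraction, PCR, validation, electrophoresis, final
# data import, step pipelining.

workflow_fixture <- function(n = 6L, envir = parent.frame()) {
  fx <- basic_fixture(envir = envir)
  db <- fx$db
  mt <- get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id
  more <- register_samples(db, data.frame(
    organism_id = vapply(seq_len(n - 1L), function(i)
      register_individual(db, "tag", sprintf("DE-%04d", i + 1L), "BOS"),
      integer(1)),
    project_id = fx$proj, material_type_id = mt))
  fx$samples <- c(fx$smp, more)
  fx
}

test_that("extract_dna traces sources and refuses cross-project pools", {
  fx <- workflow_fixture()
  db <- fx$db
  d1 <- extract_dna(db, fx$samples[1L])
  expect_equal(dna_sources(db, d1)$sample_id, fx$samples[1L])
  d2 <- extract_dna(db, fx$samples[2:6])
  expect_equal(nrow(dna_sources(db, d2)), 5L)
  for (s in fx$samples[2:6])
    expect_true(d2 %in% trace_sample(db, s)$dna$dna_id)
  expect_error(extract_dna(db, integer(0)), class = "genolims_invalid_value")
  p2 <- add_project(db, "P2", "unknown")
  org2 <- register_individual(db, "tag", "XX-1", "BOS")
  s2 <- register_sample(db, org2, p2, "BLOOD")
  expect_error(extract_dna(db, c(fx$samples[1L], s2)),
               class = "genolims_cross_project")
})

test_that("setup_pcr builds marker and amplified rows with auto wells", {
  fx <- workflow_fixture()
  db <- fx$db
  dnas <- vapply(fx$samples[1:3], function(s) extract_dna(db, s), integer(1))
  pcr <- setup_pcr(db, dnas, c("MK01", "MK02"))
  mk <- search_records(db, "pcr_markers", list(list("pcr_id", "equals", pcr)))
  amp <- search_records(db, "amplified_samples",
                        list(list("pcr_id", "equals", pcr)))
  expect_equal(nrow(mk), 2L)
  expect_equal(nrow(amp), 3L)
  # row-major plate-order oracle: element i sits in row (i-1)%/%12, col (i-1)%%12
  oracle_wells <- vapply(seq_along(dnas), function(i)
    paste0(LETTERS[(i - 1L) %/% 12L + 1L], (i - 1L) %% 12L + 1L), "")
  expect_identical(amp$well, oracle_wells)
  expect_error(setup_pcr(db, dnas, character(0)), class = "genolims_invalid_value")
  expect_error(setup_pcr(db, integer(0), "MK01"), class = "genolims_invalid_value")
  expect_error(setup_pcr(db, dnas, "NOPE"), class = "genolims_unknown_code")
})

test_that("validation accepts the three results and stores gel blobs", {
  fx <- workflow_fixture()
  db <- fx$db
  dna <- extract_dna(db, fx$samples[1L])
  pcr <- setup_pcr(db, dna, "MK01")
  gel <- random_binary_file(512L)
  v1 <- record_validation(db, "dna", dna, "pass", gel_image = gel)
  gels <- search_records(db, "gel_images")
  expect_equal(nrow(gels), 1L)
  expect_identical(retrieve_blob(db, gels$blob_id), readBin(gel, "raw", 512L))
  v2 <- record_validation(db, "pcr", pcr, "fail")   # image skippable
  expect_equal(nrow(search_records(db, "gel_images")), 1L)
  expect_error(record_validation(db, "dna", dna, "maybe"),
               class = "genolims_invalid_value")
  expect_error(record_validation(db, "pcr", 999L, "pass"),
               class = "genolims_not_found")
})

test_that("electrophoresis stores arbitrary raw files byte-exactly", {
  fx <- workflow_fixture()
  db <- fx$db
  dna <- extract_dna(db, fx$samples[1L])
  pcr <- setup_pcr(db, dna, "MK01")
  set.seed(5)
  files <- replicate(10L, random_binary_file(sample(1:2048, 1L)))
  run <- record_electrophoresis(db, pcr, machine = "ABI 3130",
                                raw_files = files)
  blobs <- search_records(db, "blobs", list(list("run_id", "equals", run)))
  expect_equal(nrow(blobs), 10L)
  # checksum-comparison oracle, independent hashing tool
  expect_setequal(blobs$checksum, unname(tools::md5sum(files)))
  for (i in seq_len(nrow(blobs)))
    expect_identical(retrieve_blob(db, blobs$blob_id[[i]]),
                     readBin(files[[match(blobs$checksum[[i]],
                                          unname(tools::md5sum(files)))]],
                             "raw", 2048L))
  run0 <- record_electrophoresis(db, pcr)   # raw data may be absent
  expect_equal(nrow(search_records(db, "blobs",
                                   list(list("run_id", "equals", run0)))), 0L)
  expect_error(record_electrophoresis(db, pcr, raw_files = tempfile()),
               class = "genolims_io_error")
})

test_that("sequence import resolves ids, is atomic, and round-trips", {
  fx <- workflow_fixture()
  db <- fx$db
  dnas <- vapply(fx$samples[1:3], function(s) extract_dna(db, s), integer(1))
  setup_pcr(db, dnas, "MK01")
  bases <- c("ACGTRYSWKMacgt", "NNNACGT", "ACGT-ACGT")
  fa <- tempfile(fileext = ".fa")
  # resolve by DNA id, by external id, and with a description after the id
  ids <- c(as.character(dnas[1L]), "DE-0002", paste(dnas[3L], "extra words"))
  writeLines(unlist(Map(function(i, b) c(paste0(">", i), b), ids, bases)), fa)
  seq_ids <- import_sequences(db, fx$proj, fa, "MK01", software = "SEQTOOL")
  expect_length(seq_ids, 3L)
  stored <- search_records(db, "sequences")
  expect_setequal(stored$bases, bases)
  expect_equal(stored$length, nchar(stored$bases))

  # re-export and compare content (order-independent)
  sel <- merge_project_sequences(db, "MK01", fx$proj)
  parsed <- oracle_parse_fasta(export_sequences(sel, "fasta"))
  expect_setequal(unname(parsed), bases)

  # atomicity: one bad id, nothing persisted
  d0 <- lims_digest(db)
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", dnas[1L]), "ACGT", ">UNKNOWN-ID", "ACGT"), fa2)
  expect_error(import_sequences(db, fx$proj, fa2, "MK01"),
               class = "genolims_unresolved_id")
  expect_identical(lims_digest(db), d0)
  # non-IUPAC content refused
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", dnas[1L]), "ACGT123"), fa3)
  expect_error(import_sequences(db, fx$proj, fa3, "MK01"),
               class = "genolims_bad_sequence")
})

test_that("microsat import handles ploidy, missing cells and round-trips", {
  fx <- workflow_fixture()
  db <- fx$db
  dnas <- vapply(fx$samples[1:3], function(s) extract_dna(db, s), integer(1))
  mat <- data.frame(
    sample = c("DE-0001", "DE-0002", "DE-0003"),
    MK01_1 = c("120", "0", "118"), MK01_2 = c("124", "", "118"),
    MK02_1 = c("200", "202", ""), MK02_2 = c("204", "202", "0"),
    stringsAsFactors = FALSE)
  csv <- tempfile(fileext = ".csv")
  write.csv(mat, csv, row.names = FALSE)
  ids <- import_microsat_matrix(db, fx$proj, csv, c("MK01", "MK02"), "diploid")
  expect_length(ids, 4L)   # 6 cells, 2 fully missing
  # round trip up to missing-value encoding
  out <- export_microsats(db, fx$proj, "two_column_diploid",
                          markers = c("MK01", "MK02"),
                          samples = mat$sample)
  expect_equal(out$MK01_1, mat$MK01_1)
  expect_equal(out$MK01_2, c("124", "0", "118"))
  expect_equal(out$MK02_2, c("204", "202", "0"))

  # structural errors abort with nothing written
  d0 <- lims_digest(db)
  expect_error(import_microsat_matrix(db, fx$proj, csv, "MK01", "haploid"),
               class = "genolims_structural_error")
  bad <- mat; bad$sample[[2L]] <- "NOBODY"
  expect_error(import_microsat_matrix(db, fx$proj, bad,
                                      c("MK01", "MK02"), "diploid"),
               class = "genolims_unresolved_id")
  expect_identical(lims_digest(db), d0)
})

test_that("a full 134-sample diploid matrix over 2 markers yields 268 results", {
  fx <- basic_fixture()
  db <- fx$db
  mt <- get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id
  orgs <- register_individuals(db, data.frame(
    id_system = "m", external_id = sprintf("S%03d", 1:134),
    species_id = get_code(db, "SPECIES", "BOS")$code_id))
  smps <- register_samples(db, data.frame(
    organism_id = orgs, project_id = fx$proj, material_type_id = mt))
  dnas <- extract_dna_batch(db, as.list(smps))
  mat <- data.frame(sample = sprintf("S%03d", 1:134),
                    MK01_1 = "120", MK01_2 = "124",
                    MK02_1 = "200", MK02_2 = "204",
                    stringsAsFactors = FALSE)
  ids <- import_microsat_matrix(db, fx$proj, mat, c("MK01", "MK02"), "diploid")
  expect_length(ids, 268L)
})

test_that("step templates pipeline into the next step's import", {
  fx <- workflow_fixture(10L)
  db <- fx$db
  tmpl <- export_step_template(db, "prepare_samples", fx$proj)
  expect_equal(nrow(tmpl), 10L)
  expect_named(tmpl, c("sample", "protocol", "date", "operator",
                       "concentration", "dna_group"))
  # pool the first two rows, import verbatim
  tmpl$dna_group[1:2] <- "pool1"
  tmpl$date <- "2024-02-01"
  n0 <- nrow(search_records(db, "dna_extraction"))
  dnas <- import_extractions(db, fx$proj, tmpl)
  expect_length(dnas, 9L)   # 10 rows, one pooled pair
  expect_equal(nrow(dna_sources(db, dnas[[1L]])), 2L)

  # extract_dna template feeds setup_pcr
  t2 <- export_step_template(db, "extract_dna", fx$proj)
  expect_equal(nrow(t2), 9L)
  pcr <- import_pcr_sheet(db, fx$proj, t2, markers = "MK01")
  expect_equal(nrow(search_records(db, "amplified_samples",
                                   list(list("pcr_id", "equals", pcr)))), 9L)
  t3 <- export_step_template(db, "setup_pcr", fx$proj)
  expect_equal(nrow(t3), 9L)
  expect_error(export_step_template(db, "nope", fx$proj),
               class = "genolims_unknown_step")
  # empty project gives a header-only sheet
  p2 <- add_project(db, "Empty", "unknown")
  expect_equal(nrow(export_step_template(db, "prepare_samples", p2)), 0L)
})

test_that("final results always trace back to a sample and an organism", {
  m <- generate_demo(demo_spec(n_samples = 40L, n_individuals = 30L,
                               n_sequences = 8L, n_microsats = 30L),
                     tempfile(fileext = ".db"))
  withr::defer(lims_close(m$db))
  db <- m$db
  dna_tab <- search_records(db, "dna_extraction")
  smp_tab <- search_records(db, "samples")
  amp <- search_records(db, "amplified_samples")
  for (s in search_records(db, "sequences")$amplified_id) {
    dna <- amp$dna_id[amp$amplified_id == s]
    src <- dna_tab$sample_id[dna_tab$dna_id == dna]
    expect_gte(length(src), 1L)
    expect_true(all(!is.na(smp_tab$organism_id[match(src, smp_tab$sample_id)])))
  }
  for (d in search_records(db, "microsatellites")$dna_id) {
    src <- dna_tab$sample_id[dna_tab$dna_id == d]
    expect_gte(length(src), 1L)
  }
})
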