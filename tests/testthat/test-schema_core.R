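# Data model, code system, blobs, rule checker, search.

test_that("a fresh schema has exactly 23 relations and 14 seeded code classes", {
  db <- tmp_db()
  expect_length(lims_relations(db), 23L)
  expect_length(DBI::dbListTables(db$con) |> setdiff("sqlite_sequence") |>
                  intersect(lims_relations(db)), 23L)
  classes <- read_code_classes()
  expect_equal(nrow(classes), 14L)
  seeded <- search_records(db, "codes")
  expect_setequal(unique(seeded$code_class), classes$class)
  expect_true(all(seeded$short_name == "unknown"))
  # every relation has a business-rule entry; every fk names a real target
  rules <- business_rules(db)
  expect_setequal(names(rules), lims_relations(db))
})

test_that("init refuses an existing schema without overwrite", {
  path <- tempfile(fileext = ".db")
  db <- init_schema(path)
  lims_close(db)
  expect_error(init_schema(path), class = "genolims_schema_exists")
  db2 <- init_schema(path, overwrite = TRUE)
  expect_length(lims_relations(db2), 23L)
  lims_close(db2)
})

test_that("add_code enforces the closed class set and per-class uniqueness", {
  db <- tmp_db()
  code <- add_code(db, "SPECIES", "BOS", "Bos taurus")
  expect_equal(code$code_class, "SPECIES")
  expect_equal(get_code(db, "SPECIES", "BOS")$long_name, "Bos taurus")
  add_code(db, "SEX", "F", "female")
  expect_error(add_code(db, "SEX", "F", "female again"),
               class = "genolims_rule_violation")
  expect_error(add_code(db, "COLOR", "RED"), class = "genolims_unknown_class")
  # same short name in a different class is fine
  expect_silent(add_code(db, "PRIMER", "F", "forward primer"))
})

test_that("blob storage round-trips bytes exactly and records checksums", {
  db <- tmp_db()
  f <- random_binary_file(1024L * 64L)
  id1 <- store_blob(db, f)
  expect_identical(retrieve_blob(db, id1),
                   readBin(f, "raw", file.size(f)))
  # independent hashing tool agrees with the recorded checksum
  expect_identical(blob_info(db, id1)$checksum, unname(tools::md5sum(f)))
  expect_identical(blob_info(db, id1)$checksum_algo, "md5")
  # same file twice: two blobs, equal checksums
  id2 <- store_blob(db, f)
  expect_false(id1 == id2)
  expect_identical(blob_info(db, id1)$checksum, blob_info(db, id2)$checksum)
  # zero-byte file
  f0 <- tempfile(); file.create(f0)
  id0 <- store_blob(db, f0)
  expect_equal(blob_info(db, id0)$size, 0L)
  expect_identical(retrieve_blob(db, id0), raw(0))
  expect_error(store_blob(db, tempfile()), class = "genolims_io_error")
})

test_that("blob round trip holds for arbitrary random binaries (property)", {
  db <- tmp_db()
  set.seed(42)
  for (n in c(1L, 17L, 4096L)) {
    f <- random_binary_file(n)
    id <- store_blob(db, f)
    expect_identical(retrieve_blob(db, id), readBin(f, "raw", n))
  }
})

test_that("check_rules matches the brute-force rule evaluator", {
  fx <- basic_fixture()
  db <- fx$db
  cases <- list(
    list("samples", list(organism_id = fx$org)),                     # missing notnull
    list("samples", list(organism_id = 999L, project_id = fx$proj,
                         material_type_id = 1L)),                    # bad fk
    list("samples", list(organism_id = fx$org, project_id = fx$proj,
      material_type_id = get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id)),
    list("codes", list(code_class = "SEX", short_name = "F",
                       active = TRUE)),                              # duplicate
    list("transfer", list(organism_id = fx$org, id_system = "tag",
                          external_id = "DE-0001")),                 # duplicate
    list("projects", list(name = "P2")),                             # missing purpose
    list("storage", list(storage_name = "Lab")))                     # duplicate root
  for (cs in cases) {
    got <- check_rules(db, cs[[1L]], cs[[2L]])
    got_key <- sort(paste(got$rule, got$column))
    expect_identical(got_key, oracle_check_rules(db, cs[[1L]], cs[[2L]]),
                     info = paste("case:", cs[[1L]]))
  }
  expect_error(check_rules(db, "nope", list()),
               class = "genolims_unknown_relation")
})

test_that("a record rejected by check_rules is never persisted", {
  fx <- basic_fixture()
  db <- fx$db
  d0 <- lims_digest(db)
  expect_error(register_sample(db, fx$org, fx$proj, "NOT_A_CODE"),
               class = "genolims_unknown_code")
  expect_error(add_code(db, "SEX", "F"), class = "genolims_rule_violation")
  expect_identical(lims_digest(db), d0)
})

test_that("search_records filters, sorts and is monotone under added criteria", {
  fx <- basic_fixture()
  db <- fx$db
  # 500-sample fixture with varying amounts across two projects
  p2 <- add_project(db, "P2", "unknown")
  mt <- get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id
  set.seed(1)
  amounts <- round(runif(499, 0, 10), 2)
  register_samples(db, data.frame(
    organism_id = fx$org, project_id = rep(c(fx$proj, p2), length.out = 499),
    material_type_id = mt, amount = amounts, amount_unit = "ml"))
  all <- search_records(db, "samples")
  expect_equal(nrow(all), 500L)

  a <- search_records(db, "samples", list(list("project_id", "equals", p2)))
  # linear-scan oracle
  expect_equal(a$sample_id, all$sample_id[all$project_id == p2])
  ab <- search_records(db, "samples",
                       list(list("project_id", "equals", p2),
                            list("amount", "lt", 3)))
  expect_true(all(ab$sample_id %in% a$sample_id))
  expect_equal(ab$sample_id,
               all$sample_id[all$project_id == p2 & !is.na(all$amount) &
                               all$amount < 3])
  btw <- search_records(db, "samples",
                        list(list("amount", "between", c(2, 4))),
                        sort = "amount")
  expect_equal(btw$amount, sort(all$amount[!is.na(all$amount) &
                                             all$amount >= 2 & all$amount <= 4]))
  expect_error(search_records(db, "samples", list(list("nope", "equals", 1))),
               class = "genolims_unknown_column")
  expect_error(search_records(db, "samples", list(list("amount", "regex", 1))),
               class = "genolims_unknown_operator")
})

test_that("contacts, units and protocols obey their rules", {
  db <- tmp_db()
  u <- add_unit(db, "Genetics")
  expect_error(add_unit(db, "Genetics"), class = "genolims_rule_violation")
  ct <- add_contact(db, "A. Person", unit_id = u)
  expect_true(is.numeric(ct))
  expect_error(add_contact(db, ""), class = "genolims_rule_violation")
  doc <- random_binary_file(256L)
  p1 <- add_protocol(db, "Salting out", "unknown", document = doc)
  expect_error(add_protocol(db, "Salting out", "unknown"),
               class = "genolims_rule_violation")
  blob <- search_records(db, "protocols")$blob_id[[1L]]
  expect_identical(retrieve_blob(db, blob), readBin(doc, "raw", 256L))
})
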