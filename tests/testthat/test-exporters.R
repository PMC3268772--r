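# Sequence format writers (7 formats, independent-parser round trips) and
# microsatellite matrix layouts.

toy_selection <- function(equal = TRUE) {
  data.frame(
    name = c("P1_AA", "P1_BB", "P2_CC"),
    bases = if (equal) c("ACGTACGTAC", "TTGCATTGCA", "ACGT-ACGTN")
    else c("ACGTACGTAC", "TTGCAT", "ACGT"),
    stringsAsFactors = FALSE)
}

test_that("the format registry holds exactly the seven formats", {
  expect_setequal(sequence_formats(),
                  c("fasta", "nexus", "phylip", "mega", "msf", "psi-blast",
                    "pfam"))
  expect_error(export_sequences(toy_selection(), "genbank"),
               class = "genolims_unknown_format")
  expect_error(export_sequences(toy_selection()[0, ], "fasta"),
               class = "genolims_empty_selection")
})

test_that("every format round-trips through an independent parser", {
  sel <- toy_selection()
  want <- stats::setNames(sel$bases, sel$name)

  # fasta: independent grammar-based parser
  expect_identical(oracle_parse_fasta(export_sequences(sel, "fasta")), want)

  # nexus and phylip: re-parsed with ape
  nex <- tempfile(fileext = ".nex")
  export_sequences(sel, "nexus", file = nex)
  parsed <- ape::read.nexus.data(nex)
  expect_identical(toupper(vapply(parsed, paste, "", collapse = "")),
                   stats::setNames(toupper(sel$bases), sel$name))

  phy <- tempfile(fileext = ".phy")
  doc <- export_sequences(sel, "phylip", file = phy)
  aln <- ape::read.dna(phy, format = "sequential", as.character = TRUE)
  expect_identical(toupper(apply(aln, 1L, paste, collapse = "")),
                   stats::setNames(toupper(sel$bases), trimws(rownames(aln))))

  # mega / msf / psi-blast / pfam: hand-written independent parsers
  expect_identical(oracle_parse_mega(export_sequences(sel, "mega")), want)
  expect_identical(oracle_parse_msf(export_sequences(sel, "msf")), want)
  expect_identical(oracle_parse_blocked(export_sequences(sel, "psi-blast")),
                   want)
  stock <- oracle_parse_stockholm(export_sequences(sel, "pfam"))
  expect_identical(as.character(stock[sel$name]), sel$bases)
})

test_that("nexus/phylip headers carry the right dimensions", {
  sel <- toy_selection()
  nex <- export_sequences(sel, "nexus")
  expect_true(any(grepl("NTAX=3", nex) & grepl("NCHAR=10", nex)))
  phy <- export_sequences(sel, "phylip")
  expect_match(phy[[1L]], "^ 3 10$")
})

test_that("alignment formats refuse ragged input unless padded", {
  sel <- toy_selection(equal = FALSE)
  expect_silent(export_sequences(sel, "fasta"))
  for (f in setdiff(sequence_formats(), "fasta"))
    expect_error(export_sequences(sel, f), class = "genolims_ragged")
  padded <- oracle_parse_fasta(
    export_sequences(sel, "fasta"))
  doc <- export_sequences(sel, "nexus", pad = TRUE)
  got <- oracle_parse_blocked(doc[grepl("^  P", doc)])
  expect_identical(unname(got), c("ACGTACGTAC", "TTGCAT----", "ACGT------"))
})

test_that("phylip names truncate to 10 chars with a reported map", {
  sel <- data.frame(
    name = c("verylongname_project_1", "verylongname_project_2", "short"),
    bases = c("ACGT", "ACGT", "ACGT"), stringsAsFactors = FALSE)
  doc <- export_sequences(sel, "phylip")
  map <- attr(doc, "truncation_map")
  expect_equal(nrow(map), 3L)
  expect_true(all(nchar(map$phylip) <= 10L))
  expect_false(anyDuplicated(map$phylip) > 0L)
})

test_that("merge_project_sequences unions projects and disambiguates names", {
  m <- generate_demo(demo_spec(n_projects = 3L, n_samples = 45L,
                               n_individuals = 30L, n_sequences = 10L,
                               n_microsats = 20L),
                     tempfile(fileext = ".db"))
  withr::defer(lims_close(m$db))
  db <- m$db
  # project 3 is the second sequencing project: import sequences there too
  smps <- search_records(db, "samples",
                         list(list("project_id", "equals", 3L)))
  dna_tab <- search_records(db, "dna_extraction")
  dnas <- unique(dna_tab$dna_id[dna_tab$sample_id %in% smps$sample_id])
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(dnas[1:4], function(d)
    c(paste0(">", d), "ACGTACGT"))), fa)
  import_sequences(db, "Demo project 3", fa, "MK01")

  sel <- merge_project_sequences(db, "MK01",
                                 c("Demo project 1", "Demo project 3"))
  # brute-force count oracle over the sequences relation
  seqs <- search_records(db, "sequences")
  mk <- get_code(db, "PRIMER", "MK01")$code_id
  expect_equal(nrow(sel), sum(seqs$primer_id == mk))
  expect_false(anyDuplicated(sel$name) > 0L)
  expect_true(all(grepl("^Demo_project_[13]_", sel$name)))
  expect_error(merge_project_sequences(db, "MK03", "Demo project 2"),
               class = "genolims_empty_selection")
})

test_that("convert_fasta is stateless, strict about duplicates, idempotent", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a desc", "ACGT", "ACGT", ">b", "TTTTTTTT", ""), fa)
  mega <- convert_fasta(fa, "mega")
  expect_identical(oracle_parse_mega(mega),
                   c(a = "ACGTACGT", b = "TTTTTTTT"))
  # normalised fasta is a fixed point of conversion
  out1 <- tempfile(fileext = ".fa")
  convert_fasta(fa, "fasta", file = out1)
  out2 <- tempfile(fileext = ".fa")
  convert_fasta(out1, "fasta", file = out2)
  expect_identical(readLines(out1), readLines(out2))
  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), dup)
  expect_error(convert_fasta(dup, "fasta"), class = "genolims_duplicate_names")
  expect_error(convert_fasta(random_binary_file(64L), "fasta"),
               class = "genolims_bad_fasta")
})

msat_fixture <- function(envir = parent.frame()) {
  fx <- basic_fixture(envir = envir)
  db <- fx$db
  mt <- get_code(db, "MATERIAL_TYPE", "BLOOD")$code_id
  orgs <- register_individuals(db, data.frame(
    id_system = "m", external_id = c("S1", "S2"),
    species_id = get_code(db, "SPECIES", "BOS")$code_id))
  smps <- register_samples(db, data.frame(
    organism_id = orgs, project_id = fx$proj, material_type_id = mt))
  extract_dna_batch(db, as.list(smps))
  fx
}

test_that("the three microsat layouts have the documented shapes", {
  expect_setequal(microsat_layouts(),
                  c("one_column_diploid", "two_column_diploid",
                    "one_column_haploid"))
  fx <- msat_fixture()
  db <- fx$db
  import_microsat_matrix(db, fx$proj, data.frame(
    sample = c("S1", "S2"), MK01_1 = c("120", "0"), MK01_2 = c("124", "0"),
    MK02_1 = c("200", "202"), MK02_2 = c("204", "202")),
    c("MK01", "MK02"), "diploid")
  two <- export_microsats(db, fx$proj, "two_column_diploid")
  expect_equal(dim(two), c(2L, 5L))   # 1 id + 2 markers x 2 columns
  one <- export_microsats(db, fx$proj, "one_column_diploid")
  expect_equal(dim(one), c(2L, 3L))
  expect_equal(one$MK01, c("120/124", "0/0"))   # missing genotype -> 0/0
  expect_error(export_microsats(db, fx$proj, "one_column_haploid"),
               class = "genolims_layout_mismatch")
  expect_error(export_microsats(db, fx$proj, "three_column"),
               class = "genolims_unknown_format")
})

test_that("haploid data exports through the haploid layout", {
  fx <- msat_fixture()
  db <- fx$db
  import_microsat_matrix(db, fx$proj, data.frame(
    sample = c("S1", "S2"), MK01 = c("97", "0")), "MK01", "haploid")
  hap <- export_microsats(db, fx$proj, "one_column_haploid",
                          samples = c("S1", "S2"))
  expect_equal(hap$MK01, c("97", "0"))
})

test_that("exports are read-only and the spreadsheet dialect parses as XML", {
  fx <- msat_fixture()
  db <- fx$db
  import_microsat_matrix(db, fx$proj, data.frame(
    sample = "S1", MK01_1 = "120", MK01_2 = "124"), "MK01", "diploid")
  d0 <- lims_digest(db)
  f <- tempfile(fileext = ".xml")
  export_microsats(db, fx$proj, "two_column_diploid",
                   file_format = "spreadsheet", file = f)
  x <- xml2::read_xml(f)
  cells <- xml2::xml_text(xml2::xml_find_all(x, "//*[local-name()='Data']"))
  expect_true(all(c("sample", "S1", "120", "124") %in% cells))
  export_sequences(data.frame(name = "a", bases = "ACGT"), "fasta",
                   file = tempfile())
  expect_identical(lims_digest(db), d0)
})
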