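# Deterministic demo-data generator: populates a database through the
# public API only (never raw writes), so every other module is testable
# without external downloads.  A fixed seed + spec yields an identical
# database digest.  In loader-compatible mode the generator restricts
# itself to what the batch loader can express (1:1 extractions, no
# storage/contacts/users, codes created by resolve_code) and can emit its
# dataset as loader sheets + configs, closing the loop for the
# batch-vs-interactive equivalence checks.

#' Specification for the demo-data generator
#'
#' @param seed RNG seed; identical seed + spec gives an identical database
#'   digest.
#' @param n_projects Number of projects (>= 2 exercises both the
#'   sequencing and the genotyping purpose; purposes alternate).
#' @param n_individuals,n_samples,n_markers Registry sizes.
#' @param n_sequences Number of final sequences (stored in the sequencing
#'   projects).
#' @param n_microsats Number of stored genotype records (non-missing
#'   cells of the genotype matrix of the first genotyping project).
#' @param missing_rate Fraction of missing cells in the genotype matrix.
#' @param raw_file_size Size in bytes of each generated binary raw file.
#' @return A `genolims_demo_spec` list.
#' @export
demo_spec <- function(seed = 1L, n_projects = 2L, n_individuals = 60L,
                      n_samples = 100L, n_markers = 4L, n_sequences = 30L,
                      n_microsats = 150L, missing_rate = 0.05,
                      raw_file_size = 4096L) {
  spec <- list(seed = as.integer(seed), n_projects = as.integer(n_projects),
               n_individuals = as.integer(n_individuals),
               n_samples = as.integer(n_samples),
               n_markers = as.integer(n_markers),
               n_sequences = as.integer(n_sequences),
               n_microsats = as.integer(n_microsats),
               missing_rate = as.numeric(missing_rate),
               raw_file_size = as.integer(raw_file_size))
  counts <- unlist(spec[startsWith(names(spec), "n_")])
  if (any(counts < 0) || spec$missing_rate < 0 || spec$missing_rate > 1 ||
      spec$raw_file_size < 0 || spec$n_projects < 1 || spec$n_individuals < 1)
    stop_genolims("invalid demo spec", "genolims_invalid_value")
  structure(spec, class = "genolims_demo_spec")
}

demo_words <- list(
  species = c(BOS = "Bos taurus", OVIS = "Ovis aries", CAPRA = "Capra hircus"),
  breeds = c(HOLSTEIN = "Holstein-Friesian", ANGUS = "Aberdeen Angus",
             MERINO = "Merino", BOER = "Boer goat"),
  sex = c(M = "male", F = "female"),
  materials = c(BLOOD = "whole blood", TISSUE = "ear tissue", HAIR = "hair roots"),
  vessels = c(VIAL = "cryo vial", TUBE = "microcentrifuge tube"),
  methods = c(CAPILLARY = "capillary electrophoresis", GEL = "agarose gel"),
  mimetypes = c(AB1 = "ABI chromatogram", PNG = "PNG image"),
  protocol_types = c(EXTRACTION = "DNA extraction", PCR = "PCR amplification"),
  purposes = c(SEQUENCING = "Sanger sequencing", GENOTYPING = "microsatellite genotyping"),
  software = c(SEQANALYZER = "sequence analysis tool",
               GENEMAPPER = "fragment analysis tool"),
  marker_types = c(STR = "microsatellite", SEQ = "sequencing locus"))

random_bases <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = "")

random_bytes <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)

# The deterministic plan everything is generated from.  Both the
# interactive route (generate_demo) and the emitted loader sheets
# (demo_loader_bundle) render this same plan.
demo_plan <- function(spec) {
  with_seed(spec$seed, {
    markers <- sprintf("MK%02d", seq_len(spec$n_markers))
    purposes <- rep(c("SEQUENCING", "GENOTYPING"),
                    length.out = spec$n_projects)
    projects <- data.frame(
      name = sprintf("Demo project %d", seq_len(spec$n_projects)),
      purpose = purposes, stringsAsFactors = FALSE)
    organisms <- data.frame(
      external_id = sprintf("ORG%05d", seq_len(spec$n_individuals)),
      species = sample(names(demo_words$species), spec$n_individuals, TRUE),
      breed = sample(names(demo_words$breeds), spec$n_individuals, TRUE),
      sex = sample(names(demo_words$sex), spec$n_individuals, TRUE),
      stringsAsFactors = FALSE)
    # one sample per individual within a project (keeps external-id row
    # keys unambiguous); an individual may appear in several projects
    project_of <- rep(seq_len(spec$n_projects), length.out = spec$n_samples)
    organism_of <- integer(spec$n_samples)
    for (p in seq_len(spec$n_projects)) {
      rows <- which(project_of == p)
      if (length(rows) > spec$n_individuals)
        stop_genolims(paste0(
          "invalid demo spec: project ", p, " would need ", length(rows),
          " distinct individuals but n_individuals = ", spec$n_individuals),
          "genolims_invalid_value")
      organism_of[rows] <- sample(seq_len(spec$n_individuals), length(rows))
    }
    samples <- data.frame(
      organism = organism_of,
      project = project_of,
      material = sample(names(demo_words$materials), spec$n_samples, TRUE),
      vessel = sample(names(demo_words$vessels), spec$n_samples, TRUE),
      amount = round(runif(spec$n_samples, 0.5, 10), 2),
      stringsAsFactors = FALSE)

    seq_projects <- which(projects$purpose == "SEQUENCING")
    gen_projects <- which(projects$purpose == "GENOTYPING")

    # pooling scheme (rich mode pools every 10th extraction with its
    # successor); final-data rows are keyed on pool representatives so a
    # DNA group is never referenced twice
    pools <- lapply(seq_len(spec$n_projects), function(p) {
      rows <- which(samples$project == p)
      groups <- list(); i <- 1L
      while (i <= length(rows)) {
        take <- if (i %% 10L == 0L && i < length(rows)) c(i, i + 1L) else i
        groups[[length(groups) + 1L]] <- rows[take]
        i <- i + length(take)
      }
      groups
    })
    reps_of <- function(p) vapply(pools[[p]], `[[`, 0L, 1L)

    # sequences: pool representatives of the first sequencing project, marker 1
    seq_rows <- if (length(seq_projects)) reps_of(seq_projects[1]) else integer(0)
    n_seq <- min(spec$n_sequences, length(seq_rows))
    sequences <- data.frame(
      sample_row = seq_rows[seq_len(n_seq)],
      bases = vapply(seq_len(n_seq), function(i)
        random_bases(sample(300:600, 1L)), ""),
      stringsAsFactors = FALSE)

    # genotype matrix: first genotyping project, all markers, exactly
    # n_microsats non-missing cells
    msat_matrix <- NULL
    if (length(gen_projects) && spec$n_microsats > 0L && spec$n_markers > 0L) {
      gen_rows <- reps_of(gen_projects[1])
      need_rows <- ceiling(spec$n_microsats / (1 - spec$missing_rate) /
                             spec$n_markers)
      if (need_rows > length(gen_rows))
        stop_genolims(paste0(
          "demo spec infeasible: n_microsats needs ", need_rows,
          " genotyping samples but only ", length(gen_rows), " exist"),
          "genolims_invalid_value")
      rows <- gen_rows[seq_len(need_rows)]
      total <- need_rows * spec$n_markers
      filled <- sort(sample(total, spec$n_microsats))
      cells <- matrix("0", need_rows, 2L * spec$n_markers)
      for (k in filled) {
        i <- (k - 1L) %/% spec$n_markers + 1L
        j <- (k - 1L) %% spec$n_markers + 1L
        a <- sort(sample(seq(100L, 300L, by = 2L), 2L, replace = TRUE))
        cells[i, 2L * j - 1L] <- as.character(a[[1L]])
        cells[i, 2L * j] <- as.character(a[[2L]])
      }
      msat_matrix <- data.frame(
        sample = organisms$external_id[samples$organism[rows]],
        cells, stringsAsFactors = FALSE)
      names(msat_matrix) <- c("sample", paste0(rep(markers, each = 2L),
                                               "_", 1:2))
    }

    # binary raw files for the first sequencing project's first samples
    raw <- NULL
    if (length(seq_projects) && spec$raw_file_size > 0L) {
      raw_rows <- head(which(samples$project == seq_projects[1]), 2L)
      raw <- lapply(raw_rows, function(i) list(
        name = paste0(organisms$external_id[samples$organism[[i]]], ".ab1"),
        bytes = random_bytes(spec$raw_file_size)))
    }

    list(spec = spec, markers = markers, projects = projects,
         organisms = organisms, samples = samples, sequences = sequences,
         msat_matrix = msat_matrix, raw = raw, pools = pools,
         seq_projects = seq_projects, gen_projects = gen_projects)
  })
}

plan_samples_sheet <- function(plan, project_idx) {
  rows <- which(plan$samples$project == project_idx)
  s <- plan$samples[rows, ]
  o <- plan$organisms[s$organism, ]
  data.frame(id_system = "demo", external_id = o$external_id,
             species = o$species, breed = o$breed, sex = o$sex,
             material_type = s$material, vessel_type = s$vessel,
             amount = s$amount, unit = "ml", stringsAsFactors = FALSE)
}

plan_fasta_lines <- function(plan) {
  if (nrow(plan$sequences) == 0L) return(NULL)
  ext <- plan$organisms$external_id[
    plan$samples$organism[plan$sequences$sample_row]]
  unlist(lapply(seq_len(nrow(plan$sequences)), function(i)
    c(paste0(">", ext[[i]]), wrap_fixed(plan$sequences$bases[[i]], 60L))))
}

#' Generate a deterministic demo database
#'
#' Populates a fresh database through the public API: code vocabulary,
#' contacts and protocols, a multi-level storage tree with placements,
#' projects of both purposes, individuals, samples, pooled DNA
#' extractions, PCRs, validations with gel images, electrophoresis runs
#' with binary raw blobs, final sequences and a genotype matrix with
#' missing data, plus one user account per role.  The same seed and spec
#' always produce the same database digest.
#'
#' @param spec A [demo_spec()].
#' @param path Database file to create.
#' @param overwrite Replace an existing file.
#' @param loader_compat Restrict generation to what the batch loader can
#'   express (see [demo_loader_bundle()]); used by the equivalence tests.
#' @return A manifest list of generated record counts (plus the database
#'   digest); the open handle in element `db`.
#' @export
generate_demo <- function(spec = demo_spec(), path,
                          overwrite = FALSE, loader_compat = FALSE) {
  plan <- demo_plan(spec)
  db <- init_schema(path, overwrite = overwrite)
  with_seed(spec$seed + 1L, lims_transaction(db, {
    if (loader_compat) demo_execute_compat(db, plan)
    else demo_execute_rich(db, plan)
  }))
  manifest <- list(
    spec = spec,
    counts = c(projects = db_count(db, "projects"),
               individuals = db_count(db, "organisms"),
               samples = db_count(db, "samples"),
               dna = dbGetQuery(db$con,
                 "SELECT COUNT(DISTINCT dna_id) AS n FROM dna_extraction")$n,
               pcrs = db_count(db, "pcr_amplification"),
               sequences = db_count(db, "sequences"),
               microsatellites = db_count(db, "microsatellites"),
               blobs = db_count(db, "blobs"),
               storage_nodes = db_count(db, "storage"),
               users = db_count(db, "users")),
    digest = lims_digest(db),
    db = db)
  manifest
}

# resolve_code-based vocabulary (exactly what a loader run would create)
demo_execute_compat <- function(db, plan) {
  spec <- plan$spec
  for (p in seq_len(nrow(plan$projects))) {
    cfgish <- list(project = plan$projects$name[[p]], id_system = "demo")
    add_project(db, plan$projects$name[[p]],
                purpose = resolve_code(db, "PURPOSE", plan$projects$purpose[[p]]))
    sheet <- plan_samples_sheet(plan, p)
    load_samples_sheet(db, c(cfgish, mode = "x"), sheet, new_load_report())
    fresh <- dbGetQuery(db$con, sprintf(
      "SELECT s.sample_id FROM samples s
        WHERE s.project_id = %d AND s.sample_id NOT IN
          (SELECT sample_id FROM dna_extraction)
        ORDER BY s.sample_id", project_id_for(db, plan$projects$name[[p]])))$sample_id
    dnas <- vapply(fresh, function(s) extract_dna(db, s), integer(1))
    if (p %in% plan$seq_projects[1] && nrow(plan$sequences) > 0L) {
      marker_ids <- vapply(plan$markers, function(m)
        resolve_code(db, "PRIMER", m), integer(1))
      loader_setup_pcrs(db, dnas, marker_ids)
      fa <- tempfile(fileext = ".fasta")
      writeLines(plan_fasta_lines(plan), fa)
      import_sequences(db, plan$projects$name[[p]], fa, marker = marker_ids[[1L]],
                       software = resolve_code(db, "SOFTWARE", "SEQANALYZER"))
      unlink(fa)
      for (r in plan$raw %||% list()) {
        f <- file.path(tempdir(), r$name)
        writeBin(r$bytes, f)
        load_raw_file(db, list(project = plan$projects$name[[p]]), f)
        unlink(f)
      }
    }
    if (p %in% plan$gen_projects[1] && !is.null(plan$msat_matrix)) {
      import_microsat_matrix(
        db, plan$projects$name[[p]], plan$msat_matrix,
        markers = vapply(plan$markers, function(m)
          resolve_code(db, "PRIMER", m), integer(1)),
        ploidy = "diploid",
        software = resolve_code(db, "SOFTWARE", "GENEMAPPER"))
    }
  }
}

demo_execute_rich <- function(db, plan) {
  spec <- plan$spec
  # vocabulary with descriptive long names
  codes <- list(SPECIES = demo_words$species, BREED = demo_words$breeds,
                SEX = demo_words$sex, MATERIAL_TYPE = demo_words$materials,
                VESSEL_TYPE = demo_words$vessels, METHOD = demo_words$methods,
                MIMETYPE = demo_words$mimetypes,
                PROTOCOL_TYPE = demo_words$protocol_types,
                PURPOSE = demo_words$purposes, SOFTWARE = demo_words$software,
                MARKER_TYPE = demo_words$marker_types,
                COUNTRY = c(DE = "Germany", VN = "Vietnam"),
                LANGUAGE = c(EN = "English", DE = "German"))
  for (cl in names(codes))
    for (i in seq_along(codes[[cl]]))
      add_code(db, cl, names(codes[[cl]])[[i]], codes[[cl]][[i]])
  for (m in plan$markers) add_code(db, "PRIMER", m, paste("demo marker", m))

  unit <- add_unit(db, "Genetics Lab", "demo laboratory")
  alice <- add_contact(db, "Alice Demo", unit_id = unit, country = "DE",
                       language = "EN", email = "alice@example.org")
  bob <- add_contact(db, "Bob Demo", unit_id = unit, country = "VN",
                     language = "EN")
  prot_ext <- add_protocol(db, "Salt extraction", "EXTRACTION")
  prot_pcr <- add_protocol(db, "Standard PCR", "PCR")

  for (u in list(c("admin", "user_administrator", "full_right"),
                 c("manager", "lab_manager", "full_right"),
                 c("alice", "scientist", "write"),
                 c("guest", "visitor", "read")))
    add_user(db, u[[1L]], paste0(u[[1L]], "-pw"), u[[2L]], u[[3L]])

  # five-level storage plus a shallow two-level lab
  boxes <- integer(0)
  lab_a <- add_storage_node(db, "Lab A")
  for (f in 1:2) {
    frz <- add_storage_node(db, paste("Freezer", f), lab_a)
    for (s in 1:2) {
      shf <- add_storage_node(db, paste("Shelf", s), frz)
      rck <- add_storage_node(db, "Rack 1", shf)
      for (b in 1:2)
        boxes <- c(boxes, add_storage_node(db, paste("Box", b), rck))
    }
  }
  lab_b <- add_storage_node(db, "Lab B")
  boxes <- c(boxes, add_storage_node(db, "Benchtop fridge", lab_b))

  for (p in seq_len(nrow(plan$projects)))
    add_project(db, plan$projects$name[[p]], purpose = plan$projects$purpose[[p]],
                owner_contact_id = alice, start_date = "2020-01-01")

  code_id <- function(cl, s) get_code(db, cl, s, required = TRUE)$code_id
  code_ids <- function(cl, s) {
    tab <- list_codes(db, cl)
    tab$code_id[match(s, tab$short_name)]
  }
  org_ids <- register_individuals(db, data.frame(
    id_system = "demo", external_id = plan$organisms$external_id,
    species_id = code_ids("SPECIES", plan$organisms$species),
    breed_id = code_ids("BREED", plan$organisms$breed),
    sex_id = code_ids("SEX", plan$organisms$sex)))

  smp <- plan$samples
  sample_ids <- register_samples(db, data.frame(
    organism_id = org_ids[smp$organism],
    project_id = smp$project,
    material_type_id = code_ids("MATERIAL_TYPE", smp$material),
    vessel_type_id = code_ids("VESSEL_TYPE", smp$vessel),
    amount = smp$amount, amount_unit = "ml"))

  place_items(db, data.frame(
    item_type = "sample", item_id = sample_ids,
    storage_id = boxes[(seq_along(sample_ids) - 1L) %% length(boxes) + 1L],
    date_in = "2021-03-01"))

  # DNA extraction following the plan's pooling scheme
  dnas_by_project <- lapply(seq_len(nrow(plan$projects)), function(p) {
    extract_dna_batch(db, lapply(plan$pools[[p]], function(rows)
      sample_ids[rows]), protocol_id = prot_ext, date = "2021-04-01",
      operator_id = bob)
  })

  marker_types <- rep(c("SEQ", "STR"), length.out = length(plan$markers))
  for (p in seq_len(nrow(plan$projects))) {
    dnas <- dnas_by_project[[p]]
    if (length(dnas) == 0L) next
    for (idx in chunk_index(length(dnas), 96L))
      setup_pcr(db, dnas[idx], plan$markers, protocol_id = prot_pcr,
                date = "2021-05-01", marker_types = marker_types)
    record_validation(db, "dna", dnas[[1L]], "pass")
  }

  # electrophoresis with binary raw files on the first sequencing project
  sp <- plan$seq_projects[1]
  if (!is.na(sp) && length(sp) && !is.null(plan$raw)) {
    pcr1 <- dbGetQuery(db$con,
      "SELECT pcr_id FROM amplified_samples WHERE dna_id = ? LIMIT 1",
      params = list(dnas_by_project[[sp]][[1L]]))$pcr_id
    files <- vapply(plan$raw, function(r) {
      f <- file.path(tempdir(), r$name)
      writeBin(r$bytes, f)
      f
    }, "")
    record_electrophoresis(db, pcr1, method = "CAPILLARY", machine = "ABI 3130",
                           date = "2021-05-02", raw_files = files)
    unlink(files)
  }

  if (!is.na(sp) && length(sp) && nrow(plan$sequences) > 0L) {
    fa <- tempfile(fileext = ".fasta")
    writeLines(plan_fasta_lines(plan), fa)
    import_sequences(db, plan$projects$name[[sp]], fa,
                     marker = plan$markers[[1L]], software = "SEQANALYZER")
    unlink(fa)
  }
  gp <- plan$gen_projects[1]
  if (!is.na(gp) && length(gp) && !is.null(plan$msat_matrix))
    import_microsat_matrix(db, plan$projects$name[[gp]], plan$msat_matrix,
                           markers = plan$markers, ploidy = "diploid",
                           software = "GENEMAPPER")
  invisible(NULL)
}

#' Emit the demo dataset as batch-loader sheets and configurations
#'
#' Writes, per project, a samples sheet plus (where applicable) the
#' genotype matrix, the FASTA file, binary raw files and a loader
#' configuration, all rendered from the same deterministic plan as
#' [generate_demo()].  Loading every emitted configuration into a fresh
#' database is content-equivalent to `generate_demo(spec, loader_compat =
#' TRUE)`.
#'
#' @param spec A [demo_spec()].
#' @param dir Output directory (created).
#' @return Character vector of the written config file paths.
#' @export
demo_loader_bundle <- function(spec, dir) {
  plan <- demo_plan(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  configs <- character(0)
  for (p in seq_len(nrow(plan$projects))) {
    pd <- file.path(dir, sprintf("project%d", p))
    dir.create(pd, showWarnings = FALSE)
    write.csv(plan_samples_sheet(plan, p), file.path(pd, "samples.csv"),
              row.names = FALSE)
    cfg <- c("mode = samples_and_final",
             paste0("project = ", plan$projects$name[[p]]),
             paste0("purpose = ", plan$projects$purpose[[p]]),
             "id_system = demo",
             paste0("samples = ", file.path(pd, "samples.csv")))
    if (p %in% plan$seq_projects[1] && nrow(plan$sequences) > 0L) {
      writeLines(plan_fasta_lines(plan), file.path(pd, "sequences.fasta"))
      cfg <- c(cfg, paste0("fasta = ", file.path(pd, "sequences.fasta")),
               paste0("fasta_marker = ", plan$markers[[1L]]),
               paste0("markers = ", paste(plan$markers, collapse = ",")),
               "software = SEQANALYZER")
      if (!is.null(plan$raw)) {
        rd <- file.path(pd, "raw")
        dir.create(rd, showWarnings = FALSE)
        for (r in plan$raw) writeBin(r$bytes, file.path(rd, r$name))
        cfg[1] <- "mode = samples_raw_and_final"
        cfg <- c(cfg, paste0("raw_dir = ", rd))
      }
    }
    if (p %in% plan$gen_projects[1] && !is.null(plan$msat_matrix)) {
      write.csv(plan$msat_matrix, file.path(pd, "genotypes.csv"),
                row.names = FALSE)
      cfg <- c(cfg, paste0("microsats = ", file.path(pd, "genotypes.csv")),
               paste0("markers = ", paste(plan$markers, collapse = ",")),
               "software = GENEMAPPER")
    }
    writeLines(cfg, file.path(pd, "load.conf"))
    configs <- c(configs, file.path(pd, "load.conf"))
  }
  configs
}
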