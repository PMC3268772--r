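# Canonical, surrogate-id-free rendering of database content.  Two
# databases built through different routes (interactive API vs batch
# loader) in different insertion orders compare equal here iff they hold
# the same information: foreign keys are dereferenced to natural keys
# (code short names, external ids, storage paths, blob checksums) and
# rows are sorted on the rendered form.

# paste0 recycles length-1 constants against zero-length vectors; these
# helpers keep empty relations empty
paste0_empty <- function(x, ...) if (length(x) == 0L) character(0) else paste0(x, ...)

canon_sort <- function(df) {
  if (nrow(df) <= 1L) { rownames(df) <- NULL; return(df) }
  key <- do.call(paste, c(lapply(df, as.character), sep = "\r"))
  df <- df[order(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Canonical content of a database
#'
#' Renders every relation with surrogate ids replaced by natural keys and
#' rows sorted, so content can be compared across databases regardless of
#' id assignment or insertion order.  Used by the batch-vs-interactive
#' equivalence checks.
#'
#' @param db A database handle.
#' @return Named list of data.frames.
#' @export
canonical_content <- function(db) {
  q <- function(sql) dbGetQuery(db$con, sql)
  shorts <- q("SELECT code_id, code_class, short_name FROM codes")
  code_nk <- function(ids) ifelse(is.na(ids), NA_character_,
    paste0(shorts$code_class, ":", shorts$short_name)[match(ids, shorts$code_id)])

  transfer <- q("SELECT organism_id, id_system, external_id FROM transfer
                 ORDER BY id_system, external_id")
  org_nk_tab <- vapply(split(paste0_empty(transfer$id_system, ":",
                                          transfer$external_id),
                             transfer$organism_id),
                       paste, "", collapse = "|")
  org_nk <- function(ids) unname(org_nk_tab[as.character(ids)])

  contacts <- q("SELECT * FROM contacts")
  contact_nk <- function(ids) contacts$name[match(ids, contacts$contact_id)]
  units <- q("SELECT * FROM unit")
  unit_nk <- function(ids) units$name[match(ids, units$unit_id)]
  projects <- q("SELECT * FROM projects")
  project_nk <- function(ids) projects$name[match(ids, projects$project_id)]
  protocols <- q("SELECT * FROM protocols")
  protocol_nk <- function(ids) ifelse(is.na(ids), NA_character_,
    paste0(code_nk(protocols$protocol_type_id), "/", protocols$name)[
      match(ids, protocols$protocol_id)])
  blobs <- q("SELECT blob_id, checksum, size, filename, run_id FROM blobs")
  blob_nk <- function(ids) blobs$checksum[match(ids, blobs$blob_id)]

  # samples: natural key + ordinal among identical tuples (id order)
  samples <- q("SELECT * FROM samples ORDER BY sample_id")
  smp_base <- paste(project_nk(samples$project_id), org_nk(samples$organism_id),
                    code_nk(samples$material_type_id),
                    code_nk(samples$vessel_type_id),
                    samples$amount, samples$amount_unit, sep = "\r")
  ord <- stats::ave(seq_along(smp_base), smp_base, FUN = seq_along)
  smp_nk_tab <- paste0_empty(smp_base, "\r#", ord)
  sample_nk <- function(ids) smp_nk_tab[match(ids, samples$sample_id)]

  dna <- q("SELECT * FROM dna_extraction ORDER BY dna_extraction_id")
  dna_groups <- split(dna, dna$dna_id)
  dna_base <- vapply(dna_groups, function(g)
    paste(paste(sort(sample_nk(g$sample_id)), collapse = "|"),
          protocol_nk(g$protocol_id[[1L]]), g$date[[1L]],
          g$concentration[[1L]], contact_nk(g$contact_id[[1L]]), sep = "\r"), "")
  dord <- stats::ave(seq_along(dna_base), dna_base, FUN = seq_along)
  dna_nk_tab <- setNames(paste0_empty(dna_base, "\r#", dord), names(dna_groups))
  dna_nk <- function(ids) unname(dna_nk_tab[as.character(ids)])

  storage <- q("SELECT * FROM storage")
  node_path <- function(id) {
    out <- character(0)
    while (!is.na(id)) {
      i <- match(id, storage$storage_id)
      out <- c(storage$storage_name[[i]], out)
      id <- storage$parent_id[[i]]
    }
    paste(out, collapse = " / ")
  }
  storage_nk <- function(ids) vapply(ids, function(i)
    if (is.na(i)) NA_character_ else node_path(i), "")

  pcr_m <- q("SELECT * FROM pcr_markers")
  pcr_a <- q("SELECT * FROM amplified_samples ORDER BY amplified_id")
  pcrs <- q("SELECT * FROM pcr_amplification ORDER BY pcr_id")
  pcr_nk_tab <- vapply(pcrs$pcr_id, function(p) {
    mk <- sort(code_nk(pcr_m$primer_id[pcr_m$pcr_id == p]))
    am <- pcr_a[pcr_a$pcr_id == p, ]
    paste(protocol_nk(pcrs$protocol_id[match(p, pcrs$pcr_id)]),
          pcrs$date[match(p, pcrs$pcr_id)],
          paste(mk, collapse = "|"),
          paste(sort(paste0(dna_nk(am$dna_id), "@", am$well)), collapse = "|"),
          sep = "\r")
  }, "")
  pcr_nk <- function(ids) pcr_nk_tab[match(ids, pcrs$pcr_id)]
  amp_nk <- function(ids) {
    i <- match(ids, pcr_a$amplified_id)
    paste0_empty(pcr_nk(pcr_a$pcr_id[i]), "\r", dna_nk(pcr_a$dna_id[i]))
  }

  vali <- q("SELECT * FROM validation ORDER BY validation_id")
  target_nk <- ifelse(vali$target_type == "dna", dna_nk(vali$target_id),
                      pcr_nk(vali$target_id))
  vali_nk <- function(ids) {
    i <- match(ids, vali$validation_id)
    paste(vali$target_type[i], target_nk[i], vali$result[i], sep = "\r")
  }

  runs <- q("SELECT * FROM electrophoresis ORDER BY run_id")
  run_nk <- function(ids) {
    i <- match(ids, runs$run_id)
    ifelse(is.na(i), NA_character_,
           paste(pcr_nk(runs$pcr_id[i]), code_nk(runs$method_id[i]),
                 runs$machine[i], runs$date[i], sep = "\r"))
  }

  seqs <- q("SELECT * FROM sequences")
  msats <- q("SELECT * FROM microsatellites")
  placements <- q("SELECT * FROM storage_samples")
  coll <- q("SELECT * FROM sample_collection")
  gels <- q("SELECT * FROM gel_images")
  users <- q("SELECT u.login, u.active, r.system_role, r.db_role
              FROM users u LEFT JOIN user_roles r ON r.user_id = u.user_id")

  list(
    codes = canon_sort(q("SELECT code_class, short_name, long_name, active
                          FROM codes")),
    unit = canon_sort(units[c("name", "description")]),
    contacts = canon_sort(data.frame(
      name = contacts$name, unit = unit_nk(contacts$unit_id),
      country = code_nk(contacts$country_id),
      language = code_nk(contacts$language_id),
      email = contacts$email, phone = contacts$phone)),
    protocols = canon_sort(data.frame(
      type = code_nk(protocols$protocol_type_id), name = protocols$name,
      doc = blob_nk(protocols$blob_id), description = protocols$description)),
    projects = canon_sort(data.frame(
      name = projects$name, purpose = code_nk(projects$purpose_id),
      owner = contact_nk(projects$owner_contact_id),
      start_date = projects$start_date)),
    organisms = canon_sort({
      o <- q("SELECT * FROM organisms")
      data.frame(ids = org_nk(o$organism_id), species = code_nk(o$species_id),
                 breed = code_nk(o$breed_id), sex = code_nk(o$sex_id),
                 birth_date = o$birth_date, comment = o$comment)
    }),
    samples = canon_sort(data.frame(nk = smp_nk_tab, comment = samples$comment)),
    storage = canon_sort(data.frame(path = storage_nk(storage$storage_id))),
    storage_samples = canon_sort(data.frame(
      item = paste0_empty(placements$item_type, "\r",
                          ifelse(placements$item_type == "sample",
                                 sample_nk(placements$item_id),
                                 dna_nk(placements$item_id))),
      node = storage_nk(placements$storage_id),
      date_in = placements$date_in, date_out = placements$date_out,
      position = placements$position_label)),
    sample_collection = canon_sort(data.frame(
      sample = sample_nk(coll$sample_id), contact = contact_nk(coll$contact_id),
      date = coll$date, comment = coll$comment)),
    dna_extraction = canon_sort(data.frame(nk = unname(dna_nk_tab))),
    pcr = canon_sort(data.frame(nk = unname(pcr_nk_tab))),
    validation = canon_sort(data.frame(
      nk = vali_nk(vali$validation_id), comment = vali$comment)),
    gel_images = canon_sort(data.frame(
      validation = vali_nk(gels$validation_id), blob = blob_nk(gels$blob_id))),
    electrophoresis = canon_sort(data.frame(nk = run_nk(runs$run_id))),
    blobs = canon_sort(data.frame(
      checksum = blobs$checksum, size = blobs$size, filename = blobs$filename,
      run = run_nk(blobs$run_id))),
    sequences = canon_sort(data.frame(
      amplified = amp_nk(seqs$amplified_id), marker = code_nk(seqs$primer_id),
      bases = seqs$bases, software = code_nk(seqs$software_id),
      length = seqs$length)),
    microsatellites = canon_sort(data.frame(
      project = project_nk(msats$project_id), dna = dna_nk(msats$dna_id),
      marker = code_nk(msats$primer_id), allele1 = msats$allele1,
      allele2 = msats$allele2, software = code_nk(msats$software_id))),
    users = canon_sort(users))
}

#' Digest of the canonical content (surrogate-id independent)
#' @param db A database handle.
#' @return A hex digest string.
#' @export
lims_content_signature <- function(db) {
  digest::digest(canonical_content(db), algo = "md5")
}
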