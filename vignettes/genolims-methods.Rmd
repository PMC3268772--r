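---
title: "genolims: data model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genolims: data model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

genolims is a headless LIMS for labs running Sanger-sequencing and
microsatellite-genotyping projects. This vignette documents the data
model, the semantics of each subsystem, the numerical and formatting
choices, what the demo-data generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

## The data model

The store is a single SQLite file holding exactly 23 relations in three
groups:

1. *Initial data*: `codes`, `unit`, `contacts`, `blobs`, `protocols`.
   All enumerable foreign keys live in the one `codes` relation, grouped
   by a **closed set of 14 classes** (species, breed, sex, material type,
   vessel type, marker type, primer, method, mimetype, protocol type,
   purpose, software, country, language). Codes within a class are open:
   users add them as needed, and every class is seeded with a sentinel
   `unknown` code so incomplete historical data can always be loaded.
2. *Sample management*: `organisms` + `transfer` (an individual may carry
   any number of `(id_system, external_id)` pairs, accommodating ear
   tags, herd books, field numbers, ...), `storage`, `samples`,
   `storage_samples`.
3. *Workflow*: `sample_collection`, `dna_extraction`, `pcr_amplification`,
   `pcr_markers`, `amplified_samples`, `validation`, `gel_images`,
   `electrophoresis`, `sequences`, `microsatellites`.

`projects`, `users` and `user_roles` complete the count of 23. Two
modelling points keep that count without auxiliary link tables:

* A pooled DNA extraction is stored as one `dna_extraction` row per
  source sample, all sharing a `dna_id` group identifier — the relation
  itself carries the traces of the original samples.
* Raw electrophoresis files are `blobs` rows with a nullable run
  reference; all binary content (gel images, chromatograms, protocol
  documents, archives) lives in the single blob relation, stored
  byte-exactly with an MD5 checksum (algorithm name recorded alongside)
  that is re-verified on every read.

## The business-rule layer

The model file (`inst/extdata/schema_rules.txt`) declares, per relation,
column types and the rule set: not-null columns, unique column sets, and
foreign keys (either `code:<CLASS>` or `ref:<relation>.<column>`). The
rule vocabulary is deliberately restricted to those four kinds.
`check_rules()` evaluates a candidate record against them and returns
violations as data; every write path — interactive or batch — calls it
inside a transaction and refuses to persist on any violation. Uniqueness
treats NULLs as equal (so two root storage nodes cannot share a name),
and empty strings count as missing for not-null purposes.

Dates are ISO `YYYY-MM-DD` text throughout; quantities are plain reals
with a free-text unit (`5.0 ml` of blood, `2 units` of filter paper —
the unit is data, not schema).

## Storage tree

Physical storage is a forest of at most **five levels** held as an
adjacency list (`storage_id`, `storage_name`, `parent_id`). Level 1 is a
location (lab, room), level 5 a box or vessel. Placements attach samples
or DNA to *leaf* nodes only; interior placements are refused (the depth
of a leaf is not fixed, so a two-level lab with a benchtop fridge is
legal). An item has at most one open placement; moving it requires an
explicit check-out that closes the old placement with a `date_out`,
keeping the full movement history. Node moves are allowed only when the
re-rooted subtree still respects the depth bound and no cycle arises.

## Batch loader

Historical data migrates from CSV spreadsheets under a name/value
configuration file with four modes (`individuals_only`,
`samples_and_final`, `samples_raw_and_final`, `final_only`). The load
order is fixed — codes, contacts, project, organisms, samples, DNA, PCR,
electrophoresis, final data — so forward references never occur.
Everything runs in one transaction through the same rule-checked write
paths as interactive entry: on any row error the database is
bit-identical to its pre-load state (verified by whole-state digests),
and `dry_run` executes everything and then rolls back unconditionally
while still producing the complete report.

Foreign-key values from sheets go through `resolve_code()`: an exact
case-insensitive match reuses the existing code; otherwise a new code is
created **and** the class is scanned for similarly spelt keys. The
similarity metric is optimal string alignment (Levenshtein plus adjacent
transposition) after case folding, threshold 1 — chosen because typo
pairs like `Holstien`/`Holstein` are one transposition apart, which plain
Levenshtein counts as 2. Near matches produce warnings for post-hoc
review; they are never merged silently.

Raw files in `samples_raw_and_final` mode must be named
`<sample external id>.<ext>`; each attaches to an electrophoresis run of
the PCR covering that sample's DNA (one run per PCR, created lazily).

## Final-data import

FASTA records resolve to amplified samples by the first
whitespace-delimited token of the record id, matched (a) against the DNA
group id, then (b) against a source-sample external id; ambiguity in
either direction is an error, and one unresolvable id aborts the whole
import. Sequences are validated against the IUPAC nucleotide alphabet
(case-insensitive, gaps allowed).

Genotype matrices are CSV with a key column and, per marker, two columns
(`M_1`, `M_2`) for diploid data or one (`M`) for haploid. Empty cells and
`"0"` are missing — the de-facto convention of microsatellite tools — and
are stored as an explicit missing state. A cell is stored when at least
one allele is present. A column count that disagrees with the declared
markers × ploidy is a structural error and nothing is written.

## Exporters

All seven sequence writers are deterministic. Everything except FASTA is
an alignment format and refuses ragged sequences unless `pad = TRUE`
right-pads with `-`. Dialect choices, each verified in the test suite by
an independent parser (ape for NEXUS/PHYLIP, hand-written grammar-based
parsers otherwise):

* **NEXUS**: a sequential `DATA` block with `NTAX`/`NCHAR` and
  `DATATYPE=DNA MISSING=? GAP=-`.
* **PHYLIP**: sequential, names padded to exactly 10 characters;
  truncation preserves uniqueness via `_k` suffixes and the map is
  attached to the document as the `truncation_map` attribute.
* **MEGA**: the minimal `#mega` / `#id` flavour accepted by common
  parsers.
* **MSF**: GCG format with per-sequence GCG checksums
  (`sum((pos-1) mod 57 + 1) * ascii`, mod 10000).
* **PSI-BLAST**: blocked `name sequence` query-anchored text.
* **PFAM**: the Stockholm-style one-line-per-sequence dialect
  (`# STOCKHOLM 1.0` ... `//`).

Genotype exports produce one row per sample (keyed by the DNA's source
sample external id) in three layouts; the one-column diploid separator is
`/` and the missing symbol `0`, both configurable but defaulted. The
spreadsheet file format is the single-file XML spreadsheet dialect
(plain text); CSV is normative for testing. Exports never write to the
database (asserted by state digests).

## Reports

The thirteen report types are a reconstruction: the upstream system names
the categories (lists of projects/contacts/individuals; samples or DNA
with storage locations per project; sequence and microsatellite
statistics per marker, per project and lab-wide; a lab data-volume
summary; a sample-distribution chart) without printing the full menu, so
the registry in `list_report_types()` is the normative list for this
package. Statistics emitted are counts, per-marker sequence length
min/mean/max, and per-marker genotype counts and allele size ranges.
Layouts come from plain-text templates under `inst/templates`, so they
can be changed without touching code; every numeric cell equals a direct
query (oracle-checked in the tests), and generation is read-only.

## Access control

Each account carries exactly one system role (SR) and one database role
(DR). The SR matrix maps the four roles to seven tasks `a`–`g`; the
published matrix gives the rows, but the task letters themselves are not
defined in the available text, so the shipped mapping is a best-effort
reconstruction (documented in the matrix file): a = manage user accounts,
b = enter/modify own workflow data, c = search/view, d = reports,
e = export, f = manage lab-wide resources, g = own account. It is
consistent with the row patterns (only the user administrator has `a`;
the visitor lacks `b` and `f`; only the lab manager has `f`). The DR
matrix grants data actions; `write` includes `read`, `full_right` is the
union of all, and `delete` is shipped as `{read, write, delete}` — the
published description says only "remove application data", and a
delete-only role that cannot read would be unusable. Both matrices are
plain-text data files; swapping them changes authorization outcomes
without a rebuild.

A handle without a bound session runs unrestricted (embedded/library
mode). Once `lims_login()` binds a session, every entry point checks the
matching task and data action; deny wins when either check fails.
Credentials are stored as salted SHA-256 digests — adequate for a lab
tool's audit trail, not a hardened password store (no key stretching).

## The demo-data generator

`generate_demo()` populates a database through the public API only. Its
defaults are the stated world of the package's tests: 2 projects (one
sequencing, one genotyping), 60 individuals, 100 samples, 4 markers, 30
final sequences, 150 genotype records, 5% missing genotype cells, 4096-
byte binary raw files. Where the build contract fixed no value, the
defaults are what a small biodiversity lab looks like: one sample per
individual within a project, amounts of 0.5–10 ml, allele sizes on an
even 100–300 bp ladder, sequence lengths of 300–600 bp, every tenth
extraction pooled with its successor. Identical seed + spec gives an
identical database digest; the genotype matrix is constructed to contain
*exactly* `n_microsats` non-missing cells with missing cells added at the
configured rate.

What it emulates: multi-level and shallow storage, pooled extractions,
both project purposes, plate-order PCR batches of ≤ 96, missing
genotypes, opaque binary raw files, one account per role. What it does
not: real chromatogram structure (blobs are random bytes — fine for a
system that treats them as opaque, useless for testing base callers),
realistic allele frequency spectra, pedigree structure, and concurrent
multi-user access. A green test therefore establishes storage,
traceability and conversion behaviour, not population-genetic realism.

`loader_compat = TRUE` restricts generation to what the batch loader can
express — codes created through `resolve_code` (no long names), 1:1
extractions, loader-shaped PCR batches, no storage/contacts/users — and
`demo_loader_bundle()` emits the same deterministic plan as loader sheets
and configurations. The batch-vs-interactive equivalence property
compares these two routes through a canonical content rendering in which
every surrogate id is replaced by natural keys (code class:short name,
external ids, storage paths, blob checksums) and rows are sorted, so the
comparison is independent of id assignment and insertion order.

## Numerical and degenerate-input choices

* Well auto-assignment is row-major `A1`..`A12`, `B1`.., up to `H12`;
  more than 96 amplified samples require explicit wells.
* Duplicate loader-config keys: last value wins, with a warning; unknown
  keys warn and are ignored.
* Display names in merged exports are `<project>_<external id>` with
  whitespace replaced by `_`; collisions get numeric suffixes `_1`, `_2`.
* Zero-byte blobs are legal (size 0, checksum of the empty string).
* A batch insert reports *all* rule violations of the batch, not just the
  first, with row indices.
* Authentication failures (unknown login, wrong secret, deactivated
  account) raise the same message, so probing cannot distinguish them.

## Known limitations

* SQLite is the only shipped backend; the DBI seam keeps the door open
  for a server-class engine but no other dialect is tested.
* One electrophoresis run belongs to one PCR (runs spanning PCRs are not
  modelled); geometric box coordinates beyond a free-text position label
  are out of scope.
* The loader's 1:1 extraction policy means pooled historical extractions
  must be migrated through the interactive API or the step-sheet import,
  which does support pooling via its `dna_group` column.
* No pedigree/kinship, phenotypes, allele binning, base calling or
  downstream analysis — final data comes from external software and
  leaves via the exporters.
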