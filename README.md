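# genolims

Laboratory information management for small-to-medium molecular genetics
labs running **Sanger sequencing** and **microsatellite (STR) genotyping**
projects.

Such labs accumulate data across many hands and years: individuals sampled
in the field under arbitrary naming schemes, biological material (blood,
tissue, hair) in freezers and boxes, DNA extractions, PCR set-ups,
validation gels, raw chromatograms from whatever sequencer was available,
and final base-called sequences and allele-size genotypes produced by
external analysis software. genolims stores all of it in one embedded
relational database with full traceability, and converts the final data
into the formats downstream population-genetics and phylogenetics tools
expect.

## The model at its core

* **A 23-relation schema** in three groups — initial data (controlled
  vocabulary `codes` in 14 closed classes, `unit`/`contacts`, `blobs`,
  `protocols`), sample management (`organisms` + `transfer` for any
  external identifier system, `storage`, `samples`, `storage_samples`) and
  workflow (`sample_collection` through `sequences`/`microsatellites`),
  plus `projects`, `users`, `user_roles`.
* **A declarative business-rule layer**: not-null, unique, foreign-key and
  type rules are read from a plain-text model file and checked by
  `check_rules()` before *every* write; a rejected record is never
  persisted (all multi-row operations are transactional).
* **A five-level storage tree** (lab → freezer → shelf → rack → box) held
  as an adjacency list; samples and DNA sit at leaf nodes, and
  `locate_item()` prints the full root-to-leaf path. Re-placement requires
  an explicit check-out, so the movement history stays auditable.
* **Raw files as opaque blobs**: gel images and chromatograms (AB1/SCF,
  any sequencer architecture) round-trip byte-exactly, with MD5 checksums
  verified on every read.
* **An atomic batch loader** for migrating historical spreadsheets: a
  name/value configuration file drives the load, foreign keys are resolved
  against the code table with similar-key detection (edit distance ≤ 1
  after case folding warns, never silently merges), and any row error
  rolls the whole load back bit-identically.
* **Exports**: sequences to FASTA, NEXUS, PHYLIP, MEGA, MSF, PSI-BLAST and
  PFAM/Stockholm (merging projects, gap padding, PHYLIP 10-character name
  truncation with a reported map); genotype matrices in one-column
  diploid (`a1/a2`), two-column diploid and one-column haploid layouts,
  missing data written as `0`.
* **Thirteen predefined reports**, dual-matrix role-based access control
  (4 system roles × 7 tasks, 5 database roles × 4 data actions; both
  matrices are editable data files), and a five-group CLI
  (`workflow`, `manage`, `report`, `export`, `admin`).

## Worked example

```r
library(genolims)

# a deterministic demo database: 2 projects (sequencing + genotyping),
# 100 samples, pooled extractions, raw blobs, final data
m  <- generate_demo(demo_spec(seed = 1), "demo.db")
db <- m$db
m$counts
#>        projects     individuals         samples             dna            pcrs
#>               2              60             100              92               2
#>       sequences microsatellites           blobs   storage_nodes           users
#>              30             150               2              21               4

# full trace of one sample: individual, storage path, workflow, final data
trace_sample(db, 1)
#> <sample trace> sample 1
#>   individual: 19 (demo:ORG00019)
#>   storage:    Lab A / Freezer 1 / Shelf 1 / Rack 1 / Box 1
#>   dna extractions: 1  raw files: 2  sequences: 1  microsatellites: 0

# merge a marker across projects and export as NEXUS (ragged ends padded)
sel <- merge_project_sequences(db, "MK01", "Demo project 1")
export_sequences(sel, "nexus", pad = TRUE, file = "mk01.nex")
#> #NEXUS
#> BEGIN DATA;
#>   DIMENSIONS NTAX=30 NCHAR=593;
#>   FORMAT DATATYPE=DNA MISSING=? GAP=-;
#>   ...

# genotype matrix, one-column diploid layout ("allele1/allele2", 0 = missing)
head(export_microsats(db, "Demo project 2", "one_column_diploid")[, 1:4], 3)
#>     sample    MK01    MK02    MK03
#> 1 ORG00008 188/202 130/188 230/236
#> 2 ORG00036 150/252 138/288 200/274
#> 3 ORG00049 140/270 174/262 132/154

# one of the 13 reports; every count equals a direct query
generate_report(db, "lab_data_volume")
#> Report: Data volume in the entire lab
#>            category count
#>            projects     2
#>         individuals    60
#>             samples   100
#>     dna_extractions    92
#>  pcr_amplifications     2
#>           sequences    30
#>     microsatellites   150
#>           raw_files     2
#>           raw_bytes  8192
```

The numbers mean: the generator registered exactly the configured 2 projects,
60 individuals and 100 samples; pooling every tenth extraction left 92 DNA
groups; 30 final sequences and exactly 150 genotype records (plus missing
cells at the configured rate) were imported through the same code paths an
interactive user would hit; and the two binary raw files of 4096 bytes
each round-tripped into blob storage.

The same dataset is usable from the command line
(`inst/cli/genolims`, or `cli_dispatch()` from R):

```sh
genolims admin demo --db demo.db --seed 1
genolims export seqs --db demo.db --marker MK01 --projects "Demo project 1" \
    --format nexus --pad --out mk01.nex
genolims report lab_data_volume --db demo.db --out volume.txt
genolims admin load --db demo.db --config migration/load.conf --dry-run
```

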