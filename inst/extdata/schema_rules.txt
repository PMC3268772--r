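# Relational model + declarative business rules.
#
# One "relation" block per table.  Column syntax:
#   column <name> <type> [notnull]
# where <type> is one of
#   id                integer surrogate primary key, assigned by the store
#   integer | number | text | date | flag | blob
#   code:<CLASS>      foreign key into codes restricted to one class
#   ref:<rel>.<col>   foreign key to another relation (any declared column)
# Other directives:
#   unique  <col>[,<col>...]   uniqueness over a column set (NULLs compare equal)
#
# Every write is validated against this file by check_rules(); the file is the
# single source of the business-rule set.

relation codes
  column code_id      id
  column code_class   text notnull
  column short_name   text notnull
  column long_name    text
  column description  text
  column active       flag notnull
  unique code_class,short_name

relation unit
  column unit_id      id
  column name         text notnull
  column description  text
  unique name

relation contacts
  column contact_id   id
  column name         text notnull
  column unit_id      ref:unit.unit_id
  column country_id   code:COUNTRY
  column language_id  code:LANGUAGE
  column email        text
  column phone        text

relation blobs
  column blob_id       id
  column filename      text
  column mimetype_id   code:MIMETYPE
  column content       blob
  column checksum      text notnull
  column checksum_algo text notnull
  column size          integer notnull
  column run_id        ref:electrophoresis.run_id

relation protocols
  column protocol_id      id
  column name             text notnull
  column protocol_type_id code:PROTOCOL_TYPE notnull
  column blob_id          ref:blobs.blob_id
  column description      text
  unique protocol_type_id,name

relation projects
  column project_id       id
  column name             text notnull
  column purpose_id       code:PURPOSE notnull
  column owner_contact_id ref:contacts.contact_id
  column start_date       date
  unique name

relation users
  column user_id    id
  column login      text notnull
  column pw_salt    text notnull
  column pw_hash    text notnull
  column contact_id ref:contacts.contact_id
  column active     flag notnull
  unique login

relation user_roles
  column user_role_id id
  column user_id      ref:users.user_id notnull
  column system_role  text notnull
  column db_role      text notnull
  unique user_id

relation organisms
  column organism_id id
  column species_id  code:SPECIES notnull
  column breed_id    code:BREED
  column sex_id      code:SEX
  column birth_date  date
  column comment     text

relation transfer
  column transfer_id id
  column organism_id ref:organisms.organism_id notnull
  column id_system   text notnull
  column external_id text notnull
  unique id_system,external_id

relation storage
  column storage_id   id
  column storage_name text notnull
  column parent_id    ref:storage.storage_id
  unique parent_id,storage_name

relation samples
  column sample_id        id
  column organism_id      ref:organisms.organism_id notnull
  column project_id       ref:projects.project_id notnull
  column material_type_id code:MATERIAL_TYPE notnull
  column vessel_type_id   code:VESSEL_TYPE
  column amount           number
  column amount_unit      text
  column comment          text

relation storage_samples
  column placement_id   id
  column item_type      text notnull
  column item_id        integer notnull
  column storage_id     ref:storage.storage_id notnull
  column date_in        date notnull
  column date_out       date
  column position_label text

relation sample_collection
  column collection_id id
  column sample_id     ref:samples.sample_id notnull
  column contact_id    ref:contacts.contact_id
  column date          date
  column comment       text

relation dna_extraction
  column dna_extraction_id id
  column dna_id            integer notnull
  column sample_id         ref:samples.sample_id notnull
  column protocol_id       ref:protocols.protocol_id
  column date              date
  column concentration     number
  column contact_id        ref:contacts.contact_id
  unique dna_id,sample_id

relation pcr_amplification
  column pcr_id      id
  column protocol_id ref:protocols.protocol_id
  column date        date
  column comment     text

relation pcr_markers
  column pcr_marker_id  id
  column pcr_id         ref:pcr_amplification.pcr_id notnull
  column primer_id      code:PRIMER notnull
  column marker_type_id code:MARKER_TYPE
  unique pcr_id,primer_id

relation amplified_samples
  column amplified_id id
  column pcr_id       ref:pcr_amplification.pcr_id notnull
  column dna_id       ref:dna_extraction.dna_id notnull
  column well         text
  unique pcr_id,dna_id

relation validation
  column validation_id id
  column target_type   text notnull
  column target_id     integer notnull
  column result        text notnull
  column comment       text

relation gel_images
  column gel_image_id  id
  column validation_id ref:validation.validation_id notnull
  column blob_id       ref:blobs.blob_id notnull

relation electrophoresis
  column run_id    id
  column pcr_id    ref:pcr_amplification.pcr_id notnull
  column method_id code:METHOD
  column machine   text
  column date      date

relation sequences
  column seq_id       id
  column amplified_id ref:amplified_samples.amplified_id notnull
  column primer_id    code:PRIMER notnull
  column bases        text notnull
  column software_id  code:SOFTWARE
  column length       integer notnull

relation microsatellites
  column msat_id     id
  column dna_id      ref:dna_extraction.dna_id notnull
  column primer_id   code:PRIMER notnull
  column allele1     integer
  column allele2     integer
  column software_id code:SOFTWARE
  column project_id  ref:projects.project_id notnull
  unique project_id,dna_id,primer_id
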