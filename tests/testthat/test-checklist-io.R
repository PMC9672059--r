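write_tiny_archive <- function(dir) {
  write_dwca(tiny_checklist()[1:4, ], dir)
  dir
}

test_that("a minimal archive reads into records with mapped statuses", {
  dir <- withr::local_tempdir()
  core <- paste(
    c(paste(c("taxonID", "scientificName", "taxonRank", "taxonomicStatus",
              "acceptedNameUsageID"), collapse = "\t"),
      "t1\tAcacia\tgenus\tAccepted\t",
      "t2\tAcacia vera\tspecies\tSynonym\tt1",
      "t3\tAcacia incerta\tspecies\tUnplaced\t"),
    collapse = "\n")
  writeLines(core, file.path(dir, "taxon.txt"))
  meta <- paste0(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    '<core encoding="UTF-8" fieldsTerminatedBy="\\t" ignoreHeaderLines="1" ',
    'rowType="http://rs.tdwg.org/dwc/terms/Taxon">',
    "<files><location>taxon.txt</location></files>",
    '<id index="0"/>',
    '<field index="0" term="http://rs.tdwg.org/dwc/terms/taxonID"/>',
    '<field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>',
    '<field index="2" term="http://rs.tdwg.org/dwc/terms/taxonRank"/>',
    '<field index="3" term="http://rs.tdwg.org/dwc/terms/taxonomicStatus"/>',
    '<field index="4" term="http://rs.tdwg.org/dwc/terms/acceptedNameUsageID"/>',
    "</core></archive>")
  writeLines(meta, file.path(dir, "meta.xml"))

  cl <- read_dwca(dir)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$taxonomic_status, c("accepted", "synonym", "unplaced"))
  syn <- cl[cl$taxonomic_status == "synonym", ]
  expect_true(nzchar(syn$accepted_name_usage_id))
  expect_equal(syn$accepted_name_usage_id, "t1")
})

test_that("reading fails loudly on missing meta.xml, duplicate ids and bad statuses", {
  dir <- withr::local_tempdir()
  expect_error(read_dwca(dir), "meta.xml")

  arch <- file.path(withr::local_tempdir(), "a")
  write_tiny_archive(arch)
  core <- readLines(file.path(arch, "taxon.txt"))
  writeLines(c(core, core[2]), file.path(arch, "taxon.txt"))
  expect_error(read_dwca(arch), "duplicate taxonID.*g1")

  arch2 <- file.path(withr::local_tempdir(), "b")
  write_tiny_archive(arch2)
  core <- readLines(file.path(arch2, "taxon.txt"))
  core[2] <- sub("accepted", "pending", core[2])
  writeLines(core, file.path(arch2, "taxon.txt"))
  expect_error(read_dwca(arch2), "unknown taxonomicStatus.*pending")
})

test_that("write/read round-trips are the identity, including at scale", {
  # hand-built fixture
  dir <- file.path(withr::local_tempdir(), "rt")
  cl <- tiny_checklist()
  write_dwca(cl, dir)
  back <- read_dwca(dir)
  expect_equal(as.data.frame(back), as.data.frame(cl), ignore_attr = TRUE)
  # a second pass is byte-identical (deterministic serialization)
  dir2 <- file.path(withr::local_tempdir(), "rt2")
  write_dwca(back, dir2)
  expect_identical(readLines(file.path(dir, "taxon.txt")),
                   readLines(file.path(dir2, "taxon.txt")))

  # synthetic checklist with ~1,000 records
  cfg <- sim_config(n_genera = 15, species_per_genus = list(mu = 15, size = 1),
                    synonyms_per_accepted = 1, seed = 3)
  big <- generate_checklist(cfg)
  dir3 <- file.path(withr::local_tempdir(), "big")
  write_dwca(big, dir3)
  back3 <- read_dwca(dir3)
  expect_equal(nrow(back3), nrow(big))
  expect_equal(as.data.frame(back3), as.data.frame(big), ignore_attr = TRUE)
})

test_that("an empty checklist writes a header-only core file in index order", {
  cl <- tiny_checklist()[0, ]
  dir <- file.path(withr::local_tempdir(), "empty")
  write_dwca(cl, dir)
  lines <- readLines(file.path(dir, "taxon.txt"))
  expect_length(lines, 1)
  expect_equal(strsplit(lines, "\t")[[1]],
               c("taxonID", "family", "genus", "specificEpithet",
                 "infraspecificEpithet", "scientificName",
                 "scientificNameAuthorship", "taxonRank", "taxonomicStatus",
                 "acceptedNameUsageID", "parentNameUsageID",
                 "originalNameUsageID", "namePublishedIn",
                 "scientificNameID", "wfoID"))
  # meta.xml declares indices 0-14 in the same order
  meta <- xml2::read_xml(file.path(dir, "meta.xml"))
  xml2::xml_ns_strip(meta)
  idx <- as.integer(xml2::xml_attr(xml2::xml_find_all(meta, ".//field"),
                                   "index"))
  expect_equal(idx, 0:14)
})

test_that("writing refuses a checklist violating record invariants", {
  bad <- tiny_checklist()
  bad$accepted_name_usage_id[bad$taxon_id == "y1"] <- ""
  expect_error(write_dwca(bad, withr::local_tempdir()),
               "missing_accepted_pointer")
})

test_that("validation reports dangling pointers without failing the read", {
  cl <- tiny_checklist()
  cl$parent_name_usage_id[cl$taxon_id == "s1"] <- "ghost"
  dir <- file.path(withr::local_tempdir(), "dang")
  # dangling parent is not a record-level invariant: write + read succeed
  write_dwca(cl, dir)
  back <- read_dwca(dir)
  issues <- validate_checklist(back)
  expect_true("dangling_parent_pointer" %in% issues$issue)
  expect_equal(issues$taxon_id[issues$issue == "dangling_parent_pointer"],
               "s1")
})

test_that("working tables read, validate headers, and convert to checklists", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- paste(c("sort_name", "plant_name_id", "ipni_id", "family",
                 "subfamily", "tribe/clade", "rank", "taxon_status",
                 "taxon_name", "place_of_publication", "volume_and_page",
                 "first_published", "geographic_area",
                 "nomenclatural_remarks", "accepted_plant_name_id",
                 "acc_ipni_id", "accepted_name", "comments", "verified"),
               collapse = ",")
  rows <- c(
    "a1,w1,,Fabaceae,Faboideae,,Genus,Accepted,Vicia L.,,,,,,,,Vicia L.,,Expert A",
    "a2,w2,,Fabaceae,Faboideae,,Species,Accepted,Vicia faba L.,,,,,,w2,,Vicia faba L.,,",
    "a3,w3,,Fabaceae,Faboideae,,Species,Orthographic,Vicia fabba L.,,,,,,w2,,Vicia faba L.,ortho,",
    "a4,w4,,Fabaceae,Faboideae,,Species,Synonym,Vicia vulgaris Gray,,,,,,w2,,Vicia faba L.,,")
  writeLines(c(hdr, rows), path)

  wr <- read_working_table(path)
  expect_equal(nrow(wr), 4)
  expect_equal(wr$verified[1], "Expert A")
  expect_equal(wr$comments[3], "ortho")

  # header-only file gives an empty collection
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, path2)
  expect_equal(nrow(read_working_table(path2)), 0)

  # missing mandatory column is named in the error
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(gsub("taxon_status,", "", hdr), path3)
  expect_error(read_working_table(path3), "taxon_status")

  cl <- working_to_dwca(wr)
  expect_equal(nrow(cl), 4)
  expect_equal(cl$taxon_id, c("w1", "w2", "w3", "w4"))
  # accepted rows get an empty accepted pointer even if self-referenced
  expect_equal(cl$accepted_name_usage_id, c("", "", "w2", "w2"))
  expect_equal(cl$taxonomic_status,
               c("accepted", "accepted", "orthographic_variant", "synonym"))
  # names split into canonical and authorship
  expect_equal(cl$scientific_name[2], "Vicia faba")
  expect_equal(cl$scientific_name_authorship[2], "L.")
  expect_equal(nrow(validate_checklist(cl)), 0)
})

test_that("a generated working table converts to an invariant-clean checklist", {
  cfg <- small_sim_config(seed = 5)
  cl <- generate_checklist(cfg)
  # project a checklist into the 19-field working dialect and back
  wt <- tibble::tibble(
    sort_name = cl$taxon_id, plant_name_id = cl$taxon_id,
    ipni_id = "", family = cl$family, subfamily = "Faboideae",
    tribe_clade = "", rank = cl$taxon_rank, taxon_status = cl$taxonomic_status,
    taxon_name = trimws(paste(cl$scientific_name,
                              cl$scientific_name_authorship)),
    place_of_publication = "", volume_and_page = "", first_published = "",
    geographic_area = "", nomenclatural_remarks = "",
    accepted_plant_name_id = cl$accepted_name_usage_id, acc_ipni_id = "",
    accepted_name = "", comments = "", verified = "")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wt, path)
  back <- working_to_dwca(read_working_table(path))
  expect_equal(nrow(back), nrow(cl))
  expect_equal(nrow(validate_checklist(back)), 0)
  expect_equal(back$scientific_name, cl$scientific_name)
  expect_equal(back$taxonomic_status, cl$taxonomic_status)
})
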