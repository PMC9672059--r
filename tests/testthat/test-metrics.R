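test_that("summaries count accepted ranks, pooled synonyms, and unplaced", {
  cl <- new_checklist(
    taxon_id = c("g", "s", "y", "u"),
    genus = c("Vicia", "Vicia", "Vicia", "Vicia"),
    specific_epithet = c("", "faba", "fabb", "ignota"),
    scientific_name = c("Vicia", "Vicia faba", "Vicia fabb", "Vicia ignota"),
    taxon_rank = c("genus", "species", "species", "species"),
    taxonomic_status = c("accepted", "accepted", "synonym", "unplaced"),
    accepted_name_usage_id = c("", "", "s", ""))
  s <- summarize_checklist(cl)
  got <- setNames(s$n, s$category)
  expect_equal(got[["genera"]], 1)
  expect_equal(got[["species"]], 1)
  expect_equal(got[["synonyms"]], 1)
  expect_equal(got[["unplaced"]], 1)
  expect_equal(got[["subspecies"]] + got[["varieties"]] + got[["forms"]], 0)

  # permutation invariance
  perm <- cl[sample(nrow(cl)), ]
  expect_equal(summarize_checklist(perm), s)

  # every pointed status pools into the synonyms bucket
  cl2 <- generate_checklist(small_sim_config(seed = 14))
  s2 <- summarize_checklist(cl2)
  got2 <- setNames(s2$n, s2$category)
  expect_equal(got2[["synonyms"]],
               sum(!cl2$taxonomic_status %in% c("accepted", "unplaced")))
  # conservation: accepted ranks + synonyms + unplaced + suprageneric rows
  supra <- sum(cl2$taxon_rank %in% c("family", "genus") &
                 cl2$taxonomic_status == "accepted")
  expect_equal(sum(got2) + supra - got2[["genera"]], nrow(cl2))
})

test_that("summary diffs are absolute, symmetric, and zero on self", {
  cl <- generate_checklist(small_sim_config(seed = 9))
  s <- summarize_checklist(cl)
  d0 <- diff_summaries(s, s)
  expect_true(all(d0$difference == 0))
  expect_equal(total_difference(d0), 0)

  # randomized summary pairs against an independent recomputation
  set.seed(77)
  for (rep in 1:10) {
    mk <- function() {
      tibble::tibble(category = c("genera", "species", "subspecies",
                                  "varieties", "forms", "synonyms"),
                     n = sample.int(5000, 6))
    }
    a <- mk()
    b <- mk()
    d <- diff_summaries(a, b)
    expect_equal(total_difference(d), sum(abs(a$n - b$n)))
    expect_equal(diff_summaries(b, a)$difference, d$difference)
    expect_equal(glance(d)$total_difference, sum(d$difference))
  }
})

test_that("verification coverage counts genera per subfamily", {
  wr <- tibble::tibble(
    sort_name = "", plant_name_id = paste0("w", 1:6), ipni_id = "",
    family = "Fabaceae",
    subfamily = c("A", "A", "A", "A", "B", "B"),
    tribe_clade = "",
    rank = c("Genus", "Species", "Genus", "Species", "Genus", "Genus"),
    taxon_status = c("Accepted", "Accepted", "Accepted", "Accepted",
                     "Accepted", "Unplaced"),
    taxon_name = c("Vicia L.", "Vicia faba L.", "Lathyrus L.",
                   "Lathyrus sylvestris L.", "Acacia Mill.",
                   "Dubiosa Anon."),
    place_of_publication = "", volume_and_page = "", first_published = "",
    geographic_area = "", nomenclatural_remarks = "",
    accepted_plant_name_id = "", acc_ipni_id = "", accepted_name = "",
    comments = "",
    verified = c("", "Expert", "", "", "", ""))
  cov <- verification_coverage(wr)
  a <- cov[cov$subfamily == "A", ]
  # two genera in A, one verified through its species record
  expect_equal(a$n_genera, 2)
  expect_equal(a$pct_verified, 50)
  b <- cov[cov$subfamily == "B", ]
  # the unplaced genus is excluded
  expect_equal(b$n_genera, 1)
  expect_equal(b$pct_verified, 0)
})

test_that("name overlap obeys its conservation identities", {
  cl <- tiny_checklist()
  other <- new_checklist(
    taxon_id = "x1", genus = "Zornia", specific_epithet = "alia",
    scientific_name = "Zornia alia", taxon_rank = "species",
    taxonomic_status = "accepted")
  # disjoint sets share nothing
  ov <- name_overlap(other, cl)
  expect_equal(ov$in_both, 0)
  expect_equal(ov$added_from_checklist, nrow(cl))
  expect_equal(ov$other_sources_only, 1)

  # checklist contained in the backbone adds nothing
  ov2 <- name_overlap(cl, cl[1:3, ])
  expect_equal(ov2$added_from_checklist, 0)
  expect_equal(ov2$in_both, 3)

  # construction oracle: deleting a known subset is recovered exactly
  cfg <- small_sim_config(seed = 23)
  big <- generate_checklist(cfg)
  deg <- degrade_backbone(big, cfg)
  ov3 <- name_overlap(build_backbone(deg$old_checklist), big)
  expect_equal(ov3$added_from_checklist, nrow(deg$manifest))
  expect_equal(ov3$other_sources_only, 0)
  expect_equal(ov3$in_both + ov3$added_from_checklist, ov3$n_checklist)
  expect_equal(ov3$in_both + ov3$other_sources_only, ov3$n_old_backbone)
  expect_equal(sum(tidy(ov3)$n[1:2]), ov3$n_checklist)
})

test_that("per-genus new-name counts respect the threshold filter", {
  cl <- tiny_checklist()
  other <- new_checklist(
    taxon_id = "x1", genus = "Zornia", specific_epithet = "alia",
    scientific_name = "Zornia alia", taxon_rank = "species",
    taxonomic_status = "accepted")
  ov <- name_overlap(other, cl)
  # threshold 0 on disjoint sets keeps every contributing genus
  all_g <- per_genus_new_names(ov, 0)
  expect_setequal(all_g$genus, "Acacia")
  # a threshold above every count empties the table
  expect_equal(nrow(per_genus_new_names(ov, 1e6)), 0)

  # construction oracle: one genus given > threshold injected names
  cfg <- small_sim_config(seed = 29)
  big <- generate_checklist(cfg)
  target <- big$genus[big$taxon_rank == "genus"][1]
  inject <- new_checklist(
    taxon_id = sprintf("inj%03d", 1:120),
    genus = target,
    specific_epithet = sprintf("novaspec%03d", 1:120),
    scientific_name = sprintf("%s novaspec%03d", target, 1:120),
    taxon_rank = "species", taxonomic_status = "accepted")
  grown <- as_grown <- dplyr::bind_rows(big, inject)
  ov4 <- name_overlap(build_backbone(big), grown)
  over100 <- per_genus_new_names(ov4, 100)
  expect_equal(over100$genus, target)
  expect_equal(over100$n_new, 120)
})
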