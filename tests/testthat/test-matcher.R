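test_that("the compiled edit distance agrees with an independent R oracle", {
  set.seed(99)
  alphabet <- letters[1:6] # small alphabet provokes transpositions
  rand_str <- function() paste(sample(alphabet, sample(0:12, 1),
                                      replace = TRUE), collapse = "")
  a <- replicate(400, rand_str())
  b <- replicate(400, rand_str())
  got <- taxacade:::.osa_pair(a, b)
  want <- mapply(osa_oracle, a, b, USE.NAMES = FALSE)
  expect_equal(got, want)
  # transposition counts as one operation
  expect_equal(taxacade:::.osa_pair("dealbata", "daelbata"), 1L)
})

test_that("an unknown epithet interprets at the genus with no species inferred", {
  bb <- build_backbone(tiny_checklist())
  res <- match_name("Acacia xyz", bb)
  expect_equal(res$interpreted_id, "g1")
  expect_equal(res$interpreted_name, "Acacia")
  expect_equal(res$interpreted_rank, "genus")
  expect_equal(res$match_type, "higher_rank_no_match")
})

test_that("exact, synonym and fuzzy stages interpret per the cascade", {
  bb <- build_backbone(tiny_checklist())

  ex <- match_name("Acacia dealbata Link", bb)
  expect_equal(ex$match_type, "exact")
  expect_equal(ex$matched_id, "s1")
  expect_equal(ex$interpreted_id, "s1")
  expect_equal(ex$interpreted_rank, "species")

  ex2 <- match_name("Acacia mearnsii", bb)
  expect_equal(ex2$match_type, "exact_canonical")
  expect_equal(ex2$interpreted_id, "s2")

  # a synonym match resolves to its accepted pointer
  syn <- match_name("Acacia decurrens Willd.", bb)
  expect_equal(syn$matched_id, "y1")
  expect_equal(syn$interpreted_id, "s1")

  # one edit away from a unique name
  fz <- match_name("Acacia dealbeta", bb)
  expect_equal(fz$match_type, "fuzzy")
  expect_equal(fz$interpreted_id, "s1")

  # matching an unplaced name falls back to the genus
  un <- match_name("Acacia dubia", bb)
  expect_equal(un$match_type, "higher_rank_unplaced")
  expect_equal(un$interpreted_id, "g1")
  expect_equal(un$interpreted_rank, "genus")

  # an unknown genus lands on the family root
  fam <- match_name("Zzyzxia nowhere", bb)
  expect_equal(fam$interpreted_rank, "family")
  expect_equal(fam$match_type, "higher_rank_no_match")
})

test_that("equally good candidates fall back to their shared genus", {
  cl <- new_checklist(
    taxon_id = c("g", "p1", "p2"),
    genus = "Vicia", specific_epithet = c("", "sativa", "sativd"),
    scientific_name = c("Vicia", "Vicia sativa", "Vicia sativd"),
    scientific_name_authorship = c("L.", "L.", "Boiss."),
    taxon_rank = c("genus", "species", "species"),
    taxonomic_status = "accepted")
  bb <- build_backbone(cl)
  # probe equidistant from both, no authorship
  amb <- match_name("Vicia sativb", bb)
  expect_equal(amb$match_type, "higher_rank_ambiguous")
  expect_equal(amb$interpreted_id, "g")
  expect_equal(amb$interpreted_rank, "genus")
  # authorship tie-break recovers a unique candidate
  tb <- match_name("Vicia sativb Boiss.", bb)
  expect_equal(tb$match_type, "fuzzy")
  expect_equal(tb$interpreted_id, "p2")
  # with the tie-break disabled the ambiguity stands
  cfg <- match_config(use_authorship_tiebreak = FALSE)
  tb2 <- match_name("Vicia sativb Boiss.", bb, cfg)
  expect_equal(tb2$match_type, "higher_rank_ambiguous")
})

test_that("an unknown infraspecific epithet falls back to the species", {
  bb <- build_backbone(tiny_checklist())
  res <- match_name("Acacia dealbata subsp. nonexistens", bb)
  expect_equal(res$interpreted_id, "s1")
  expect_equal(res$interpreted_rank, "species")
  expect_equal(res$match_type, "higher_rank_no_match")
})

test_that("matching is deterministic and total on parseable input", {
  cl <- generate_checklist(small_sim_config(seed = 31))
  bb <- build_backbone(cl)
  deg <- degrade_backbone(cl, small_sim_config(seed = 31))
  occ <- generate_occurrences(cl, 120, small_sim_config(seed = 31),
                              deleted_ids = deg$manifest$taxon_id)
  r1 <- match_batch(occ$occurrences, bb)
  r2 <- match_batch(occ$occurrences, bb)
  expect_identical(r1, r2)
  expect_false(any(is.na(r1$interpreted_id)))
})

test_that("match_batch equals element-wise match_name and preserves order", {
  cl <- generate_checklist(small_sim_config(seed = 17))
  bb <- build_backbone(cl)
  occ <- generate_occurrences(cl, 60, small_sim_config(seed = 17))
  batch <- match_batch(occ$occurrences, bb)
  expect_equal(batch$occurrence_id, occ$occurrences$occurrence_id)
  single <- dplyr::bind_rows(lapply(occ$occurrences$verbatim_name,
                                    function(v) match_name(v, bb)))
  expect_equal(dplyr::select(batch, -occurrence_id), single)

  expect_equal(nrow(match_batch(character(0), bb)), 0)

  tiny <- build_backbone(tiny_checklist())
  three <- match_batch(c("Acacia dealbata Link", "Acacia xyz",
                         "Nowhereia missingensis"), tiny)
  expect_equal(three$interpreted_rank, c("species", "genus", "family"))
})

test_that("the fuzzy stage equals a brute-force scan on random backbones", {
  # seeded sweep over small random backbones with randomly mutilated queries
  n_backbones <- 12
  n_queries <- 25
  set.seed(123)
  seeds <- sample.int(10000, n_backbones)
  cfg <- match_config()
  for (s in seeds) {
    cl <- generate_checklist(sim_config(
      n_genera = 4, species_per_genus = list(mu = 10, size = 1),
      synonyms_per_accepted = 0.5, n_ambiguity_pairs = 1, seed = s))
    bb <- build_backbone(cl)
    names_all <- cl$scientific_name
    sp <- cl[cl$taxon_rank == "species", ]
    for (qi in seq_len(n_queries)) {
      base <- sp[sample.int(nrow(sp), 1), ]
      # free-form corruption: 0-2 random edits anywhere in the epithet
      ep <- base$specific_epithet
      k <- sample(0:2, 1)
      for (e in seq_len(k)) ep <- taxacade:::random_edit(ep)
      if (nchar(ep) < 2 || !grepl("^[a-z]+$", ep)) next
      q <- paste(base$genus, ep)

      res <- match_name(q, bb)
      if (tolower(q) %in% tolower(names_all)) {
        expect_true(res$match_type %in% c("exact", "exact_canonical",
                                          "higher_rank_ambiguous",
                                          "higher_rank_unplaced"))
        next
      }
      best <- brute_force_best(q, names_all, cfg)
      if (length(best) == 0) {
        expect_true(res$match_type %in% c("higher_rank_no_match"))
      } else if (length(best) == 1) {
        if (cl$taxonomic_status[best] == "unplaced") {
          expect_equal(res$match_type, "higher_rank_unplaced")
        } else {
          expect_equal(res$matched_id, cl$taxon_id[best],
                       label = paste("query", q))
          expect_equal(res$match_type, "fuzzy")
        }
      } else {
        # several equally best: ambiguity fallback (authorship absent)
        expect_equal(res$match_type, "higher_rank_ambiguous")
      }
    }
  }
})

test_that("deleting the matched record never refines an interpretation", {
  cl <- generate_checklist(small_sim_config(seed = 41))
  cfg <- small_sim_config(seed = 41)
  bb <- build_backbone(cl)
  occ <- generate_occurrences(cl, 80, cfg)
  res <- match_batch(occ$occurrences, bb)
  depth <- function(r) match(r, c("family", "genus", "species",
                                  "infraspecific"))
  hit <- which(!is.na(res$matched_id))[1:30]
  for (i in hit[!is.na(hit)]) {
    cl2 <- cl[cl$taxon_id != res$matched_id[i], ]
    # drop records orphaned by the deletion so the backbone stays valid
    cl2 <- cl2[!(cl2$accepted_name_usage_id %in% res$matched_id[i]), ]
    attr(cl2, "ambiguity_pairs") <- attr(cl, "ambiguity_pairs")
    bb2 <- build_backbone(cl2)
    res2 <- match_name(occ$occurrences$verbatim_name[i], bb2)
    expect_lte(depth(res2$interpreted_rank), depth(res$interpreted_rank[i]))
  }
})
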