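# A small hand-built checklist: one genus, two species, one synonym, one
# unplaced record, one variety. Used across the backbone/matcher/metrics
# tests.
tiny_checklist <- function() {
  new_checklist(
    taxon_id = c("g1", "s1", "s2", "y1", "u1", "v1"),
    family = "Fabaceae",
    genus = c("Acacia", "Acacia", "Acacia", "Acacia", "Acacia", "Acacia"),
    specific_epithet = c("", "dealbata", "mearnsii", "decurrens", "dubia",
                         "dealbata"),
    infraspecific_epithet = c("", "", "", "", "", "subalpina"),
    scientific_name = c("Acacia", "Acacia dealbata", "Acacia mearnsii",
                        "Acacia decurrens", "Acacia dubia",
                        "Acacia dealbata subsp. subalpina"),
    scientific_name_authorship = c("Mill.", "Link", "De Wild.", "Willd.",
                                   "", "Tindale & Kodela"),
    taxon_rank = c("genus", "species", "species", "species", "species",
                   "subspecies"),
    taxonomic_status = c("accepted", "accepted", "accepted", "synonym",
                         "unplaced", "accepted"),
    accepted_name_usage_id = c("", "", "", "s1", "", ""),
    parent_name_usage_id = c("", "g1", "g1", "", "", "s1"),
    metadata = list(title = "Tiny fixture checklist", version = "1",
                    citation = "fixture")
  )
}

# fast small simulation settings used by the property tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_genera = 8, species_per_genus = list(mu = 8, size = 1),
             synonyms_per_accepted = 0.8, infraspecific_fraction = 0.15,
             unplaced_fraction = 0.03, degrade_fraction = 0.2,
             n_ambiguity_pairs = 2, seed = seed, ...)
}
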