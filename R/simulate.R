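#' Simulation configuration
#'
#' Parameters of the synthetic checklist / backbone-pair / occurrence-stream
#' generator. The defaults define the package's reference study conditions:
#' a family-sized checklist of roughly 5,000 names with a long-tailed
#' species-per-genus distribution, an "old backbone" formed by deleting 10%
#' of species-group names, and an occurrence stream whose verbatim names are
#' corrupted with the mix 40% exact / 20% synonym use / 15% single-edit typo
#' / 10% unknown epithet / 10% genus-only / 5% engineered ambiguity —
#' emulating the main failure modes of real occurrence streams (missing
#' names, misspellings, provider-level genus determinations).
#'
#' @param n_genera number of accepted genera.
#' @param species_per_genus list with `mu` (mean) and `size` (negative
#'   binomial dispersion; small values give the long tail that makes
#'   per-genus threshold plots non-degenerate).
#' @param synonyms_per_accepted Poisson mean of synonyms per accepted
#'   species-group name.
#' @param infraspecific_fraction probability that an accepted species also
#'   carries one infraspecific taxon.
#' @param unplaced_fraction expected unplaced records per accepted species.
#' @param degrade_fraction fraction of species-group names deleted to form
#'   the old backbone.
#' @param corruption_mix named probabilities over
#'   `exact`, `synonym_use`, `typo1`, `typo2`, `unknown_epithet`,
#'   `genus_only`, `ambiguous`; must sum to 1 (tolerance 1e-9).
#' @param n_ambiguity_pairs engineered pairs of equidistant names planted in
#'   the checklist for the `ambiguous` corruption class.
#' @param seed integer seed driving all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genera = 80,
                       species_per_genus = list(mu = 25, size = 0.8),
                       synonyms_per_accepted = 1.1,
                       infraspecific_fraction = 0.15,
                       unplaced_fraction = 0.02,
                       degrade_fraction = 0.10,
                       corruption_mix = c(exact = 0.40, synonym_use = 0.20,
                                          typo1 = 0.15, typo2 = 0,
                                          unknown_epithet = 0.10,
                                          genus_only = 0.10,
                                          ambiguous = 0.05),
                       n_ambiguity_pairs = 12,
                       seed = 1L) {
  if (n_genera < 1) stop("degenerate config: n_genera must be >= 1",
                         call. = FALSE)
  classes <- c("exact", "synonym_use", "typo1", "typo2", "unknown_epithet",
               "genus_only", "ambiguous")
  mix <- setNames(rep(0, length(classes)), classes)
  mix[names(corruption_mix)] <- corruption_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("corruption_mix must be non-negative and sum to 1", call. = FALSE)
  }
  probs <- c(infraspecific_fraction, unplaced_fraction, degrade_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_genera = as.integer(n_genera),
    species_per_genus = species_per_genus,
    synonyms_per_accepted = synonyms_per_accepted,
    infraspecific_fraction = infraspecific_fraction,
    unplaced_fraction = unplaced_fraction,
    degrade_fraction = degrade_fraction,
    corruption_mix = mix,
    n_ambiguity_pairs = as.integer(n_ambiguity_pairs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_syllables <- function() {
  con <- c("b", "c", "d", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  as.vector(outer(con, vow, paste0))
}

sim_authors <- function() {
  c("L.", "Benth.", "DC.", "(L.) DC.", "Harv.", "Baker", "Taub.",
    "(Benth.) Harv.", "Mill.", "Willd.", "Kunth", "Vogel", "E.Mey.",
    "(Willd.) Kuntze", "Schltr.", "Burch.", "Thunb.", "Guill. & Perr.",
    "Benth. ex Harv.", "Hochst.")
}

sim_word <- function(n_syllables, ending = "") {
  paste0(paste(sample(sim_syllables(), n_syllables, replace = TRUE),
               collapse = ""), ending)
}

# pronounceable epithet at OSA distance >= min_sep from every word in `used`
sim_new_word <- function(used, min_sep = 5L, endings = c("a", "um", "is",
                                                         "ensis", "oides",
                                                         "ata", "osa")) {
  for (try in 1:500) {
    w <- sim_word(sample(3:5, 1), sample(endings, 1))
    if (nchar(w) < 6) next
    if (length(used) == 0 || min(.osa_to_many(w, used)) >= min_sep) return(w)
  }
  stop("name sampler failed to find a sufficiently distinct word",
       call. = FALSE)
}

#' Generate a synthetic checklist
#'
#' Builds a hierarchical checklist (family root, genera, species,
#' infraspecific taxa) with synonym groups, a sprinkling of the other
#' pointed statuses, unplaced records, and optional engineered ambiguity
#' pairs, using pseudo-Latin names from a deterministic syllable sampler.
#' All record and referential invariants hold by construction, and every
#' pointed-status record points to an accepted record.
#'
#' Two separation rules keep corruption-class semantics unambiguous for the
#' analytic ground truth: epithets within a genus are pairwise at least 5
#' edits apart (ambiguity pairs excepted), and genus names sharing an
#' initial letter are more than 1 edit apart.
#'
#' @param config a [sim_config()].
#' @return a `taxon_checklist`; the attribute `"ambiguity_pairs"` holds the
#'   engineered pairs (`genus`, `id_a`, `id_b`, `probe`).
#' @export
generate_checklist <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_checklist_impl(config))
}

generate_checklist_impl <- function(config) {
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("T%06d", counter)
  }
  authors <- sim_authors()
  rows <- vector("list", 0)
  add_row <- function(taxon_id, genus = "", spec = "", infra = "",
                      name, auth, rank, status, accepted = "", parent = "") {
    rows[[length(rows) + 1L]] <<- c(
      taxon_id = taxon_id, family = "Fabaceae", genus = genus,
      specific_epithet = spec, infraspecific_epithet = infra,
      scientific_name = name, scientific_name_authorship = auth,
      taxon_rank = rank, taxonomic_status = status,
      accepted_name_usage_id = accepted, parent_name_usage_id = parent,
      original_name_usage_id = "", name_published_in = "",
      scientific_name_id = "", wfo_id = "")
  }
  rows_tbl <- function() {
    m <- do.call(rbind, rows)
    tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  }

  fam_id <- next_id()
  add_row(fam_id, name = "Fabaceae", auth = "Lindl.", rank = "family",
          status = "accepted")

  # genera: unique, and > 1 edit apart when sharing an initial letter
  genera <- character(0)
  while (length(genera) < config$n_genera) {
    g <- sim_word(sample(2:4, 1), sample(c("us", "a", "ia", "aria"), 1))
    substr(g, 1, 1) <- toupper(substr(g, 1, 1))
    if (nchar(g) < 5) next
    same_letter <- genera[substr(genera, 1, 1) == substr(g, 1, 1)]
    if (length(same_letter) > 0 &&
        min(.osa_to_many(tolower(g), tolower(same_letter))) <= 1) next
    genera <- c(genera, g)
  }
  genus_ids <- character(config$n_genera)
  for (k in seq_along(genera)) {
    genus_ids[k] <- next_id()
    add_row(genus_ids[k], genus = genera[k], name = genera[k],
            auth = sample(authors, 1), rank = "genus", status = "accepted",
            parent = fam_id)
  }

  used_words <- lapply(seq_along(genera), function(i) character(0))
  names(used_words) <- genera

  n_species <- pmax(1L, stats::rnbinom(config$n_genera,
                                       size = config$species_per_genus$size,
                                       mu = config$species_per_genus$mu))
  status_pool <- c(synonym = 0.80, orthographic_variant = 0.08,
                   illegitimate = 0.05, invalid = 0.03, incomplete = 0.02,
                   misapplied = 0.01, artificial_hybrid = 0.01)

  accepted_ids <- character(0) # species-group accepted, eligible as truths
  for (k in seq_along(genera)) {
    g <- genera[k]
    for (s in seq_len(n_species[k])) {
      ep <- sim_new_word(used_words[[g]])
      used_words[[g]] <- c(used_words[[g]], ep)
      sid <- next_id()
      add_row(sid, genus = g, spec = ep, name = paste(g, ep),
              auth = sample(authors, 1), rank = "species",
              status = "accepted", parent = genus_ids[k])
      accepted_ids <- c(accepted_ids, sid)

      if (stats::runif(1) < config$infraspecific_fraction) {
        iep <- sim_new_word(used_words[[g]])
        used_words[[g]] <- c(used_words[[g]], iep)
        marker <- sample(c("subsp.", "var.", "f."), 1)
        rank <- c("subsp." = "subspecies", "var." = "variety",
                  "f." = "form")[[marker]]
        iid <- next_id()
        add_row(iid, genus = g, spec = ep, infra = iep,
                name = make_canonical(g, ep, marker, iep),
                auth = sample(authors, 1), rank = rank,
                status = "accepted", parent = sid)
        accepted_ids <- c(accepted_ids, iid)
      }
    }
  }

  # synonyms and other pointed statuses, attached within the same genus
  rec_so_far <- rows_tbl()
  acc <- rec_so_far[rec_so_far$taxon_id %in% accepted_ids, ]
  for (i in seq_len(nrow(acc))) {
    k_syn <- stats::rpois(1, config$synonyms_per_accepted)
    if (k_syn == 0) next
    g <- acc$genus[i]
    gid <- genus_ids[match(g, genera)]
    for (j in seq_len(k_syn)) {
      ep <- sim_new_word(used_words[[g]])
      used_words[[g]] <- c(used_words[[g]], ep)
      st <- sample(names(status_pool), 1, prob = status_pool)
      add_row(next_id(), genus = g, spec = ep, name = paste(g, ep),
              auth = sample(authors, 1), rank = "species", status = st,
              accepted = acc$taxon_id[i], parent = gid)
    }
  }

  # unplaced species-level records
  n_unplaced <- stats::rpois(1, config$unplaced_fraction * length(accepted_ids))
  for (j in seq_len(n_unplaced)) {
    k <- sample(seq_along(genera), 1)
    g <- genera[k]
    ep <- sim_new_word(used_words[[g]])
    used_words[[g]] <- c(used_words[[g]], ep)
    add_row(next_id(), genus = g, spec = ep, name = paste(g, ep),
            auth = sample(authors, 1), rank = "species", status = "unplaced",
            parent = genus_ids[k])
  }

  # engineered ambiguity pairs: two accepted species one edit either side of
  # an unused probe string
  pairs <- tibble::tibble(genus = character(), id_a = character(),
                          id_b = character(), probe = character())
  alpha <- letters
  k_pair <- 0L
  while (k_pair < config$n_ambiguity_pairs) {
    k <- sample(seq_along(genera), 1)
    g <- genera[k]
    base <- sim_new_word(used_words[[g]], min_sep = 7L)
    pos <- sample(2:(nchar(base) - 1), 1)
    ch <- sample(alpha, 3)
    mk <- function(c1) {
      w <- base
      substr(w, pos, pos) <- c1
      w
    }
    eA <- mk(ch[1]); eB <- mk(ch[2]); probe <- mk(ch[3])
    words <- used_words[[g]]
    if (length(words) > 0 &&
        min(.osa_to_many(eA, words), .osa_to_many(eB, words),
            .osa_to_many(probe, words)) < 5) next
    ida <- next_id(); idb <- next_id()
    add_row(ida, genus = g, spec = eA, name = paste(g, eA),
            auth = sample(authors, 1), rank = "species",
            status = "accepted", parent = genus_ids[k])
    add_row(idb, genus = g, spec = eB, name = paste(g, eB),
            auth = sample(authors, 1), rank = "species",
            status = "accepted", parent = genus_ids[k])
    used_words[[g]] <- c(used_words[[g]], eA, eB, probe)
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      genus = g, id_a = ida, id_b = idb, probe = paste(g, probe)))
    k_pair <- k_pair + 1L
  }

  out <- as_checklist(rows_tbl(), metadata = list(
    title = "Synthetic legume-family checklist",
    version = paste0("seed-", config$seed),
    citation = "taxacade synthetic data generator"))
  attr(out, "ambiguity_pairs") <- pairs
  out
}

#' Degrade a checklist into an "old backbone" snapshot
#'
#' Deletes a controlled fraction of species-group names (never the genus or
#' family scaffold) to emulate an aggregator backbone from before the
#' curated checklist was incorporated. Deletion is closed over pointers:
#' when an accepted name is deleted, its synonyms and infraspecific children
#' go with it, so the degraded checklist still satisfies all referential
#' invariants. The deletion manifest is the construction oracle for
#' [name_overlap()] and [evaluate_impact()].
#'
#' @param checklist a checklist from [generate_checklist()].
#' @param config the same [sim_config()].
#' @return list with `old_checklist` (a `taxon_checklist`) and `manifest`
#'   (tibble of deleted records: `taxon_id`, `scientific_name`,
#'   `scientific_name_authorship`, `genus`, `taxon_rank`).
#' @export
degrade_backbone <- function(checklist, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    sp_group <- which(checklist$taxon_rank %in%
                        c("species", "subspecies", "variety", "form"))
    n_del <- round(config$degrade_fraction * length(sp_group))
    base <- resample(sp_group, n_del)
    deleted <- checklist$taxon_id[base]
    repeat {
      more <- which((checklist$accepted_name_usage_id %in% deleted |
                       checklist$parent_name_usage_id %in% deleted) &
                      !(checklist$taxon_id %in% deleted))
      if (length(more) == 0) break
      deleted <- c(deleted, checklist$taxon_id[more])
    }
    keep <- !(checklist$taxon_id %in% deleted)
    old <- as_checklist(checklist[keep, ],
                        metadata = checklist_metadata(checklist))
    attr(old, "ambiguity_pairs") <- attr(checklist, "ambiguity_pairs")
    manifest <- checklist[!keep, c("taxon_id", "scientific_name",
                                   "scientific_name_authorship", "genus",
                                   "taxon_rank")]
    list(old_checklist = old, manifest = tibble::as_tibble(manifest))
  })
}
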