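#' Generate a corrupted occurrence stream with analytic ground truth
#'
#' Samples occurrence records against a generated checklist. Each
#' occurrence draws a true accepted species-group name and a corruption
#' class, and its verbatim name is constructed accordingly:
#'
#' * `exact` — canonical name plus authorship, verbatim;
#' * `synonym_use` — the name of one of the truth's synonyms;
#' * `typo1` / `typo2` — one / two random edit operations applied inside
#'   the terminal epithet, verified to stay strictly closest to the truth;
#' * `unknown_epithet` — the epithet replaced by a string far from every
#'   name in the checklist;
#' * `genus_only` — epithets dropped;
#' * `ambiguous` — the probe string of an engineered ambiguity pair,
#'   equidistant from two accepted names.
#'
#' The ground truth records, for every occurrence, the analytically
#' expected interpreted rank under the full checklist and under the
#' degraded one, derived from the matcher's documented cascade — not by
#' running the matcher. Running [evaluate_impact()] on the generated triple
#' must reproduce the implied transition matrix cell for cell; that is the
#' pipeline's end-to-end oracle.
#'
#' @param checklist checklist from [generate_checklist()].
#' @param n number of occurrences.
#' @param config the same [sim_config()].
#' @param deleted_ids taxon ids absent from the degraded "old" checklist
#'   (the `manifest$taxon_id` from [degrade_backbone()]); empty means the
#'   old and new backbones coincide.
#' @return list with `occurrences` (tibble `occurrence_id`, `verbatim_name`,
#'   `verbatim_authorship`) and `truth` (tibble `occurrence_id`,
#'   `true_taxon_id`, `corruption_class`, `expected_new_rank`,
#'   `expected_old_rank`).
#' @export
generate_occurrences <- function(checklist, n, config = sim_config(),
                                 deleted_ids = character()) {
  stopifnot(inherits(config, "sim_config"))
  if (n == 0) {
    return(list(
      occurrences = tibble::tibble(occurrence_id = character(),
                                   verbatim_name = character(),
                                   verbatim_authorship = character()),
      truth = tibble::tibble(occurrence_id = character(),
                             true_taxon_id = character(),
                             corruption_class = character(),
                             expected_new_rank = character(),
                             expected_old_rank = character())))
  }
  withr::with_seed(config$seed + 2L,
                   generate_occurrences_impl(checklist, n, config,
                                             deleted_ids))
}

generate_occurrences_impl <- function(cl, n, config, deleted_ids) {
  pairs <- attr(cl, "ambiguity_pairs")
  pair_ids <- if (is.null(pairs)) character() else c(pairs$id_a, pairs$id_b)
  mix <- config$corruption_mix
  if (mix[["ambiguous"]] > 0 && length(pair_ids) == 0) {
    stop("corruption_mix assigns mass to 'ambiguous' but the checklist has ",
         "no ambiguity pairs", call. = FALSE)
  }

  rec <- tibble::as_tibble(as.data.frame(cl))
  id_row <- setNames(seq_len(nrow(rec)), rec$taxon_id)
  present_old <- !(rec$taxon_id %in% deleted_ids)

  sp_acc <- which(rec$taxonomic_status == "accepted" &
                    rec$taxon_rank %in% c("species", "subspecies", "variety",
                                          "form") &
                    !(rec$taxon_id %in% pair_ids))
  syn_rows <- which(rec$taxonomic_status == "synonym")
  syn_by_acc <- split(syn_rows, rec$accepted_name_usage_id[syn_rows])
  sp_with_syn <- sp_acc[rec$taxon_id[sp_acc] %in% names(syn_by_acc)]
  genus_rows <- which(rec$taxon_rank == "genus" &
                        rec$taxonomic_status == "accepted")
  if (length(sp_acc) == 0) stop("checklist has no accepted species-group names",
                                call. = FALSE)

  # canonical registry per genus for corruption collision checks
  can_by_genus <- split(tolower(rec$scientific_name), rec$genus)

  pooled <- pool_rank(rec$taxon_rank)
  # expected rank for a query whose matched record is `i`, under presence mask
  expected_for_truth <- function(i, present) {
    if (present[i]) return(pooled[i])
    # fallback: strip terminal epithet
    if (pooled[i] == "infraspecific") {
      key <- which(rec$taxon_rank == "species" &
                     rec$taxonomic_status == "accepted" &
                     rec$genus == rec$genus[i] &
                     rec$specific_epithet == rec$specific_epithet[i])
      if (length(key) > 0 && any(present[key])) return("species")
    }
    "genus"
  }

  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  v_verbatim <- character(n)
  v_tid <- character(n)
  v_new <- character(n)
  v_old <- character(n)
  for (o in seq_len(n)) {
    cls <- classes[o]
    tid <- NA_character_
    verbatim <- NULL
    exp_new <- exp_old <- NULL

    if (cls == "exact") {
      i <- resample(sp_acc)
      tid <- rec$taxon_id[i]
      verbatim <- paste(rec$scientific_name[i],
                        rec$scientific_name_authorship[i])
      exp_new <- pooled[i]
      exp_old <- expected_for_truth(i, present_old)
    } else if (cls == "synonym_use") {
      i <- resample(sp_with_syn)
      tid <- rec$taxon_id[i]
      syns <- syn_by_acc[[rec$taxon_id[i]]]
      s <- resample(syns)
      verbatim <- paste(rec$scientific_name[s],
                        rec$scientific_name_authorship[s])
      exp_new <- pooled[i]
      exp_old <- if (present_old[s]) pooled[i] else "genus"
    } else if (cls %in% c("typo1", "typo2")) {
      k <- if (cls == "typo1") 1L else 2L
      made <- NULL
      for (try in 1:200) {
        i <- resample(sp_acc)
        if (k == 2L && nchar(rec$scientific_name[i]) < 11) next
        made <- corrupt_epithet(rec, i, k, can_by_genus)
        if (!is.null(made)) break
      }
      if (is.null(made)) stop("failed to construct a typo occurrence",
                              call. = FALSE)
      tid <- rec$taxon_id[i]
      verbatim <- paste(made, rec$scientific_name_authorship[i])
      exp_new <- pooled[i]
      exp_old <- expected_for_truth(i, present_old)
    } else if (cls == "unknown_epithet") {
      i <- resample(sp_acc[rec$taxon_rank[sp_acc] == "species"])
      tid <- rec$taxon_id[i]
      g <- rec$genus[i]
      eps <- sub(paste0("^", tolower(g), " "), "", can_by_genus[[g]])
      w <- sim_new_word(unique(eps))
      verbatim <- paste(g, w)
      exp_new <- "genus"
      exp_old <- "genus"
    } else if (cls == "genus_only") {
      i <- resample(genus_rows)
      tid <- rec$taxon_id[i]
      verbatim <- rec$scientific_name[i]
      exp_new <- "genus"
      exp_old <- "genus"
    } else { # ambiguous
      p <- sample(nrow(pairs), 1)
      verbatim <- pairs$probe[p]
      tid <- NA_character_
      a_in <- function(present) {
        c(present[id_row[[pairs$id_a[p]]]], present[id_row[[pairs$id_b[p]]]])
      }
      exp_rank <- function(present) {
        inb <- a_in(present)
        if (sum(inb) == 1) "species" else "genus"
      }
      exp_new <- exp_rank(rep(TRUE, nrow(rec)))
      exp_old <- exp_rank(present_old)
    }

    v_verbatim[o] <- verbatim
    v_tid[o] <- tid
    v_new[o] <- exp_new
    v_old[o] <- exp_old
  }
  oid <- sprintf("OCC%06d", seq_len(n))
  list(
    occurrences = tibble::tibble(occurrence_id = oid,
                                 verbatim_name = v_verbatim,
                                 verbatim_authorship = ""),
    truth = tibble::tibble(occurrence_id = oid, true_taxon_id = v_tid,
                           corruption_class = classes,
                           expected_new_rank = v_new,
                           expected_old_rank = v_old))
}

# apply k edits to the terminal epithet of record i; return the corrupted
# canonical, or NULL when no corruption satisfying the separation
# guarantees was found
corrupt_epithet <- function(rec, i, k, can_by_genus) {
  target <- if (nzchar(rec$infraspecific_epithet[i]))
    rec$infraspecific_epithet[i] else rec$specific_epithet[i]
  prefix <- sub(paste0(target, "$"), "", rec$scientific_name[i])
  others <- setdiff(can_by_genus[[rec$genus[i]]],
                    tolower(rec$scientific_name[i]))
  for (try in 1:50) {
    w <- target
    for (e in seq_len(k)) w <- random_edit(w)
    if (nchar(w) < 3) next
    corrupt <- paste0(prefix, w)
    if (.osa_pair(tolower(corrupt), tolower(rec$scientific_name[i])) != k) next
    if (length(others) > 0 &&
        min(.osa_to_many(tolower(corrupt), others)) <= 2) next
    return(corrupt)
  }
  NULL
}

random_edit <- function(w) {
  op <- sample(c("sub", "ins", "del", "swap"), 1)
  nc <- nchar(w)
  if (op == "sub") {
    p <- sample(nc, 1)
    ch <- sample(setdiff(letters, substr(w, p, p)), 1)
    substr(w, p, p) <- ch
    w
  } else if (op == "ins") {
    p <- sample(0:nc, 1)
    paste0(substr(w, 0, p), sample(letters, 1), substr(w, p + 1, nc))
  } else if (op == "del" && nc > 3) {
    p <- sample(nc, 1)
    paste0(substr(w, 0, p - 1), substr(w, p + 1, nc))
  } else if (nc > 1) { # swap adjacent distinct characters
    p <- sample(nc - 1, 1)
    a <- substr(w, p, p)
    b <- substr(w, p + 1, p + 1)
    if (a == b) return(random_edit(w))
    paste0(substr(w, 0, p - 1), b, a, substr(w, p + 2, nc))
  } else {
    w
  }
}
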