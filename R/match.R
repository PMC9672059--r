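#' Matching configuration
#'
#' Thresholds and tie-break behaviour of the name-interpretation cascade.
#' Edit distance is the optimal-string-alignment (restricted
#' Damerau-Levenshtein) distance on the lower-cased canonical name.
#'
#' @param max_edit_distance_short maximum distance for canonical names of
#'   8 characters or fewer.
#' @param max_edit_distance_long maximum distance for longer canonicals.
#' @param genus_max_distance maximum distance allowed on the genus token of
#'   a fuzzy candidate; the initial letter must always agree.
#' @param use_authorship_tiebreak whether authorship agreement participates
#'   in candidate tie-breaking.
#' @return a `match_config` list.
#' @export
match_config <- function(max_edit_distance_short = 1L,
                         max_edit_distance_long = 2L,
                         genus_max_distance = 1L,
                         use_authorship_tiebreak = TRUE) {
  stopifnot(max_edit_distance_short >= 0, max_edit_distance_long >= 0,
            genus_max_distance >= 0,
            max_edit_distance_short <= max_edit_distance_long)
  structure(list(
    max_edit_distance_short = as.integer(max_edit_distance_short),
    max_edit_distance_long = as.integer(max_edit_distance_long),
    genus_max_distance = as.integer(genus_max_distance),
    use_authorship_tiebreak = isTRUE(use_authorship_tiebreak)
  ), class = "match_config")
}

match_types <- function() {
  c("exact", "exact_canonical", "fuzzy", "higher_rank_no_match",
    "higher_rank_ambiguous", "higher_rank_unplaced", "none")
}

#' Interpret one verbatim name against a backbone
#'
#' Implements the interpretation cascade used when indexing occurrence
#' records against a taxonomic backbone:
#'
#' 1. exact canonical + authorship match;
#' 2. exact canonical match when unique (authorship used as tie-break among
#'    canonical homonyms when enabled);
#' 3. fuzzy match: candidates within the configured edit distance of the
#'    canonical, ranked by distance then authorship agreement; the genus
#'    token of a species-group candidate must lie within
#'    `genus_max_distance` of the query genus and share its initial letter;
#' 4. the single best candidate's accepted form (via [resolve_accepted()])
#'    becomes the interpretation;
#' 5. a best candidate that is unplaced falls back to the next higher rank
#'    (`higher_rank_unplaced`);
#' 6. no candidate: the terminal epithet is stripped and the coarser query
#'    re-matched, recursively down to the family root
#'    (`higher_rank_no_match`);
#' 7. two or more equally best candidates surviving all tie-breaks fall
#'    back to the finest rank they share — their common genus if they have
#'    one, else the family (`higher_rank_ambiguous`).
#'
#' The family root guarantees that every query receives an interpretation.
#' When recursion coarsens a query more than once, the reported
#' `match_type` is the first fallback trigger.
#'
#' @param query a single verbatim name string, or a one-row tibble from
#'   [parse_name()].
#' @param backbone a `taxon_backbone`.
#' @param config a [match_config()].
#' @return one-row tibble: `query_canonical`, `query_rank`, `matched_id`,
#'   `interpreted_id`, `interpreted_name`, `interpreted_rank` (pooled:
#'   family/genus/species/infraspecific), `match_type`,
#'   `candidates_considered`.
#' @examples
#' cl <- new_checklist(
#'   taxon_id = c("g1", "s1"),
#'   genus = c("Acacia", "Acacia"),
#'   specific_epithet = c("", "dealbata"),
#'   scientific_name = c("Acacia", "Acacia dealbata"),
#'   taxon_rank = c("genus", "species"),
#'   taxonomic_status = c("accepted", "accepted"))
#' bb <- build_backbone(cl)
#' match_name("Acacia xyz", bb)  # interpreted at genus Acacia
#' @export
match_name <- function(query, backbone, config = match_config()) {
  if (nrow(backbone$records) == 0) stop("empty backbone", call. = FALSE)
  q <- if (is.character(query)) parse_name(query) else query
  if (!is.data.frame(q) || nrow(q) != 1) {
    stop("query must be a single name", call. = FALSE)
  }
  if (!isTRUE(q$parse_ok)) {
    return(result_tibble(list(match_result(q, NA, NA, NA, NA, "none", 0L))))
  }
  result_tibble(list(match_cascade(q, backbone, config)))
}

match_result <- function(q, matched_id, interpreted_id, interpreted_name,
                         interpreted_rank, match_type, considered) {
  list(
    query_canonical = if (is.null(q$canonical)) NA_character_ else q$canonical,
    query_rank = if (is.null(q$implied_rank)) NA_character_ else q$implied_rank,
    matched_id = as.character(matched_id),
    interpreted_id = as.character(interpreted_id),
    interpreted_name = as.character(interpreted_name),
    interpreted_rank = as.character(interpreted_rank),
    match_type = match_type,
    candidates_considered = as.integer(considered)
  )
}

result_tibble <- function(results) {
  get_chr <- function(f) vapply(results, function(r) r[[f]], character(1))
  tibble::tibble(
    query_canonical = get_chr("query_canonical"),
    query_rank = get_chr("query_rank"),
    matched_id = get_chr("matched_id"),
    interpreted_id = get_chr("interpreted_id"),
    interpreted_name = get_chr("interpreted_name"),
    interpreted_rank = get_chr("interpreted_rank"),
    match_type = get_chr("match_type"),
    candidates_considered = vapply(results, function(r)
      r$candidates_considered, integer(1))
  )
}

match_cascade <- function(q, backbone, config) {
  rec <- backbone$records
  considered <- 0L
  state <- list(canonical = q$canonical, genus = q$genus,
                specific_epithet = q$specific_epithet,
                rank = q$implied_rank, authorship = q$authorship)
  trigger <- NA_character_ # first fallback reason

  repeat {
    att <- attempt_rank(state, backbone, config)
    considered <- considered + att$considered

    if (att$outcome == "matched") {
      i <- backbone_row(backbone, att$matched_id)
      res <- resolve_accepted(backbone, att$matched_id)
      if (!is.na(res$accepted_id)) {
        j <- backbone_row(backbone, res$accepted_id)
        type <- if (!is.na(trigger)) trigger else att$stage
        return(match_result(q, att$matched_id, res$accepted_id,
                            rec$scientific_name[j], rec$pooled_rank[j],
                            type, considered))
      }
      # unplaced (or broken chain): fall back one rank
      if (is.na(trigger)) trigger <- "higher_rank_unplaced"
      state <- coarsen(state)
    } else if (att$outcome == "ambiguous") {
      if (is.na(trigger)) trigger <- "higher_rank_ambiguous"
      shared <- shared_genus_interpretation(att$candidate_ids, backbone)
      if (!is.null(shared)) {
        j <- backbone_row(backbone, shared)
        return(match_result(q, NA_character_, shared,
                            rec$scientific_name[j], rec$pooled_rank[j],
                            trigger, considered))
      }
      state <- coarsen(state)
      if (is.null(state)) state <- list(rank = "family")
    } else { # no candidates
      if (is.na(trigger)) trigger <- "higher_rank_no_match"
      state <- coarsen(state)
    }

    if (is.null(state) || identical(state$rank, "family")) {
      fid <- backbone$family_id
      j <- backbone_row(backbone, fid)
      type <- if (!is.na(trigger)) trigger else "higher_rank_no_match"
      return(match_result(q, NA_character_, fid, rec$scientific_name[j],
                          "family", type, considered))
    }
  }
}

# strip the terminal epithet: infraspecific -> species -> genus -> family
coarsen <- function(state) {
  if (identical(state$rank, "infraspecific")) {
    list(canonical = make_canonical(state$genus, state$specific_epithet),
         genus = state$genus, specific_epithet = state$specific_epithet,
         rank = "species", authorship = NA_character_)
  } else if (identical(state$rank, "species")) {
    list(canonical = state$genus, genus = state$genus,
         specific_epithet = NA_character_, rank = "genus",
         authorship = NA_character_)
  } else {
    list(rank = "family")
  }
}

# one attempt at the query's current rank; returns outcome + candidates
attempt_rank <- function(state, backbone, config) {
  rec <- backbone$records
  key <- tolower(state$canonical)
  exact_ids <- get0(key, envir = backbone$canonical_index,
                    ifnotfound = character())
  considered <- length(exact_ids)
  auth <- state$authorship
  has_auth <- !is.null(auth) && !is.na(auth) && nzchar(auth)

  if (length(exact_ids) > 0) {
    # stage 1: exact canonical + authorship
    if (has_auth) {
      rows <- vapply(exact_ids, function(id) backbone_row(backbone, id), 1L)
      agree <- normalize_authorship(rec$scientific_name_authorship[rows]) ==
        normalize_authorship(auth)
      agree[is.na(agree)] <- FALSE
      if (sum(agree) == 1) {
        return(list(outcome = "matched", matched_id = exact_ids[agree],
                    stage = "exact", considered = considered))
      }
      if (sum(agree) > 1) {
        return(list(outcome = "ambiguous", candidate_ids = exact_ids[agree],
                    considered = considered))
      }
    }
    # stage 2: unique exact canonical
    if (length(exact_ids) == 1) {
      return(list(outcome = "matched", matched_id = exact_ids,
                  stage = "exact_canonical", considered = considered))
    }
    return(list(outcome = "ambiguous", candidate_ids = exact_ids,
                considered = considered))
  }

  # stage 3: fuzzy
  threshold <- if (nchar(state$canonical) <= 8L)
    config$max_edit_distance_short else config$max_edit_distance_long
  if (threshold == 0) {
    return(list(outcome = "none", considered = considered))
  }
  cand_rows <- fuzzy_candidate_rows(state, backbone, config)
  considered <- considered + length(cand_rows)
  if (length(cand_rows) == 0) {
    return(list(outcome = "none", considered = considered))
  }
  d <- .osa_to_many(key, rec$canonical_lower[cand_rows])
  keep <- which(d <= threshold)
  if (length(keep) == 0) {
    return(list(outcome = "none", considered = considered))
  }
  dmin <- min(d[keep])
  best <- cand_rows[d == dmin & d <= threshold]
  if (length(best) > 1 && config$use_authorship_tiebreak && has_auth) {
    agree <- normalize_authorship(rec$scientific_name_authorship[best]) ==
      normalize_authorship(auth)
    agree[is.na(agree)] <- FALSE
    if (sum(agree) == 1) best <- best[agree]
  }
  if (length(best) == 1) {
    return(list(outcome = "matched", matched_id = rec$taxon_id[best],
                stage = "fuzzy", considered = considered))
  }
  list(outcome = "ambiguous", candidate_ids = rec$taxon_id[best],
       considered = considered)
}

# candidate blocking: species-group candidates must have a genus within
# genus_max_distance of the query genus sharing its first letter;
# genus-rank queries scan genus-rank records under the same constraint
fuzzy_candidate_rows <- function(state, backbone, config) {
  rec <- backbone$records
  qg <- state$genus
  if (is.null(qg) || is.na(qg) || !nzchar(qg)) return(integer())
  qg_low <- tolower(qg)
  first <- substr(qg_low, 1, 1)

  if (identical(state$rank, "genus")) {
    rows <- which(rec$taxon_rank == "genus")
    gl <- rec$canonical_lower[rows]
  } else {
    rows <- which(rec$pooled_rank %in% c("species", "infraspecific"))
    gl <- tolower(rec$genus[rows])
  }
  same_first <- substr(gl, 1, 1) == first
  rows <- rows[same_first]
  gl <- gl[same_first]
  if (length(rows) == 0) return(integer())
  gd <- .osa_to_many(qg_low, gl)
  rows[gd <= config$genus_max_distance]
}

# finest rank shared by equally best candidates: common genus, else NULL
shared_genus_interpretation <- function(candidate_ids, backbone) {
  rec <- backbone$records
  rows <- vapply(candidate_ids, function(id) backbone_row(backbone, id), 1L)
  gn <- unique(rec$genus[rows])
  gn <- gn[nzchar(gn)]
  if (length(gn) != 1) return(NULL)
  gid <- get0(gn, envir = backbone$genus_index, ifnotfound = NULL)
  gid
}

#' Interpret a batch of verbatim names
#'
#' Order-preserving vectorized driver over [match_name()]; per-item parse
#' failures yield `match_type = "none"` rows instead of aborting the batch.
#'
#' @param queries character vector of verbatim names, or a tibble from
#'   [parse_name()], or a tibble with columns `occurrence_id` and
#'   `verbatim_name`.
#' @inheritParams match_name
#' @return tibble with one row per query, the columns of [match_name()],
#'   plus `occurrence_id` when supplied.
#' @export
match_batch <- function(queries, backbone, config = match_config()) {
  occ_id <- NULL
  if (is.character(queries)) {
    parsed <- parse_name(queries, quiet = TRUE)
  } else if (is.data.frame(queries) && "verbatim_name" %in% names(queries)) {
    occ_id <- queries$occurrence_id
    parsed <- parse_name(queries$verbatim_name, quiet = TRUE)
  } else if (is.data.frame(queries) && "canonical" %in% names(queries)) {
    parsed <- queries
  } else {
    stop("queries must be names, parsed names, or an occurrence tibble",
         call. = FALSE)
  }
  if (nrow(parsed) == 0) {
    out <- tibble::tibble(
      query_canonical = character(), query_rank = character(),
      matched_id = character(), interpreted_id = character(),
      interpreted_name = character(), interpreted_rank = character(),
      match_type = character(), candidates_considered = integer())
    if (!is.null(occ_id)) out <- dplyr::bind_cols(
      tibble::tibble(occurrence_id = character()), out)
    return(out)
  }
  # plain-list query states avoid per-row tibble subsetting in the hot loop
  qs <- lapply(seq_len(nrow(parsed)), function(i) {
    list(canonical = parsed$canonical[i], genus = parsed$genus[i],
         specific_epithet = parsed$specific_epithet[i],
         implied_rank = parsed$implied_rank[i],
         authorship = parsed$authorship[i],
         parse_ok = parsed$parse_ok[i])
  })
  res <- lapply(qs, function(q) {
    if (!isTRUE(q$parse_ok)) {
      match_result(q, NA, NA, NA, NA, "none", 0L)
    } else {
      match_cascade(q, backbone, config)
    }
  })
  out <- result_tibble(res)
  if (!is.null(occ_id)) {
    out <- dplyr::bind_cols(tibble::tibble(occurrence_id = occ_id), out)
  }
  out
}
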