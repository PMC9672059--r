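#' Quantify occurrence re-interpretation impact between two backbones
#'
#' Matches every occurrence's verbatim name against an older and a newer
#' backbone via [match_batch()] and tabulates the rank transitions of the
#' interpreted names over the pooled rank ladder family < genus < species <
#' infraspecific. An occurrence is *improved* when its new interpreted rank
#' is strictly finer than the old one; same-rank changes of identity are
#' counted separately as reassigned. Parse failures are counted, never
#' silently dropped.
#'
#' @param occurrences tibble with columns `occurrence_id` and
#'   `verbatim_name` (occurrence ids must be unique).
#' @param old_backbone,new_backbone `taxon_backbone` objects.
#' @param config a [match_config()].
#' @return an `impact_report`: list with `transitions` (tibble `old_rank`,
#'   `new_rank`, `n` over all 16 cells), `improved_total`, `per_genus_improved`
#'   (tibble `genus`, `n`), `still_higher_rank` (occurrences interpreted
#'   above species under the new backbone), `reassigned_same_rank`,
#'   `parse_failures`, `n` and a per-occurrence `audit` tibble.
#' @export
evaluate_impact <- function(occurrences, old_backbone, new_backbone,
                            config = match_config()) {
  stopifnot(all(c("occurrence_id", "verbatim_name") %in% names(occurrences)))
  if (anyDuplicated(occurrences$occurrence_id)) {
    stop("occurrence_id values must be unique", call. = FALSE)
  }
  parsed <- parse_name(occurrences$verbatim_name, quiet = TRUE)
  ok <- parsed$parse_ok
  old_res <- match_batch(parsed[ok, , drop = FALSE], old_backbone, config)
  new_res <- match_batch(parsed[ok, , drop = FALSE], new_backbone, config)

  audit <- tibble::tibble(
    occurrence_id = occurrences$occurrence_id[ok],
    verbatim_name = occurrences$verbatim_name[ok],
    query_rank = parsed$implied_rank[ok],
    old_id = old_res$interpreted_id,
    old_rank = old_res$interpreted_rank,
    old_match_type = old_res$match_type,
    new_id = new_res$interpreted_id,
    new_rank = new_res$interpreted_rank,
    new_match_type = new_res$match_type
  )
  audit$improved <- rank_depth(audit$new_rank) > rank_depth(audit$old_rank)
  audit$reassigned <- !audit$improved &
    audit$new_rank == audit$old_rank & audit$new_id != audit$old_id

  lv <- pooled_rank_levels()
  transitions <- audit %>%
    dplyr::count(old_rank = factor(old_rank, lv),
                 new_rank = factor(new_rank, lv), .drop = FALSE,
                 name = "n") %>%
    dplyr::mutate(old_rank = as.character(old_rank),
                  new_rank = as.character(new_rank))

  new_rec <- new_backbone$records
  genus_of_new <- vapply(seq_len(nrow(audit)), function(i) {
    if (!isTRUE(audit$improved[i])) return(NA_character_)
    j <- backbone_row(new_backbone, audit$new_id[i])
    if (is.null(j)) return(NA_character_)
    g <- new_rec$genus[j]
    if (nzchar(g)) g
    else if (new_rec$taxon_rank[j] == "genus") new_rec$scientific_name[j]
    else NA_character_
  }, character(1))
  per_genus <- tibble::tibble(genus = genus_of_new) %>%
    dplyr::filter(!is.na(genus)) %>%
    dplyr::count(genus, name = "n") %>%
    dplyr::arrange(dplyr::desc(n), genus)

  rep <- structure(list(
    transitions = transitions,
    improved_total = sum(audit$improved),
    per_genus_improved = per_genus,
    still_higher_rank = sum(audit$new_rank %in% c("family", "genus")),
    reassigned_same_rank = sum(audit$reassigned),
    parse_failures = sum(!ok),
    n = nrow(occurrences),
    audit = audit
  ), class = "impact_report")
  stopifnot(sum(transitions$n) == nrow(audit))
  rep
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report> ", x$n, " occurrences (", x$parse_failures,
      " unparseable)\n", sep = "")
  cat("  improved to a finer rank: ", x$improved_total, "\n", sep = "")
  cat("  reassigned at same rank:  ", x$reassigned_same_rank, "\n", sep = "")
  cat("  still above species:      ", x$still_higher_rank, "\n", sep = "")
  wide <- tidyr::pivot_wider(x$transitions, names_from = "new_rank",
                             values_from = "n")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' Genera with many improved occurrences
#'
#' @param report an `impact_report`.
#' @param threshold minimum improved-occurrence count (exclusive).
#' @return tibble `genus`, `n`, descending.
#' @export
per_genus_improvements <- function(report, threshold = 60) {
  report$per_genus_improved %>%
    dplyr::filter(n > threshold) %>%
    dplyr::arrange(dplyr::desc(n), genus)
}

#' Partition residual coarse interpretations by cause
#'
#' Classifies the occurrences whose new interpretation is still coarser
#' than the rank their verbatim name implies: infraspecific names matched
#' only at species level (missing infraspecific name in the backbone),
#' species-or-finer names interpreted above species (missing species
#' name or unresolved ambiguity), and names that were genus-only at source,
#' which cannot be improved without curating the source data.
#'
#' @param report an `impact_report`.
#' @return named list of counts: `infraspecific_to_species`,
#'   `species_level_unmatched`, `genus_only_inputs`.
#' @export
classify_residual <- function(report) {
  a <- report$audit
  residual <- rank_depth(a$new_rank) < rank_depth(a$query_rank) |
    a$query_rank == "genus"
  qr <- a$query_rank[residual]
  nr <- a$new_rank[residual]
  list(
    infraspecific_to_species =
      sum(qr == "infraspecific" & nr == "species"),
    species_level_unmatched =
      sum(qr != "genus" & !(qr == "infraspecific" & nr == "species") &
            rank_depth(nr) < rank_depth(qr)),
    genus_only_inputs = sum(qr == "genus")
  )
}
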