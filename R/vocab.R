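#' Controlled vocabularies
#'
#' The nine-value taxonomic status vocabulary and the rank vocabulary used
#' throughout the package. Every status other than `accepted` and `unplaced`
#' points to an accepted name via `accepted_name_usage_id`.
#'
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
taxon_statuses <- function() {
  c("accepted", "artificial_hybrid", "illegitimate", "incomplete", "invalid",
    "misapplied", "orthographic_variant", "synonym", "unplaced")
}

#' @rdname vocabularies
#' @export
taxon_ranks <- function() {
  c("family", "genus", "species", "subspecies", "variety", "form", "other")
}

# statuses that must carry an accepted_name_usage_id
pointed_statuses <- function() {
  setdiff(taxon_statuses(), c("accepted", "unplaced"))
}

#' Normalize a taxonomic status token
#'
#' Tokens are matched case-insensitively after trimming; internal whitespace,
#' hyphens and underscores are equivalent. `"Orthographic"` and
#' `"Orthographic variant"` map to the same value, as both spellings occur in
#' curated checklists.
#'
#' @param x character vector of status tokens.
#' @return character vector drawn from [taxon_statuses()], `NA` where the
#'   token is not in the vocabulary.
#' @export
normalize_status <- function(x) {
  key <- gsub("[ _-]+", " ", tolower(trimws(as.character(x))))
  map <- c(
    "accepted" = "accepted",
    "artificial hybrid" = "artificial_hybrid",
    "hybrid" = "artificial_hybrid",
    "illegitimate" = "illegitimate",
    "incomplete" = "incomplete",
    "invalid" = "invalid",
    "misapplied" = "misapplied",
    "orthographic" = "orthographic_variant",
    "orthographic variant" = "orthographic_variant",
    "synonym" = "synonym",
    "unplaced" = "unplaced"
  )
  unname(map[key])
}

#' Normalize a taxonomic rank token
#'
#' @param x character vector of rank tokens (e.g. `"Species"`, `"subsp."`,
#'   `"var."`). Unrecognized tokens map to `"other"`; empty/NA stay `NA`.
#' @return character vector drawn from [taxon_ranks()].
#' @export
normalize_rank <- function(x) {
  key <- gsub("\\.$", "", gsub("[ _-]+", " ", tolower(trimws(as.character(x)))))
  map <- c(
    "family" = "family",
    "genus" = "genus",
    "species" = "species",
    "subspecies" = "subspecies", "subsp" = "subspecies", "ssp" = "subspecies",
    "variety" = "variety", "var" = "variety",
    "form" = "form", "forma" = "form", "f" = "form"
  )
  out <- unname(map[key])
  out[is.na(out) & !is.na(key) & nzchar(key)] <- "other"
  out[is.na(x) | !nzchar(trimws(as.character(x)))] <- NA_character_
  out
}

# rank pooling used by the impact accounting: family < genus < species <
# infraspecific (subspecies/variety/form pooled)
pool_rank <- function(rank) {
  dplyr::case_when(
    rank == "family" ~ "family",
    rank == "genus" ~ "genus",
    rank == "species" ~ "species",
    rank %in% c("subspecies", "variety", "form") ~ "infraspecific",
    TRUE ~ NA_character_
  )
}

pooled_rank_levels <- function() c("family", "genus", "species", "infraspecific")

# numeric fineness: larger = finer
rank_depth <- function(pooled) {
  match(pooled, pooled_rank_levels())
}
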