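#' Checklist column layout
#'
#' A checklist is a tibble with one row per name record, in the 15-field
#' Darwin Core taxon dialect. Column order matches the archive field indices
#' 0-14. Extra (unknown) columns read from an archive are retained after
#' these 15.
#'
#' @return character vector of the 15 canonical column names.
#' @export
checklist_columns <- function() {
  c("taxon_id", "family", "genus", "specific_epithet",
    "infraspecific_epithet", "scientific_name", "scientific_name_authorship",
    "taxon_rank", "taxonomic_status", "accepted_name_usage_id",
    "parent_name_usage_id", "original_name_usage_id", "name_published_in",
    "scientific_name_id", "wfo_id")
}

# DwC term local names in field-index order 0-14
dwc_terms <- function() {
  c("taxonID", "family", "genus", "specificEpithet", "infraspecificEpithet",
    "scientificName", "scientificNameAuthorship", "taxonRank",
    "taxonomicStatus", "acceptedNameUsageID", "parentNameUsageID",
    "originalNameUsageID", "namePublishedIn", "scientificNameID", "wfoID")
}

dwc_term_uri <- function(term) {
  if (term == "wfoID") return("http://rs.gbif.org/terms/1.0/wfoID")
  paste0("http://rs.tdwg.org/dwc/terms/", term)
}

#' Construct a checklist tibble
#'
#' Builds a checklist from per-record vectors, filling absent optional fields
#' with `""`. Statuses and ranks are normalized to the controlled
#' vocabularies ([taxon_statuses()], [taxon_ranks()]).
#'
#' @param ... named vectors for any subset of [checklist_columns()];
#'   `taxon_id`, `scientific_name`, `taxon_rank` and `taxonomic_status` are
#'   required.
#' @param metadata optional named list (title, version, citation) attached as
#'   the checklist metadata.
#' @return a `taxon_checklist` tibble.
#' @export
new_checklist <- function(..., metadata = list()) {
  dots <- tibble::tibble(...)
  need <- c("taxon_id", "scientific_name", "taxon_rank", "taxonomic_status")
  missing <- setdiff(need, names(dots))
  if (length(missing) > 0) {
    stop("missing required checklist column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(checklist_columns(), names(dots))) {
    dots[[col]] <- ""
  }
  dots <- dots[, c(checklist_columns(),
                   setdiff(names(dots), checklist_columns()))]
  dots$taxonomic_status <- normalize_status(dots$taxonomic_status)
  dots$taxon_rank <- normalize_rank(dots$taxon_rank)
  as_checklist(dots, metadata)
}

as_checklist <- function(df, metadata = list()) {
  df <- tibble::as_tibble(df)
  class(df) <- unique(c("taxon_checklist", class(df)))
  attr(df, "metadata") <- metadata
  df
}

#' @export
print.taxon_checklist <- function(x, ...) {
  md <- attr(x, "metadata")
  if (!is.null(md$title) && nzchar(md$title %||% "")) {
    cat("# Checklist:", md$title, "\n")
  }
  cat("# ", nrow(x), " name records\n", sep = "")
  NextMethod()
}

#' Checklist metadata
#' @param checklist a checklist tibble.
#' @return named list with elements such as `title`, `version`, `citation`.
#' @export
checklist_metadata <- function(checklist) {
  attr(checklist, "metadata") %||% list()
}

#' Validate a checklist
#'
#' Checks the record-level and referential invariants: non-empty unique
#' `taxon_id`; `taxonomic_status` in the nine-value vocabulary; every status
#' other than accepted and unplaced carries an `accepted_name_usage_id`;
#' accepted and parent pointers refer to ids present in the checklist; and
#' `scientific_name` agrees with the concatenation of genus, epithets and
#' rank marker for species-group ranks.
#'
#' Dangling pointers are reported, not fatal: aggregated checklists contain
#' them in practice and the pipeline must diagnose them rather than crash.
#'
#' @param checklist a checklist tibble.
#' @return tibble of issues with columns `issue`, `taxon_id`, `detail`
#'   (zero rows when the checklist is clean).
#' @export
validate_checklist <- function(checklist) {
  cl <- checklist
  iss <- list()
  add <- function(issue, ids, detail) {
    if (length(ids) == 0) return()
    iss[[length(iss) + 1]] <<- tibble::tibble(
      issue = issue, taxon_id = as.character(ids), detail = detail)
  }

  # note: paste0() maps zero-length inputs to "", so the row labels must be
  # truncated back to the index length
  empty_id <- which(is.na(cl$taxon_id) | !nzchar(cl$taxon_id))
  add("empty_id", paste0("row ", empty_id)[seq_along(empty_id)],
      "taxon_id is empty")

  dup <- cl$taxon_id[duplicated(cl$taxon_id) & nzchar(cl$taxon_id)]
  add("duplicate_id", unique(dup), "taxon_id occurs more than once")

  bad_status <- which(is.na(cl$taxonomic_status) |
                        !(cl$taxonomic_status %in% taxon_statuses()))
  add("unknown_status", cl$taxon_id[bad_status],
      paste0("status token not in vocabulary (row ", bad_status, ")"))

  pointed <- cl$taxonomic_status %in% pointed_statuses()
  no_ptr <- which(pointed & (is.na(cl$accepted_name_usage_id) |
                               !nzchar(cl$accepted_name_usage_id)))
  add("missing_accepted_pointer", cl$taxon_id[no_ptr],
      "non-accepted, non-unplaced record lacks accepted_name_usage_id")

  ids <- cl$taxon_id
  acc <- cl$accepted_name_usage_id
  dang_acc <- which(!is.na(acc) & nzchar(acc) & !(acc %in% ids))
  add("dangling_accepted_pointer", cl$taxon_id[dang_acc],
      paste0("acceptedNameUsageID '", acc[dang_acc], "' not in checklist"))

  par <- cl$parent_name_usage_id
  dang_par <- which(!is.na(par) & nzchar(par) & !(par %in% ids))
  add("dangling_parent_pointer", cl$taxon_id[dang_par],
      paste0("parentNameUsageID '", par[dang_par], "' not in checklist"))

  sp_group <- cl$taxon_rank %in% c("species", "subspecies", "variety", "form")
  marker <- c(species = NA, subspecies = "subsp.", variety = "var.",
              form = "f.")[cl$taxon_rank]
  expect <- mapply(make_canonical, cl$genus, cl$specific_epithet, marker,
                   cl$infraspecific_epithet, USE.NAMES = FALSE)
  has_parts <- nzchar(blank_na(cl$genus)) & nzchar(blank_na(cl$specific_epithet))
  mism <- which(sp_group & has_parts &
                  tolower(expect) != tolower(cl$scientific_name))
  add("name_mismatch", cl$taxon_id[mism],
      paste0("scientificName '", cl$scientific_name[mism],
             "' != assembled '", expect[mism], "'"))

  if (length(iss) == 0) {
    return(tibble::tibble(issue = character(), taxon_id = character(),
                          detail = character()))
  }
  dplyr::bind_rows(iss)
}

# hard record-level invariants enforced before writing
assert_writable <- function(checklist) {
  issues <- validate_checklist(checklist)
  hard <- issues[issues$issue %in%
                   c("empty_id", "duplicate_id", "unknown_status",
                     "missing_accepted_pointer"), ]
  if (nrow(hard) > 0) {
    msg <- paste0(hard$issue, " [", hard$taxon_id, "]: ", hard$detail)
    stop("checklist violates record invariants; refusing to write:\n  ",
         paste(msg, collapse = "\n  "), call. = FALSE)
  }
  invisible(checklist)
}
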