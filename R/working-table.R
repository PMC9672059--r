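#' Read a checklist working table
#'
#' Reads the 19-field working-spreadsheet format used during collaborative
#' checklist curation, exported as UTF-8 CSV or TSV. The header must name
#' all 19 fields (order-insensitive); `tribe/clade` and `tribe_clade` are
#' accepted interchangeably. `comments` and `verified` are preserved
#' verbatim — a non-empty `verified` marks an expert-checked record.
#'
#' @param path delimited text file; the delimiter is taken from the
#'   extension (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is
#'   given.
#' @param delim optional field delimiter override.
#' @return tibble with the 19 working-table columns, one row per record.
#' @export
read_working_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- normalize_working_header(names(raw))
  missing <- setdiff(working_columns(), names(raw))
  if (length(missing) > 0) {
    stop("working table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- raw[, working_columns()]
  bad <- which(!nzchar(blank_na(out$plant_name_id)) |
                 !nzchar(blank_na(out$taxon_name)))
  if (length(bad) > 0) {
    stop("plant_name_id and taxon_name may not be empty (row ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' @rdname read_working_table
#' @export
working_columns <- function() {
  c("sort_name", "plant_name_id", "ipni_id", "family", "subfamily",
    "tribe_clade", "rank", "taxon_status", "taxon_name",
    "place_of_publication", "volume_and_page", "first_published",
    "geographic_area", "nomenclatural_remarks", "accepted_plant_name_id",
    "acc_ipni_id", "accepted_name", "comments", "verified")
}

normalize_working_header <- function(x) {
  key <- gsub("[ /]+", "_", tolower(trimws(x)))
  key[key == "tribe_clade"] <- "tribe_clade"
  key
}

#' Convert working-table records to a checklist
#'
#' Maps the 19-field working format onto the Darwin Core checklist layout:
#' `plant_name_id` becomes `taxon_id`, `taxon_status` is mapped onto the
#' nine-value vocabulary (case- and space-insensitively), and `taxon_name`
#' (which carries authorship) is split into canonical parts and authorship
#' by [parse_name()]. Accepted rows get an empty accepted pointer even when
#' the source self-references.
#'
#' @param records tibble from [read_working_table()].
#' @param metadata optional metadata list for the resulting checklist.
#' @return a `taxon_checklist` tibble.
#' @export
working_to_dwca <- function(records, metadata = list()) {
  status <- normalize_status(records$taxon_status)
  bad <- which(is.na(status))
  if (length(bad) > 0) {
    stop("unmappable taxon_status token(s): ",
         paste0("row ", utils::head(bad, 5), " '",
                records$taxon_status[utils::head(bad, 5)], "'",
                collapse = "; "), call. = FALSE)
  }
  parsed <- parse_name(records$taxon_name, quiet = TRUE)
  if (any(!parsed$parse_ok)) {
    bad <- which(!parsed$parse_ok)
    stop("unparseable taxon_name (row ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  rank <- normalize_rank(records$rank)
  # rank falls back to the parsed structure when the source token is absent
  fallback <- dplyr::case_when(
    parsed$implied_rank == "genus" ~ "genus",
    parsed$implied_rank == "infraspecific" ~
      dplyr::coalesce(normalize_rank(parsed$rank_marker), "variety"),
    TRUE ~ "species")
  rank <- dplyr::coalesce(rank, fallback)

  accepted <- blank_na(records$accepted_plant_name_id)
  accepted[status == "accepted" | status == "unplaced"] <- ""

  pub <- trimws(paste(blank_na(records$place_of_publication),
                      blank_na(records$volume_and_page)))

  new_checklist(
    taxon_id = records$plant_name_id,
    family = blank_na(records$family),
    genus = blank_na(parsed$genus),
    specific_epithet = blank_na(parsed$specific_epithet),
    infraspecific_epithet = blank_na(parsed$infraspecific_epithet),
    scientific_name = parsed$canonical,
    scientific_name_authorship = blank_na(parsed$authorship),
    taxon_rank = rank,
    taxonomic_status = status,
    accepted_name_usage_id = accepted,
    parent_name_usage_id = "",
    original_name_usage_id = "",
    name_published_in = pub,
    scientific_name_id = blank_na(records$ipni_id),
    wfo_id = "",
    metadata = metadata
  )
}
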