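#' Summarize a checklist by rank and status
#'
#' Counts accepted records per rank (genera, species, subspecies, varieties,
#' forms) and pools every non-accepted, non-unplaced status into a single
#' synonyms bucket, mirroring the headline table of a checklist release.
#' Unplaced records are reported separately and never counted in the
#' accepted or synonym buckets.
#'
#' @param checklist a checklist tibble.
#' @return a `rank_summary` tibble with columns `category`
#'   (`genera`, `species`, `subspecies`, `varieties`, `forms`, `synonyms`,
#'   `unplaced`) and `n`.
#' @export
summarize_checklist <- function(checklist) {
  st <- checklist$taxonomic_status
  rk <- checklist$taxon_rank
  acc <- st == "accepted"
  cats <- c(genera = "genus", species = "species", subspecies = "subspecies",
            varieties = "variety", forms = "form")
  n_acc <- vapply(cats, function(r) sum(acc & rk == r, na.rm = TRUE), 0L)
  out <- tibble::tibble(
    category = c(names(cats), "synonyms", "unplaced"),
    n = c(unname(n_acc),
          sum(st %in% pointed_statuses(), na.rm = TRUE),
          sum(st == "unplaced", na.rm = TRUE))
  )
  class(out) <- unique(c("rank_summary", class(out)))
  out
}

#' Difference between two checklist summaries
#'
#' Per-category absolute differences between two [summarize_checklist()]
#' results across the six headline categories (genera, species, subspecies,
#' varieties, forms, synonyms), plus their total. Differences are absolute
#' because a release table reports the magnitude of change per category
#' regardless of direction; the signed delta (`b - a`) is exposed alongside
#' for transparency.
#'
#' @param a,b `rank_summary` tibbles.
#' @return a `summary_diff` tibble with columns `category`, `n_a`, `n_b`,
#'   `signed`, `difference`; the total is available via [glance()] or
#'   `attr(x, "total_difference")`.
#' @export
diff_summaries <- function(a, b) {
  cats <- c("genera", "species", "subspecies", "varieties", "forms",
            "synonyms")
  take <- function(s) {
    v <- setNames(s$n, s$category)[cats]
    v[is.na(v)] <- 0L
    v
  }
  va <- take(a)
  vb <- take(b)
  out <- tibble::tibble(
    category = cats, n_a = unname(va), n_b = unname(vb),
    signed = unname(vb - va), difference = abs(unname(vb - va)))
  attr(out, "total_difference") <- sum(out$difference)
  class(out) <- unique(c("summary_diff", class(out)))
  out
}

#' Expert-verification coverage per subfamily
#'
#' From working-table records, counts the genera within each subfamily
#' (excluding unplaced genera) and the percentage of them verified by a
#' taxon expert. A genus counts as verified when any of its records carries
#' a non-empty `verified` entry. Percentages are rounded to integers.
#'
#' @param working_records tibble from [read_working_table()].
#' @return tibble with columns `subfamily`, `n_genera`, `pct_verified`.
#' @export
verification_coverage <- function(working_records) {
  wr <- working_records
  parsed_genus <- vapply(strsplit(trimws(wr$taxon_name), "\\s+"),
                         function(t) t[1], character(1))
  status <- normalize_status(wr$taxon_status)
  rank <- normalize_rank(wr$rank)
  ver <- nzchar(blank_na(wr$verified))

  # verified flag aggregated over every record of the genus
  ver_by_genus <- tapply(ver, parsed_genus, any)

  genera <- tibble::tibble(
    subfamily = blank_na(wr$subfamily),
    genus = parsed_genus,
    rank = rank, status = status
  ) %>%
    dplyr::filter(rank == "genus", status != "unplaced" | is.na(status)) %>%
    dplyr::distinct(subfamily, genus)

  genera$verified <- unname(ver_by_genus[genera$genus])
  genera %>%
    dplyr::group_by(subfamily) %>%
    dplyr::summarise(
      n_genera = dplyr::n(),
      pct_verified = as.integer(round(100 * mean(verified))),
      .groups = "drop") %>%
    dplyr::arrange(subfamily)
}

#' Name overlap between an older backbone and a checklist
#'
#' Set arithmetic over normalized name strings (lower-cased canonical plus
#' normalized authorship — names are compared as strings because the two
#' systems are independently keyed): how many names exist in both, how many
#' the checklist adds, and how many the old backbone holds from other
#' sources only. The two conservation identities
#' `in_both + added_from_checklist = |checklist|` and
#' `in_both + other_sources_only = |old backbone|` are asserted on every
#' call.
#'
#' @param old_backbone a `taxon_backbone` or checklist tibble (the older
#'   snapshot).
#' @param checklist a checklist tibble (the newer, curated list).
#' @return an `overlap_report`: list with counts `in_both`,
#'   `added_from_checklist`, `other_sources_only` and a `detail` tibble
#'   (`name_key`, `genus`, `set` in both/checklist_only/backbone_only).
#' @export
name_overlap <- function(old_backbone, checklist) {
  old_rec <- if (inherits(old_backbone, "taxon_backbone")) {
    dplyr::filter(old_backbone$records, taxon_id != "__family_root__")
  } else {
    old_backbone
  }
  key_old <- unique(make_name_key(old_rec$scientific_name,
                                  old_rec$scientific_name_authorship))
  new_keys <- make_name_key(checklist$scientific_name,
                            checklist$scientific_name_authorship)
  key_new <- unique(new_keys)

  in_both <- intersect(key_new, key_old)
  added <- setdiff(key_new, key_old)
  other <- setdiff(key_old, key_new)

  stopifnot(length(in_both) + length(added) == length(key_new),
            length(in_both) + length(other) == length(key_old))

  genus_of <- setNames(blank_na(checklist$genus), new_keys)
  genus_old <- setNames(blank_na(old_rec$genus),
                        make_name_key(old_rec$scientific_name,
                                      old_rec$scientific_name_authorship))
  detail <- dplyr::bind_rows(
    tibble::tibble(name_key = in_both, genus = unname(genus_of[in_both]),
                   set = "both"),
    tibble::tibble(name_key = added, genus = unname(genus_of[added]),
                   set = "checklist_only"),
    tibble::tibble(name_key = other, genus = unname(genus_old[other]),
                   set = "backbone_only"))

  structure(list(
    in_both = length(in_both),
    added_from_checklist = length(added),
    other_sources_only = length(other),
    n_checklist = length(key_new),
    n_old_backbone = length(key_old),
    detail = detail
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n",
      "  in both:               ", x$in_both, "\n",
      "  added from checklist:  ", x$added_from_checklist, "\n",
      "  other sources only:    ", x$other_sources_only, "\n", sep = "")
  invisible(x)
}

#' Genera contributing many new names
#'
#' Filters the per-genus counts of names newly added from the checklist to
#' those exceeding a threshold, in descending order.
#'
#' @param overlap an `overlap_report` from [name_overlap()].
#' @param threshold minimum count (exclusive).
#' @return tibble with columns `genus`, `n_new`, descending.
#' @export
per_genus_new_names <- function(overlap, threshold = 250) {
  overlap$detail %>%
    dplyr::filter(set == "checklist_only", !is.na(genus), nzchar(genus)) %>%
    dplyr::count(genus, name = "n_new") %>%
    dplyr::filter(n_new > threshold) %>%
    dplyr::arrange(dplyr::desc(n_new), genus)
}
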