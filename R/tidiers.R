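#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an overlap report
#'
#' @param x an `overlap_report` from [name_overlap()].
#' @param ... unused.
#' @return one row per overlap class: `set`, `n`.
#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(
    set = c("both", "checklist_only", "backbone_only"),
    n = c(x$in_both, x$added_from_checklist, x$other_sources_only))
}

#' @rdname tidy.overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(in_both = x$in_both,
                 added_from_checklist = x$added_from_checklist,
                 other_sources_only = x$other_sources_only,
                 n_checklist = x$n_checklist,
                 n_old_backbone = x$n_old_backbone)
}

#' Tidy an impact report
#'
#' @param x an `impact_report` from [evaluate_impact()].
#' @param ... unused.
#' @return the rank-transition matrix in long form (`old_rank`, `new_rank`,
#'   `n`).
#' @export
tidy.impact_report <- function(x, ...) x$transitions

#' @rdname tidy.impact_report
#' @export
glance.impact_report <- function(x, ...) {
  tibble::tibble(n = x$n, improved_total = x$improved_total,
                 reassigned_same_rank = x$reassigned_same_rank,
                 still_higher_rank = x$still_higher_rank,
                 parse_failures = x$parse_failures)
}

#' Tidy a summary diff
#'
#' @param x a `summary_diff` from [diff_summaries()].
#' @param ... unused.
#' @return the per-category difference table.
#' @export
tidy.summary_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "summary_diff")
  out
}

#' @rdname tidy.summary_diff
#' @export
glance.summary_diff <- function(x, ...) {
  tibble::tibble(total_difference = attr(x, "total_difference"))
}

#' Tidy a backbone
#'
#' @param x a `taxon_backbone`.
#' @param ... unused.
#' @return the indexed record table.
#' @export
tidy.taxon_backbone <- function(x, ...) tibble::as_tibble(x$records)

#' @rdname tidy.taxon_backbone
#' @export
glance.taxon_backbone <- function(x, ...) {
  rec <- x$records
  tibble::tibble(
    n_records = nrow(rec),
    n_accepted = sum(rec$taxonomic_status == "accepted"),
    n_synonymized = sum(rec$taxonomic_status %in% pointed_statuses()),
    n_unplaced = sum(rec$taxonomic_status == "unplaced"),
    n_issues = nrow(x$issues))
}

#' Total of a summary diff
#' @param diff a `summary_diff`.
#' @return integer total of the per-category absolute differences.
#' @export
total_difference <- function(diff) attr(diff, "total_difference")
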