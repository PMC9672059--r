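#' Build an indexed taxonomic backbone from a checklist
#'
#' Turns a checklist into a validated, indexed taxonomy supporting synonym
#' resolution and hierarchical fallback. The build populates a canonical-name
#' index (authorship-stripped, case-folded), a genus index over accepted
#' genus records, and resolves a parent for every record: an explicit
#' `parent_name_usage_id` when present and valid, otherwise the accepted
#' genus record matching the `genus` field (species-group records) or the
#' family root (genus records). A single family-rank root is synthesized
#' when the checklist has none, so family-level fallback always has a
#' target.
#'
#' Validation enumerates dangling pointers, accepted-pointer chains longer
#' than one hop, parent cycles and rank inversions; offending records are
#' indexed but flagged in the report.
#'
#' @param checklist a checklist tibble ([read_dwca()], [new_checklist()], ...).
#' @return an object of class `taxon_backbone`.
#' @export
build_backbone <- function(checklist) {
  if (nrow(checklist) == 0) stop("cannot build a backbone from an empty checklist",
                                 call. = FALSE)
  rec <- tibble::as_tibble(as.data.frame(checklist))
  for (col in checklist_columns()) rec[[col]] <- blank_na(rec[[col]])

  issues <- validate_checklist(rec)

  # synthesized family root
  fam_rows <- which(rec$taxon_rank == "family")
  if (length(fam_rows) > 0) {
    family_id <- rec$taxon_id[fam_rows[1]]
  } else {
    fam_name <- names(sort(table(rec$family[nzchar(rec$family)]),
                           decreasing = TRUE))[1]
    if (is.null(fam_name) || is.na(fam_name)) fam_name <- "Fabaceae"
    family_id <- "__family_root__"
    root <- rec[0, ]
    root[1, ] <- as.list(setNames(rep("", ncol(rec)), names(rec)))
    root$taxon_id <- family_id
    root$family <- fam_name
    root$scientific_name <- fam_name
    root$taxon_rank <- "family"
    root$taxonomic_status <- "accepted"
    rec <- dplyr::bind_rows(rec, root)
  }

  rec$canonical_lower <- tolower(rec$scientific_name)
  rec$pooled_rank <- pool_rank(rec$taxon_rank)

  ids <- rec$taxon_id
  id_index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(ids)) assign(ids[i], i, envir = id_index)

  # parent resolution
  genus_rows <- which(rec$taxon_rank == "genus" &
                        rec$taxonomic_status == "accepted")
  genus_index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in genus_rows) {
    gname <- if (nzchar(rec$genus[i])) rec$genus[i] else rec$scientific_name[i]
    if (nzchar(gname) && !exists(gname, envir = genus_index, inherits = FALSE)) {
      assign(gname, ids[i], envir = genus_index)
    }
  }
  # accepted species records keyed by "genus epithet" (for infraspecific parents)
  species_key <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in which(rec$taxon_rank == "species" &
                    rec$taxonomic_status == "accepted")) {
    key <- tolower(paste(rec$genus[i], rec$specific_epithet[i]))
    if (!exists(key, envir = species_key, inherits = FALSE)) {
      assign(key, ids[i], envir = species_key)
    }
  }

  parent <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    p <- rec$parent_name_usage_id[i]
    if (nzchar(p) && exists(p, envir = id_index, inherits = FALSE)) {
      parent[i] <- p
      next
    }
    rk <- rec$taxon_rank[i]
    if (identical(rec$taxon_id[i], family_id)) {
      parent[i] <- ""
    } else if (rk %in% c("subspecies", "variety", "form")) {
      key <- tolower(paste(rec$genus[i], rec$specific_epithet[i]))
      sp <- if (exists(key, envir = species_key, inherits = FALSE))
        get(key, envir = species_key) else ""
      if (nzchar(sp)) parent[i] <- sp
      else if (exists(rec$genus[i], envir = genus_index, inherits = FALSE))
        parent[i] <- get(rec$genus[i], envir = genus_index)
      else parent[i] <- family_id
    } else if (rk == "species") {
      if (nzchar(rec$genus[i]) &&
          exists(rec$genus[i], envir = genus_index, inherits = FALSE))
        parent[i] <- get(rec$genus[i], envir = genus_index)
      else parent[i] <- family_id
    } else {
      parent[i] <- family_id
    }
  }
  rec$parent_resolved <- parent

  # canonical index over all records
  canonical_index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(rec))) {
    key <- rec$canonical_lower[i]
    if (!nzchar(key)) next
    cur <- get0(key, envir = canonical_index, ifnotfound = character())
    assign(key, c(cur, ids[i]), envir = canonical_index)
  }

  bb <- structure(
    list(records = rec, id_index = id_index, canonical_index = canonical_index,
         genus_index = genus_index, family_id = family_id,
         issues = issues),
    class = "taxon_backbone")

  bb$issues <- dplyr::bind_rows(issues, chain_issues(bb))
  bb
}

# accepted-chain, cycle and rank-inversion diagnostics
chain_issues <- function(bb) {
  rec <- bb$records
  iss <- list()
  pointed <- which(rec$taxonomic_status %in% pointed_statuses() &
                     nzchar(rec$accepted_name_usage_id))
  for (i in pointed) {
    tgt <- backbone_row(bb, rec$accepted_name_usage_id[i])
    if (is.null(tgt)) next # dangling already reported
    if (rec$taxonomic_status[tgt] != "accepted") {
      iss[[length(iss) + 1]] <- tibble::tibble(
        issue = "accepted_chain", taxon_id = rec$taxon_id[i],
        detail = paste0("accepted pointer lands on non-accepted record '",
                        rec$taxon_id[tgt], "' (", rec$taxonomic_status[tgt],
                        "); chain longer than one hop"))
    }
  }
  # parent cycles / rank inversions
  depth <- rank_depth(rec$pooled_rank)
  for (i in seq_len(nrow(rec))) {
    p <- rec$parent_resolved[i]
    if (!nzchar(p)) next
    j <- backbone_row(bb, p)
    if (is.null(j)) next
    if (!is.na(depth[i]) && !is.na(depth[j]) && depth[j] >= depth[i]) {
      iss[[length(iss) + 1]] <- tibble::tibble(
        issue = "rank_inversion", taxon_id = rec$taxon_id[i],
        detail = paste0("parent '", p, "' (", rec$taxon_rank[j],
                        ") is not coarser than ", rec$taxon_rank[i]))
    }
    # cycle walk (bounded)
    seen <- character()
    cur <- rec$taxon_id[i]
    while (nzchar(cur)) {
      if (cur %in% seen) {
        iss[[length(iss) + 1]] <- tibble::tibble(
          issue = "parent_cycle", taxon_id = rec$taxon_id[i],
          detail = paste0("parent chain revisits '", cur, "'"))
        break
      }
      seen <- c(seen, cur)
      k <- backbone_row(bb, cur)
      if (is.null(k)) break
      cur <- rec$parent_resolved[k]
    }
  }
  if (length(iss) == 0) {
    return(tibble::tibble(issue = character(), taxon_id = character(),
                          detail = character()))
  }
  dplyr::distinct(dplyr::bind_rows(iss))
}

backbone_row <- function(bb, taxon_id) {
  get0(taxon_id, envir = bb$id_index, ifnotfound = NULL)
}

#' @export
print.taxon_backbone <- function(x, ...) {
  cat("<taxon_backbone> ", nrow(x$records), " records (",
      sum(x$records$taxonomic_status == "accepted"), " accepted); ",
      nrow(x$issues), " validation issue(s)\n", sep = "")
  invisible(x)
}

#' Validation issues of a backbone
#' @param backbone a `taxon_backbone`.
#' @return tibble of issues (`issue`, `taxon_id`, `detail`).
#' @export
backbone_issues <- function(backbone) backbone$issues

#' Resolve a record to its accepted name
#'
#' An accepted record resolves to itself; synonyms and the other pointed
#' statuses follow `accepted_name_usage_id` (chains longer than the one-hop
#' contract are followed to their accepted terminus, and flagged at build
#' time); unplaced records have no accepted name. A misapplied start carries
#' `terminal_status = "misapplied"` so downstream consumers can exclude
#' misapplications while still obtaining the pointer target.
#'
#' @param backbone a `taxon_backbone`.
#' @param taxon_id a single record identifier.
#' @return list with `accepted_id` (`NA` when unresolvable) and
#'   `terminal_status`.
#' @export
resolve_accepted <- function(backbone, taxon_id) {
  i <- backbone_row(backbone, taxon_id)
  if (is.null(i)) stop("unknown taxon_id: ", taxon_id, call. = FALSE)
  rec <- backbone$records
  status0 <- rec$taxonomic_status[i]
  if (status0 == "accepted") {
    return(list(accepted_id = rec$taxon_id[i], terminal_status = "accepted"))
  }
  if (status0 == "unplaced") {
    return(list(accepted_id = NA_character_, terminal_status = "unplaced"))
  }
  cur <- i
  hops <- 0L
  while (hops < nrow(rec)) {
    nxt_id <- rec$accepted_name_usage_id[cur]
    if (!nzchar(nxt_id)) {
      return(list(accepted_id = NA_character_,
                  terminal_status = rec$taxonomic_status[cur]))
    }
    j <- backbone_row(backbone, nxt_id)
    if (is.null(j)) {
      return(list(accepted_id = NA_character_,
                  terminal_status = rec$taxonomic_status[cur]))
    }
    if (rec$taxonomic_status[j] == "accepted") {
      terminal <- if (status0 == "misapplied") "misapplied" else "accepted"
      return(list(accepted_id = rec$taxon_id[j], terminal_status = terminal))
    }
    if (rec$taxonomic_status[j] == "unplaced") {
      return(list(accepted_id = NA_character_, terminal_status = "unplaced"))
    }
    cur <- j
    hops <- hops + 1L
  }
  list(accepted_id = NA_character_, terminal_status = rec$taxonomic_status[cur])
}

#' Walk parent pointers to an ancestor at a given rank
#'
#' @param backbone a `taxon_backbone`.
#' @param taxon_id a single record identifier.
#' @param rank target rank (coarser than the record's own rank), one of
#'   `"family"`, `"genus"`, `"species"`.
#' @return the ancestor's `taxon_id`, or `NA` if the chain is broken before
#'   reaching the requested rank.
#' @export
parent_at_rank <- function(backbone, taxon_id, rank) {
  rank <- match.arg(rank, c("family", "genus", "species"))
  i <- backbone_row(backbone, taxon_id)
  if (is.null(i)) stop("unknown taxon_id: ", taxon_id, call. = FALSE)
  rec <- backbone$records
  cur <- rec$parent_resolved[i]
  steps <- 0L
  while (nzchar(cur) && steps < nrow(rec)) {
    j <- backbone_row(backbone, cur)
    if (is.null(j)) return(NA_character_)
    if (identical(rec$taxon_rank[j], rank)) return(rec$taxon_id[j])
    cur <- rec$parent_resolved[j]
    steps <- steps + 1L
  }
  NA_character_
}
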