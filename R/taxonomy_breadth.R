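#' Phylogenetic breadth of a family
#'
#' Counts, at each of the eight named ranks, how many distinct named taxa are
#' represented among a family's members, using the NCBI-style lineage of each
#' member's source genome. Distinctness is by taxon name at the rank; members
#' whose taxon id is absent from the lineage table, or whose lineage is
#' unnamed at a rank, contribute nothing at that rank.
#'
#' @param members member table for one family.
#' @param lineages lineage table from \code{\link{read_lineage_table}}.
#' @return list with \code{family_id}, \code{distinct} (named integer vector
#'   over \code{\link{RANKS}}) and \code{n_members_with_lineage}.
#' @export
breadth_profile <- function(members, lineages) {
  hit <- match(members$taxon_id, lineages$taxon_id)
  lin <- lineages[hit[!is.na(hit)], , drop = FALSE]
  distinct <- vapply(RANKS, function(r) {
    length(unique(lin[[r]][!is.na(lin[[r]])]))
  }, integer(1))
  list(family_id = members$family_id[1L], distinct = distinct,
       n_members_with_lineage = sum(!is.na(hit)))
}

#' Breadth profiles for every family in a catalog
#'
#' @param catalog a \code{family_catalog}.
#' @param lineages lineage table.
#' @return data.frame: \code{family_id}, \code{n_species} ...
#'   \code{n_domains}, \code{n_members_with_lineage}.
#' @export
breadth_table <- function(catalog, lineages) {
  fams <- split_families(catalog)
  rows <- lapply(fams, function(m) {
    bp <- breadth_profile(m, lineages)
    df <- as.data.frame(as.list(bp$distinct))
    names(df) <- RANK_COLS
    cbind(data.frame(family_id = bp$family_id, stringsAsFactors = FALSE), df,
          n_members_with_lineage = bp$n_members_with_lineage)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select and rank function-unknown families (FUnkFams)
#'
#' A family is a FUnkFam when it passes the quality filter, no member has an
#' exact-match domain annotation, and its members span at least
#' \code{min_distinct} distinct taxa at \code{rank} (by default two or more
#' classes). Selected families are ranked by phylogenetic breadth:
#' lexicographically on (distinct domains, distinct phyla, distinct classes,
#' number of unique sequences), all descending, with ascending
#' \code{family_id} as the final deterministic tiebreak. The ranking score is
#' this package's convention; it is echoed in output headers.
#'
#' @param screened output of \code{\link{screen_families}} merged with
#'   \code{\link{breadth_table}} (one row per family carrying filter,
#'   annotation and breadth columns).
#' @param rank rank at which breadth is thresholded (default \code{"class"}).
#' @param min_distinct minimum distinct taxa at \code{rank} (default 2).
#' @return data.frame sorted by rank score with columns of \code{screened}
#'   plus \code{is_funkfam}, \code{rank_used}, \code{distinct_at_rank}.
#' @export
select_funkfams <- function(screened, rank = "class", min_distinct = 2L) {
  if (!rank %in% RANKS) {
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(RANKS, collapse = ", "))
  }
  need <- c("family_id", "pass_filter", "annotated", "n_unique", RANK_COLS)
  missing <- setdiff(need, names(screened))
  if (length(missing)) {
    stop("screened table missing column(s): ", paste(missing, collapse = ", "))
  }
  rank_col <- RANK_COLS[match(rank, RANKS)]
  out <- screened
  out$rank_used <- rank
  out$distinct_at_rank <- out[[rank_col]]
  out$is_funkfam <- out$pass_filter & !out$annotated &
    out$distinct_at_rank >= min_distinct
  ord <- order(-out$n_domains, -out$n_phyla, -out$n_classes, -out$n_unique,
               out$family_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breadth histogram of selected FUnkFams
#'
#' For each rank, the number of FUnkFams whose members span at least
#' \code{min_distinct} distinct taxa at that rank.
#'
#' @param selections output of \code{\link{select_funkfams}}.
#' @param min_distinct breadth threshold per rank (default 2).
#' @return named integer vector over \code{\link{RANKS}}.
#' @export
breadth_histogram <- function(selections, min_distinct = 2L) {
  ff <- selections[selections$is_funkfam, , drop = FALSE]
  counts <- vapply(RANK_COLS, function(col) {
    sum(ff[[col]] >= min_distinct)
  }, integer(1))
  names(counts) <- RANKS
  counts
}
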