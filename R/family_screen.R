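#' Number of unique member sequences in a family
#'
#' Distinct normalized amino-acid sequences among the members; duplicated
#' proteins (identical after normalization) count once.
#'
#' @param members member table for one family (rows of a
#'   \code{\link{read_family_catalog}} result).
#' @return integer count of distinct sequences.
#' @export
count_unique <- function(members) {
  if (NROW(members) == 0L) stop("family has no members")
  length(unique(normalize_aa(members$aa_seq)))
}

#' Family quality filter
#'
#' A family passes when it has at least \code{min_unique} distinct member
#' sequences and at most \code{max_truncated_frac} of its members are
#' truncated. A member is truncated when the underlying gene call lacks a
#' start codon or a stop codon (inclusive or). The truncation bound is a
#' strict inequality: a family with exactly half its members truncated
#' passes the truncation test.
#'
#' @param members member table for one family.
#' @param min_unique minimum distinct sequences (default 3).
#' @param max_truncated_frac maximum tolerated truncated fraction (default
#'   0.5; families with strictly more fail).
#' @return list with \code{family_id}, \code{n_members}, \code{n_unique},
#'   \code{frac_truncated}, \code{passed}, \code{reasons} (character vector,
#'   subset of \code{TOO_FEW_UNIQUE}, \code{TOO_MANY_TRUNCATED}).
#' @export
filter_family <- function(members, min_unique = 3L, max_truncated_frac = 0.5) {
  if (NROW(members) == 0L) stop("family has no members")
  if (!is.numeric(min_unique) || min_unique < 1) {
    stop("min_unique must be >= 1")
  }
  if (!is.numeric(max_truncated_frac) || max_truncated_frac < 0 ||
      max_truncated_frac > 1) {
    stop("max_truncated_frac must lie in [0, 1]")
  }
  n_members <- NROW(members)
  n_unique <- count_unique(members)
  truncated <- !(members$has_start & members$has_stop)
  frac_truncated <- mean(truncated)
  reasons <- character()
  if (n_unique < min_unique) reasons <- c(reasons, "TOO_FEW_UNIQUE")
  if (frac_truncated > max_truncated_frac) {
    reasons <- c(reasons, "TOO_MANY_TRUNCATED")
  }
  list(family_id = members$family_id[1L], n_members = n_members,
       n_unique = n_unique, frac_truncated = frac_truncated,
       passed = length(reasons) == 0L, reasons = reasons)
}

#' Build an exact-match annotation index
#'
#' Hash index from normalized amino-acid sequence to the database records
#' carrying that exact sequence. Because annotation screening asks for a 100%
#' identical hit over the full protein length, string equality on normalized
#' sequences is sufficient and bit-exact; no aligner is involved. Multiple
#' records with the same sequence are kept as a list under one key.
#'
#' @param records annotation records from \code{\link{read_annotation_db}};
#'   all rows must share one \code{db_name}.
#' @return object of class \code{annotation_index}.
#' @export
build_annotation_index <- function(records) {
  if (NROW(records) && length(unique(records$db_name)) != 1L) {
    stop("annotation index requires records from a single database")
  }
  env <- new.env(hash = TRUE, parent = emptyenv(),
                 size = max(29L, NROW(records)))
  if (NROW(records)) {
    keys <- normalize_aa(records$aa_seq)
    for (i in seq_len(NROW(records))) {
      k <- keys[i]
      entry <- list(seq_id = records$seq_id[i],
                    domain_accessions = records$domain_accessions[[i]])
      env[[k]] <- c(if (!is.null(env[[k]])) env[[k]], list(entry))
    }
  }
  structure(list(db_name = if (NROW(records)) records$db_name[1L]
                           else NA_character_,
                 lookup = env, n_records = NROW(records)),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", x$db_name, "-", x$n_records, "records,",
      length(ls(x$lookup)), "distinct sequences\n")
  invisible(x)
}

#' Annotation status of a family
#'
#' A member hits a database when its normalized sequence equals a database
#' sequence exactly (100% identity over the full length). The family is
#' \code{annotated} when at least one hit carries one or more domain
#' accessions; exact hits to database entries with an empty domain list are
#' recorded for transparency but do not set the flag.
#'
#' @param members member table for one family.
#' @param indexes list of \code{annotation_index} objects.
#' @return list with \code{family_id}, \code{hits} (data.frame: db_name,
#'   seq_id, db_seq_id, domains as comma-joined string) and \code{annotated}.
#' @export
annotation_status <- function(members, indexes) {
  if (inherits(indexes, "annotation_index")) indexes <- list(indexes)
  keys <- normalize_aa(members$aa_seq)
  rows <- list()
  annotated <- FALSE
  for (idx in indexes) {
    for (i in seq_along(keys)) {
      found <- idx$lookup[[keys[i]]]
      if (is.null(found)) next
      for (entry in found) {
        rows[[length(rows) + 1L]] <- data.frame(
          db_name = idx$db_name, seq_id = members$seq_id[i],
          db_seq_id = entry$seq_id,
          domains = paste(entry$domain_accessions, collapse = ","),
          stringsAsFactors = FALSE)
        if (length(entry$domain_accessions)) annotated <- TRUE
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(db_name = character(), seq_id = character(),
               db_seq_id = character(), domains = character(),
               stringsAsFactors = FALSE)
  list(family_id = members$family_id[1L], hits = hits, annotated = annotated)
}

#' Screen every family in a catalog
#'
#' Applies \code{\link{filter_family}} and \code{\link{annotation_status}}
#' to each family and returns one row per family. Only exact-match
#' (\code{annotation_mode = "exact"}) screening is implemented; the homology
#' mode is reserved for catalogs whose genomes are absent from the annotation
#' databases and is not supported.
#'
#' @param catalog a \code{family_catalog}.
#' @param indexes list of \code{annotation_index} objects.
#' @param min_unique,max_truncated_frac passed to \code{\link{filter_family}}.
#' @param annotation_mode \code{"exact"} (the default) or \code{"homology"}
#'   (errors: not supported).
#' @return data.frame with one row per family: \code{family_id},
#'   \code{n_members}, \code{n_unique}, \code{frac_truncated},
#'   \code{pass_filter}, \code{reasons}, \code{annotated}.
#' @export
screen_families <- function(catalog, indexes, min_unique = 3L,
                            max_truncated_frac = 0.5,
                            annotation_mode = c("exact", "homology")) {
  annotation_mode <- match.arg(annotation_mode)
  if (annotation_mode == "homology") {
    stop("homology-mode annotation screening is not supported; ",
         "use exact matching or pre-annotate the catalog")
  }
  fams <- split_families(catalog)
  rows <- lapply(fams, function(m) {
    dec <- filter_family(m, min_unique, max_truncated_frac)
    ann <- annotation_status(m, indexes)
    data.frame(family_id = dec$family_id, n_members = dec$n_members,
               n_unique = dec$n_unique, frac_truncated = dec$frac_truncated,
               pass_filter = dec$passed,
               reasons = paste(dec$reasons, collapse = ";"),
               annotated = ann$annotated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
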