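# The eight named ranks used throughout, ordered from most to least specific.
#' Taxonomic ranks tracked by breadth profiling
#'
#' Character vector of the eight named ranks, ordered species to domain.
#' @export
RANKS <- c("species", "genus", "family", "order", "class", "phylum",
           "kingdom", "domain")

# Plural column names used in the catalog report, parallel to RANKS.
RANK_COLS <- c("n_species", "n_genera", "n_families", "n_orders",
               "n_classes", "n_phyla", "n_kingdoms", "n_domains")

# IUPAC amino-acid alphabet (20 standard + B J O U X Z ambiguity/rare codes).
AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYBJOUXZ", "")[[1]]

#' Normalize an amino-acid sequence
#'
#' Uppercases the sequence and strips exactly one trailing translation-stop
#' symbol \code{"*"}. An internal \code{"*"} (a likely pseudogene or frameshift
#' artifact) or any letter outside the IUPAC amino-acid alphabet is an error.
#' Normalization is idempotent.
#'
#' @param aa character vector of amino-acid sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_aa <- function(aa) {
  if (!is.character(aa)) stop("amino-acid sequences must be character")
  out <- toupper(aa)
  out <- sub("\\*$", "", out)
  if (any(!nzchar(out))) {
    stop("empty amino-acid sequence after normalization")
  }
  bad <- grepl("\\*", out, fixed = FALSE)
  if (any(bad)) {
    stop("internal stop symbol '*' in sequence(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  residues <- unique(strsplit(paste(out, collapse = ""), "")[[1]])
  alien <- setdiff(residues, AA_LETTERS)
  if (length(alien)) {
    stop("non-IUPAC amino-acid letter(s): ", paste(alien, collapse = ", "))
  }
  out
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, comment.char = "")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
}

#' Read a protein-family catalog
#'
#' Reads the family multi-FASTA and its membership table and joins them into a
#' single validated catalog. Every FASTA record must have a membership row and
#' vice versa; sequence ids must be unique. Sequences are normalized (see
#' \code{\link{normalize_aa}}). Rows are returned in lexicographic
#' \code{family_id}, then \code{seq_id}, order.
#'
#' The membership table is a header-bearing TSV with columns
#' \code{seq_id}, \code{family_id}, \code{taxon_id}, \code{has_start},
#' \code{has_stop}; the two flags are encoded 1/0 and record whether the
#' underlying gene call had a start / stop codon.
#'
#' @param fasta_path path to the protein multi-FASTA.
#' @param membership_tsv_path path to the membership TSV.
#' @return a \code{data.frame} of class \code{family_catalog} with columns
#'   \code{seq_id}, \code{aa_seq}, \code{family_id}, \code{taxon_id},
#'   \code{has_start}, \code{has_stop}.
#' @export
read_family_catalog <- function(fasta_path, membership_tsv_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  memb <- read_tsv_strict(membership_tsv_path)
  need <- c("seq_id", "family_id", "taxon_id", "has_start", "has_stop")
  if (!all(need %in% names(memb))) {
    stop("membership table missing column(s): ",
         paste(setdiff(need, names(memb)), collapse = ", "))
  }
  if (anyDuplicated(memb$seq_id)) {
    stop("duplicate seq_id in membership table: ",
         paste(unique(memb$seq_id[duplicated(memb$seq_id)]), collapse = ", "))
  }
  only_fa <- setdiff(ids, memb$seq_id)
  if (length(only_fa)) {
    stop("FASTA id(s) absent from membership table: ",
         paste(only_fa, collapse = ", "))
  }
  only_tsv <- setdiff(memb$seq_id, ids)
  if (length(only_tsv)) {
    stop("membership id(s) absent from FASTA: ",
         paste(only_tsv, collapse = ", "))
  }
  flags <- function(x, col) {
    if (!all(x %in% c("0", "1"))) {
      stop("column ", col, " must be encoded 1/0")
    }
    x == "1"
  }
  cat <- data.frame(
    seq_id = memb$seq_id,
    aa_seq = normalize_aa(as.character(seqs)[match(memb$seq_id, ids)]),
    family_id = memb$family_id,
    taxon_id = memb$taxon_id,
    has_start = flags(memb$has_start, "has_start"),
    has_stop = flags(memb$has_stop, "has_stop"),
    stringsAsFactors = FALSE
  )
  cat <- cat[order(cat$family_id, cat$seq_id, method = "radix"), ,
             drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- c("family_catalog", "data.frame")
  cat
}

#' Split a catalog into per-family member tables
#'
#' @param catalog a \code{family_catalog}.
#' @return named list of member data.frames, in lexicographic family order.
#' @export
split_families <- function(catalog) {
  split(as.data.frame(catalog), factor(catalog$family_id,
        levels = sort(unique(catalog$family_id), method = "radix")))
}

#' Read a flattened taxonomy lineage table
#'
#' The TSV must have a \code{taxon_id} column plus exactly the eight named
#' ranks (\code{species} ... \code{domain}) in its header. Blank cells become
#' \code{NA} (taxon unnamed at that rank); duplicate taxon ids and unknown
#' rank columns are errors.
#'
#' @param tsv_path path to the lineage TSV.
#' @return data.frame keyed by \code{taxon_id} with one column per rank.
#' @export
read_lineage_table <- function(tsv_path) {
  lin <- read_tsv_strict(tsv_path)
  if (!"taxon_id" %in% names(lin)) stop("lineage table needs a taxon_id column")
  extra <- setdiff(names(lin), c("taxon_id", RANKS))
  if (length(extra)) {
    stop("unknown rank column(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(RANKS, names(lin))
  if (length(missing)) {
    stop("lineage table missing rank column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lin$taxon_id)) {
    stop("duplicate taxon_id: ",
         paste(unique(lin$taxon_id[duplicated(lin$taxon_id)]), collapse = ", "))
  }
  for (r in RANKS) lin[[r]][!nzchar(lin[[r]])] <- NA_character_
  lin <- lin[, c("taxon_id", RANKS)]
  rownames(lin) <- lin$taxon_id
  lin
}

#' Read BLAST/Diamond tabular alignments (outfmt 6, "m8")
#'
#' Parses the standard 12-column tab-separated alignment report. Only the
#' query, subject, percent-identity, alignment-length, e-value and bit-score
#' columns are retained; extra columns beyond 12 are ignored. Rows with
#' non-numeric values in the numeric columns are rejected with their line
#' number rather than skipped.
#'
#' @param path path to the m8 file.
#' @return data.frame with columns \code{read_id}, \code{subject_id},
#'   \code{pct_identity}, \code{align_len}, \code{evalue}, \code{bit_score},
#'   one row per alignment in file order.
#' @export
read_m8 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(read_id = character(), subject_id = character(),
                      pct_identity = numeric(), align_len = integer(),
                      evalue = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L)) {
    stop("m8 line ", which(nf < 12L)[1L], " has fewer than 12 columns")
  }
  pick <- function(i) vapply(parts, `[[`, character(1), i)
  num <- function(i, name) {
    x <- suppressWarnings(as.numeric(pick(i)))
    if (anyNA(x)) {
      stop("non-numeric ", name, " in m8 line ", which(is.na(x))[1L])
    }
    x
  }
  hits <- data.frame(
    read_id = pick(1L),
    subject_id = pick(2L),
    pct_identity = num(3L, "pident"),
    align_len = as.integer(num(4L, "length")),
    evalue = num(11L, "evalue"),
    bit_score = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pident outside [0, 100] in m8 file ", path)
  }
  if (any(hits$align_len < 1L)) stop("alignment length < 1 in m8 file ", path)
  hits
}

#' Read an annotation database (FASTA + domain table)
#'
#' The domain table is a TSV with columns \code{seq_id} and
#' \code{domain_accessions}; the latter holds comma-separated accessions and
#' may be empty (a catalogued sequence with no assigned domain). Sequences are
#' normalized exactly like catalog sequences so that exact-match screening is
#' bit-exact string equality.
#'
#' @param fasta_path annotated-protein FASTA.
#' @param domains_tsv_path TSV mapping sequence id to domain accessions.
#' @param db_name label for this database (e.g. \code{"pfam"}).
#' @return data.frame with columns \code{db_name}, \code{seq_id},
#'   \code{aa_seq} and list-column \code{domain_accessions}.
#' @export
read_annotation_db <- function(fasta_path, domains_tsv_path, db_name) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  dom <- read_tsv_strict(domains_tsv_path)
  if (!all(c("seq_id", "domain_accessions") %in% names(dom))) {
    stop("domain table needs seq_id and domain_accessions columns")
  }
  if (anyDuplicated(dom$seq_id)) stop("duplicate seq_id in domain table")
  miss <- setdiff(ids, dom$seq_id)
  if (length(miss)) {
    stop("annotation FASTA id(s) without domain row: ",
         paste(miss, collapse = ", "))
  }
  acc <- dom$domain_accessions[match(ids, dom$seq_id)]
  data.frame(
    db_name = db_name,
    seq_id = ids,
    aa_seq = normalize_aa(as.character(seqs)),
    domain_accessions = I(lapply(acc, function(a) {
      if (!nzchar(a)) character() else strsplit(a, ",", fixed = TRUE)[[1]]
    })),
    stringsAsFactors = FALSE
  )
}

#' Read sample metadata
#'
#' Required columns: \code{sample_id}, \code{environment},
#' \code{read_length} (bp), \code{genome_equivalents} (library depth divided
#' by average genome size, as estimated upstream), \code{stratum}. Any further
#' columns are treated as covariates and kept as character; numeric covariates
#' are coerced at model-fit time.
#'
#' @param tsv_path metadata TSV.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_sample_metadata <- function(tsv_path) {
  md <- read_tsv_strict(tsv_path)
  need <- c("sample_id", "environment", "read_length", "genome_equivalents",
            "stratum")
  if (!all(need %in% names(md))) {
    stop("sample metadata missing column(s): ",
         paste(setdiff(need, names(md)), collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md$read_length <- as.integer(md$read_length)
  md$genome_equivalents <- as.numeric(md$genome_equivalents)
  if (anyNA(md$read_length) || any(md$read_length <= 0L)) {
    stop("read_length must be a positive integer")
  }
  if (anyNA(md$genome_equivalents) || any(md$genome_equivalents <= 0)) {
    stop("genome_equivalents must be positive")
  }
  rownames(md) <- md$sample_id
  md
}

#' Write / read the per-family catalog report
#'
#' One row per family with its filter decision, annotation status, breadth
#' profile and final selection flag. Re-reading the file reproduces the data
#' frame (round-trip identity on the column set).
#'
#' @param report data.frame with columns \code{family_id}, \code{n_members},
#'   \code{n_unique}, \code{pass_filter}, \code{annotated},
#'   \code{n_species} ... \code{n_domains}, \code{is_funkfam}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_catalog_report <- function(report, path) {
  need <- c("family_id", "n_members", "n_unique", "pass_filter", "annotated",
            RANK_COLS, "is_funkfam")
  missing <- setdiff(need, names(report))
  if (length(missing)) {
    stop("catalog report missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- report[, need, drop = FALSE]
  for (col in c("pass_filter", "annotated", "is_funkfam")) {
    out[[col]] <- as.integer(out[[col]])
  }
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_catalog_report
#' @export
read_catalog_report <- function(path) {
  rep <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE)
  for (col in c("pass_filter", "annotated", "is_funkfam")) {
    rep[[col]] <- as.logical(rep[[col]])
  }
  rep$family_id <- as.character(rep$family_id)
  rep
}

#' Write a numeric family-by-sample matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param key name of the first (row-name) column.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, key = "family_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- key
  write_tsv_plain(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, key = "family_id") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), key), drop = FALSE])
  rownames(mat) <- as.character(df[[key]])
  mat
}
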