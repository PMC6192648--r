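#' Best hit per read
#'
#' Reduces an alignment table to one hit per read: the hit with the highest
#' bit score, breaking ties by lower e-value and then by lexicographically
#' smallest subject id, so results are independent of input row order. Hits
#' whose subject is not in the family map are dropped (their count is
#' reported in the \code{n_unmapped} attribute).
#'
#' @param hits alignment table from \code{\link{read_m8}}.
#' @param subject_to_family named character vector mapping subject
#'   (protein) ids to family ids.
#' @return data.frame with one row per read (\code{read_id},
#'   \code{family_id}, \code{subject_id}, \code{pct_identity},
#'   \code{align_len}, \code{evalue}, \code{bit_score}), ordered by
#'   \code{read_id}; attribute \code{n_unmapped} counts dropped hit rows.
#' @export
best_hit_per_read <- function(hits, subject_to_family) {
  fam <- unname(subject_to_family[hits$subject_id])
  n_unmapped <- sum(is.na(fam))
  keep <- !is.na(fam)
  hits <- hits[keep, , drop = FALSE]
  fam <- fam[keep]
  if (!NROW(hits)) {
    out <- data.frame(read_id = character(), family_id = character(),
                      subject_id = character(), pct_identity = numeric(),
                      align_len = integer(), evalue = numeric(),
                      bit_score = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  ord <- order(hits$read_id, -hits$bit_score, hits$evalue, hits$subject_id,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  fam <- fam[ord]
  first <- !duplicated(hits$read_id)
  out <- data.frame(read_id = hits$read_id[first], family_id = fam[first],
                    hits[first, c("subject_id", "pct_identity", "align_len",
                                  "evalue", "bit_score")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-family read counts for one sample
#'
#' A read counts toward its best-hit family only when the hit has at least
#' \code{min_identity} percent identity and the alignment covers the whole
#' read (\code{align_len >= read_length}). A family with at least one
#' counted read is called present.
#'
#' @param assignments best-hit table from \code{\link{best_hit_per_read}}.
#' @param read_length the sample's read length in bp.
#' @param min_identity identity threshold in percent (default 99).
#' @param family_ids families to report (rows of the output); defaults to
#'   the families seen in \code{assignments}.
#' @return named integer vector of counts over \code{family_ids}.
#' @export
call_presence <- function(assignments, read_length, min_identity = 99.0,
                          family_ids = NULL) {
  if (missing(read_length) || is.null(read_length) || is.na(read_length)) {
    stop("read_length is required to assess whole-read coverage")
  }
  accepted <- assignments$pct_identity >= min_identity &
    assignments$align_len >= read_length
  if (is.null(family_ids)) {
    family_ids <- sort(unique(assignments$family_id), method = "radix")
  }
  tab <- table(factor(assignments$family_id[accepted], levels = family_ids))
  counts <- as.integer(tab)
  names(counts) <- family_ids
  counts
}

#' Counts matrix over samples
#'
#' Runs best-hit reduction and presence calling for each sample's m8 file and
#' assembles the family-by-sample counts matrix.
#'
#' @param m8_paths named character vector: sample id to m8 file path.
#' @param subject_to_family subject-to-family map.
#' @param samples sample metadata (\code{\link{read_sample_metadata}}).
#' @param family_ids row set of the output matrix.
#' @param min_identity identity threshold in percent.
#' @return integer matrix, families x samples.
#' @export
profile_counts <- function(m8_paths, subject_to_family, samples, family_ids,
                           min_identity = 99.0) {
  sample_ids <- names(m8_paths)
  if (is.null(sample_ids) || !all(sample_ids %in% samples$sample_id)) {
    stop("m8_paths must be named by sample ids present in the metadata")
  }
  counts <- matrix(0L, nrow = length(family_ids), ncol = length(sample_ids),
                   dimnames = list(family_ids, sample_ids))
  for (s in sample_ids) {
    hits <- read_m8(m8_paths[[s]])
    best <- best_hit_per_read(hits, subject_to_family)
    counts[, s] <- call_presence(
      best, read_length = samples[samples$sample_id == s, "read_length"],
      min_identity = min_identity, family_ids = family_ids)
  }
  counts
}

#' RPKG abundance
#'
#' Reads per kilobase of gene per genome equivalent: the read count divided
#' by the family's mean member length (amino acids x 3, in kb) and by the
#' sample's genome equivalents. Normalizes abundances for gene length and for
#' sequencing effort scaled by average genome size, making values comparable
#' across families and samples.
#'
#' @param counts family-by-sample counts matrix.
#' @param family_mean_len_aa named numeric vector: mean member protein length
#'   (aa) per family.
#' @param genome_equivalents named positive numeric vector per sample.
#' @return numeric matrix of RPKG values, same dimnames as \code{counts}.
#' @export
rpkg <- function(counts, family_mean_len_aa, genome_equivalents) {
  fams <- rownames(counts)
  smps <- colnames(counts)
  len <- family_mean_len_aa[fams]
  ge <- genome_equivalents[smps]
  if (anyNA(len)) stop("missing mean length for some families")
  if (anyNA(ge) || any(ge <= 0)) stop("genome_equivalents must be positive")
  kb <- len * 3 / 1000
  sweep(counts / kb, 2L, ge, "/")
}

#' Mean member length per family, in amino acids
#'
#' @param catalog a \code{family_catalog}.
#' @return named numeric vector over families.
#' @export
family_mean_length <- function(catalog) {
  vapply(split(nchar(catalog$aa_seq), catalog$family_id), mean, numeric(1))
}

#' Per-environment prevalence
#'
#' Fraction of each environment's samples in which a family is present.
#' Environments with zero samples are excluded.
#'
#' @param presence logical family-by-sample matrix.
#' @param sample_environments named character vector: sample id to
#'   environment label.
#' @return numeric matrix, families x environments, values in [0, 1].
#' @export
prevalence <- function(presence, sample_environments) {
  env <- sample_environments[colnames(presence)]
  if (anyNA(env)) stop("every sample needs an environment label")
  envs <- sort(unique(env), method = "radix")
  out <- vapply(envs, function(e) {
    rowMeans(presence[, env == e, drop = FALSE])
  }, numeric(nrow(presence)))
  out <- matrix(out, nrow = nrow(presence),
                dimnames = list(rownames(presence), envs))
  out
}

#' Binary entropy of a presence pattern
#'
#' Shannon entropy in bits of a family's present/absent indicator across all
#' samples: H(p) = -p log2 p - (1-p) log2(1-p) with p the presence fraction
#' and 0 log2 0 taken as 0. Maximal (1 bit) at 50% prevalence; 0 when the
#' family is always or never present.
#'
#' @param presence logical vector (one family across samples) or logical
#'   matrix (families x samples).
#' @return numeric entropy in bits (vector over families for matrix input).
#' @export
presence_entropy <- function(presence) {
  h <- function(p) {
    terms <- c(p, 1 - p)
    -sum(ifelse(terms > 0, terms * log2(terms), 0))
  }
  if (is.matrix(presence)) {
    if (!ncol(presence)) stop("need at least one sample")
    vapply(rowMeans(presence), h, numeric(1))
  } else {
    if (!length(presence)) stop("need at least one sample")
    h(mean(presence))
  }
}

#' Retain families with high presence entropy
#'
#' Keeps families whose entropy reaches the empirical
#' \code{(1 - top_fraction)} quantile (linear-interpolation quantile); ties
#' at the threshold are retained. Used to pre-filter families without enough
#' presence variation for association testing.
#'
#' @param entropies named numeric vector of entropies (bits) per family.
#' @param top_fraction fraction to retain, in (0, 1] (default 0.25).
#' @return character vector of retained family ids.
#' @export
entropy_filter <- function(entropies, top_fraction = 0.25) {
  if (!length(entropies)) stop("no entropies supplied")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]")
  }
  cut <- stats::quantile(entropies, probs = 1 - top_fraction, type = 7,
                         names = FALSE)
  names(entropies)[entropies >= cut]
}

#' Retain families spanning several phyla
#'
#' @param selections table carrying \code{family_id} and \code{n_phyla}
#'   (e.g. \code{\link{select_funkfams}} output).
#' @param min_phyla minimum distinct phyla (default 2).
#' @return character vector of retained family ids.
#' @export
phylum_filter <- function(selections, min_phyla = 2L) {
  selections$family_id[selections$n_phyla >= min_phyla]
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' 1 - 2 sum(min(x_i, y_i)) / (sum x + sum y): 0 when the two samples share
#' all families in equal abundance, 1 when they share none.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis dissimilarity matrix over samples
#'
#' Computed with \code{vegan::vegdist} on the transposed abundance matrix
#' (samples as rows).
#'
#' @param abundance family-by-sample abundance matrix (counts or RPKG).
#' @return symmetric sample-by-sample matrix with zero diagonal.
#' @export
bc_matrix <- function(abundance) {
  if (any(colSums(abundance) == 0)) {
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(colnames(abundance)[colSums(abundance) == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(abundance), method = "bray"))
}

#' Within- and between-environment dissimilarity distributions
#'
#' Partitions the off-diagonal sample pairs of a dissimilarity matrix into
#' within-environment and between-environment groups and tests whether
#' between-environment dissimilarity is higher than within (one-sided
#' Mann-Whitney U against the pooled within-group values).
#'
#' @param bc symmetric sample dissimilarity matrix.
#' @param sample_environments named environment labels (exactly two levels).
#' @return list with one \code{within_<env>} numeric vector per environment,
#'   \code{between}, and \code{p_value}. Environments with fewer than two
#'   samples yield an empty within-group vector.
#' @export
beta_diversity_groups <- function(bc, sample_environments) {
  env <- sample_environments[colnames(bc)]
  if (anyNA(env)) stop("every sample needs an environment label")
  envs <- sort(unique(env), method = "radix")
  if (length(envs) != 2L) stop("expected exactly two environment labels")
  pairs <- which(upper.tri(bc), arr.ind = TRUE)
  vals <- bc[pairs]
  e1 <- env[pairs[, 1L]]
  e2 <- env[pairs[, 2L]]
  within <- lapply(envs, function(e) vals[e1 == e & e2 == e])
  names(within) <- paste0("within_", envs)
  between <- vals[e1 != e2]
  pooled_within <- unlist(within, use.names = FALSE)
  p <- if (length(between) && length(pooled_within)) {
    stats::wilcox.test(between, pooled_within, alternative = "greater",
                       exact = FALSE)$p.value
  } else {
    NA_real_
  }
  c(within, list(between = between, p_value = p))
}
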