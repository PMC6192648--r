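# Fixture builders and independent oracles shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_prot <- function(len) paste(sample(AA, len, replace = TRUE),
                                 collapse = "")

make_members <- function(seqs, family_id = "FAM1", taxa = NULL,
                         has_start = TRUE, has_stop = TRUE) {
  n <- length(seqs)
  data.frame(
    seq_id = sprintf("%s_m%02d", rep_len(family_id, n), seq_len(n)),
    aa_seq = seqs, family_id = rep_len(family_id, n),
    taxon_id = if (is.null(taxa)) sprintf("T%02d", seq_len(n)) else taxa,
    has_start = rep_len(has_start, n), has_stop = rep_len(has_stop, n),
    stringsAsFactors = FALSE)
}

make_lineage <- function(taxon_id, ...) {
  ranks <- list(...)
  df <- data.frame(taxon_id = taxon_id, stringsAsFactors = FALSE)
  # lower ranks default to unique names per taxon; unspecified upper ranks
  # nest inside the rank above them so lineages stay internally consistent
  for (r in c("species", "genus", "family", "order")) {
    df[[r]] <- if (is.null(ranks[[r]])) sprintf("%s_%s", r, taxon_id)
               else ranks[[r]]
  }
  df$domain <- if (is.null(ranks$domain)) "domain_all" else ranks$domain
  df$kingdom <- if (is.null(ranks$kingdom)) paste0("kingdom_", df$domain)
                else ranks$kingdom
  df$phylum <- if (is.null(ranks$phylum)) paste0("phylum_", df$kingdom)
               else ranks$phylum
  df$class <- if (is.null(ranks$class)) paste0("class_", df$phylum)
              else ranks$class
  df[, c("taxon_id", funkfams::RANKS)]
}

make_db <- function(seqs, domains, db_name = "db1") {
  data.frame(db_name = rep_len(db_name, length(seqs)),
             seq_id = sprintf("%s_p%03d", rep_len(db_name, length(seqs)),
                              seq_along(seqs)),
             aa_seq = seqs,
             domain_accessions = I(domains), stringsAsFactors = FALSE)
}

# Oracle: all-pairs string-equality scan for family annotation status.
brute_annotated <- function(members, dbs) {
  mem <- toupper(sub("\\*$", "", members$aa_seq))
  for (db in dbs) {
    for (i in seq_len(nrow(db))) {
      if (length(db$domain_accessions[[i]]) == 0L) next
      if (any(mem == db$aa_seq[i])) return(TRUE)
    }
  }
  FALSE
}

# Oracle: textbook Benjamini-Hochberg step-up, written from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m))
  }
  pmin(1, q_sorted)[order(ord)]
}

# Oracle: two-stage grid search for the 2-parameter logistic MLE.
grid_mle_logistic <- function(y, x, lim = 4, coarse = 0.05, fine = 5e-4) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  best <- c(0, 0)
  for (stage in list(c(-lim, lim, coarse), c(-0.1, 0.1, fine))) {
    b0s <- best[1] + seq(stage[1], stage[2], by = stage[3])
    b1s <- best[2] + seq(stage[1], stage[2], by = stage[3])
    ll <- outer(b0s, b1s, Vectorize(loglik))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[ix[1]], b1s[ix[2]])
  }
  best
}

# Write a catalog fixture (FASTA + membership TSV) from a members table.
write_catalog_files <- function(members, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  writeLines(paste0(">", members$seq_id, "\n", members$aa_seq),
             file.path(dir, "cat.fasta"))
  memb <- members[, c("seq_id", "family_id", "taxon_id")]
  memb$has_start <- as.integer(members$has_start)
  memb$has_stop <- as.integer(members$has_stop)
  utils::write.table(memb, file.path(dir, "memb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(fasta = file.path(dir, "cat.fasta"),
       tsv = file.path(dir, "memb.tsv"))
}

# Generate the full default fixture into a temp dir; used by several files.
make_default_fixture <- function(seed = 7L, dir = withr::local_tempdir(
                                   .local_envir = parent.frame()), ...) {
  cfg <- sim_config(seed = seed, ...)
  truth <- generate_catalog(cfg, dir)
  mg <- generate_metagenomes(cfg, truth, dir)
  list(cfg = cfg, truth = truth, mg = mg, dir = dir)
}

default_pipeline_config <- function(dir, out_dir,
                                    covariates = c("group", "exposure"),
                                    ...) {
  pipeline_config(
    catalog_fasta = file.path(dir, "catalog.fasta"),
    membership_tsv = file.path(dir, "membership.tsv"),
    lineage_tsv = file.path(dir, "lineage.tsv"),
    annotation_dbs = list(
      db1 = list(fasta = file.path(dir, "db1.fasta"),
                 domains = file.path(dir, "db1_domains.tsv")),
      db2 = list(fasta = file.path(dir, "db2.fasta"),
                 domains = file.path(dir, "db2_domains.tsv"))),
    samples_tsv = file.path(dir, "samples.tsv"),
    m8_dir = dir, out_dir = out_dir, covariates = covariates, ...)
}

md5_of_dir <- function(dir, exclude = "manifest.json") {
  files <- setdiff(list.files(dir), exclude)
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  sums[order(names(sums))]
}
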