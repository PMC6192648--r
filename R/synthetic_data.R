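# 20 standard amino acids used for simulated proteins.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Assembles and validates the configuration for the synthetic fixture
#' generator. One seed fully determines every emitted byte. Families are
#' planted in four classes: passing and annotated, passing and unannotated
#' with broad taxonomic spread (the planted FUnkFams), passing and
#' unannotated but confined to one class, and failing (too few unique
#' sequences or too many truncated members).
#'
#' @param seed integer RNG seed.
#' @param n_families total number of families.
#' @param n_funkfams planted broad unannotated families.
#' @param frac_annotated fraction of families planted as annotated.
#' @param n_fail_few,n_fail_trunc failing families of each kind.
#' @param members_per_family integer range (min, max) of members for passing
#'   families.
#' @param mean_len_aa,sd_len_aa member protein length distribution
#'   (amino acids); the default mean of 250 aa matches typical full-length
#'   bacterial proteins.
#' @param frac_truncated_members per-member truncation probability within
#'   passing families (capped so no passing family exceeds 50%).
#' @param n_domains,n_phyla_per_domain,n_classes_per_phylum,n_taxa_per_class
#'   taxonomy shape.
#' @param n_samples_per_env samples per environment (two environments,
#'   \code{ENV_A} and \code{ENV_B}).
#' @param read_length read length in bp for all samples.
#' @param reads_per_present_family integer range of accepted reads for a
#'   present family in a sample.
#' @param identity_noise_frac decoy hit rows (sub-threshold identity or
#'   short alignment) per accepted read; decoys never alter counts.
#' @param frac_duplicate_hits fraction of accepted reads that also receive a
#'   second, lower-scoring hit row (exercises best-hit deduplication).
#' @param genome_equivalents_range positive range for per-sample genome
#'   equivalents.
#' @param base_prevalence presence probability of a family in samples of an
#'   environment it occupies (before planted effects).
#' @param bg_prevalence presence probability outside a family's home
#'   environment.
#' @param planted_effects list of planted presence-covariate effects, each a
#'   list with \code{family_index} (index into the planted FUnkFams),
#'   \code{covariate}, \code{stratum}, \code{beta} (log-odds).
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 20L,
                       n_funkfams = 5L,
                       frac_annotated = 0.25,
                       n_fail_few = 2L,
                       n_fail_trunc = 2L,
                       members_per_family = c(4L, 8L),
                       mean_len_aa = 250, sd_len_aa = 25,
                       frac_truncated_members = 0.1,
                       n_domains = 2L, n_phyla_per_domain = 2L,
                       n_classes_per_phylum = 2L, n_taxa_per_class = 4L,
                       n_samples_per_env = 10L,
                       read_length = 100L,
                       reads_per_present_family = c(1L, 20L),
                       identity_noise_frac = 0.3,
                       frac_duplicate_hits = 0.25,
                       genome_equivalents_range = c(5, 50),
                       base_prevalence = 0.7,
                       bg_prevalence = 0.05,
                       planted_effects = list(
                         list(family_index = 1L, covariate = "group",
                              stratum = "ENV_A", beta = 3))) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              n_funkfams = as.integer(n_funkfams),
              frac_annotated = frac_annotated,
              n_fail_few = as.integer(n_fail_few),
              n_fail_trunc = as.integer(n_fail_trunc),
              members_per_family = as.integer(members_per_family),
              mean_len_aa = mean_len_aa, sd_len_aa = sd_len_aa,
              frac_truncated_members = frac_truncated_members,
              n_domains = as.integer(n_domains),
              n_phyla_per_domain = as.integer(n_phyla_per_domain),
              n_classes_per_phylum = as.integer(n_classes_per_phylum),
              n_taxa_per_class = as.integer(n_taxa_per_class),
              n_samples_per_env = as.integer(n_samples_per_env),
              read_length = as.integer(read_length),
              reads_per_present_family = as.integer(reads_per_present_family),
              identity_noise_frac = identity_noise_frac,
              frac_duplicate_hits = frac_duplicate_hits,
              genome_equivalents_range = genome_equivalents_range,
              base_prevalence = base_prevalence,
              bg_prevalence = bg_prevalence,
              planted_effects = planted_effects)
  fracs <- c(cfg$frac_annotated, cfg$frac_truncated_members,
             cfg$identity_noise_frac, cfg$frac_duplicate_hits,
             cfg$base_prevalence, cfg$bg_prevalence)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  n_annot <- round(cfg$frac_annotated * cfg$n_families)
  if (cfg$n_funkfams + n_annot + cfg$n_fail_few + cfg$n_fail_trunc >
      cfg$n_families) {
    stop("planted family classes exceed n_families")
  }
  n_classes <- cfg$n_domains * cfg$n_phyla_per_domain *
    cfg$n_classes_per_phylum
  if (n_classes < 2L) {
    stop("taxonomy shape must provide at least two classes to plant ",
         "broad families")
  }
  if (any(cfg$genome_equivalents_range <= 0)) {
    stop("genome_equivalents_range must be positive")
  }
  if (diff(cfg$members_per_family) < 0 ||
      cfg$members_per_family[1L] < 3L) {
    stop("members_per_family must be an increasing range with min >= 3")
  }
  structure(cfg, class = "sim_config")
}

set_sim_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Derive a distinct member sequence by substituting one residue at a
# member-specific position; exact equality is the only similarity any
# downstream operation measures, so point substitution suffices.
mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- sample(setdiff(AA20, chars[pos]), 1L)
  paste(chars, collapse = "")
}

build_taxonomy <- function(cfg) {
  rows <- list()
  t_idx <- 0L
  for (d in seq_len(cfg$n_domains)) {
    for (p in seq_len(cfg$n_phyla_per_domain)) {
      for (cl in seq_len(cfg$n_classes_per_phylum)) {
        for (t in seq_len(cfg$n_taxa_per_class)) {
          t_idx <- t_idx + 1L
          rows[[t_idx]] <- data.frame(
            taxon_id = sprintf("T%04d", t_idx),
            species = sprintf("Species_%04d", t_idx),
            genus = sprintf("Genus_%04d", t_idx),
            family = sprintf("Family_%04d", t_idx),
            order = sprintf("Order_%04d", t_idx),
            class = sprintf("Class_%d_%d_%d", d, p, cl),
            phylum = sprintf("Phylum_%d_%d", d, p),
            kingdom = sprintf("Kingdom_%d", d),
            domain = sprintf("Domain_%d", d),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  lin <- do.call(rbind, rows)
  lin[, c("taxon_id", RANKS)]
}

#' Generate a synthetic protein-family catalog
#'
#' Writes a complete, internally consistent catalog fixture to \code{dir}:
#' protein FASTA, membership TSV, lineage TSV, two annotation databases
#' (FASTA + domain TSV each) and a ground-truth manifest JSON. Annotated
#' families have one member copied verbatim into a database with a domain
#' accession; one narrow unannotated family additionally matches a database
#' entry that carries no domains (an exact hit that must not count as
#' annotation). The same seed reproduces the files byte for byte.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir output directory (created if absent).
#' @return the ground-truth list, invisibly mirrored in
#'   \code{manifest.json}: \code{families} (data.frame with the expected
#'   filter decision, annotation flag, breadth counts and FUnkFam flag per
#'   family), \code{paths}, \code{config}.
#' @export
generate_catalog <- function(config, dir) {
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set_sim_seed(cfg$seed)

  lineage <- build_taxonomy(cfg)
  classes <- sort(unique(lineage$class), method = "radix")

  n_annot <- round(cfg$frac_annotated * cfg$n_families)
  kinds <- c(rep("funkfam", cfg$n_funkfams), rep("annotated", n_annot),
             rep("fail_few", cfg$n_fail_few),
             rep("fail_trunc", cfg$n_fail_trunc))
  kinds <- c(kinds, rep("narrow", cfg$n_families - length(kinds)))

  seq_rows <- list()
  fam_rows <- list()
  db_rows <- list(list(), list())
  seq_idx <- 0L
  acc_idx <- 0L
  narrow_decoy_done <- FALSE

  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    fam_id <- sprintf("F%04d", i)
    len <- max(50L, round(stats::rnorm(1L, cfg$mean_len_aa, cfg$sd_len_aa)))
    ancestor <- random_protein(len)
    n_mem <- sample(seq(cfg$members_per_family[1L],
                        cfg$members_per_family[2L]), 1L)
    if (kind == "fail_few") n_mem <- 3L
    if (kind == "fail_trunc") n_mem <- 4L

    seqs <- vapply(seq_len(n_mem), function(m) mutate_at(ancestor, m),
                   character(1))
    if (kind == "fail_few") seqs[2L] <- seqs[1L]  # only 2 unique of 3

    # taxon assignment controls breadth: broad kinds span >=2 classes
    broad <- kind %in% c("funkfam", "annotated")
    if (broad) {
      cls <- sample(classes, 2L)
      pool <- lineage$taxon_id[lineage$class %in% cls]
    } else {
      cls <- sample(classes, 1L)
      pool <- lineage$taxon_id[lineage$class == cls]
    }
    taxa <- sample(pool, n_mem, replace = TRUE)
    if (broad) {  # guarantee both classes are represented
      taxa[1L] <- sample(lineage$taxon_id[lineage$class == cls[1L]], 1L)
      taxa[2L] <- sample(lineage$taxon_id[lineage$class == cls[2L]], 1L)
    }

    truncated <- stats::runif(n_mem) < cfg$frac_truncated_members
    if (kind != "fail_trunc" && sum(truncated) / n_mem > 0.5) {
      truncated[seq_len(n_mem)] <- FALSE
      truncated[seq_len(floor(n_mem / 2))] <- TRUE
    }
    if (kind == "fail_trunc") {
      truncated <- c(TRUE, TRUE, TRUE, FALSE)  # 75% > 50%
    }
    lacks_start <- truncated & (stats::runif(n_mem) < 0.5)
    lacks_stop <- truncated & !lacks_start

    ids <- sprintf("S%05d", seq_idx + seq_len(n_mem))
    seq_idx <- seq_idx + n_mem
    fam_rows[[i]] <- data.frame(
      seq_id = ids, family_id = fam_id, taxon_id = taxa,
      has_start = as.integer(!lacks_start),
      has_stop = as.integer(!lacks_stop), stringsAsFactors = FALSE)
    seq_rows[[i]] <- data.frame(seq_id = ids, aa_seq = seqs,
                                stringsAsFactors = FALSE)

    if (kind == "annotated") {
      acc_idx <- acc_idx + 1L
      db <- 1L + (acc_idx %% 2L)
      db_rows[[db]][[length(db_rows[[db]]) + 1L]] <- data.frame(
        seq_id = sprintf("DBP%04d", acc_idx), aa_seq = seqs[1L],
        domain_accessions = sprintf("D%04d", acc_idx),
        stringsAsFactors = FALSE)
    }
    if (kind == "narrow" && !narrow_decoy_done) {
      # exact DB hit with an empty domain list: recorded, not annotating
      db_rows[[1L]][[length(db_rows[[1L]]) + 1L]] <- data.frame(
        seq_id = "DBP_NODOM", aa_seq = seqs[1L], domain_accessions = "",
        stringsAsFactors = FALSE)
      narrow_decoy_done <- TRUE
    }
  }

  # unrelated database entries, with and without domains
  for (j in seq_len(6L)) {
    db <- 1L + (j %% 2L)
    db_rows[[db]][[length(db_rows[[db]]) + 1L]] <- data.frame(
      seq_id = sprintf("DBX%04d", j), aa_seq = random_protein(200L),
      domain_accessions = if (j %% 3L == 0L) "" else sprintf("DX%04d", j),
      stringsAsFactors = FALSE)
  }

  membership <- do.call(rbind, fam_rows)
  seqs_df <- do.call(rbind, seq_rows)

  paths <- list(
    catalog_fasta = file.path(dir, "catalog.fasta"),
    membership_tsv = file.path(dir, "membership.tsv"),
    lineage_tsv = file.path(dir, "lineage.tsv"),
    db1_fasta = file.path(dir, "db1.fasta"),
    db1_domains = file.path(dir, "db1_domains.tsv"),
    db2_fasta = file.path(dir, "db2.fasta"),
    db2_domains = file.path(dir, "db2_domains.tsv"),
    manifest = file.path(dir, "manifest.json"))

  write_fasta <- function(df, path) {
    writeLines(paste0(">", df$seq_id, "\n", df$aa_seq), path)
  }
  write_fasta(seqs_df, paths$catalog_fasta)
  write_tsv_plain(membership, paths$membership_tsv)
  write_tsv_plain(lineage, paths$lineage_tsv)
  for (db in 1:2) {
    df <- if (length(db_rows[[db]])) do.call(rbind, db_rows[[db]]) else
      data.frame(seq_id = character(), aa_seq = character(),
                 domain_accessions = character(), stringsAsFactors = FALSE)
    write_fasta(df, paths[[paste0("db", db, "_fasta")]])
    write_tsv_plain(df[, c("seq_id", "domain_accessions")],
                    paths[[paste0("db", db, "_domains")]])
  }

  # ground truth bookkeeping, from the generator's own assignments
  fam_ids <- sprintf("F%04d", seq_along(kinds))
  gt_rows <- lapply(seq_along(kinds), function(i) {
    m <- fam_rows[[i]]
    s <- seq_rows[[i]]
    lin <- lineage[match(m$taxon_id, lineage$taxon_id), , drop = FALSE]
    distinct <- vapply(RANKS, function(r) length(unique(lin[[r]])),
                       integer(1))
    n_unique <- length(unique(s$aa_seq))
    frac_trunc <- mean(!(m$has_start == 1L & m$has_stop == 1L))
    passed <- n_unique >= 3L && frac_trunc <= 0.5
    annotated <- kinds[i] == "annotated"
    df <- data.frame(family_id = fam_ids[i], kind = kinds[i],
                     n_members = nrow(m), n_unique = n_unique,
                     frac_truncated = frac_trunc, pass_filter = passed,
                     annotated = annotated, stringsAsFactors = FALSE)
    for (k in seq_along(RANKS)) df[[RANK_COLS[k]]] <- distinct[k]
    df$is_funkfam <- passed && !annotated && distinct["class"] >= 2L
    df
  })
  families <- do.call(rbind, gt_rows)
  stopifnot(identical(families$is_funkfam, families$kind == "funkfam"))

  truth <- list(families = families, paths = paths,
                config = unclass(cfg))
  jsonlite::write_json(truth, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  truth
}

balanced_labels <- function(levels, n) {
  sample(rep(levels, length.out = n))
}

#' Generate synthetic metagenome alignments and sample metadata
#'
#' Simulates shotgun-metagenome read recruitment for the catalog produced by
#' \code{\link{generate_catalog}}: per-sample m8 alignment files plus a
#' sample-metadata TSV for two environments. Presence of each passing family
#' in each sample follows a logistic model combining the family's
#' environment affinity with the configured planted covariate effects.
#' Accepted reads carry identity of at least 99% and an alignment spanning
#' the whole read; decoy hit rows (low identity or short alignment) and
#' duplicated hit rows are injected and must never change counts.
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth ground truth from \code{\link{generate_catalog}}.
#' @param dir output directory.
#' @return list: \code{samples} (metadata data.frame), \code{m8_paths}
#'   (named vector), \code{counts} (expected family-by-sample accepted-read
#'   tallies), \code{planted_effects} (resolved to family ids, with signs).
#'   Also appended to \code{manifest.json}.
#' @export
generate_metagenomes <- function(config, truth, dir) {
  cfg <- config
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set_sim_seed(cfg$seed + 1000003L)

  families <- truth$families
  fam_ids <- families$family_id
  membership <- read_tsv_strict(truth$paths$membership_tsv)
  members_of <- split(membership$seq_id, membership$family_id)

  envs <- c("ENV_A", "ENV_B")
  n <- cfg$n_samples_per_env
  samples <- do.call(rbind, lapply(envs, function(e) {
    data.frame(
      sample_id = sprintf("%s_S%03d", e, seq_len(n)),
      environment = e, stratum = e,
      read_length = cfg$read_length,
      genome_equivalents = round(stats::runif(
        n, cfg$genome_equivalents_range[1L],
        cfg$genome_equivalents_range[2L]), 3),
      group = balanced_labels(c("X", "Y"), n),
      exposure = balanced_labels(c(0L, 1L), n),
      stringsAsFactors = FALSE)
  }))

  # resolve planted effects: family_index indexes the planted FUnkFams
  ff_ids <- families$family_id[families$kind == "funkfam"]
  effects <- lapply(cfg$planted_effects, function(pe) {
    if (pe$family_index > length(ff_ids)) {
      stop("planted effect refers to a FUnkFam index beyond those planted")
    }
    list(family_id = ff_ids[pe$family_index], covariate = pe$covariate,
         stratum = pe$stratum, beta = pe$beta,
         term = if (pe$covariate == "group") "groupY" else pe$covariate,
         sign = sign(pe$beta))
  })

  # environment affinity per family: A-only, B-only, both, or rare
  affinity <- sample(c("A", "B", "both", "rare"), nrow(families),
                     replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
  logit <- function(p) log(p / (1 - p))
  base_logit <- matrix(logit(cfg$bg_prevalence), nrow(families), length(envs),
                       dimnames = list(fam_ids, envs))
  base_logit[affinity %in% c("A", "both"), "ENV_A"] <-
    logit(cfg$base_prevalence)
  base_logit[affinity %in% c("B", "both"), "ENV_B"] <-
    logit(cfg$base_prevalence)

  counts <- matrix(0L, nrow(families), nrow(samples),
                   dimnames = list(fam_ids, samples$sample_id))
  m8_paths <- stats::setNames(
    file.path(dir, paste0(samples$sample_id, ".m8")), samples$sample_id)

  for (s in seq_len(nrow(samples))) {
    smp <- samples[s, ]
    rows <- character()
    read_no <- 0L
    for (f in seq_along(fam_ids)) {
      if (!families$pass_filter[f]) next  # failing families carry no signal
      eta <- base_logit[f, smp$environment]
      for (pe in effects) {
        if (pe$family_id != fam_ids[f] || pe$stratum != smp$stratum) next
        # symmetric contrast: group log-odds difference is beta
        x <- if (pe$covariate == "group") as.numeric(smp$group == "Y")
             else as.numeric(smp[[pe$covariate]])
        eta <- eta + pe$beta * (x - 0.5)
      }
      present <- stats::runif(1L) < stats::plogis(eta)
      if (!present) next
      n_reads <- sample(seq(cfg$reads_per_present_family[1L],
                            cfg$reads_per_present_family[2L]), 1L)
      counts[f, s] <- n_reads
      mem <- members_of[[fam_ids[f]]]
      for (r in seq_len(n_reads)) {
        read_no <- read_no + 1L
        rid <- sprintf("%s_R%05d", smp$sample_id, read_no)
        subj <- sample(mem, 1L)
        bs <- round(stats::runif(1L, 70, 95), 1)
        rows <- c(rows, m8_row(rid, subj,
                               pident = round(stats::runif(1L, 99, 100), 1),
                               alen = cfg$read_length, evalue = 1e-20,
                               bits = bs))
        if (stats::runif(1L) < cfg$frac_duplicate_hits) {
          # secondary hit on the same read, strictly lower bit score
          rows <- c(rows, m8_row(rid, sample(mem, 1L),
                                 pident = round(stats::runif(1L, 95, 100), 1),
                                 alen = cfg$read_length, evalue = 1e-10,
                                 bits = bs - 10))
        }
      }
    }
    n_decoys <- round(cfg$identity_noise_frac * max(1L, read_no))
    all_subjects <- membership$seq_id
    for (d in seq_len(n_decoys)) {
      read_no <- read_no + 1L
      rid <- sprintf("%s_R%05d", smp$sample_id, read_no)
      short <- stats::runif(1L) < 0.5
      rows <- c(rows, m8_row(
        rid, sample(all_subjects, 1L),
        pident = if (short) round(stats::runif(1L, 99, 100), 1)
                 else round(stats::runif(1L, 80, 98.9), 1),
        alen = if (short) cfg$read_length - sample(5:50, 1L)
               else cfg$read_length,
        evalue = 1e-5, bits = round(stats::runif(1L, 40, 60), 1)))
    }
    writeLines(rows, m8_paths[[smp$sample_id]])
  }

  write_tsv_plain(samples, file.path(dir, "samples.tsv"))

  out <- list(samples = samples, m8_paths = m8_paths, counts = counts,
              planted_effects = effects)
  manifest <- jsonlite::read_json(truth$paths$manifest)
  manifest$metagenomes <- list(
    samples_tsv = file.path(dir, "samples.tsv"),
    m8_paths = as.list(m8_paths),
    counts = list(family_id = rownames(counts),
                  sample_id = colnames(counts),
                  values = unname(apply(counts, 1L, as.list))),
    planted_effects = effects)
  jsonlite::write_json(manifest, truth$paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out
}

m8_row <- function(rid, subj, pident, alen, evalue, bits) {
  mism <- max(0L, round(alen * (100 - pident) / 100))
  paste(rid, subj, sprintf("%.1f", pident), alen, mism, 0L, 1L, alen, 1L,
        alen, format(evalue, scientific = TRUE), sprintf("%.1f", bits),
        sep = "\t")
}

#' Simulate a presence matrix with optional planted covariate effects
#'
#' Association-level fixture: a family-by-sample presence matrix drawn from
#' per-family logistic models, together with sample metadata carrying one
#' categorical (\code{group}) and one numeric binary (\code{exposure})
#' covariate in a single stratum. With \code{effect = NULL} presence is
#' independent of the covariates (a null fixture); otherwise \code{effect}
#' is a list with \code{family_index}, \code{covariate} and \code{beta} and
#' shifts that family's log-odds by \code{beta} per covariate unit.
#'
#' @param n_families number of families.
#' @param n_samples number of samples (one stratum, \code{ENV_A}).
#' @param effect optional planted effect (see above).
#' @param base_prevalence_range presence probability range from which each
#'   family's baseline is drawn.
#' @param seed RNG seed.
#' @return list: \code{presence} (logical matrix), \code{samples}
#'   (metadata), \code{effect} (resolved with family id).
#' @export
simulate_presence <- function(n_families = 200L, n_samples = 100L,
                              effect = NULL,
                              base_prevalence_range = c(0.2, 0.8),
                              seed = 1L) {
  set_sim_seed(seed)
  fam_ids <- sprintf("F%04d", seq_len(n_families))
  samples <- data.frame(
    sample_id = sprintf("ENV_A_S%04d", seq_len(n_samples)),
    environment = "ENV_A", stratum = "ENV_A",
    read_length = 100L, genome_equivalents = 20,
    group = balanced_labels(c("X", "Y"), n_samples),
    exposure = balanced_labels(c(0L, 1L), n_samples),
    stringsAsFactors = FALSE)
  base_p <- stats::runif(n_families, base_prevalence_range[1L],
                         base_prevalence_range[2L])
  eta <- matrix(log(base_p / (1 - base_p)), n_families, n_samples)
  resolved <- NULL
  if (!is.null(effect)) {
    # symmetric contrast (+/- beta/2 around the baseline): the group
    # log-odds difference is beta without saturating either group
    x <- if (effect$covariate == "group") as.numeric(samples$group == "Y")
         else as.numeric(samples[[effect$covariate]])
    eta[effect$family_index, ] <- eta[effect$family_index, ] +
      effect$beta * (x - 0.5)
    resolved <- list(family_id = fam_ids[effect$family_index],
                     covariate = effect$covariate, beta = effect$beta,
                     term = if (effect$covariate == "group") "groupY"
                            else effect$covariate,
                     sign = sign(effect$beta))
  }
  presence <- matrix(stats::runif(length(eta)) < stats::plogis(eta),
                     n_families, n_samples,
                     dimnames = list(fam_ids, samples$sample_id))
  list(presence = presence, samples = samples, effect = resolved)
}
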