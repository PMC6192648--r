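#' Pipeline configuration
#'
#' Collects and validates every input path and threshold the pipeline uses.
#' Thresholds default to the screening and profiling constants used
#' throughout the package: families need at least 3 unique sequences and at
#' most 50% truncated members; FUnkFams span at least 2 classes; reads count
#' at 99% identity over the whole read; association pre-filters keep the top
#' 25% presence-entropy families spanning at least 2 phyla; discoveries are
#' called at q < 0.05.
#'
#' @param catalog_fasta,membership_tsv,lineage_tsv catalog input paths.
#' @param annotation_dbs named list: db name -> list(fasta, domains).
#' @param samples_tsv sample metadata path.
#' @param m8_dir directory holding one \code{<sample_id>.m8} per sample.
#' @param out_dir report directory (created).
#' @param min_unique,max_truncated_frac family quality filter.
#' @param breadth_rank,min_distinct FUnkFam breadth criterion.
#' @param min_identity read-recruitment identity threshold (percent).
#' @param entropy_top_fraction,min_phyla association pre-filters.
#' @param covariates,adjustment,stratum_var,q_threshold,fdr_pool association
#'   settings.
#' @param annotation_mode \code{"exact"} only (see
#'   \code{\link{screen_families}}).
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(catalog_fasta, membership_tsv, lineage_tsv,
                            annotation_dbs, samples_tsv = NULL,
                            m8_dir = NULL, out_dir,
                            min_unique = 3L, max_truncated_frac = 0.5,
                            breadth_rank = "class", min_distinct = 2L,
                            min_identity = 99.0,
                            entropy_top_fraction = 0.25, min_phyla = 2L,
                            covariates = character(),
                            adjustment = character(),
                            stratum_var = "stratum", q_threshold = 0.05,
                            fdr_pool = "per_stratum_covariate",
                            annotation_mode = "exact") {
  stopifnot(min_unique >= 1L,
            max_truncated_frac >= 0, max_truncated_frac <= 1,
            breadth_rank %in% RANKS, min_distinct >= 1L,
            min_identity >= 0, min_identity <= 100,
            entropy_top_fraction > 0, entropy_top_fraction <= 1,
            min_phyla >= 1L, q_threshold > 0, q_threshold < 1)
  structure(list(
    catalog_fasta = catalog_fasta, membership_tsv = membership_tsv,
    lineage_tsv = lineage_tsv, annotation_dbs = annotation_dbs,
    samples_tsv = samples_tsv, m8_dir = m8_dir, out_dir = out_dir,
    min_unique = as.integer(min_unique),
    max_truncated_frac = max_truncated_frac,
    breadth_rank = breadth_rank, min_distinct = as.integer(min_distinct),
    min_identity = min_identity,
    entropy_top_fraction = entropy_top_fraction,
    min_phyla = as.integer(min_phyla), covariates = covariates,
    adjustment = adjustment, stratum_var = stratum_var,
    q_threshold = q_threshold, fdr_pool = fdr_pool,
    annotation_mode = annotation_mode), class = "pipeline_config")
}

pipeline_stages <- c("screen", "breadth", "select", "profile", "ecology",
                     "associate")

#' Run the discovery and profiling pipeline
#'
#' Executes the stages in order — screen, breadth, select, profile, ecology,
#' associate — writing one TSV per product into \code{config$out_dir} plus a
#' run manifest (\code{manifest.json}) with the configuration, stage
#' funnel counts and file list. Identical configuration and inputs produce
#' identical output files; the wall-clock timestamp lives only in the
#' manifest. A subset of stages can be run (\code{stages}); later stages
#' load the earlier stages' products from \code{out_dir}, so resumed runs
#' match single-shot runs. The profile, ecology and associate stages are
#' skipped when no sample metadata / alignments are configured.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages character subset of the stage names, in any order.
#' @return invisible list of in-memory products: \code{report},
#'   \code{selections}, \code{counts}, \code{presence}, \code{rpkg},
#'   \code{ecology}, \code{association}, \code{funnel}.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- pipeline_stages[pipeline_stages %in% stages]

  inputs <- c(config$catalog_fasta, config$membership_tsv,
              config$lineage_tsv,
              unlist(lapply(config$annotation_dbs, unlist)),
              config$samples_tsv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  state <- list(funnel = list())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  need_catalog <- function() {
    if (is.null(state$catalog)) {
      state$catalog <<- read_family_catalog(config$catalog_fasta,
                                            config$membership_tsv)
    }
    state$catalog
  }
  need_screened <- function() {
    if (is.null(state$screened)) {
      state$screened <- utils::read.delim(out("screen.tsv"), sep = "\t",
                                          quote = "", check.names = FALSE,
                                          colClasses = NA)
      state$screened$family_id <- as.character(state$screened$family_id)
      state$screened$reasons[is.na(state$screened$reasons)] <- ""
      state <<- state
    }
    state$screened
  }
  need_selections <- function() {
    if (is.null(state$selections)) {
      sel <- utils::read.delim(out("funkfams.tsv"), sep = "\t", quote = "",
                               check.names = FALSE)
      sel$family_id <- as.character(sel$family_id)
      sel$is_funkfam <- as.logical(sel$is_funkfam)
      state$selections <<- sel
    }
    state$selections
  }

  if ("screen" %in% stages) {
    catalog <- need_catalog()
    indexes <- lapply(names(config$annotation_dbs), function(nm) {
      db <- config$annotation_dbs[[nm]]
      build_annotation_index(read_annotation_db(db$fasta, db$domains, nm))
    })
    state$screened <- screen_families(
      catalog, indexes, min_unique = config$min_unique,
      max_truncated_frac = config$max_truncated_frac,
      annotation_mode = config$annotation_mode)
    write_tsv_plain(state$screened, out("screen.tsv"))
    state$funnel$families_in <- nrow(state$screened)
    state$funnel$families_pass_filter <- sum(state$screened$pass_filter)
    state$funnel$families_unannotated <-
      sum(state$screened$pass_filter & !state$screened$annotated)
    log_stage("screen", nrow(state$screened), " families in, ",
              state$funnel$families_pass_filter, " pass filter, ",
              state$funnel$families_unannotated, " pass and unannotated")
  }

  if ("breadth" %in% stages) {
    catalog <- need_catalog()
    lineages <- read_lineage_table(config$lineage_tsv)
    state$breadth <- breadth_table(catalog, lineages)
    write_tsv_plain(state$breadth, out("breadth.tsv"))
    log_stage("breadth", "profiled ", nrow(state$breadth), " families")
  }

  if ("select" %in% stages) {
    screened <- need_screened()
    if (is.null(state$breadth)) {
      state$breadth <- utils::read.delim(out("breadth.tsv"), sep = "\t",
                                         quote = "", check.names = FALSE)
      state$breadth$family_id <- as.character(state$breadth$family_id)
    }
    merged <- merge(screened, state$breadth, by = "family_id", sort = TRUE)
    state$selections <- select_funkfams(merged, rank = config$breadth_rank,
                                        min_distinct = config$min_distinct)
    write_tsv_plain(state$selections, out("funkfams.tsv"))
    report <- state$selections
    report <- report[order(report$family_id, method = "radix"), ,
                     drop = FALSE]
    write_catalog_report(report, out("catalog_report.tsv"))
    hist <- breadth_histogram(state$selections)
    write_tsv_plain(data.frame(rank = names(hist), n_funkfams = hist),
                    out("breadth_histogram.tsv"))
    state$funnel$funkfams_selected <- sum(state$selections$is_funkfam)
    log_stage("select", state$funnel$funkfams_selected,
              " FUnkFams selected (rank score: domains, phyla, classes, ",
              "unique members; package convention)")
  }

  has_samples <- !is.null(config$samples_tsv) && !is.null(config$m8_dir)
  if ("profile" %in% stages && has_samples) {
    catalog <- need_catalog()
    samples <- read_sample_metadata(config$samples_tsv)
    state$samples <- samples
    m8_paths <- stats::setNames(
      file.path(config$m8_dir, paste0(samples$sample_id, ".m8")),
      samples$sample_id)
    absent <- m8_paths[!file.exists(m8_paths)]
    if (length(absent)) {
      stop("missing m8 file(s): ", paste(absent, collapse = ", "))
    }
    fam_ids <- sort(unique(catalog$family_id), method = "radix")
    subject_to_family <- stats::setNames(catalog$family_id, catalog$seq_id)
    state$counts <- profile_counts(m8_paths, subject_to_family, samples,
                                   fam_ids,
                                   min_identity = config$min_identity)
    state$presence <- state$counts >= 1L
    state$rpkg <- rpkg(state$counts, family_mean_length(catalog),
                       stats::setNames(samples$genome_equivalents,
                                       samples$sample_id))
    write_matrix_tsv(state$counts, out("counts.tsv"))
    write_matrix_tsv(state$presence * 1L, out("presence.tsv"))
    write_matrix_tsv(state$rpkg, out("rpkg.tsv"))
    state$funnel$samples_profiled <- nrow(samples)
    log_stage("profile", nrow(samples), " samples, ",
              sum(state$counts), " accepted reads")
  }

  if (any(c("ecology", "associate") %in% stages) && has_samples) {
    if (is.null(state$samples)) {
      state$samples <- read_sample_metadata(config$samples_tsv)
    }
    if (is.null(state$presence)) {
      # recompute rpkg from the exact integer counts rather than reading
      # back the formatted rpkg.tsv, so resumed runs are bit-identical
      state$counts <- read_matrix_tsv(out("counts.tsv"))
      state$presence <- state$counts >= 1L
      catalog <- need_catalog()
      state$rpkg <- rpkg(state$counts, family_mean_length(catalog),
                         stats::setNames(state$samples$genome_equivalents,
                                         state$samples$sample_id))
    }
  }

  if ("ecology" %in% stages && has_samples) {
    samples <- state$samples
    env <- stats::setNames(samples$environment, samples$sample_id)
    state$ecology <- list(
      prevalence = prevalence(state$presence, env),
      entropy = presence_entropy(state$presence))
    screened <- need_screened()
    pass <- screened$family_id[screened$pass_filter]
    abundance <- state$rpkg[pass, , drop = FALSE]
    nonzero <- colSums(abundance) > 0
    state$ecology$bc <- bc_matrix(abundance[, nonzero, drop = FALSE])
    state$ecology$beta_groups <-
      beta_diversity_groups(state$ecology$bc, env)
    write_matrix_tsv(state$ecology$prevalence, out("prevalence.tsv"))
    write_tsv_plain(data.frame(family_id = names(state$ecology$entropy),
                               entropy_bits = state$ecology$entropy),
                    out("entropy.tsv"))
    write_matrix_tsv(state$ecology$bc, out("bray_curtis.tsv"),
                     key = "sample_id")
    log_stage("ecology", "between- vs within-environment beta diversity ",
              "Mann-Whitney p = ",
              format(state$ecology$beta_groups$p_value, digits = 4))
  }

  if ("associate" %in% stages && has_samples &&
      length(config$covariates)) {
    selections <- need_selections()
    if (is.null(state$ecology)) {
      ent <- utils::read.delim(out("entropy.tsv"), sep = "\t", quote = "")
      state$ecology <- list(entropy = stats::setNames(
        ent$entropy_bits, as.character(ent$family_id)))
    }
    ff <- selections$family_id[selections$is_funkfam]
    keep <- intersect(
      intersect(ff, entropy_filter(state$ecology$entropy[ff],
                                   config$entropy_top_fraction)),
      phylum_filter(selections, config$min_phyla))
    state$funnel$families_tested <- length(keep)
    if (length(keep)) {
      state$association <- run_association(
        state$presence[keep, , drop = FALSE], state$samples,
        covariates = config$covariates, adjustment = config$adjustment,
        stratum_var = config$stratum_var,
        q_threshold = config$q_threshold, fdr_pool = config$fdr_pool)
      write_tsv_plain(state$association, out("association.tsv"))
      log_stage("associate", length(keep), " families tested, ",
                sum(state$association$significant), " significant at q < ",
                config$q_threshold)
    } else {
      log_stage("associate", "no family passed the pre-filters; skipped")
    }
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- tempfile()
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("funkfams")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages_run = stages,
    funnel = state$funnel,
    outputs = list.files(config$out_dir))
  unlink(cfg_file)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = state$selections, selections = state$selections,
                 counts = state$counts, presence = state$presence,
                 rpkg = state$rpkg, ecology = state$ecology,
                 association = state$association, funnel = state$funnel))
}
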