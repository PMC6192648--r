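#' Phenotype eligibility for association testing
#'
#' A covariate is eligible within a stratum when, after dropping missing
#' values, at least \code{min_levels} of its values occur at least
#' \code{min_obs_per_level} times ("at least two values with more than four
#' observations"). The same rule applies to numeric covariates, treating
#' distinct values as levels; a continuous covariate whose values never
#' repeat is therefore ineligible.
#'
#' @param values covariate values (character, factor or numeric); \code{NA}
#'   and empty strings are dropped first.
#' @param min_levels minimum number of qualifying levels (default 2).
#' @param min_obs_per_level minimum observations per qualifying level
#'   (default 5, i.e. strictly more than four).
#' @return list with \code{level_counts} (named integer vector) and
#'   \code{eligible}.
#' @export
phenotype_eligible <- function(values, min_levels = 2L,
                               min_obs_per_level = 5L) {
  v <- values
  if (is.character(v)) v[!nzchar(v)] <- NA
  v <- v[!is.na(v)]
  counts <- table(as.character(v))
  level_counts <- stats::setNames(as.integer(counts), names(counts))
  list(level_counts = level_counts,
       eligible = sum(level_counts >= min_obs_per_level) >= min_levels)
}

#' Fit a logistic regression by maximum likelihood
#'
#' Fits presence/absence against a design matrix by iteratively reweighted
#' least squares (convergence when the relative deviance change is below
#' 1e-8, at most 100 iterations). Perfect or quasi-separation — some fitted
#' probability within 1e-10 of 0 or 1 together with a diverging coefficient —
#' is flagged rather than reported as an estimate, since the maximum
#' likelihood does not exist there.
#'
#' @param y binary response vector (0/1 or logical) with both classes
#'   present.
#' @param design numeric model matrix including the intercept column.
#' @return object of class \code{logistic_fit}: \code{coefficients},
#'   \code{std_errors}, \code{converged}, \code{separation_flag},
#'   \code{n_obs}, \code{df_residual}.
#' @export
fit_logistic <- function(y, design) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) stop("response is single-class; nothing to fit")
  if (!is.matrix(design)) design <- as.matrix(design)
  if (nrow(design) != length(y)) stop("design rows must match response length")
  if (nrow(design) < ncol(design)) {
    stop("fewer observations than parameters")
  }
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = design, y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  coefs <- fit$coefficients
  mu <- fit$fitted.values
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(coefs)) > 10
  p <- ncol(design)
  covmat <- chol2inv(qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  names(se) <- names(coefs)
  structure(list(coefficients = coefs, std_errors = se,
                 converged = fit$converged, separation_flag = separated,
                 n_obs = length(y), df_residual = length(y) - p),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit:", x$n_obs, "obs,", length(x$coefficients),
      "parameters; converged:", x$converged,
      if (x$separation_flag) "(separated)" else "", "\n")
  print(cbind(coefficient = x$coefficients, std_error = x$std_errors))
  invisible(x)
}

#' Wald t-tests on logistic coefficients
#'
#' t = coefficient / standard error, with a two-sided p-value from the
#' Student t distribution on \code{n_obs - n_parameters} degrees of freedom.
#'
#' @param fit a \code{logistic_fit} (converged, not separated).
#' @return data.frame: \code{term}, \code{coefficient}, \code{std_error},
#'   \code{t_stat}, \code{p_value}.
#' @export
wald_tests <- function(fit) {
  if (!fit$converged || fit$separation_flag) {
    stop("Wald tests require a converged, non-separated fit")
  }
  if (any(fit$std_errors == 0)) stop("zero standard error")
  t_stat <- fit$coefficients / fit$std_errors
  p <- 2 * stats::pt(abs(t_stat), df = fit$df_residual, lower.tail = FALSE)
  data.frame(term = names(fit$coefficients),
             coefficient = unname(fit$coefficients),
             std_error = unname(fit$std_errors),
             t_stat = unname(t_stat), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR correction; input order is preserved in the output.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Coerce a metadata column: numeric if every non-missing value parses,
# otherwise a factor referenced on its most frequent level.
covariate_column <- function(values) {
  v <- as.character(values)
  v[!nzchar(v)] <- NA
  num <- suppressWarnings(as.numeric(v))
  if (!any(is.na(num) & !is.na(v))) return(num)
  counts <- sort(table(v), decreasing = TRUE)
  factor(v, levels = c(names(counts)[1L],
                       setdiff(sort(names(counts)), names(counts)[1L])))
}

# Build the design matrix for one stratum: intercept + adjustment terms +
# covariate terms. Numeric columns are standardized within the stratum.
build_design <- function(md, covariate, adjustment) {
  vars <- c(adjustment, covariate)
  df <- data.frame(row.names = seq_len(nrow(md)))
  for (v in vars) df[[v]] <- covariate_column(md[[v]])
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  for (v in vars) {
    if (is.numeric(df[[v]])) {
      s <- stats::sd(df[[v]])
      df[[v]] <- if (is.na(s) || s == 0) df[[v]] - mean(df[[v]])
                 else (df[[v]] - mean(df[[v]])) / s
    } else {
      df[[v]] <- droplevels(df[[v]])
    }
  }
  form <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  mm <- stats::model.matrix(form, data = df)
  cov_assign <- which(attr(stats::terms(form), "term.labels") == covariate)
  list(design = mm, complete = complete,
       covariate_cols = colnames(mm)[attr(mm, "assign") == cov_assign])
}

skipped_rows <- function(family_ids, covariate, stratum, status) {
  data.frame(family_id = family_ids, covariate = covariate,
             stratum = stratum, term = NA_character_,
             coefficient = NA_real_, std_error = NA_real_,
             t_stat = NA_real_, p_value = NA_real_, q_value = NA_real_,
             status = status, stringsAsFactors = FALSE)
}

#' Stratified presence-covariate association testing
#'
#' For each stratum and each eligible covariate, fits one logistic
#' regression per family — presence ~ intercept + adjustment terms +
#' covariate — and tests the covariate terms with Wald t-tests.
#' Benjamini-Hochberg correction is pooled across families within each
#' (stratum, covariate) pair; alternatively a single global pool may be
#' requested. Families whose presence is constant within a stratum, and
#' covariates failing the eligibility rule, are skipped; separated or
#' non-converged fits are flagged and excluded from the FDR pool.
#'
#' @param presence logical family-by-sample matrix.
#' @param samples sample metadata (\code{\link{read_sample_metadata}}).
#' @param covariates character vector of covariate column names to test.
#' @param adjustment character vector of adjustment column names (may be
#'   empty).
#' @param stratum_var metadata column defining the strata (default
#'   \code{"stratum"}).
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param fdr_pool \code{"per_stratum_covariate"} (default) or
#'   \code{"global"}.
#' @return data.frame with one row per family x covariate term x stratum:
#'   \code{family_id}, \code{covariate}, \code{stratum}, \code{term},
#'   \code{coefficient}, \code{std_error}, \code{t_stat}, \code{p_value},
#'   \code{q_value}, \code{status}, \code{significant}. Coefficients for
#'   numeric covariates are on the standardized (mean 0, sd 1) scale.
#' @export
run_association <- function(presence, samples, covariates,
                            adjustment = character(),
                            stratum_var = "stratum", q_threshold = 0.05,
                            fdr_pool = c("per_stratum_covariate", "global")) {
  fdr_pool <- match.arg(fdr_pool)
  vars <- c(covariates, adjustment, stratum_var)
  missing_vars <- setdiff(vars, names(samples))
  if (length(missing_vars)) {
    stop("metadata missing column(s): ", paste(missing_vars, collapse = ", "))
  }
  fam_ids <- rownames(presence)
  strata <- sort(unique(samples[[stratum_var]]), method = "radix")
  blocks <- list()
  for (st in strata) {
    md <- samples[samples[[stratum_var]] == st, , drop = FALSE]
    smp <- intersect(md$sample_id, colnames(presence))
    md <- md[match(smp, md$sample_id), , drop = FALSE]
    for (cv in covariates) {
      elig <- phenotype_eligible(md[[cv]])
      if (!elig$eligible) {
        blocks[[length(blocks) + 1L]] <-
          skipped_rows(fam_ids, cv, st, "SKIPPED_INELIGIBLE")
        next
      }
      ds <- build_design(md, cv, adjustment)
      X <- ds$design
      use_samples <- smp[ds$complete]
      if (nrow(X) < ncol(X) + 1L) {
        blocks[[length(blocks) + 1L]] <-
          skipped_rows(fam_ids, cv, st, "SKIPPED_INELIGIBLE")
        next
      }
      rows <- lapply(fam_ids, function(f) {
        y <- as.numeric(presence[f, use_samples])
        if (length(unique(y)) < 2L) {
          return(skipped_rows(f, cv, st, "SKIPPED_INELIGIBLE"))
        }
        fit <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
          return(skipped_rows(f, cv, st, "NOT_CONVERGED"))
        }
        if (fit$separation_flag) {
          return(skipped_rows(f, cv, st, "SEPARATED"))
        }
        w <- wald_tests(fit)
        w <- w[w$term %in% ds$covariate_cols, , drop = FALSE]
        data.frame(family_id = f, covariate = cv, stratum = st,
                   term = w$term, coefficient = w$coefficient,
                   std_error = w$std_error, t_stat = w$t_stat,
                   p_value = w$p_value, q_value = NA_real_,
                   status = "OK", stringsAsFactors = FALSE)
      })
      blocks[[length(blocks) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    skipped_rows(character(), character(), character(), character())
  rownames(res) <- NULL
  ok <- res$status == "OK"
  if (any(ok)) {
    if (fdr_pool == "global") {
      res$q_value[ok] <- bh_fdr(res$p_value[ok])
    } else {
      pool <- interaction(res$stratum[ok], res$covariate[ok], drop = TRUE)
      q <- res$q_value[ok]
      for (g in levels(pool)) {
        sel <- pool == g
        q[sel] <- bh_fdr(res$p_value[ok][sel])
      }
      res$q_value[ok] <- q
    }
  }
  res$significant <- !is.na(res$q_value) & res$q_value < q_threshold
  attr(res, "q_threshold") <- q_threshold
  attr(res, "fdr_pool") <- fdr_pool
  attr(res, "note") <- paste(
    "samples treated as independent observations;",
    "numeric covariate coefficients are on the standardized scale")
  res
}
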