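#' Pipeline configuration
#'
#' @param input `"synthetic"` (generate cohorts) or `"files"` (load graphs
#'   from disk)
#' @param cohorts named list of [cohort_config()]s (synthetic mode); the
#'   default mirrors the study design: a 12-subject patient-like cohort and
#'   a 12-subject healthy-volunteer-like cohort, two sessions each
#' @param files for files mode: list with `functional` (named vector or
#'   list of adjacency paths, names `"<subject>.<session>"`), `structural`
#'   (named by subject), optional `attributes` (named by subject) and
#'   `sessions` (data.frame `subject_id`, `session`, `group`)
#' @param specs specification names to fit (all four by default)
#' @param gwesp_decay fixed GWESP decay for the gwesp/complete fits
#' @param alpha significance level
#' @param method `"mple"` or `"mcmcmle"`
#' @param control an [control_ergm()] (mcmcmle method)
#' @param run_gof compute goodness-of-fit reports per fit
#' @param n_sims simulations per goodness-of-fit report
#' @param seed master seed
#' @param out_dir optional output directory for tables/JSON
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(input = c("synthetic", "files"),
                            cohorts = NULL, files = NULL,
                            specs = c("base", "structural", "gwesp",
                                      "complete"),
                            gwesp_decay = 0.5, alpha = 0.05,
                            method = c("mple", "mcmcmle"),
                            control = control_ergm(),
                            run_gof = FALSE, n_sims = 100L,
                            seed = 1L, out_dir = NULL) {
  input <- match.arg(input)
  method <- match.arg(method)
  if (input == "synthetic" && is.null(cohorts))
    cohorts <- list(
      patients = cohort_config(scenario = "patients", seed = seed),
      hcp = cohort_config(scenario = "hcp", seed = seed + 500L))
  structure(list(input = input, cohorts = cohorts, files = files,
                 specs = specs, gwesp_decay = gwesp_decay, alpha = alpha,
                 method = method, control = control, run_gof = run_gof,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Fit all specifications to one subject-session
#'
#' @param g functional [brain_graph()]
#' @param attrs attribute table with structural covariates and latent
#'   clusters
#' @param specs character vector of specification names
#' @param gwesp_decay,alpha,method,control,seed see [pipeline_config()]
#' @return named list of `ergm_fit`s
#' @export
fit_session <- function(g, attrs, specs = c("base", "structural", "gwesp",
                                            "complete"),
                        gwesp_decay = 0.5, alpha = 0.05, method = "mple",
                        control = control_ergm(), seed = 1L) {
  fits <- list()
  for (sname in specs) {
    spec <- model_spec(sname, gwesp_decay)
    fits[[sname]] <- tryCatch({
      if (method == "mcmcmle")
        suppressWarnings(mcmcmle_fit(g, attrs, spec, alpha = alpha,
                                     seed = seed, control = control))
      else suppressWarnings(mple_fit(g, attrs, spec, alpha = alpha))
    }, error = function(e) {
      structure(list(converged = FALSE, error = conditionMessage(e),
                     spec = spec, method = toupper(method)),
                class = c("ergm_fit_failed", "ergm_fit"))
    })
  }
  fits
}

#' Run the full analysis pipeline
#'
#' For every subject-session: derives/receives structural covariates, fits
#' the requested nested ERGM specifications, optionally runs
#' simulation-based goodness of fit, audits the three full/partial
#' comparisons into FP/FN/TP/TN records, then pools error tallies and fits
#' one multinomial rate regression per comparison and cohort.  Stage
#' failures are logged in the manifest and skipped; the pipeline always
#' returns partial results.
#'
#' @param config a [pipeline_config()]
#' @return list of class `pipeline_result`: `manifest` (one row per fit),
#'   `records`, `tallies`, `rate_models`, `gof` (if requested), `sessions`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort_data <- assemble_inputs(config)
  manifest <- list(); records <- list(); gof_out <- list()
  rate_models <- list(); tallies <- list()
  for (cname in names(cohort_data)) {
    co <- cohort_data[[cname]]
    for (k in seq_len(nrow(co$sessions))) {
      sid <- co$sessions$subject_id[k]
      sess <- co$sessions$session[k]
      key <- paste(sid, sess, sep = ".")
      g <- co$graphs[[key]]
      attrs <- co$attrs[[sid]]
      fit_seed <- as.integer((as.numeric(config$seed) * 7919 +
                                k * 104729) %% 2147483647)
      fits <- fit_session(g, attrs, specs = config$specs,
                          gwesp_decay = config$gwesp_decay,
                          alpha = config$alpha, method = config$method,
                          control = config$control, seed = fit_seed)
      for (sname in names(fits)) {
        f <- fits[[sname]]
        manifest[[length(manifest) + 1L]] <- data.frame(
          cohort = cname, subject_id = sid, session = sess, spec = sname,
          method = if (inherits(f, "ergm_fit_failed")) NA_character_
                   else f$method,
          converged = isTRUE(f$converged), seed = fit_seed,
          error = if (inherits(f, "ergm_fit_failed")) f$error
                  else NA_character_,
          stringsAsFactors = FALSE)
      }
      if (config$run_gof) {
        for (sname in intersect(names(fits), c("gwesp", "complete"))) {
          f <- fits[[sname]]
          if (!isTRUE(f$converged)) next
          gof_out[[paste(cname, key, sname, sep = ".")]] <-
            gof_report(f, g, attrs, model_spec(sname, config$gwesp_decay),
                       n_sims = config$n_sims, seed = fit_seed)
        }
      }
      for (cmp in comparison_specs(config$gwesp_decay)) {
        full <- fits[[cmp$full$name]]
        partial <- fits[[cmp$partial$name]]
        if (is.null(full) || is.null(partial)) next
        if (!isTRUE(full$converged) || !isTRUE(partial$converged)) {
          warning(sprintf("session %s %s: skipping %s (non-converged fit)",
                          cname, key, cmp$name))
          next
        }
        records[[paste(cname, key, cmp$name, sep = ".")]] <- cbind(
          cohort = cname,
          audit_comparison(full, partial, attrs, subject_id = sid,
                           session = sess, comparison = cmp$name))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  records <- if (length(records) > 0) do.call(rbind, records) else NULL
  if (!is.null(records)) rownames(records) <- NULL
  for (cname in names(cohort_data)) {
    co <- cohort_data[[cname]]
    rec <- records[records$cohort == cname, , drop = FALSE]
    if (is.null(rec) || nrow(rec) == 0) next
    tallies[[cname]] <- tally_errors(rec, co$sessions)
    ref <- reference_group_of(co$sessions$group)
    for (cmp_name in unique(rec$comparison)) {
      r <- rec[rec$comparison == cmp_name, , drop = FALSE]
      idx <- match(paste(r$subject_id, r$session),
                   paste(co$sessions$subject_id, co$sessions$session))
      obs <- data.frame(
        outcome = ifelse(r$outcome %in% c("TP", "TN"), "none",
                         paste(r$outcome, r$cortical_grouping, sep = ".")),
        group = co$sessions$group[idx], stringsAsFactors = FALSE)
      rate_models[[paste(cname, cmp_name, sep = ".")]] <- tryCatch(
        suppressWarnings(
          fit_multinomial(obs, reference_outcome = "none",
                          reference_group = ref)),
        error = function(e) e)
    }
  }
  res <- structure(list(manifest = manifest, records = records,
                        tallies = tallies, rate_models = rate_models,
                        gof = gof_out,
                        sessions = lapply(cohort_data, `[[`, "sessions"),
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

reference_group_of <- function(groups) {
  u <- unique(groups)
  for (cand in c("conscious_acute", "rest1")) if (cand %in% u) return(cand)
  sort(u)[1]
}

assemble_inputs <- function(config) {
  if (config$input == "synthetic") {
    out <- list()
    for (cname in names(config$cohorts)) {
      cohort <- gen_functional_cohort(config$cohorts[[cname]])
      sess <- cohort$sessions
      # groups from the outcome-inference rule where GCS subscales exist
      if (all(c("gcs_v", "gcs_m") %in% names(sess))) {
        gose <- infer_gose(sess$gcs_v, sess$gcs_m)
        sess$group <- ifelse(sess$session == "acute",
                             ifelse(gose == 2, "unconscious",
                                    "conscious_acute"),
                             "conscious_chronic")
      }
      out[[cname]] <- list(sessions = sess, graphs = cohort$graphs,
                           attrs = cohort$attrs,
                           ground_truth = cohort$ground_truth)
    }
    return(out)
  }
  fl <- config$files
  if (is.null(fl$functional) || is.null(fl$sessions))
    stop("files mode needs 'functional' paths and a 'sessions' table")
  graphs <- lapply(fl$functional, read_adjacency)
  subjects <- unique(fl$sessions$subject_id)
  attrs <- list()
  for (sid in subjects) {
    if (!is.null(fl$attributes) && !is.null(fl$attributes[[sid]])) {
      a <- read_attributes(fl$attributes[[sid]])
    } else {
      stop("files mode needs an attribute table per subject")
    }
    if (!is.null(fl$structural) && !is.null(fl$structural[[sid]])) {
      s <- read_adjacency(fl$structural[[sid]])
      met <- structural_metrics(s)
      a <- merge(a[setdiff(names(a), names(met)[-1])], met, by = "node_id",
                 sort = FALSE)
      a <- scale_struct_covariates(a)
      a$latent_cluster <- latent_clusters(s, k = "auto",
                                          seed = config$seed)
    }
    attrs[[sid]] <- validate_attrs(a)
  }
  list(files = list(sessions = fl$sessions, graphs = graphs, attrs = attrs))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(res$records))
    write.csv(res$records, file.path(out_dir, "error_records.csv"),
              row.names = FALSE)
  for (nm in names(res$tallies))
    write.csv(res$tallies[[nm]],
              file.path(out_dir, paste0("tally_", nm, ".csv")),
              row.names = FALSE)
  for (nm in names(res$rate_models)) {
    rm_ <- res$rate_models[[nm]]
    if (inherits(rm_, "rate_model"))
      write.csv(as.data.frame(rm_),
                file.path(out_dir, paste0("rates_", nm, ".csv")),
                row.names = FALSE)
  }
  for (nm in names(res$gof))
    write_gof_csv(res$gof[[nm]],
                  file.path(out_dir, paste0("gof_", nm, ".csv")))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d fits (%d converged), %s error records\n",
              nrow(x$manifest), sum(x$manifest$converged),
              if (is.null(x$records)) 0 else nrow(x$records)))
  invisible(x)
}
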