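#' Infer the Glasgow Outcome Scale-Extended from GCS subscales
#'
#' Acute-stage consciousness is inferred from the post-resuscitation
#' Glasgow Coma Scale verbal (V) and motor (M) subscales: V <= 3 together
#' with M <= 4 maps to an inferred GOS-E of 2 (consistent with a vegetative
#' state); any higher combination maps to 3 (emerged).
#'
#' @param gcs_v verbal subscale, integer 1-5
#' @param gcs_m motor subscale, integer 1-6
#' @return integer vector of inferred GOS-E values in `{2, 3}`
#' @examples
#' infer_gose(1, 4)  # 2: vegetative-state range
#' infer_gose(5, 6)  # 3: emerged
#' @export
infer_gose <- function(gcs_v, gcs_m) {
  if (any(gcs_v < 1 | gcs_v > 5 | gcs_v != round(gcs_v)))
    stop("gcs_v must be an integer in 1..5")
  if (any(gcs_m < 1 | gcs_m > 6 | gcs_m != round(gcs_m)))
    stop("gcs_m must be an integer in 1..6")
  ifelse(gcs_v <= 3 & gcs_m <= 4, 2L, 3L)
}

#' The three nested model comparisons
#'
#' Each comparison pairs the base specification (partial model) with a
#' fuller specification (full model): `structural_effect` isolates the
#' omission of structural-connectivity terms, `gwesp_effect` the omission
#' of the triadic-closure term, and `interaction_effect` the omission of
#' both.
#'
#' @param gwesp_decay decay passed to the gwesp/complete specifications
#' @return named list of `list(name, full, partial)` entries
#' @export
comparison_specs <- function(gwesp_decay = 0.5) {
  list(
    structural_effect = list(name = "structural_effect",
                             full = model_spec("structural"),
                             partial = model_spec("base")),
    gwesp_effect = list(name = "gwesp_effect",
                        full = model_spec("gwesp", gwesp_decay),
                        partial = model_spec("base")),
    interaction_effect = list(name = "interaction_effect",
                              full = model_spec("complete", gwesp_decay),
                              partial = model_spec("base"))
  )
}

#' Classify one parameter estimate across a full/partial comparison
#'
#' A false positive (FP) is a term significant in the partial model but not
#' the full model; a false negative (FN) is significant in the full model
#' but not the partial; TP and TN are significant or non-significant in
#' both.  The classification depends only on the two significance calls.
#'
#' @param full `ergm_fit` of the fuller specification
#' @param partial `ergm_fit` of the base specification
#' @param term term name present in both fits
#' @return one of `"FP"`, `"FN"`, `"TP"`, `"TN"`
#' @export
classify_pe <- function(full, partial, term) {
  stopifnot(inherits(full, "ergm_fit"), inherits(partial, "ergm_fit"))
  if (!isTRUE(full$converged) || !isTRUE(partial$converged))
    stop("both fits must have converged")
  if (!term %in% names(full$significant) ||
      !term %in% names(partial$significant))
    stop("term '", term, "' missing from one of the fits")
  sf <- full$significant[[term]]
  sp <- partial$significant[[term]]
  if (sp && !sf) "FP" else if (sf && !sp) "FN" else if (sf && sp) "TP" else "TN"
}

#' Cortical grouping of a mixing term
#'
#' @param label_a,label_b the two labels of a mixing cell
#' @param group_map named character vector mapping each label to
#'   `"cortical"` or `"subcortical"`
#' @return `"within_cortical"`, `"within_subcortical"` or
#'   `"cortico_subcortical"`
#' @export
cortical_grouping <- function(label_a, label_b, group_map) {
  ga <- group_map[label_a]
  gb <- group_map[label_b]
  if (anyNA(ga) || anyNA(gb))
    stop("unknown label(s): ",
         paste(c(label_a, label_b)[is.na(c(ga, gb))], collapse = ", "))
  unname(ifelse(ga == "cortical" & gb == "cortical", "within_cortical",
                ifelse(ga == "subcortical" & gb == "subcortical",
                       "within_subcortical", "cortico_subcortical")))
}

label_group_map <- function(attrs) {
  attrs <- validate_attrs(attrs)
  m <- unique(attrs[c("rsn_label", "cortical_group")])
  if (anyDuplicated(m$rsn_label))
    stop("label mapped to more than one cortical_group: ",
         paste(m$rsn_label[duplicated(m$rsn_label)], collapse = ", "))
  setNames(m$cortical_group, m$rsn_label)
}

#' Audit all selective-mixing terms of one full/partial comparison
#'
#' @param full,partial converged `ergm_fit`s sharing the mixing terms
#' @param attrs node attribute table (supplies the label -> cortical map)
#' @param subject_id,session,comparison bookkeeping fields copied into the
#'   records
#' @return data.frame of error records: one row per mixing term with its
#'   cortical grouping and FP/FN/TP/TN outcome
#' @export
audit_comparison <- function(full, partial, attrs, subject_id = NA,
                             session = NA, comparison = NA) {
  terms <- mixing_term_names(attrs)
  gm <- label_group_map(attrs)
  parts <- do.call(rbind, strsplit(sub("^mix\\.", "", terms), ".",
                                   fixed = TRUE))
  data.frame(
    subject_id = subject_id, session = session, comparison = comparison,
    term = terms,
    cortical_grouping = cortical_grouping(parts[, 1], parts[, 2], gm),
    outcome = vapply(terms, function(tm) classify_pe(full, partial, tm),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Tally error records by group and cortical grouping
#'
#' Pools TP and TN into a `"none"` category (the reference outcome of the
#' rate regressions) and counts records per subject group, cortical
#' grouping and outcome.
#'
#' @param records error-record data.frame from [audit_comparison()]
#' @param sessions data.frame with columns `subject_id`, `session`, `group`
#'   resolving every record to a subject group
#' @return data.frame of counts by `comparison`, `group`,
#'   `cortical_grouping` and `outcome` (`FP`, `FN`, `none`)
#' @export
tally_errors <- function(records, sessions) {
  key <- paste(records$subject_id, records$session)
  skey <- paste(sessions$subject_id, sessions$session)
  idx <- match(key, skey)
  if (anyNA(idx))
    stop("unresolvable subject/session in records: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  records$group <- sessions$group[idx]
  records$outcome <- ifelse(records$outcome %in% c("TP", "TN"), "none",
                            records$outcome)
  out <- as.data.frame(table(comparison = records$comparison,
                             group = records$group,
                             cortical_grouping = records$cortical_grouping,
                             outcome = records$outcome),
                       stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "count"
  out[order(out$comparison, out$group, out$cortical_grouping, out$outcome), ,
      drop = FALSE]
}
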