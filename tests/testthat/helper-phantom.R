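# Shared fixtures. Small phantom cases are cheap to build per test; the
# study-scale cohort used by the end-to-end checks is generated once per
# session and cached.

small_spec <- function(seed = 1, ...) {
  args <- list(grid_shape = c(48L, 48L, 48L), n_lesions = 6L,
               rim_fraction = 1 / 3, confluence_rate = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

.fixture_env <- new.env(parent = emptyenv())

# 20-subject cohort at the emulated study conditions (~50 lesions/subject,
# 12% rim prevalence, rim contrast -2 background SD), with per-subject
# labelling and feature extraction.
study_fixture <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  spec <- phantom_spec(seed = 20210827)
  cohort <- generate_cohort(20, spec, seed = 20210827)
  per_subject <- lapply(names(cohort), function(sid) {
    cs <- cohort[[sid]]
    lab <- label_lesions(cs$prob_map, cs$gold_mask, cs$csf_mask, cs$gm_mask,
                         cs$prl_annotation, subject_id = sid)
    list(case = cs, labelling = lab,
         features = extract_feature_table(cs$phase, lab$labels, lab$records,
                                          include_size = TRUE))
  })
  names(per_subject) <- names(cohort)
  features <- dplyr::bind_rows(lapply(per_subject, `[[`, "features"))
  counts <- tibble::tibble(
    subject_id = names(per_subject),
    n_prl = vapply(per_subject, function(x) x$labelling$n_prl, integer(1)),
    n_rim_truth = vapply(per_subject,
                         function(x) sum(x$case$truth$is_rim), integer(1)))
  .fixture_env$study <- list(spec = spec, cohort = cohort,
                             per_subject = per_subject,
                             features = features, counts = counts)
  .fixture_env$study
}
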