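# Shared replicate computations for the synthetic-cohort performance
# analyses. Several test blocks examine different summaries of the same
# 50 whole-data fits, so the fits are computed once per session and
# memoized here.

.replicate_cache <- new.env(parent = emptyenv())

whole_data_replicates <- function(n_reps = 50) {
  key <- sprintf("reps_%d", n_reps)
  if (is.null(.replicate_cache[[key]])) {
    .replicate_cache[[key]] <- lapply(seq_len(n_reps), function(i) {
      cohort <- gen_feature_cohort(cohort_config(seed = i))
      ana <- run_tissue_level(cohort, penalty = "lasso",
                              criterion = "deviance", seed = 10000 + i)
      list(training_accuracy = ana$training_accuracy,
           selected = ana$selected_features,
           macro_auc = roc_analysis(ana)$macro_auc,
           cert_correct = ana$mean_certainty_correct,
           cert_incorrect = ana$mean_certainty_incorrect)
    })
  }
  .replicate_cache[[key]]
}
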