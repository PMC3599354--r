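# Featurizing the default 108-mesh dataset takes ~30 s, and several
# end-to-end tests need the same datasets; cache per master seed.
.study_cache <- new.env(parent = emptyenv())

default_study <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.study_cache[[key]])) {
    ds <- generate_injury_dataset(seed = seed)
    x <- featurize(ds$meshes)
    plan <- make_stratified_folds(ds$labels, k = 6, seed = seed)
    .study_cache[[key]] <- list(x = x, labels = ds$labels, plan = plan)
  }
  .study_cache[[key]]
}

default_clean_cv <- function(seed) {
  key <- paste0("cv_", seed)
  if (is.null(.study_cache[[key]])) {
    st <- default_study(seed)
    .study_cache[[key]] <- run_cross_validation(st$x, st$labels, st$plan,
                                                on_empty = "top")
  }
  .study_cache[[key]]
}
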