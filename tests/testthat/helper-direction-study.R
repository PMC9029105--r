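# The scaled-down replication study shared by the end-to-end acceptance
# checks: the default synthetic corpus (160 positive / 290 negative users,
# hidden_fraction 0.3), three seeds, with and without the sentence-level
# mask. Computed once per test run and cached.
direction_study_cache <- new.env(parent = emptyenv())

direction_study_seeds <- c(101L, 202L, 303L)

direction_study <- function() {
  if (!is.null(direction_study_cache$study)) {
    return(direction_study_cache$study)
  }
  rows <- list()
  for (seed in direction_study_seeds) {
    gen <- generate_corpus(generator_config(seed = seed))
    for (mask in c(FALSE, TRUE)) {
      wd <- file.path(tempdir(), sprintf("direction_%d_%d", seed, mask))
      cfg <- experiment_config(gen$corpus, wd, mask = mask, clean = FALSE,
                               baselines = c("single", "dhe_sd"), seed = seed)
      res <- run_experiment(cfg, quiet = TRUE)
      cmp <- tibble::as_tibble(res$comparison)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        cmp[, c("method", "accuracy", "f1")],
        seed = seed,
        condition = if (mask) "masked" else "unmasked")
    }
  }
  direction_study_cache$study <- dplyr::bind_rows(rows)
  direction_study_cache$study
}

median_f1 <- function(study, cond, meth) {
  stats::median(study$f1[study$condition == cond & study$method == meth])
}
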