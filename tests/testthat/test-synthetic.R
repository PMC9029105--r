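test_that("the generator is a pure function of its config", {
  cfg <- generator_config(n_positive = 160L, n_negative = 290L, seed = 7)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1, g2)
  g3 <- generate_corpus(generator_config(n_positive = 160L,
                                         n_negative = 290L, seed = 8))
  expect_false(identical(g1$corpus, g3$corpus))
})

test_that("class prevalence matches the config exactly", {
  gen <- generate_corpus(generator_config(n_positive = 23L, n_negative = 41L,
                                          seed = 2))
  users <- corpus_users(gen$corpus)
  expect_equal(sum(users$label == "suicidal"), 23L)
  expect_equal(sum(users$label == "non_suicidal"), 41L)
  expect_equal(nrow(gen$truth), 64L)
  expect_true(all(users$n_posts >= 1L))
})

test_that("only positive users post in the tree hole; hidden signal sits there", {
  gen <- generate_corpus(generator_config(n_positive = 30L, n_negative = 30L,
                                          hidden_fraction = 0.5, seed = 3))
  th_users <- unique(gen$corpus$user_id[gen$corpus$source == "tree_hole"])
  labels <- corpus_users(gen$corpus)
  expect_true(all(labels$label[match(th_users, labels$user_id)] == "suicidal"))
  hidden <- gen$truth[gen$truth$hidden, ]
  expect_gt(nrow(hidden), 0L)
  for (i in seq_len(nrow(hidden))) {
    uid <- hidden$user_id[[i]]
    sig <- hidden$signal_posts[[i]]
    expect_gt(length(sig), 0L)
    srcs <- gen$corpus$source[gen$corpus$user_id == uid][sig]
    expect_true(all(srcs == "tree_hole"))
  }
})

test_that("disabling tree-hole posting makes the mask a no-op", {
  gen <- generate_corpus(generator_config(n_positive = 20L, n_negative = 30L,
                                          treehole_post_rate = 0, seed = 4))
  expect_equal(sum(gen$corpus$source == "tree_hole"), 0L)
  expect_identical(strip_corpus(apply_sentence_mask(gen$corpus)),
                   strip_corpus(gen$corpus))
})

test_that("fully hidden positives are indistinguishable from negatives after masking", {
  pvals <- vapply(1:10, function(seed) {
    gen <- generate_corpus(generator_config(
      n_positive = 40L, n_negative = 60L, hidden_fraction = 1,
      posts_per_user_mean = c(positive = 6, negative = 6),
      post_length_mean = c(positive = 10, negative = 10), seed = seed))
    masked <- apply_sentence_mask(gen$corpus)
    toks <- concat_posts(masked)
    counts_by <- function(lab) {
      table(unlist(toks$tokens[toks$label == lab], use.names = FALSE))
    }
    pos <- counts_by("suicidal")
    neg <- counts_by("non_suicidal")
    all_tok <- union(names(pos), names(neg))
    all_tok <- setdiff(all_tok, "<sep>")
    tab <- rbind(as.integer(pos[all_tok]), as.integer(neg[all_tok]))
    tab[is.na(tab)] <- 0L
    tab <- tab[, colSums(tab) >= 5, drop = FALSE]
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, 0)
  expect_gt(stats::median(pvals), 0.01)
})

test_that("the injection ledger predicts the cleaning tally exactly", {
  for (seed in c(5L, 19L)) {
    dirty <- generate_dirty_corpus(
      generator_config(n_positive = 12L, n_negative = 18L, seed = seed))
    cfg <- cleaning_config(location_list = "Springfield",
                           min_posts_per_user = 1L)
    cleaned <- clean_corpus(dirty$corpus, cfg)
    tl <- removal_tally(cleaned)
    ledger <- dirty$ledger
    for (rule in c("url", "mention", "emoticon", "boilerplate", "location",
                   "supertopic")) {
      expect_equal(tl$matches_removed[tl$rule == rule],
                   ledger$n[ledger$rule == rule],
                   label = sprintf("matches for rule %s (seed %d)", rule, seed))
    }
    expect_equal(tl$posts_removed[tl$rule == "system"],
                 ledger$n[ledger$rule == "system"])
    expect_equal(tl$posts_removed[tl$rule == "empty_residue"],
                 ledger$n[ledger$rule == "empty_residue"])
    # nothing the cleaner targets survives
    expect_equal(sum(stringr::str_count(cleaned$text, "http|@|\\[sad\\]|#")), 0L)
  }
})

test_that("zero noise rates reproduce the clean corpus", {
  cfg <- generator_config(n_positive = 8L, n_negative = 10L, seed = 6)
  quiet <- noise_config(url_rate = 0, mention_rate = 0, emoticon_rate = 0,
                        boilerplate_rate = 0, location_rate = 0,
                        supertopic_rate = 0, system_post_rate = 0,
                        url_only_post_rate = 0)
  dirty <- generate_dirty_corpus(cfg, quiet)
  expect_identical(strip_corpus(dirty$corpus),
                   strip_corpus(generate_corpus(cfg)$corpus))
  expect_true(all(dirty$ledger$n == 0L))
})

test_that("masking hardens the task when signal hides in the tree hole", {
  # a fast surrogate for the full study: the convex bag-of-words scorer
  f1s <- vapply(1:3, function(seed) {
    gen <- generate_corpus(generator_config(
      n_positive = 40L, n_negative = 60L, hidden_fraction = 0.4,
      posts_per_user_mean = c(positive = 6, negative = 7),
      seed = seed))
    run_one <- function(corpus) {
      sp <- stratified_split(corpus, c(0.6, 0.2, 0.2), seed = seed)
      clf <- train_base_classifier(
        corpus_partition(corpus, sp, "train"),
        corpus_partition(corpus, sp, "val"),
        train_config("dummy", epochs = 15, seed = seed))
      pred <- predict_label(clf, corpus_partition(corpus, sp, "test"))
      suppressWarnings(compute_metrics(pred)$f1)
    }
    c(unmasked = run_one(gen$corpus),
      masked = run_one(apply_sentence_mask(gen$corpus)))
  }, c(unmasked = 0, masked = 0))
  expect_lte(stats::median(f1s["masked", ]),
             stats::median(f1s["unmasked", ]))
})

test_that("ground truth and manifest serialize losslessly enough to audit", {
  gen <- generate_corpus(generator_config(n_positive = 5L, n_negative = 5L,
                                          seed = 9))
  dir <- withr::local_tempdir()
  write_ground_truth(gen$truth, file.path(dir, "truth.jsonl"))
  lines <- readLines(file.path(dir, "truth.jsonl"))
  expect_length(lines, 10L)
  rec <- jsonlite::fromJSON(lines[[1]])
  expect_equal(rec$user_id, gen$truth$user_id[[1]])
  write_generator_manifest(generator_config(seed = 9), file.path(dir, "m.json"))
  m <- jsonlite::fromJSON(file.path(dir, "m.json"))
  expect_equal(m$seed, 9L)
  expect_error(generator_config(hidden_fraction = 2), "\\[0, 1\\]")
})
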