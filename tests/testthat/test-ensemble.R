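test_that("majority_vote matches the counting oracle on all inputs up to k = 9", {
  for (k in 1:9) {
    bits <- expand.grid(rep(list(0:1), k))
    for (i in seq_len(nrow(bits))) {
      v <- as.integer(bits[i, ])
      expect_identical(majority_vote(v, "positive"), oracle_majority(v, TRUE))
      expect_identical(majority_vote(v, "negative"), oracle_majority(v, FALSE))
    }
  }
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c("suicidal", "non_suicidal"),
                             tie_rule = "positive"), "suicidal")
  expect_error(majority_vote(integer(0)), "non-empty")
})

test_that("hierarchical_predict equals the two-stage oracle on all 512 3x3 grids", {
  for (grid in all_grids(3, 3)) {
    hp <- hierarchical_predict(grid)
    expect_identical(hp$final, oracle_hierarchical(grid))
    for (p in 1:3) {
      expect_identical(hp$first_level[[p]], oracle_majority(grid[p, ]))
    }
  }
})

test_that("four correct votes can carry the hierarchy but never the flat vote", {
  # rows 110 / 110 / 000: 4 of 9 correct, two rows carried
  grid <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0))
  expect_equal(hierarchical_predict(grid)$final, 1L)
  expect_equal(flat_ensemble_oracle(grid), 0L)
  # flat is correct iff >= 5 of 9 votes are correct
  for (grid in all_grids(3, 3)) {
    expect_identical(flat_ensemble_oracle(grid) == 1L, sum(grid) >= 5)
  }
})

test_that("single-row and single-column grids degenerate to the flat vote", {
  withr::with_seed(20, {
    for (i in 1:2000) {
      m <- sample(1:9, 1)
      v <- sample(0:1, m, replace = TRUE)
      expect_identical(hierarchical_predict(matrix(v, 1, m))$final,
                       flat_ensemble_oracle(matrix(v, 1, m)))
      expect_identical(hierarchical_predict(matrix(v, m, 1))$final,
                       flat_ensemble_oracle(matrix(v, m, 1)))
    }
  })
})

test_that("the hierarchy is invariant to permuting subsets and models", {
  withr::with_seed(33, {
    for (i in 1:200) {
      n <- sample(2:4, 1)
      m <- sample(2:4, 1)
      grid <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
      base <- hierarchical_predict(grid)$final
      perm_rows <- grid[sample(n), , drop = FALSE]
      expect_identical(hierarchical_predict(perm_rows)$final, base)
      perm_within <- t(apply(grid, 1, sample))
      expect_identical(hierarchical_predict(perm_within)$final, base)
    }
  })
})

test_that("ragged or empty grids are rejected", {
  expect_error(hierarchical_predict(list(c(1, 0), c(1, 0, 1))), "ragged")
  expect_error(run_dhe_sd(list(), make_corpus(list(u = "x"))), "list")
})

test_that("the 3x3 census reproduces the hierarchical advantage", {
  cen <- vote_pattern_census(3, 3)
  expect_equal(attr(cen, "min_k_flat"), 5)
  expect_equal(attr(cen, "min_k_hier"), 4)
  expect_equal(cen$n_placements, choose(9, 0:9))
  # every pattern with <= 4 correct votes fails the flat vote
  expect_true(all(cen$n_flat_correct[cen$k <= 4] == 0))
  expect_true(cen$n_hier_correct[cen$k == 4] > 0)
  # cross-check one k against the exhaustive oracle
  n4 <- sum(vapply(all_grids(3, 3), function(g) {
    sum(g) == 4 && oracle_hierarchical(g) == 1L
  }, TRUE))
  expect_equal(cen$n_hier_correct[cen$k == 4], n4)
})

test_that("a 1 x m census collapses onto the flat census", {
  cen <- vote_pattern_census(1, 9)
  expect_identical(cen$n_hier_correct, cen$n_flat_correct)
  expect_error(vote_pattern_census(5, 5), "<= 20")
})

train_tiny_dummy <- function(seed, corpus = NULL) {
  if (is.null(corpus)) corpus <- generate_corpus(separable_config(3))$corpus
  sp <- stratified_split(corpus, c(0.7, 0.3, 0), seed = 1)
  train_base_classifier(
    corpus_partition(corpus, sp, "train"), corpus_partition(corpus, sp, "val"),
    train_config("dummy", epochs = 12, seed = seed))
}

test_that("a grid of identical classifiers propagates its rule unanimously", {
  gen <- generate_corpus(separable_config(3))
  clf <- train_tiny_dummy(1, gen$corpus)
  grid <- replicate(3, replicate(3, clf, simplify = FALSE), simplify = FALSE)
  test_c <- gen$corpus
  res <- run_dhe_sd(grid, test_c)
  single <- predict_label(clf, test_c)
  expect_identical(res$.pred, single$.pred)
  expect_true(all(res$vote_1_1 == res$vote_3_3))
  # n = m = 1 degenerates to the base classifier
  res1 <- run_dhe_sd(list(list(clf)), test_c)
  expect_identical(res1$.pred, single$.pred)
})

test_that("prediction tables replay both ensemble levels exactly", {
  gen <- generate_corpus(separable_config(5, n_positive = 12L, n_negative = 16L))
  clfs <- lapply(1:3, function(p) lapply(1:3, function(q) {
    train_tiny_dummy(p * 10 + q, gen$corpus)
  }))
  res <- run_dhe_sd(clfs, gen$corpus)
  for (i in sample(nrow(res), 5)) {
    grid <- matrix(as.integer(unlist(res[i, sprintf("vote_%d_%d",
                                                    rep(1:3, each = 3), 1:3)])),
                   3, 3, byrow = TRUE)
    hp <- hierarchical_predict(grid)
    expect_identical(unname(unlist(res[i, sprintf("first_%d", 1:3)])),
                     hp$first_level)
    expect_identical(res$.pred[[i]], as_character_label(hp$final))
  }
  long <- tidy(res)
  expect_equal(nrow(long), nrow(res) * 9)
  f <- withr::local_tempfile()
  write_predictions(res, f)
  expect_true(file.exists(f))
})
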