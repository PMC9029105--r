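test_that("clean_post strips artefacts and drops system/empty posts", {
  expect_equal(clean_post("see this http://t.cn/abc @alice", "ordinary")$text,
               "see this")
  sys <- clean_post("auto check-in", "system")
  expect_true(sys$removed)
  expect_equal(sys$rule, "system")
  urlonly <- clean_post("http://t.cn/xyz", "ordinary")
  expect_true(urlonly$removed)
  expect_equal(urlonly$rule, "empty_residue")
  expect_equal(clean_post("去 #抑郁症# 看看 [哭] \U0001F622", "ordinary")$text,
               "去 看看")
})

test_that("clean_post is idempotent under fuzzing", {
  cfg <- cleaning_config(boilerplate_phrases = c("sharing pictures"),
                         location_list = c("Springfield"))
  pool <- c("word", "@user1", "http://t.cn/ab", "[sad]", "#topic tag#",
            "sharing pictures", "Springfield", "好", "\U0001F600", "x")
  withr::with_seed(77, {
    for (i in 1:300) {
      txt <- paste(sample(pool, sample(1:10, 1), replace = TRUE),
                   collapse = " ")
      once <- clean_post(txt, "ordinary", cfg)
      if (once$removed) {
        expect_true(is.na(once$text))
      } else {
        twice <- clean_post(once$text, "ordinary", cfg)
        expect_false(twice$removed)
        expect_identical(twice$text, once$text)
      }
    }
  })
})

test_that("clean_corpus tallies every rule on a hand-counted fixture", {
  # 10 posts: 2 system, 1 URL-only, 7 ordinary survivors
  cp <- make_corpus(
    list(u1 = c("keep one", "sys", "http://t.cn/only", "keep two", "keep three"),
         u2 = c("sys", "keep @bob four", "keep five", "keep six", "keep seven")),
    sources = list(c("ordinary", "system", "ordinary", "ordinary", "ordinary"),
                   c("system", "ordinary", "ordinary", "ordinary", "ordinary")))
  out <- clean_corpus(cp, cleaning_config(min_posts_per_user = 1))
  tl <- removal_tally(out)
  expect_equal(tl$posts_removed[tl$rule == "system"], 2L)
  expect_equal(tl$posts_removed[tl$rule == "empty_residue"], 1L)
  expect_equal(tl$matches_removed[tl$rule == "mention"], 1L)
  expect_equal(nrow(out), 7L)
  expect_equal(out$text[out$user_id == "u2"][1], "keep four")
})

test_that("cleaning an already-clean corpus is a fixed point with zero tallies", {
  cp <- make_corpus(list(u1 = c("all clean", "nothing here", "fine"),
                         u2 = c("ok", "good", "yes")))
  out <- clean_corpus(cp)
  expect_identical(strip_corpus(out), strip_corpus(cp))
  tl <- removal_tally(out)
  expect_true(all(tl$matches_removed == 0L))
  expect_true(all(tl$users_removed == 0L))
})

test_that("users falling under the post threshold are dropped", {
  cp <- make_corpus(list(u1 = c("http://t.cn/a", "b ok", "c ok"),
                         u2 = c("x ok", "y ok", "z ok")))
  out <- clean_corpus(cp, cleaning_config(min_posts_per_user = 3))
  expect_identical(unique(out$user_id), "u2")
  tl <- removal_tally(out)
  expect_equal(tl$users_removed[tl$rule == "min_posts"], 1L)
  expect_equal(tl$posts_removed[tl$rule == "min_posts"], 2L)
})

table2_style_user <- function() {
  make_corpus(
    list(u1 = c("Loop this song infinitely, crying while listening.",
                "I want to see my blood pouring out of my arm.",
                "Mom, happy holidays! I miss you so much.")),
    labels = list("suicidal"),
    sources = list(c("ordinary", "tree_hole", "ordinary")))
}

test_that("the sentence-level mask deletes exactly the tree-hole posts", {
  cp <- table2_style_user()
  masked <- apply_sentence_mask(cp)
  expect_equal(nrow(masked), 2L)
  expect_false(any(grepl("blood", masked$text)))
  expect_identical(masked$text,
                   cp$text[cp$source != "tree_hole"])
  expect_equal(masked$post_idx, 1:2)
  tl <- removal_tally(masked)
  expect_equal(tl$posts_removed, 1L)
})

test_that("masking is idempotent, monotone, and identity without tree holes", {
  cp <- rand_corpus(12, seed = 31)
  cp <- cp[cp$source != "system", ]
  cp <- dhesd:::renumber_posts(cp)
  m1 <- apply_sentence_mask(cp)
  m2 <- apply_sentence_mask(m1)
  expect_identical(strip_corpus(m2), strip_corpus(m1))
  n_before <- corpus_users(cp)
  n_after <- corpus_users(m1)
  shared <- intersect(n_before$user_id, n_after$user_id)
  expect_true(all(n_after$n_posts[match(shared, n_after$user_id)] <=
                    n_before$n_posts[match(shared, n_before$user_id)]))

  no_th <- make_corpus(list(u1 = c("a", "b")),
                       sources = list(c("ordinary", "ordinary")))
  expect_identical(strip_corpus(apply_sentence_mask(no_th)),
                   strip_corpus(no_th))
})

test_that("users with only tree-hole posts are dropped and reported", {
  cp <- make_corpus(list(u1 = c("th one", "th two"), u2 = "stays"),
                    sources = list(c("tree_hole", "tree_hole"), "ordinary"))
  masked <- apply_sentence_mask(cp)
  expect_identical(unique(masked$user_id), "u2")
  expect_equal(removal_tally(masked)$users_removed, 1L)
  expect_identical(attr(masked, "dropped_users"), "u1")
})

test_that("masking commutes with cleaning away from the user threshold", {
  cp <- make_corpus(
    list(u1 = c("a http://t.cn/x one", "treehole text", "b two", "c three"),
         u2 = c("d @who four", "e five", "f six")),
    sources = list(c("ordinary", "tree_hole", "ordinary", "ordinary"),
                   c("ordinary", "ordinary", "ordinary")))
  cfg <- cleaning_config(min_posts_per_user = 1)
  a <- clean_corpus(apply_sentence_mask(cp), cfg)
  b <- apply_sentence_mask(clean_corpus(cp, cfg))
  expect_identical(strip_corpus(a), strip_corpus(b))
})

test_that("cleaning and mask configs load from YAML with location file", {
  dir <- withr::local_tempdir()
  writeLines(c("南京市", "兰州市"), file.path(dir, "locs.txt"))
  writeLines(c("min_posts_per_user: 2",
               "boilerplate_phrases:",
               "  - sharing pictures",
               "location_file: locs.txt"), file.path(dir, "clean.yaml"))
  cfg <- read_cleaning_config(file.path(dir, "clean.yaml"))
  expect_equal(cfg$min_posts_per_user, 2L)
  expect_equal(cfg$location_list, c("南京市", "兰州市"))
  expect_error(cleaning_config(url_pattern = "(unclosed"), "compile")
  expect_error(mask_config(character()), "non-empty")
})
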