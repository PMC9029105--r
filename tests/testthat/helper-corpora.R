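# in-code fixtures shared across test files

# quick corpus builder: posts is a named list user_id -> character vector of
# post texts; sources/labels optional parallel structures
make_corpus <- function(posts, labels = NULL, sources = NULL) {
  rows <- lapply(seq_along(posts), function(i) {
    uid <- names(posts)[[i]]
    txt <- posts[[i]]
    src <- if (is.null(sources)) rep("ordinary", length(txt)) else sources[[i]]
    lab <- if (is.null(labels)) "non_suicidal" else labels[[i]]
    tibble::tibble(user_id = uid, label = lab, post_idx = seq_along(txt),
                   text = txt, source = src, created_at = NA_character_)
  })
  dplyr::bind_rows(rows)
}

# random corpus with unicode text (CJK, emoji, ascii) for round-trip fuzzing
rand_corpus <- function(n_users, seed) {
  withr::with_seed(seed, {
    pool <- c(letters, "好", "难", "受", "哈", "笑", "\U0001F600", "\U0001F622",
              "#", "@", "[", "]", "http://x", "  ", "\t")
    rows <- lapply(seq_len(n_users), function(i) {
      n_posts <- sample(1:4, 1)
      txt <- vapply(seq_len(n_posts), function(j) {
        paste(sample(pool, sample(1:8, 1), replace = TRUE), collapse = " ")
      }, "")
      tibble::tibble(
        user_id = sprintf("u%03d", i),
        label = sample(c("suicidal", "non_suicidal", NA_character_), 1),
        post_idx = seq_len(n_posts),
        text = txt,
        source = sample(c("tree_hole", "ordinary", "system"), n_posts,
                        replace = TRUE),
        created_at = sample(c("2021-05-01T10:00:00Z", NA_character_), n_posts,
                            replace = TRUE)
      )
    })
    dplyr::bind_rows(rows)
  })
}

# one labeled single-post row per user, for split/plan tests where text is
# irrelevant
make_user_stub <- function(n_positive, n_negative) {
  tibble::tibble(
    user_id = sprintf("u%05d", seq_len(n_positive + n_negative)),
    label = rep(c("suicidal", "non_suicidal"), c(n_positive, n_negative)),
    post_idx = 1L, text = "x", source = "ordinary",
    created_at = NA_character_
  )
}

# drop report attributes so cleaned/masked corpora compare on content only
strip_corpus <- function(x) {
  as.data.frame(x)[c("user_id", "label", "post_idx", "text", "source",
                     "created_at")]
}

# a small linearly separable corpus: disjoint class vocabularies, no hidden
# users, strong signal
separable_config <- function(seed, n_positive = 40L, n_negative = 60L) {
  generator_config(
    n_positive = n_positive, n_negative = n_negative,
    posts_per_user_mean = c(positive = 5, negative = 6),
    post_length_mean = c(positive = 10, negative = 10),
    vocab_sizes = c(shared = 150L, positive_signal = 40L,
                    treehole_signal = 40L, negative_signal = 40L),
    signal_strength = 0.8, hidden_fraction = 0, treehole_post_rate = 0.2,
    seed = seed
  )
}
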