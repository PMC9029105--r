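test_that("posts concatenate in order with separators", {
  cp <- make_corpus(list(u1 = c("a b", "c")))
  expect_identical(concat_posts(cp)$tokens[[1]], c("a", "b", "<sep>", "c"))
  single <- make_corpus(list(u1 = "x"))
  expect_identical(concat_posts(single)$tokens[[1]], "x")
  swapped <- make_corpus(list(u1 = c("q", "p")))
  ordered <- make_corpus(list(u1 = c("p", "q")))
  expect_false(identical(concat_posts(swapped)$tokens,
                         concat_posts(ordered)$tokens))
})

test_that("vocabulary ids are deterministic and respect min_frequency", {
  cp <- make_corpus(list(u1 = "a a", u2 = "a b"))
  v <- build_vocabulary(cp, min_frequency = 2)
  expect_equal(nrow(v), 1L)
  expect_equal(v$token, "a")
  expect_equal(v$id, 2L)
  expect_equal(attr(v, "pad_id"), 0L)
  expect_equal(attr(v, "unk_id"), 1L)
  expect_equal(vocab_size(v), 3L)
  expect_identical(build_vocabulary(cp, min_frequency = 2), v)
  # empty-token corpus keeps only the specials
  v0 <- build_vocabulary(make_corpus(list(u1 = "zz")), min_frequency = 5)
  expect_equal(nrow(v0), 0L)
  expect_equal(vocab_size(v0), 2L)
})

test_that("encoding pads, truncates and maps unknowns", {
  cp <- make_corpus(list(u1 = "a b c d e"))
  docs <- concat_posts(cp)
  v <- build_vocabulary(make_corpus(list(u1 = "a b c")))
  enc <- encode_documents(docs, v, max_len = 8)
  expect_length(enc$token_ids[[1]], 8L)
  expect_equal(enc$true_length, 5L)
  expect_equal(sum(enc$token_ids[[1]] == 1L), 2L) # d, e unknown
  expect_equal(enc$token_ids[[1]][6:8], rep(0L, 3))
  head_enc <- encode_documents(docs, v, max_len = 3, truncation = "head")
  expect_equal(head_enc$true_length, 3L)
  tail_enc <- encode_documents(docs, v, max_len = 3, truncation = "tail")
  expect_false(identical(head_enc$token_ids, tail_enc$token_ids))
})

test_that("default training protocol matches the study setup", {
  cfg <- train_config("textcnn")
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$epochs, 20L)
  expect_equal(train_config("dpcnn")$epochs, 20L)
  expect_equal(train_config("fasttext")$epochs, 50L)
  expect_error(train_config("textcnn", epochs = 0), "epochs")
})

# finite-difference gradient check: the independent oracle for the
# hand-derived backpropagation of every architecture
grad_check_worst <- function(arch_name, cfg, seed = 404) {
  arch <- dhesd:::nn_arch(arch_name)
  withr::with_seed(seed, {
    vs <- 11L
    B <- 3L
    L <- 7L
    lens <- c(7L, 4L, 5L)
    ids <- matrix(sample(1:(vs - 1L), B * L, replace = TRUE), B, L)
    for (b in 1:B) if (lens[b] < L) ids[b, (lens[b] + 1L):L] <- 0L
    y <- c(1L, 0L, 1L)
    params <- arch$init(vs, cfg)
    loss_fn <- function(p) {
      dhesd:::softmax_ce(arch$forward(p, ids, lens, cfg)$logits, y)$loss
    }
    fwd <- arch$forward(params, ids, lens, cfg)
    grads <- arch$backward(params, fwd$cache,
                           dhesd:::softmax_ce(fwd$logits, y)$dlogits)
    worst <- 0
    for (nm in names(grads)) {
      g <- grads[[nm]]
      probe <- seq_along(g)
      if (nm == "E") { # the frozen zero pad row is excluded by design
        probe <- probe[((probe - 1L) %% nrow(params$E)) != 0L]
      }
      probe <- sample(probe, min(length(probe), 30L))
      for (i in probe) {
        eps <- 1e-5
        p2 <- params
        p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params
        p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
        worst <- max(worst, abs(num - g[i]) /
                       max(1e-6, abs(num) + abs(g[i])))
      }
    }
    worst
  })
}

test_that("analytic gradients match finite differences for every architecture", {
  small <- function(a) {
    train_config(a, embedding_dim = 5L, n_filters = 4L,
                 kernel_sizes = c(2L, 3L), n_blocks = 2L,
                 hash_buckets = 16L, max_len = 7L)
  }
  expect_lt(grad_check_worst("fasttext", small("fasttext")), 1e-4)
  expect_lt(grad_check_worst("textcnn", small("textcnn")), 1e-4)
  expect_lt(grad_check_worst("dpcnn", small("dpcnn")), 1e-4)
  expect_lt(grad_check_worst("dummy", small("dummy")), 1e-4)
})

test_that("the dummy scorer trains fast and is seed-reproducible", {
  gen <- generate_corpus(separable_config(17, n_positive = 5L,
                                          n_negative = 5L))
  cfg <- train_config("dummy", epochs = 10, seed = 9)
  t0 <- proc.time()[["elapsed"]]
  c1 <- train_base_classifier(gen$corpus, gen$corpus, cfg)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
  c2 <- train_base_classifier(gen$corpus, gen$corpus, cfg)
  expect_identical(predict_label(c1, gen$corpus),
                   predict_label(c2, gen$corpus))
})

test_that("reported validation F1 is the best checkpoint of the log", {
  gen <- generate_corpus(separable_config(23))
  sp <- stratified_split(gen$corpus, c(0.7, 0.3, 0), seed = 1)
  clf <- train_base_classifier(corpus_partition(gen$corpus, sp, "train"),
                               corpus_partition(gen$corpus, sp, "val"),
                               train_config("fasttext", seed = 2))
  expect_equal(clf$validation_f1, max(clf$training_log$val_f1))
  expect_true(clf$validation_f1 >= 0 && clf$validation_f1 <= 1)
  g <- glance(clf)
  expect_equal(g$validation_f1, clf$validation_f1)
  expect_identical(tidy(clf), clf$training_log)
})

test_that("all three architectures separate a disjoint-vocabulary corpus", {
  gen <- generate_corpus(separable_config(29, n_positive = 80L,
                                          n_negative = 100L))
  sp <- stratified_split(gen$corpus, c(0.8, 0.2, 0), seed = 1)
  tr <- corpus_partition(gen$corpus, sp, "train")
  va <- corpus_partition(gen$corpus, sp, "val")
  for (a in c("textcnn", "fasttext", "dpcnn")) {
    clf <- train_base_classifier(tr, va, train_config(a, seed = 31))
    expect_gte(clf$validation_f1, 0.95)
  }
})

test_that("prediction is deterministic and favors signal vocabulary", {
  gen <- generate_corpus(separable_config(37))
  sp <- stratified_split(gen$corpus, c(0.7, 0.3, 0), seed = 1)
  clf <- train_base_classifier(corpus_partition(gen$corpus, sp, "train"),
                               corpus_partition(gen$corpus, sp, "val"),
                               train_config("fasttext", seed = 5))
  # a user writing purely in the positive-signal vocabulary
  pure_pos <- make_corpus(list(probe = c("p1 p2 p3 p4", "p5 p1 p2")),
                          labels = list(NA_character_))
  expect_equal(predict_label(clf, pure_pos)$.pred, "suicidal")
  p1 <- predict_label(clf, gen$corpus)
  p2 <- predict_label(clf, gen$corpus)
  expect_identical(p1, p2)
})

test_that("classifiers persist through checkpoints with a JSON sidecar", {
  gen <- generate_corpus(separable_config(41, n_positive = 6L,
                                          n_negative = 8L))
  clf <- train_base_classifier(gen$corpus, gen$corpus,
                               train_config("dummy", epochs = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".rds")
  write_classifier(clf, f)
  back <- read_classifier(f)
  expect_identical(predict_label(back, gen$corpus),
                   predict_label(clf, gen$corpus))
  sidecar <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(sidecar$architecture, "dummy")
  expect_equal(sidecar$validation_f1, clf$validation_f1)
})

test_that("training rejects unusable inputs", {
  gen <- generate_corpus(separable_config(43, n_positive = 4L,
                                          n_negative = 4L))
  unlabeled <- gen$corpus
  unlabeled$label <- NA_character_
  expect_error(
    train_base_classifier(unlabeled, gen$corpus,
                          train_config("dummy", epochs = 2)), "labeled")
  empty_vocab <- build_vocabulary(gen$corpus, min_frequency = 10000L)
  expect_error(
    train_base_classifier(gen$corpus, gen$corpus,
                          train_config("dummy", epochs = 2),
                          vocabulary = empty_vocab[0, ]), "empty")
})
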