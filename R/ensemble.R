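#' Hard majority vote
#'
#' Returns the strictly more frequent label; an exact tie returns the
#' `tie_rule` label. The default tie rule favours the positive (suicidal)
#' class, preferring recall in a screening context. At the default ensemble
#' shape (3 subsets x 3 models) every vote count is odd, so ties never occur.
#'
#' @param labels Non-empty vector of binary votes (canonical label strings or
#'   0/1).
#' @param tie_rule `"positive"` or `"negative"`.
#' @return A single vote, in the same coding as the input.
#' @examples
#' majority_vote(c(1, 1, 0))
#' majority_vote(c("suicidal", "non_suicidal"), tie_rule = "positive")
#' @export
majority_vote <- function(labels, tie_rule = c("positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  if (!length(labels)) stop("labels must be non-empty", call. = FALSE)
  b <- as_binary_label(labels)
  if (anyNA(b)) stop("votes must not be missing", call. = FALSE)
  pos <- sum(b)
  neg <- length(b) - pos
  out <- if (pos > neg) 1L else if (neg > pos) 0L else {
    if (tie_rule == "positive") 1L else 0L
  }
  restore_vote_type(out, labels)
}

restore_vote_type <- function(bin, template) {
  if (is.character(template) || is.factor(template)) {
    as_character_label(bin)
  } else {
    as.integer(bin)
  }
}

check_vote_grid <- function(votes) {
  if (is.data.frame(votes)) votes <- as.matrix(votes)
  if (is.list(votes)) {
    lens <- lengths(votes)
    if (length(unique(lens)) != 1L) {
      stop("ragged vote grid: rows have differing lengths", call. = FALSE)
    }
    votes <- do.call(rbind, votes)
  }
  if (!is.matrix(votes)) stop("votes must be an n x m matrix", call. = FALSE)
  votes
}

#' Two-level hierarchical ensemble of a vote grid
#'
#' Reduces an `n x m` grid of base-classifier votes (row p = the m models
#' trained on balanced sub-dataset p) in two stages: a first-level majority
#' vote within each row, then a second-level majority vote across the n row
#' verdicts. A pure function of the grid. Unlike a flat majority over all
#' `n*m` votes, the hierarchy can return the correct label even when fewer
#' than half of the base classifiers are correct (e.g. rows
#' `110 / 110 / 000`: four correct votes out of nine carry both levels).
#'
#' @param votes An `n x m` matrix (or data frame / list of equal-length rows)
#'   of binary votes.
#' @inheritParams majority_vote
#' @return A list with `votes` (the grid), `first_level` (length-n vector of
#'   row verdicts) and `final` (the second-level verdict).
#' @export
hierarchical_predict <- function(votes, tie_rule = c("positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  votes <- check_vote_grid(votes)
  first <- apply(votes, 1L, majority_vote, tie_rule = tie_rule)
  final <- majority_vote(first, tie_rule = tie_rule)
  list(votes = votes, first_level = first, final = final)
}

#' Flat (classical) majority ensemble over a vote grid
#'
#' A single majority over all `n*m` votes, ignoring the subset structure.
#' Kept as the reference against which the hierarchical reduction is
#' compared.
#'
#' @inheritParams hierarchical_predict
#' @return A single vote.
#' @export
flat_ensemble_oracle <- function(votes, tie_rule = c("positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  votes <- check_vote_grid(votes)
  majority_vote(as.vector(votes), tie_rule = tie_rule)
}

#' Census of correctness patterns for hierarchical vs. flat voting
#'
#' Enumerates all `2^(n*m)` patterns of which base classifiers are correct
#' and tabulates, for each count `k` of correct classifiers, how many of the
#' `choose(n*m, k)` placements yield a correct hierarchical verdict and a
#' correct flat verdict. With nine classifiers in a 3 x 3 grid, the flat
#' ensemble needs at least 5 correct classifiers while the hierarchy can
#' already be correct with 4 (two rows at 2-of-3) — the structural advantage
#' of two-level voting.
#'
#' @param n,m Grid dimensions; `n * m <= 20` (exhaustive enumeration bound).
#' @param tie_rule Tie rule used at both levels.
#' @param truth Which class the "correct" classifiers vote for; with even
#'   vote counts the tie rule interacts with this (default `"positive"`).
#' @return A tibble with `k`, `n_placements`, `n_hier_correct`,
#'   `n_flat_correct`, of class `dhesd_census`, with attributes `min_k_hier`
#'   and `min_k_flat` (smallest k at which each scheme can be correct).
#' @export
vote_pattern_census <- function(n, m, tie_rule = c("positive", "negative"),
                                truth = c("positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  truth <- match.arg(truth)
  assert_scalar_count(n, "n")
  assert_scalar_count(m, "m")
  nm <- n * m
  if (nm > 20L) stop("n * m must be <= 20 for exhaustive enumeration",
                     call. = FALSE)
  tie_correct <- (tie_rule == truth)
  bits <- as.matrix(expand.grid(rep(list(0:1), nm), KEEP.OUT.ATTRS = FALSE))
  # row p of the grid occupies columns (p-1)*m + 1 .. p*m
  row_counts <- vapply(seq_len(n), function(p) {
    rowSums(bits[, ((p - 1L) * m + 1L):(p * m), drop = FALSE])
  }, numeric(nrow(bits)))
  if (is.null(dim(row_counts))) row_counts <- matrix(row_counts, ncol = n)
  row_correct <- row_counts * 2 > m |
    (row_counts * 2 == m & tie_correct)
  n_rows_correct <- rowSums(row_correct)
  hier_correct <- n_rows_correct * 2 > n |
    (n_rows_correct * 2 == n & tie_correct)
  n_correct <- rowSums(bits)
  flat_correct <- n_correct * 2 > nm | (n_correct * 2 == nm & tie_correct)
  kf <- factor(n_correct, 0:nm)
  out <- tibble(
    k = 0:nm,
    n_placements = as.integer(tabulate(n_correct + 1L, nbins = nm + 1L)),
    n_hier_correct = as.integer(tapply(hier_correct, kf, sum)),
    n_flat_correct = as.integer(tapply(flat_correct, kf, sum))
  )
  attr(out, "min_k_hier") <- min(out$k[out$n_hier_correct > 0L])
  attr(out, "min_k_flat") <- min(out$k[out$n_flat_correct > 0L])
  class(out) <- c("dhesd_census", class(out))
  out
}

#' @rdname vote_pattern_census
#' @param census A `dhesd_census` table.
#' @param path Output TSV path.
#' @export
write_census <- function(census, path) {
  utils::write.table(as.data.frame(census), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @method autoplot dhesd_census
#' @export
autoplot.dhesd_census <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(object),
                  hierarchical = .data$n_hier_correct / .data$n_placements,
                  flat = .data$n_flat_correct / .data$n_placements),
    cols = c("hierarchical", "flat"),
    names_to = "scheme", values_to = "fraction_correct")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$fraction_correct,
                                     colour = .data$scheme)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of correct base classifiers",
                  y = "fraction of placements giving a correct verdict",
                  colour = NULL,
                  title = "Hierarchical vs. flat majority voting") +
    ggplot2::theme_minimal()
}

#' Run the full hierarchical ensemble on a test corpus
#'
#' Fills the `n x m` vote grid for every test user by querying each trained
#' base classifier, then reduces it with [hierarchical_predict()]. The
#' returned table is a bit-exact replay of both ensemble levels: one column
#' per base vote (`vote_p_q`), per first-level verdict (`first_p`), and the
#' final label.
#'
#' @param classifiers A list of `n` lists, each holding the `m` trained
#'   classifiers of one balanced sub-dataset (see [train_base_classifier()]).
#' @param test_corpus Corpus of users to classify (labels optional).
#' @inheritParams majority_vote
#' @return A tibble of class `dhesd_prediction`: `user_id`, `label` (true
#'   label, possibly `NA`), the vote/verdict columns, and `.pred` (the final
#'   label).
#' @export
run_dhe_sd <- function(classifiers, test_corpus,
                       tie_rule = c("positive", "negative")) {
  tie_rule <- match.arg(tie_rule)
  if (!length(classifiers) || !all(vapply(classifiers, is.list, TRUE))) {
    stop("classifiers must be a list of lists (subsets x models)",
         call. = FALSE)
  }
  m <- length(classifiers[[1]])
  if (m < 1L || !all(lengths(classifiers) == m)) {
    stop("every subset must hold the same number of trained models",
         call. = FALSE)
  }
  n <- length(classifiers)
  for (p in seq_len(n)) for (q in seq_len(m)) {
    if (!inherits(classifiers[[p]][[q]], "dhesd_classifier")) {
      stop(sprintf("missing or untrained classifier at subset %d, model %d",
                   p, q), call. = FALSE)
    }
  }
  users <- corpus_users(test_corpus)
  votes <- matrix(0L, nrow(users), n * m)
  cn <- character(n * m)
  for (p in seq_len(n)) for (q in seq_len(m)) {
    pred <- predict_label(classifiers[[p]][[q]], test_corpus)
    stopifnot(identical(pred$user_id, users$user_id))
    votes[, (p - 1L) * m + q] <- as_binary_label(pred$.pred)
    cn[(p - 1L) * m + q] <- sprintf("vote_%d_%d", p, q)
  }
  colnames(votes) <- cn
  first <- matrix(0L, nrow(users), n)
  for (p in seq_len(n)) {
    block <- votes[, (p - 1L) * m + seq_len(m), drop = FALSE]
    pos <- rowSums(block)
    first[, p] <- as.integer(pos * 2 > m |
                               (pos * 2 == m & tie_rule == "positive"))
  }
  colnames(first) <- sprintf("first_%d", seq_len(n))
  pos2 <- rowSums(first)
  final <- as.integer(pos2 * 2 > n | (pos2 * 2 == n & tie_rule == "positive"))
  out <- dplyr::bind_cols(
    tibble(user_id = users$user_id, label = users$label),
    as_tibble(votes), as_tibble(first),
    tibble(.pred = as_character_label(final))
  )
  attr(out, "n_subsets") <- n
  attr(out, "m_models") <- m
  attr(out, "tie_rule") <- tie_rule
  class(out) <- c("dhesd_prediction", class(out))
  out
}

#' @describeIn run_dhe_sd Long view of the vote grid: one row per
#'   (user, subset, model) with the base vote, plus the first-level and final
#'   verdicts joined on.
#' @param x A `dhesd_prediction`.
#' @param ... Unused.
#' @method tidy dhesd_prediction
#' @export
tidy.dhesd_prediction <- function(x, ...) {
  n <- attr(x, "n_subsets")
  m <- attr(x, "m_models")
  long <- tidyr::pivot_longer(
    as_tibble(x)[, c("user_id", grep("^vote_", names(x), value = TRUE))],
    cols = -"user_id", names_to = c("subset", "model"),
    names_pattern = "vote_(\\d+)_(\\d+)", names_transform = as.integer,
    values_to = "vote")
  firsts <- tidyr::pivot_longer(
    as_tibble(x)[, c("user_id", grep("^first_", names(x), value = TRUE))],
    cols = -"user_id", names_to = "subset", names_pattern = "first_(\\d+)",
    names_transform = as.integer, values_to = "first_level")
  out <- dplyr::left_join(long, firsts, by = c("user_id", "subset"))
  dplyr::left_join(out, as_tibble(x)[, c("user_id", ".pred")], by = "user_id")
}

#' Write a predictions table as TSV
#'
#' @param predictions A `dhesd_prediction` (or any data frame).
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(as.data.frame(predictions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
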