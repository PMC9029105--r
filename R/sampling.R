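#' Build a partition plan of balanced sub-datasets
#'
#' Divides an imbalanced training corpus into `n_subsets` balanced
#' sub-datasets. Every subset contains *all* minority-class users plus an
#' equal-sized sample of majority-class users, so each subset is exactly
#' balanced. Two strategies are offered for the majority samples:
#'
#' * `"independent_sample"` (default): each subset's majority sample is drawn
#'   independently without replacement (within the subset). Samples may
#'   overlap across subsets — unavoidable whenever
#'   `n_subsets * |minority| > |majority|`, as in a 3-subset plan over a
#'   1284:2333 training split.
#' * `"disjoint_cycle"`: majority users are shuffled once and dealt
#'   round-robin to the subsets, recycling (reshuffling the full majority
#'   pool) only when exhausted. Guarantees that every majority user appears in
#'   at least one subset whenever `n_subsets * |minority| >= |majority|`,
#'   i.e. the union of the subsets covers the training corpus.
#'
#' @inheritParams corpus-format
#' @param n_subsets Number of balanced sub-datasets (n >= 1).
#' @param seed Integer seed; identical seeds replay identical plans.
#' @param strategy `"independent_sample"` or `"disjoint_cycle"`.
#' @return An object of class `dhesd_partition_plan`: a list with `subsets`
#'   (a tibble with `subset_index` and list-columns `minority_ids`,
#'   `majority_ids`), `seed`, `strategy`, and `minority_label`.
#' @export
build_partition_plan <- function(corpus, n_subsets = 3L, seed = 1L,
                                 strategy = c("independent_sample",
                                              "disjoint_cycle")) {
  strategy <- match.arg(strategy)
  assert_scalar_count(n_subsets, "n_subsets")
  users <- corpus_users(corpus)
  if (any(is.na(users$label))) {
    stop("all users must be labeled", call. = FALSE)
  }
  counts <- table(factor(users$label, .label_levels))
  if (any(counts == 0L)) {
    stop("corpus must contain both classes", call. = FALSE)
  }
  minority_label <- names(counts)[which.min(counts)]
  minority <- users$user_id[users$label == minority_label]
  majority <- users$user_id[users$label != minority_label]
  k <- length(minority)
  if (k > length(majority)) {
    stop("minority class is larger than majority class", call. = FALSE)
  }

  majority_samples <- withr::with_seed(seed, {
    if (strategy == "independent_sample") {
      lapply(seq_len(n_subsets), function(p) sample(majority, k))
    } else {
      deal_round_robin(majority, n_subsets, k)
    }
  })
  subsets <- tibble(
    subset_index = seq_len(n_subsets),
    minority_ids = rep(list(minority), n_subsets),
    majority_ids = majority_samples
  )
  structure(list(subsets = subsets, seed = as.integer(seed),
                 strategy = strategy, minority_label = minority_label),
            class = "dhesd_partition_plan")
}

# Deal the shuffled majority pool to n subsets round-robin; when the deck runs
# out, reshuffle the full pool and continue, skipping cards a subset already
# holds. The first |majority| deals use each user exactly once, so coverage
# holds whenever n * k >= |majority|.
deal_round_robin <- function(majority, n, k) {
  deck <- sample(majority)
  hands <- replicate(n, character(0), simplify = FALSE)
  for (round in seq_len(k)) {
    for (p in seq_len(n)) {
      if (!length(deck)) deck <- sample(majority)
      pick <- which(!(deck %in% hands[[p]]))[1L]
      if (is.na(pick)) { # subset already holds the whole remaining deck
        deck <- sample(majority)
        pick <- which(!(deck %in% hands[[p]]))[1L]
      }
      hands[[p]] <- c(hands[[p]], deck[[pick]])
      deck <- deck[-pick]
    }
  }
  hands
}

#' @export
print.dhesd_partition_plan <- function(x, ...) {
  k <- length(x$subsets$minority_ids[[1]])
  cat(sprintf(
    "<dhesd_partition_plan> %d balanced subset(s) of %d + %d users (%s, seed %d)\n",
    nrow(x$subsets), k, k, x$strategy, x$seed))
  invisible(x)
}

#' Users of one balanced subset
#'
#' @inheritParams corpus-format
#' @param plan A [build_partition_plan()] result.
#' @param subset_index Which subset to extract.
#' @return The corpus rows of that subset's users, in corpus order.
#' @export
subset_corpus <- function(corpus, plan, subset_index) {
  row <- plan$subsets[plan$subsets$subset_index == subset_index, ]
  if (nrow(row) != 1L) stop("no such subset: ", subset_index, call. = FALSE)
  corpus_subset_users(corpus, c(row$minority_ids[[1]], row$majority_ids[[1]]))
}

#' Serialize / restore a partition plan as JSON
#'
#' Plans are stored verbatim (ids, seed, strategy) so an experiment can be
#' replayed exactly.
#'
#' @param plan A `dhesd_partition_plan`.
#' @param path JSON file path.
#' @export
write_partition_plan <- function(plan, path) {
  obj <- list(
    seed = plan$seed, strategy = plan$strategy,
    minority_label = plan$minority_label,
    subsets = lapply(seq_len(nrow(plan$subsets)), function(i) {
      list(subset_index = plan$subsets$subset_index[[i]],
           minority_ids = plan$subsets$minority_ids[[i]],
           majority_ids = plan$subsets$majority_ids[[i]])
    })
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_partition_plan
#' @export
read_partition_plan <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  subsets <- tibble(
    subset_index = vapply(obj$subsets, function(s) as.integer(s$subset_index), 1L),
    minority_ids = lapply(obj$subsets, function(s)
      vapply(s$minority_ids, as.character, "")),
    majority_ids = lapply(obj$subsets, function(s)
      vapply(s$majority_ids, as.character, ""))
  )
  structure(list(subsets = subsets, seed = as.integer(obj$seed),
                 strategy = obj$strategy, minority_label = obj$minority_label),
            class = "dhesd_partition_plan")
}

#' @describeIn build_partition_plan Long per-user view of a plan: one row per
#'   (subset, user) with the user's role.
#' @param x A `dhesd_partition_plan`.
#' @param ... Unused.
#' @method tidy dhesd_partition_plan
#' @export
tidy.dhesd_partition_plan <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(x$subsets)), function(i) {
    tibble(subset_index = x$subsets$subset_index[[i]],
           user_id = c(x$subsets$minority_ids[[i]], x$subsets$majority_ids[[i]]),
           role = rep(c("minority", "majority"),
                      c(length(x$subsets$minority_ids[[i]]),
                        length(x$subsets$majority_ids[[i]]))))
  }))
}

#' Oversample the minority class to balance a corpus
#'
#' Whole users (never individual posts) are duplicated: minority users are
#' sampled uniformly with replacement and appended under fresh
#' `"<id>#dup<k>"` ids until class counts are equal. The classification unit
#' is the user, so duplication preserves each duplicated user's entire
#' posting sequence.
#'
#' @inheritParams corpus-format
#' @param seed Integer seed.
#' @return A balanced corpus tibble (originals first, duplicates appended).
#' @export
oversample_minority <- function(corpus, seed = 1L) {
  users <- sampling_classes(corpus)
  deficit <- length(users$majority) - length(users$minority)
  if (deficit == 0L) return(corpus)
  dup_sources <- withr::with_seed(seed,
    sample(users$minority, deficit, replace = TRUE))
  dups <- lapply(seq_along(dup_sources), function(i) {
    block <- corpus[corpus$user_id == dup_sources[[i]], , drop = FALSE]
    block$user_id <- sprintf("%s#dup%d", dup_sources[[i]], i)
    block
  })
  dplyr::bind_rows(c(list(corpus), dups))
}

#' Undersample the majority class to balance a corpus
#'
#' Retains a uniform without-replacement sample of majority users equal in
#' number to the minority class; all minority users are kept. Corpus row
#' order is preserved.
#'
#' @inheritParams oversample_minority
#' @return A balanced corpus tibble.
#' @export
undersample_majority <- function(corpus, seed = 1L) {
  users <- sampling_classes(corpus)
  k <- length(users$minority)
  if (length(users$majority) == k) return(corpus)
  keep_majority <- withr::with_seed(seed, sample(users$majority, k))
  corpus[corpus$user_id %in% c(users$minority, keep_majority), , drop = FALSE]
}

sampling_classes <- function(corpus) {
  users <- corpus_users(corpus)
  if (any(is.na(users$label))) stop("all users must be labeled", call. = FALSE)
  counts <- table(factor(users$label, .label_levels))
  if (any(counts == 0L)) stop("corpus must contain both classes", call. = FALSE)
  minority_label <- names(counts)[which.min(counts)]
  list(minority = users$user_id[users$label == minority_label],
       majority = users$user_id[users$label != minority_label],
       minority_label = minority_label)
}

#' Balanced validation view for one subset
#'
#' Each balanced training subset evaluates against its own balanced view of
#' the global validation partition, built by undersampling the validation
#' majority with a seed derived as `plan seed + subset_index`, so the whole
#' plan remains replayable from one seed.
#'
#' @param val_corpus The validation partition of the corpus.
#' @param plan A `dhesd_partition_plan`.
#' @param subset_index Which subset the view is for.
#' @return A balanced validation corpus.
#' @export
balanced_validation <- function(val_corpus, plan, subset_index) {
  undersample_majority(val_corpus, seed = derive_seed(plan$seed, subset_index))
}
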