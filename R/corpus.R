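#' Corpora of labeled users and their posts
#'
#' A corpus is a tibble with one row per post, ordered as on disk:
#'
#' * `user_id` — opaque string, unique per user; all rows of a user are
#'   contiguous and in posting-sequence order.
#' * `label` — `"suicidal"`, `"non_suicidal"`, or `NA` (unknown, e.g.
#'   prediction-only input). Constant within a user.
#' * `post_idx` — 1-based position of the post within the user's sequence.
#' * `text` — post body (UTF-8).
#' * `source` — `"tree_hole"`, `"ordinary"`, or `"system"`. Tree-hole posts
#'   are those synchronised from a semi-anonymous venue such as a Depression
#'   SuperTopic; they carry the provenance used by the sentence-level mask.
#' * `created_at` — optional ISO-8601 timestamp string, or `NA`.
#'
#' The classification unit is the user: models consume the concatenation of a
#' user's posts, and every user keeps at least one post. The on-disk format is
#' JSON Lines, one object per user:
#' `{"user_id": ..., "label": ..., "posts": [{"text": ..., "source": ...,
#' "created_at": ...}, ...]}`.
#'
#' @param corpus A corpus tibble as described above.
#' @name corpus-format
NULL

corpus_cols <- c("user_id", "label", "post_idx", "text", "source", "created_at")

empty_corpus <- function() {
  tibble(
    user_id = character(), label = character(), post_idx = integer(),
    text = character(), source = character(), created_at = character()
  )
}

#' Validate a corpus tibble
#'
#' Checks the schema and invariants described in [corpus-format]: required
#' columns, legal `source` and `label` values, contiguous users, per-user
#' `post_idx` running 1..n, and no duplicated `user_id`.
#'
#' @inheritParams corpus-format
#' @return The corpus, invisibly. Errors describe the first violation found.
#' @export
validate_corpus <- function(corpus) {
  if (!is.data.frame(corpus)) stop("corpus must be a data frame", call. = FALSE)
  missing_cols <- setdiff(corpus_cols, names(corpus))
  if (length(missing_cols)) {
    stop("corpus is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(corpus) == 0L) return(invisible(corpus))
  if (any(!corpus$source %in% .source_levels)) {
    stop("corpus contains invalid source values", call. = FALSE)
  }
  bad_label <- !is.na(corpus$label) & !(corpus$label %in% .label_levels)
  if (any(bad_label)) {
    stop("corpus contains invalid label values", call. = FALSE)
  }
  runs <- rle(corpus$user_id)
  if (anyDuplicated(runs$values)) {
    stop("duplicate user_id: ",
         runs$values[duplicated(runs$values)][1L], call. = FALSE)
  }
  idx_ok <- unlist(lapply(runs$lengths, seq_len), use.names = FALSE)
  if (!identical(as.integer(corpus$post_idx), idx_ok)) {
    stop("post_idx must run 1..n within each user", call. = FALSE)
  }
  lab_per_user <- tapply(corpus$label, factor(corpus$user_id, runs$values),
                         function(l) length(unique(l)))
  if (any(lab_per_user != 1L)) {
    stop("label must be constant within a user", call. = FALSE)
  }
  invisible(corpus)
}

#' Read a user corpus from a JSON Lines file
#'
#' One JSON object per line per user (see [corpus-format]). Users are returned
#' in file order and posts in array order; nothing is sorted. Unknown labels
#' (`"label": null`) are permitted for prediction-only input.
#'
#' @param path Path to a UTF-8 JSON Lines file.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_corpus())

  seen <- new.env(parent = emptyenv())
  parts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- line_no[[i]]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d: %s", ln,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    uid <- rec[["user_id"]]
    if (!is.character(uid) || length(uid) != 1L || !nzchar(uid)) {
      stop(sprintf("line %d: missing or invalid 'user_id'", ln), call. = FALSE)
    }
    if (!is.null(seen[[uid]])) {
      stop(sprintf("duplicate user_id '%s' (line %d)", uid, ln), call. = FALSE)
    }
    seen[[uid]] <- TRUE
    if (!("posts" %in% names(rec)) || !is.list(rec[["posts"]])) {
      stop(sprintf("line %d: missing 'posts'", ln), call. = FALSE)
    }
    posts <- rec[["posts"]]
    if (!length(posts)) {
      stop(sprintf("line %d: user '%s' has no posts", ln, uid), call. = FALSE)
    }
    label <- rec[["label"]]
    if (!is.null(label) &&
        (!is.character(label) || !(label %in% .label_levels))) {
      stop(sprintf("line %d: invalid 'label'", ln), call. = FALSE)
    }
    text <- character(length(posts))
    src <- character(length(posts))
    created <- rep(NA_character_, length(posts))
    for (j in seq_along(posts)) {
      p <- posts[[j]]
      if (!is.list(p) || !is.character(p[["text"]] %||% NULL) ||
          !is.character(p[["source"]] %||% NULL)) {
        stop(sprintf("line %d: post %d lacks 'text'/'source'", ln, j),
             call. = FALSE)
      }
      if (!(p[["source"]] %in% .source_levels)) {
        stop(sprintf("line %d: post %d has invalid source '%s'", ln, j,
                     p[["source"]]), call. = FALSE)
      }
      text[[j]] <- p[["text"]]
      src[[j]] <- p[["source"]]
      if (!is.null(p[["created_at"]])) created[[j]] <- p[["created_at"]]
    }
    parts[[i]] <- tibble(
      user_id = uid,
      label = if (is.null(label)) NA_character_ else label,
      post_idx = seq_along(posts),
      text = text, source = src, created_at = created
    )
  }
  out <- dplyr::bind_rows(parts)
  validate_corpus(out)
  out
}

#' Write a user corpus to a JSON Lines file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(corpus, path))`
#' reproduces `corpus` field for field, including post order and any
#' supplementary-plane characters in `text`.
#'
#' @inheritParams corpus-format
#' @param path Output path; overwritten if it exists.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(corpus) > 0L) {
    runs <- rle(corpus$user_id)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    out <- character(length(runs$values))
    for (i in seq_along(runs$values)) {
      rows <- starts[[i]]:ends[[i]]
      posts <- lapply(rows, function(r) {
        list(text = corpus$text[[r]], source = corpus$source[[r]],
             created_at = corpus$created_at[[r]])
      })
      rec <- list(user_id = runs$values[[i]], label = corpus$label[[starts[[i]]]],
                  posts = posts)
      out[[i]] <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                   na = "null")
    }
    writeLines(enc2utf8(out), con, useBytes = TRUE)
  }
  invisible(path)
}

#' One row per user of a corpus
#'
#' @inheritParams corpus-format
#' @return A tibble with `user_id`, `label` and `n_posts`, users in corpus
#'   order.
#' @export
corpus_users <- function(corpus) {
  validate_corpus(corpus)
  if (nrow(corpus) == 0L) {
    return(tibble(user_id = character(), label = character(),
                  n_posts = integer()))
  }
  runs <- rle(corpus$user_id)
  firsts <- cumsum(runs$lengths) - runs$lengths + 1L
  tibble(user_id = runs$values, label = corpus$label[firsts],
         n_posts = runs$lengths)
}

# Half-down rounding: 160.6 -> 161 but 291.5 -> 291. With an 8:1:1 split this
# reproduces per-class partition sizes 1284/161/161 (from 1606 users) and
# 2333/291/291 (from 2915 users): val and test take their rounded quota, the
# training partition absorbs the remainder.
round_half_down <- function(x) as.integer(ceiling(x - 0.5))

#' Stratified train/validation/test split
#'
#' Users are split within each class so that class proportions are preserved
#' (within one user per class per partition). The validation and test
#' partitions each receive their exact quota rounded half-down; the training
#' partition takes the remainder. Deterministic given `seed`.
#'
#' @inheritParams corpus-format
#' @param ratios Three non-negative numbers summing to 1, in the order train,
#'   validation, test. Default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed controlling the shuffle within each class.
#' @return A tibble with `user_id` and `partition`
#'   (`"train"`/`"val"`/`"test"`), one row per corpus user.
#' @export
stratified_split <- function(corpus, ratios = c(train = 0.8, val = 0.1, test = 0.1),
                             seed = 1L) {
  users <- corpus_users(corpus)
  if (nrow(users) == 0L) stop("corpus has no users", call. = FALSE)
  if (any(is.na(users$label))) {
    stop("every user must be labeled before splitting", call. = FALSE)
  }
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three non-negative numbers summing to 1",
         call. = FALSE)
  }
  class_sizes <- table(users$label)
  if (all(ratios > 0) && any(class_sizes < 3L)) {
    stop("each class needs at least 3 users for a three-way split",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    pieces <- lapply(split(users$user_id, users$label), function(ids) {
      ids <- sample(ids)
      n <- length(ids)
      n_val <- round_half_down(n * ratios[[2]])
      n_test <- round_half_down(n * ratios[[3]])
      n_train <- n - n_val - n_test
      if (n_train < 0L) stop("ratios leave no room for training users",
                             call. = FALSE)
      tibble(user_id = ids,
             partition = rep(c("train", "val", "test"),
                             c(n_train, n_val, n_test)))
    })
    assignment <- dplyr::bind_rows(pieces)
  })
  # report in corpus user order
  assignment[match(users$user_id, assignment$user_id), ]
}

#' Read/write a split assignment as two-column TSV
#'
#' @param split A tibble with `user_id` and `partition`.
#' @param path File path.
#' @return `write_split()` returns `path` invisibly; `read_split()` returns the
#'   assignment tibble.
#' @export
write_split <- function(split, path) {
  stopifnot(all(c("user_id", "partition") %in% names(split)))
  utils::write.table(split[, c("user_id", "partition")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              colClasses = "character",
                              fileEncoding = "UTF-8"))
}

#' Restrict a corpus to one partition of a split
#'
#' @inheritParams corpus-format
#' @param split A split assignment from [stratified_split()].
#' @param partition One of `"train"`, `"val"`, `"test"`.
#' @return The corpus rows of the selected users, in corpus order.
#' @export
corpus_partition <- function(corpus, split, partition = c("train", "val", "test")) {
  partition <- match.arg(partition)
  keep <- split$user_id[split$partition == partition]
  corpus[corpus$user_id %in% keep, , drop = FALSE]
}

#' Restrict a corpus to a set of users
#'
#' Rows keep corpus order; users absent from the corpus are an error.
#'
#' @inheritParams corpus-format
#' @param user_ids Character vector of user ids.
#' @return The corpus rows of the selected users.
#' @export
corpus_subset_users <- function(corpus, user_ids) {
  missing_ids <- setdiff(user_ids, corpus$user_id)
  if (length(missing_ids)) {
    stop("user(s) not in corpus: ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  corpus[corpus$user_id %in% user_ids, , drop = FALSE]
}
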