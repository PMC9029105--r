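#' Cleaning configuration
#'
#' Parameters of the eight-step post-cleaning pipeline. The steps run in a
#' fixed order: (1) drop system-generated posts, then strip (2) URLs,
#' (3) @-mentions, (4) emoticon tokens, (5) boilerplate phrases such as
#' "sharing pictures", (6) administrative-division location strings, and
#' (7) SuperTopic titles; a post whose residue is empty is dropped, and
#' (8) users left with fewer than `min_posts_per_user` posts are dropped.
#' A post removed by an earlier rule is never counted by a later one.
#'
#' The default patterns are deliberately replaceable: the exact emoticon
#' inventory, boilerplate list and division list of any given platform are
#' deployment-specific, so every field can be overridden (or loaded from a
#' YAML file with [read_cleaning_config()]).
#'
#' @param url_pattern,mention_pattern,emoticon_pattern,supertopic_pattern
#'   ICU regular-expression sources (as used by \pkg{stringr}).
#' @param boilerplate_phrases Character vector of fixed phrases to delete.
#' @param location_list Character vector of fixed location strings to delete
#'   (e.g. an administrative-division list, one term per line via
#'   [read_location_list()]).
#' @param min_posts_per_user Users with fewer retained posts are dropped.
#' @return An object of class `dhesd_cleaning_config`.
#' @export
cleaning_config <- function(
    url_pattern = "(?:https?://\\S+|t\\.cn/\\S+|www\\.\\S+)",
    mention_pattern = "@\\S+",
    emoticon_pattern = "\\[[^\\[\\]]{1,8}\\]|\\p{So}",
    boilerplate_phrases = c("sharing pictures", "分享图片"),
    location_list = character(),
    supertopic_pattern = "#[^#]{1,50}#",
    min_posts_per_user = 3L) {
  for (pat in c(url_pattern, mention_pattern, emoticon_pattern,
                supertopic_pattern)) {
    ok <- tryCatch({
      stringr::str_detect("probe", stringr::regex(pat))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("regex does not compile: ", pat, call. = FALSE)
  }
  assert_scalar_count(min_posts_per_user, "min_posts_per_user")
  structure(
    list(url_pattern = url_pattern, mention_pattern = mention_pattern,
         emoticon_pattern = emoticon_pattern,
         boilerplate_phrases = boilerplate_phrases,
         location_list = location_list,
         supertopic_pattern = supertopic_pattern,
         min_posts_per_user = as.integer(min_posts_per_user)),
    class = "dhesd_cleaning_config"
  )
}

#' Read a cleaning/mask configuration from a YAML file
#'
#' Keys mirror the arguments of [cleaning_config()] and [mask_config()];
#' absent keys keep their defaults. A `location_file` key is read with
#' [read_location_list()] relative to the config file.
#'
#' @param path Path to a YAML document.
#' @return A `dhesd_cleaning_config`.
#' @export
read_cleaning_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  if (!is.null(raw$location_file)) {
    raw$location_list <- read_location_list(
      file.path(dirname(path), raw$location_file))
    raw$location_file <- NULL
  }
  known <- names(formals(cleaning_config))
  do.call(cleaning_config, raw[intersect(names(raw), known)])
}

#' @rdname read_cleaning_config
#' @export
read_location_list <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(trimws(x))]
}

# rules in pipeline order; system and empty_residue delete whole posts,
# min_posts deletes whole users.
cleaning_rules <- c("system", "url", "mention", "emoticon", "boilerplate",
                    "location", "supertopic", "empty_residue", "min_posts")

#' Clean a single post
#'
#' Applies steps (1)-(7) of the pipeline to one post. Total and idempotent:
#' cleaning an already-clean post returns it unchanged.
#'
#' @param text Post body.
#' @param source Post provenance (`"tree_hole"`, `"ordinary"`, `"system"`).
#' @param config A [cleaning_config()].
#' @return A list with `text` (cleaned body, `NA` if removed), `removed`
#'   (logical) and `rule` (the rule that removed the post, or `NA`).
#' @examples
#' clean_post("see this http://t.cn/abc @alice", "ordinary")$text
#' @export
clean_post <- function(text, source = "ordinary", config = cleaning_config()) {
  stopifnot(length(text) == 1L, length(source) == 1L)
  if (source == "system") {
    return(list(text = NA_character_, removed = TRUE, rule = "system"))
  }
  cleaned <- strip_post_text(text, config)
  if (!nzchar(cleaned)) {
    return(list(text = NA_character_, removed = TRUE, rule = "empty_residue"))
  }
  list(text = cleaned, removed = FALSE, rule = NA_character_)
}

# vectorised steps (2)-(7) + whitespace squish; returns the cleaned text
strip_post_text <- function(text, config) {
  text <- stringr::str_remove_all(text, stringr::regex(config$url_pattern))
  text <- stringr::str_remove_all(text, stringr::regex(config$mention_pattern))
  text <- stringr::str_remove_all(text, stringr::regex(config$emoticon_pattern))
  for (ph in config$boilerplate_phrases) {
    text <- stringr::str_remove_all(text, stringr::fixed(ph))
  }
  for (loc in config$location_list) {
    text <- stringr::str_remove_all(text, stringr::fixed(loc))
  }
  text <- stringr::str_remove_all(text, stringr::regex(config$supertopic_pattern))
  stringr::str_squish(text)
}

count_matches <- function(text, pattern, fixed = FALSE) {
  pat <- if (fixed) stringr::fixed(pattern) else stringr::regex(pattern)
  sum(stringr::str_count(text, pat))
}

#' Clean every post of a corpus
#'
#' Runs the full pipeline, including step (8): users whose retained post count
#' falls below `config$min_posts_per_user` are dropped. The returned corpus
#' carries a removal tally (see [removal_tally()]) recording, per rule, how
#' many pattern matches were stripped, how many whole posts were deleted, and
#' how many users were dropped.
#'
#' @inheritParams corpus-format
#' @param config A [cleaning_config()].
#' @return A cleaned corpus tibble with attribute `removal_tally`.
#' @export
clean_corpus <- function(corpus, config = cleaning_config()) {
  validate_corpus(corpus)
  tally <- tibble(rule = cleaning_rules, matches_removed = 0L,
                  posts_removed = 0L, users_removed = 0L)
  bump <- function(t, rule, matches = 0L, posts = 0L, users = 0L) {
    i <- match(rule, t$rule)
    t$matches_removed[i] <- t$matches_removed[i] + as.integer(matches)
    t$posts_removed[i] <- t$posts_removed[i] + as.integer(posts)
    t$users_removed[i] <- t$users_removed[i] + as.integer(users)
    t
  }
  out <- corpus
  is_system <- out$source == "system"
  tally <- bump(tally, "system", matches = sum(is_system),
                posts = sum(is_system))
  out <- out[!is_system, , drop = FALSE]

  if (nrow(out)) {
    txt <- out$text
    tally <- bump(tally, "url", count_matches(txt, config$url_pattern))
    txt <- stringr::str_remove_all(txt, stringr::regex(config$url_pattern))
    tally <- bump(tally, "mention", count_matches(txt, config$mention_pattern))
    txt <- stringr::str_remove_all(txt, stringr::regex(config$mention_pattern))
    tally <- bump(tally, "emoticon", count_matches(txt, config$emoticon_pattern))
    txt <- stringr::str_remove_all(txt, stringr::regex(config$emoticon_pattern))
    for (ph in config$boilerplate_phrases) {
      tally <- bump(tally, "boilerplate", count_matches(txt, ph, fixed = TRUE))
      txt <- stringr::str_remove_all(txt, stringr::fixed(ph))
    }
    for (loc in config$location_list) {
      tally <- bump(tally, "location", count_matches(txt, loc, fixed = TRUE))
      txt <- stringr::str_remove_all(txt, stringr::fixed(loc))
    }
    tally <- bump(tally, "supertopic",
                  count_matches(txt, config$supertopic_pattern))
    txt <- stringr::str_remove_all(txt, stringr::regex(config$supertopic_pattern))
    txt <- stringr::str_squish(txt)
    empty <- !nzchar(txt)
    tally <- bump(tally, "empty_residue", matches = sum(empty),
                  posts = sum(empty))
    out$text <- txt
    out <- out[!empty, , drop = FALSE]
  }

  # step (8): drop users with too few remaining posts
  if (nrow(out)) {
    counts <- table(out$user_id)
    few <- names(counts)[counts < config$min_posts_per_user]
    n_dropped_posts <- sum(out$user_id %in% few)
    tally <- bump(tally, "min_posts", posts = n_dropped_posts,
                  users = length(few))
    out <- out[!(out$user_id %in% few), , drop = FALSE]
  } else {
    # everyone already gone: count originally present users as min_posts drops
    tally <- bump(tally, "min_posts",
                  users = length(unique(corpus$user_id)))
  }
  out <- renumber_posts(out)
  attr(out, "removal_tally") <- tally
  out
}

renumber_posts <- function(corpus) {
  if (!nrow(corpus)) return(corpus)
  runs <- rle(corpus$user_id)
  corpus$post_idx <- unlist(lapply(runs$lengths, seq_len), use.names = FALSE)
  corpus
}

#' Mask configuration
#'
#' Which provenance tags the sentence-level mask deletes. Masking is by source
#' tag only — never by content — because tree-hole posts are identified by
#' where they were synchronised from, not by what they say.
#'
#' @param masked_sources Non-empty subset of
#'   `c("tree_hole", "ordinary", "system")`; default `"tree_hole"`.
#' @return An object of class `dhesd_mask_config`.
#' @export
mask_config <- function(masked_sources = "tree_hole") {
  if (!length(masked_sources) || !all(masked_sources %in% .source_levels)) {
    stop("masked_sources must be a non-empty subset of the source levels",
         call. = FALSE)
  }
  structure(list(masked_sources = unique(masked_sources)),
            class = "dhesd_mask_config")
}

#' Apply the sentence-level mask
#'
#' Deletes every post whose `source` is in `mask$masked_sources` (by default
#' all tree-hole posts), producing the harder "masked" condition in which a
#' user's explicit tree-hole disclosures are unavailable. User order and the
#' order of remaining posts are preserved; each user's post count can only
#' shrink; users reduced to zero posts are dropped and reported in the tally.
#' Masking is idempotent.
#'
#' @inheritParams corpus-format
#' @param mask A [mask_config()].
#' @return The masked corpus with attribute `removal_tally`.
#' @export
apply_sentence_mask <- function(corpus, mask = mask_config()) {
  validate_corpus(corpus)
  drop <- corpus$source %in% mask$masked_sources
  out <- corpus[!drop, , drop = FALSE]
  survivors <- unique(out$user_id)
  users_removed <- setdiff(unique(corpus$user_id), survivors)
  out <- renumber_posts(out)
  attr(out, "removal_tally") <- tibble(
    rule = "masked_source",
    matches_removed = sum(drop),
    posts_removed = sum(drop),
    users_removed = length(users_removed)
  )
  attr(out, "dropped_users") <- users_removed
  out
}

#' Removal tally of a cleaned or masked corpus
#'
#' @param x A corpus returned by [clean_corpus()] or [apply_sentence_mask()].
#' @return A tibble with columns `rule`, `matches_removed`, `posts_removed`,
#'   `users_removed`.
#' @export
removal_tally <- function(x) {
  t <- attr(x, "removal_tally")
  if (is.null(t)) stop("object carries no removal tally", call. = FALSE)
  t
}

#' @rdname removal_tally
#' @param path Output TSV path.
#' @export
write_removal_tally <- function(x, path) {
  utils::write.table(removal_tally(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
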