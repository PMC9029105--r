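#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

# Canonical label strings. The positive class is "suicidal" throughout:
# TP counts correctly detected suicide-prone users.
.positive_label <- "suicidal"
.negative_label <- "non_suicidal"
.label_levels <- c("suicidal", "non_suicidal")
.source_levels <- c("tree_hole", "ordinary", "system")

#' Label helpers
#'
#' Convert between the canonical character labels (`"suicidal"`,
#' `"non_suicidal"`) and the internal binary coding (1 = positive/suicidal,
#' 0 = negative). Numeric and logical vectors are passed through as 0/1.
#'
#' @param x A character, numeric or logical vector of labels/votes.
#' @return `as_binary_label()` returns an integer vector of 0/1;
#'   `as_character_label()` returns a character vector of canonical labels.
#' @examples
#' as_binary_label(c("suicidal", "non_suicidal"))
#' as_character_label(c(1, 0))
#' @export
as_binary_label <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    bad <- !(x %in% .label_levels) & !is.na(x)
    if (any(bad)) {
      stop("unknown label(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    as.integer(x == .positive_label)
  } else if (is.numeric(x) || is.logical(x)) {
    x <- as.integer(x)
    if (any(!(x %in% c(0L, 1L)) & !is.na(x))) {
      stop("numeric votes must be 0 or 1", call. = FALSE)
    }
    x
  } else {
    stop("cannot interpret labels of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

#' @rdname as_binary_label
#' @export
as_character_label <- function(x) {
  b <- as_binary_label(x)
  ifelse(is.na(b), NA_character_,
         ifelse(b == 1L, .positive_label, .negative_label))
}

# Keep derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
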