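# independent counting oracle, written loop-wise on purpose: it shares no
# code with the package's vectorised reductions
oracle_majority <- function(v, tie_positive = TRUE) {
  ones <- 0
  for (x in v) if (x == 1) ones <- ones + 1
  zeros <- length(v) - ones
  if (ones > zeros) 1L else if (zeros > ones) 0L else {
    if (tie_positive) 1L else 0L
  }
}

oracle_hierarchical <- function(grid, tie_positive = TRUE) {
  firsts <- integer(nrow(grid))
  for (p in seq_len(nrow(grid))) {
    firsts[p] <- oracle_majority(grid[p, ], tie_positive)
  }
  oracle_majority(firsts, tie_positive)
}

all_grids <- function(n, m) {
  bits <- expand.grid(rep(list(0:1), n * m))
  lapply(seq_len(nrow(bits)), function(i) {
    matrix(as.integer(bits[i, ]), n, m, byrow = TRUE)
  })
}


# independent reference: direct set counting on label strings, no shared code
ref_metrics <- function(truth, pred) {
  pos <- "suicidal"
  tp <- length(which(truth == pos & pred == pos))
  tn <- length(which(truth != pos & pred != pos))
  fp <- length(which(truth != pos & pred == pos))
  fn <- length(which(truth == pos & pred != pos))
  P <- if (tp + fp == 0) 0 else tp / (tp + fp)
  R <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(acc = (tp + tn) / length(truth),
       p = P, r = R,
       f1 = if (P + R == 0) 0 else 2 * P * R / (P + R))
}

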