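# Independent oracles: deliberately different implementations from the
# package internals they check.

# breadth-first enumeration of accepting label strings with <= max_pairs
# terminals (package uses recursive DFS; this is an iterative queue)
bfs_accepting_paths <- function(g, max_pairs) {
  tr <- g$transitions
  frontier <- list(list(state = g$start, labels = character(0)))
  acc <- character(0)
  for (depth in seq_len(max_pairs)) {
    nxt <- list()
    for (node in frontier) {
      rows <- which(tr$from == node$state)
      for (r in rows) {
        labs <- c(node$labels, tr$label[r])
        if (tr$to[r] %in% g$accepts)
          acc <- c(acc, paste(labs, collapse = " "))
        nxt[[length(nxt) + 1L]] <- list(state = tr$to[r], labels = labs)
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  sort(unique(acc))
}

# direct occurrence count of an n-gram (as a vector) in a corpus, by
# position-wise comparison
brute_ngram_count <- function(gram, corpus) {
  n <- length(gram)
  total <- 0L
  for (item in corpus) {
    if (length(item) < n) next
    for (i in seq_len(length(item) - n + 1L))
      if (all(item[i:(i + n - 1L)] == gram)) total <- total + 1L
  }
  total
}

brute_chunk_strength <- function(stimulus, corpus, n, view) {
  tf <- function(x) if (view == "interval") diff(as.numeric(x)) else as.numeric(x)
  s <- tf(stimulus)
  corp <- lapply(corpus, tf)
  counts <- vapply(seq_len(length(s) - n + 1L), function(i)
    brute_ngram_count(s[i:(i + n - 1L)], corp), numeric(1))
  mean(counts)
}

# brute-force sums-of-squares decomposition for a BALANCED split-plot design:
# two between factors A, B and one within factor C. y is an array indexed by
# subject rows of `wide`; returns the classical F table.
split_plot_oracle <- function(wide, A, B, within_cols) {
  Y <- as.matrix(wide[within_cols])
  a <- factor(wide[[A]]); b <- factor(wide[[B]])
  c_n <- ncol(Y); N <- nrow(Y)
  grand <- mean(Y)
  mA <- tapply(rowMeans(Y), a, mean); mB <- tapply(rowMeans(Y), b, mean)
  mAB <- tapply(rowMeans(Y), list(a, b), mean)
  # balanced: equal cell sizes
  ncell <- N / (nlevels(a) * nlevels(b))
  SS_A <- c_n * ncell * nlevels(b) * sum((mA - grand)^2)
  SS_B <- c_n * ncell * nlevels(a) * sum((mB - grand)^2)
  SS_AB <- c_n * ncell * sum((mAB - outer(mA, rep(1, nlevels(b))) -
                              outer(rep(1, nlevels(a)), mB) + grand)^2)
  subj_mean <- rowMeans(Y)
  cell_of <- interaction(a, b)
  SS_bet_err <- c_n * sum((subj_mean - ave(subj_mean, cell_of))^2)
  mC <- colMeans(Y)
  SS_C <- N * sum((mC - grand)^2)
  # interaction of between cells with C
  mAC <- apply(Y, 2, function(col) tapply(col, a, mean))  # c x a
  SS_AC <- ncell * nlevels(b) *
    sum((mAC - outer(mA, rep(1, c_n)) -
         outer(rep(1, nlevels(a)), mC) + grand)^2)
  mBC <- apply(Y, 2, function(col) tapply(col, b, mean))
  SS_BC <- ncell * nlevels(a) *
    sum((mBC - outer(mB, rep(1, c_n)) -
         outer(rep(1, nlevels(b)), mC) + grand)^2)
  # three-way: cell x C means
  SS_cells_C <- 0
  mABC <- array(0, c(nlevels(a), nlevels(b), c_n))
  for (i in seq_len(nlevels(a))) for (j in seq_len(nlevels(b)))
    for (k in seq_len(c_n))
      mABC[i, j, k] <- mean(Y[a == levels(a)[i] & b == levels(b)[j], k])
  for (i in seq_len(nlevels(a))) for (j in seq_len(nlevels(b)))
    for (k in seq_len(c_n))
      SS_cells_C <- SS_cells_C + ncell *
        (mABC[i, j, k] - mAB[i, j] - mC[k] + grand)^2
  SS_ABC <- SS_cells_C - SS_AC - SS_BC
  # within error: residual after subject and cell-by-C means
  SS_win_err <- 0
  for (s in seq_len(N)) for (k in seq_len(c_n)) {
    i <- as.integer(a[s]); j <- as.integer(b[s])
    SS_win_err <- SS_win_err +
      (Y[s, k] - subj_mean[s] - mABC[i, j, k] + mAB[i, j])^2
  }
  df_bet_err <- N - nlevels(a) * nlevels(b)
  df_win_err <- df_bet_err * (c_n - 1)
  mk <- function(ss, df, sse, dfe)
    list(F = unname((ss / df) / (sse / dfe)), df1 = df, df2 = dfe,
         pes = unname(ss / (ss + sse)))
  list(A = mk(SS_A, nlevels(a) - 1, SS_bet_err, df_bet_err),
       B = mk(SS_B, nlevels(b) - 1, SS_bet_err, df_bet_err),
       AB = mk(SS_AB, (nlevels(a) - 1) * (nlevels(b) - 1), SS_bet_err, df_bet_err),
       C = mk(SS_C, c_n - 1, SS_win_err, df_win_err),
       AC = mk(SS_AC, (nlevels(a) - 1) * (c_n - 1), SS_win_err, df_win_err),
       BC = mk(SS_BC, (nlevels(b) - 1) * (c_n - 1), SS_win_err, df_win_err),
       ABC = mk(SS_ABC, (nlevels(a) - 1) * (nlevels(b) - 1) * (c_n - 1),
                SS_win_err, df_win_err))
}
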