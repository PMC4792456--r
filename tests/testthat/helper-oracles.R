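## Independent oracles and small fixture builders shared across the suite.
## Oracles are deliberately naive (brute force / exhaustive) and kept apart
## from the package implementation paths they check.

DNA4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste0(sample(DNA4, n, replace = TRUE), collapse = "")

rc_chr <- function(s) { # independent reverse complement
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

## brute-force k-mer windows of one string (no canonicalisation)
windows_of <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  w <- substring(s, 1:(L - k + 1), k:L)
  w[!grepl("N", w, fixed = TRUE)]
}

## suffix-prefix overlap oracle via base R adist(): for each candidate
## prefix length y of b (longest first), the minimum edit distance between
## b[1..y] and any suffix of a; first y meeting the thresholds wins.
## qualifying = edit fraction strictly below max_rate; the winner has the
## lowest edit fraction, longest first among ties (same rule as the package,
## distances recomputed independently with adist)
oracle_overlap <- function(a, b, min_len, max_rate) {
  la <- nchar(a); lb <- nchar(b)
  suffixes <- substring(a, 0:la + 1L, la) # includes the empty suffix
  best <- c(len = 0L, edits = -1L)
  if (lb < min_len) return(best)
  for (y in rev(seq(min_len, lb, by = 1))) {
    e <- min(utils::adist(suffixes, substr(b, 1, y)))
    if (e / y >= max_rate) next
    if (best[["len"]] == 0L || e / y < best[["edits"]] / best[["len"]])
      best <- c(len = y, edits = e)
  }
  best
}

## Smith-Waterman oracle (match 1, mismatch -2, gap -2.5), score + spans
oracle_sw <- function(q, s, match = 1, mismatch = -2, gap = -2.5) {
  n <- nchar(q); m <- nchar(s)
  qb <- strsplit(q, "")[[1]]; sb <- strsplit(s, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    sc <- if (qb[i] == sb[j]) match else mismatch
    v <- max(0, H[i, j] + sc, H[i, j + 1] + gap, H[i + 1, j] + gap)
    H[i + 1, j + 1] <- v
    if (v > best) { best <- v; bi <- i; bj <- j }
  }
  if (best <= 0) return(list(score = 0, qspan = 0, sspan = c(0, 0)))
  ## traceback for spans
  i <- bi; j <- bj
  repeat {
    v <- H[i + 1, j + 1]
    if (v == 0) break
    sc <- if (qb[i] == sb[j]) match else mismatch
    if (i > 0 && j > 0 && v == H[i, j] + sc) { i <- i - 1; j <- j - 1 }
    else if (i > 0 && v == H[i, j + 1] + gap) i <- i - 1
    else j <- j - 1
    if (H[i + 1, j + 1] == 0) break
  }
  list(score = best, qspan = bi - i, sspan = c(j + 1, bj))
}

## all-pairs reachability by repeated squaring of the boolean adjacency
oracle_reachable <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  rownames(A) <- colnames(A) <- nodes
  if (nrow(edges)) A[cbind(edges$source, edges$target)] <- TRUE
  for (i in seq_len(ceiling(log2(max(n, 2))) + 1L)) A <- (A %*% A) > 0
  A
}

## SCC oracle: mutual reachability partition
oracle_sccs <- function(nodes, edges) {
  R <- oracle_reachable(nodes, edges)
  M <- R & t(R)
  comps <- unique(lapply(nodes, function(v) sort(nodes[M[v, ]])))
  comps[order(vapply(comps, `[`, character(1), 1))]
}

## exhaustive maximum non-overlapping interval coverage (<= ~15 intervals)
oracle_max_cov <- function(ref_len, iv) {
  iv <- as.matrix(iv)
  n <- nrow(iv)
  if (n == 0) return(0)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1) {
      o <- order(iv[sel, 1])
      ss <- iv[sel, , drop = FALSE][o, , drop = FALSE]
      if (any(ss[-1, 1] <= ss[-nrow(ss), 2])) next
    }
    best <- max(best, sum(iv[sel, 2] - iv[sel, 1] + 1))
  }
  best / ref_len
}

## random directed graph over ids a, b, c, ... with edge probability p
rand_graph <- function(n, p, allow_cycles = TRUE) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  if (!allow_cycles) pairs <- pairs[pairs$source < pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  list(nodes = ids, edges = pairs[keep, , drop = FALSE])
}

## a read set with only mate 1 carrying sequence (mate 2 all-N contributes
## no k-mer windows and no mappings) -- handy for single-read examples
single_reads <- function(seqs) {
  read_set(seqs, strrep("N", nchar(seqs[1])))
}
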