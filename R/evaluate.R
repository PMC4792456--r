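## Assembly evaluation against a reference repeat library: matching ratio,
## hit counting at cutoff t_L, optimal non-overlapping coverage, longest
## single-contig coverage, N50.

## internal: substitution matrix for megablast-like local alignment
eval_submat <- function(match = 1, mismatch = -2) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

## internal: best local alignment of query vs reference over both strands.
## Returns list(score, q0, q1, s0, s1, pid, strand) or NULL when nothing
## aligns; coordinates 1-based closed on the forward reference.
best_local <- function(query, reference, match = 1, mismatch = -2, gap = 2.5) {
  sm <- eval_submat(match, mismatch)
  score_one <- function(q) {
    Biostrings::pairwiseAlignment(q, reference, type = "local",
                                  substitutionMatrix = sm,
                                  gapOpening = 0, gapExtension = gap)
  }
  pa_f <- score_one(query)
  pa_r <- score_one(revcomp(query))
  use_r <- Biostrings::score(pa_r) > Biostrings::score(pa_f)
  pa <- if (use_r) pa_r else pa_f
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  list(score = sc,
       q0 = Biostrings::start(Biostrings::pattern(pa)),
       q1 = Biostrings::end(Biostrings::pattern(pa)),
       s0 = Biostrings::start(Biostrings::subject(pa)),
       s1 = Biostrings::end(Biostrings::subject(pa)),
       pid = Biostrings::pid(pa),
       strand = if (use_r) "-" else "+")
}

#' Matching ratio of a query against a reference sequence
#'
#' Best local alignment (match +1, mismatch -2, gap -2.5 per base, both
#' strands) of the query against the reference; the ratio is the aligned
#' query span divided by the query length. A ratio of at least the matching
#' cutoff `t_L` (default 0.85) declares a hit.
#'
#' @param query,reference Sequences (character scalars), both non-empty.
#' @return List with `ratio`, `interval` (1-based closed matched interval on
#'   the reference, `NULL` when nothing aligned), `identity` (percent
#'   identity over the aligned region), `strand`.
#' @export
matching_ratio <- function(query, reference) {
  query <- toupper(query); reference <- toupper(reference)
  if (!nzchar(query) || !nzchar(reference))
    rf_stop("query and reference must be non-empty", "degenerate_input_error")
  al <- best_local(query, reference)
  if (is.null(al))
    return(list(ratio = 0, interval = NULL, identity = NA_real_, strand = NA_character_))
  list(ratio = (al$q1 - al$q0 + 1L) / nchar(query),
       interval = c(al$s0, al$s1),
       identity = al$pid,
       strand = al$strand)
}

#' Count reference-library hits
#'
#' A library entry counts as hit when at least one assembled repeat matches
#' it with [matching_ratio()] (library entry as query) at least `t_L`.
#'
#' @param repeats `assembled_repeats` data frame (or any data frame with a
#'   `sequence` column).
#' @param library Named character vector of library consensus sequences.
#' @param t_L Matching cutoff (default 0.85).
#' @return Integer: number of library entries hit.
#' @export
count_hits <- function(repeats, library, t_L = 0.85) {
  if (nrow(repeats) == 0L || length(library) == 0L) return(0L)
  hit <- vapply(library, function(lib) {
    for (s in repeats$sequence)
      if (matching_ratio(lib, s)$ratio >= t_L) return(TRUE)
    FALSE
  }, logical(1))
  sum(hit)
}

#' Maximum non-overlapping interval coverage of a reference
#'
#' The largest total length achievable by a pairwise non-overlapping subset
#' of matched intervals, divided by the reference length. Computed exactly by
#' weighted interval scheduling (sort by end, dynamic programming over the
#' latest compatible predecessor).
#'
#' @param reference_length Length of the reference sequence.
#' @param intervals Two-column matrix or data frame of 1-based closed
#'   intervals (`start`, `end`) on the reference; may have zero rows.
#' @return Fraction in `[0, 1]`.
#' @examples
#' greedy_max_coverage(100, rbind(c(1, 60), c(51, 100)))
#' @export
greedy_max_coverage <- function(reference_length, intervals) {
  iv <- as.matrix(intervals)
  if (length(iv) == 0L || nrow(iv) == 0L) return(0)
  if (any(iv[, 1] < 1) || any(iv[, 2] > reference_length))
    rf_stop("interval outside the reference", "parameter_error")
  ord <- order(iv[, 2], iv[, 1])
  s <- iv[ord, 1]; e <- iv[ord, 2]
  w <- e - s + 1
  n <- length(s)
  ## p[i]: last interval ending before s[i]
  p <- vapply(seq_len(n), function(i) {
    ok <- which(e < s[i])
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  opt <- numeric(n + 1L)
  for (i in seq_len(n))
    opt[i + 1L] <- max(opt[i], opt[p[i] + 1L] + w[i])
  opt[n + 1L] / reference_length
}

#' Longest single-interval coverage of a reference
#'
#' The length of the longest single matched interval divided by the reference
#' length (0 when there are no intervals) — how much of the reference the
#' best single assembled repeat covers.
#'
#' @inheritParams greedy_max_coverage
#' @return Fraction in `[0, 1]`.
#' @export
longest_single_coverage <- function(reference_length, intervals) {
  iv <- as.matrix(intervals)
  if (length(iv) == 0L || nrow(iv) == 0L) return(0)
  max(iv[, 2] - iv[, 1] + 1) / reference_length
}

#' N50 of a set of lengths
#'
#' The first length, scanning from longest to shortest, at which the
#' cumulative sum reaches at least half the total.
#'
#' @param lengths Positive integer vector (non-empty).
#' @return Integer N50.
#' @examples
#' n50(c(80, 70, 50, 40, 30))
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L)
    rf_stop("N50 of an empty length set is undefined", "degenerate_input_error")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Evaluate assembled repeats against a reference library
#'
#' For every (library entry, repeat) pair the best local alignment is
#' computed; per entry the report records the best matching ratio, the
#' optimal non-overlapping coverage by all matched repeats, and the coverage
#' by the single longest match. Matched intervals are taken one per repeat
#' (its best-scoring alignment).
#'
#' @param repeats `assembled_repeats` data frame.
#' @param library Named character vector of reference consensus sequences.
#' @param config A [pipeline_config()] (supplies `matching_cutoff`).
#' @return Object of class `evaluation_report`: list with `summary`
#'   (`N`, `N_h`, `avg_coverage`, `max_single_coverage`, `n50`) and
#'   `per_entry` data frame (`entry`, `best_ratio`, `greedy_coverage`,
#'   `longest_coverage`, `hit`).
#' @export
evaluate_repeats <- function(repeats, library, config = pipeline_config()) {
  t_L <- config$matching_cutoff
  n_rep <- nrow(repeats)
  rows <- lapply(names(library), function(nm) {
    lib <- library[[nm]]
    liblen <- nchar(lib)
    ivs <- matrix(numeric(0), ncol = 2)
    best_ratio <- 0
    if (n_rep > 0L) for (s in repeats$sequence) {
      mr <- matching_ratio(lib, s)
      best_ratio <- max(best_ratio, mr$ratio)
      al <- best_local(s, lib) # interval of this repeat on the library entry
      if (!is.null(al)) ivs <- rbind(ivs, c(al$s0, al$s1))
    }
    data.frame(entry = nm, best_ratio = best_ratio,
               greedy_coverage = greedy_max_coverage(liblen, ivs),
               longest_coverage = longest_single_coverage(liblen, ivs),
               hit = best_ratio >= t_L, stringsAsFactors = FALSE)
  })
  per_entry <- do.call(rbind, rows)
  hits <- per_entry[per_entry$hit, , drop = FALSE]
  summary <- list(
    N = n_rep,
    N_h = sum(per_entry$hit),
    avg_coverage = if (nrow(hits)) mean(hits$greedy_coverage) else NA_real_,
    max_single_coverage = if (nrow(hits)) mean(hits$longest_coverage) else NA_real_,
    n50 = if (n_rep > 0L) n50(repeats$length) else NA_real_
  )
  structure(list(summary = summary, per_entry = per_entry),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat("Repeat assembly evaluation\n")
  cat(sprintf("  N (assembled repeats):     %d\n", s$N))
  cat(sprintf("  N_h (library hits):        %d / %d\n", s$N_h, nrow(x$per_entry)))
  cat(sprintf("  mean greedy coverage:      %s\n",
              ifelse(is.na(s$avg_coverage), "NA", sprintf("%.3f", s$avg_coverage))))
  cat(sprintf("  mean longest-single cover: %s\n",
              ifelse(is.na(s$max_single_coverage), "NA",
                     sprintf("%.3f", s$max_single_coverage))))
  cat(sprintf("  N50:                       %s\n",
              ifelse(is.na(s$n50), "NA", format(s$n50))))
  invisible(x)
}

#' Write an evaluation report TSV
#'
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(report, path) {
  utils::write.table(report$per_entry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
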