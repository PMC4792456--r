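#' Count k-mers in a read set
#'
#' Builds the k-mer occurrence catalog for one k: every window of `k`
#' consecutive non-`N` bases in every read (both mates) contributes one count.
#' With `canonical = TRUE` (the default) a window is counted under the
#' lexicographic minimum of itself and its reverse complement, making the
#' spectrum strand-independent. This is the sparse restriction of the full
#' occurrence vector over all 4^k k-mers to those actually observed.
#'
#' @param reads A [read_set()].
#' @param k K-mer length; must be smaller than the read length.
#' @param canonical Count canonical k-mers.
#' @return A `kmer_catalog`: list with elements `k`, `kmers` (sorted character
#'   vector), `counts` (parallel integer vector), `total_occurrences`,
#'   `distinct_count`, `canonical`, and `n_bases` (total read bases, used by
#'   the depth-based frequency baseline).
#' @examples
#' rs <- read_set("ACGTACGT", "AAAAAAAA")
#' count_kmers(rs, 3, canonical = FALSE)$counts
#' @export
count_kmers <- function(reads, k, canonical = TRUE) {
  k <- as.integer(k)
  if (k >= reads$read_length)
    rf_stop(sprintf("k = %d must be smaller than the read length (%d)",
                    k, reads$read_length), "parameter_error")
  all_reads <- c(reads$fwd, reads$rev)
  res <- count_kmers_cpp(all_reads, k, canonical)
  structure(list(
    k = k,
    kmers = as.character(res$kmer),
    counts = as.integer(res$count),
    total_occurrences = res$total,
    distinct_count = length(res$kmer),
    canonical = canonical,
    n_bases = as.numeric(length(all_reads)) * reads$read_length
  ), class = "kmer_catalog")
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat(sprintf("kmer_catalog: k = %d, %d distinct k-mers, %.0f occurrences (%s)\n",
              x$k, x$distinct_count, x$total_occurrences,
              if (x$canonical) "canonical" else "forward-strand"))
  invisible(x)
}

#' Average k-mer frequency of a catalog
#'
#' The baseline against which frequent k-mers are selected. The default
#' (`"distinct-mean"`) is total occurrences divided by the number of distinct
#' observed k-mers. `"depth-estimate"` instead uses the typical count of a
#' single-copy genomic k-mer — the median count over k-mers seen at least
#' twice (singletons are dominated by sequencing-error k-mers) — as a proxy
#' for the per-k-mer read depth.
#'
#' @param catalog A `kmer_catalog`.
#' @param baseline `"distinct-mean"` or `"depth-estimate"`.
#' @return A positive number.
#' @export
average_frequency <- function(catalog, baseline = c("distinct-mean", "depth-estimate")) {
  baseline <- match.arg(baseline)
  if (catalog$distinct_count == 0L)
    rf_stop("empty catalog: no k-mers observed", "degenerate_input_error")
  if (baseline == "distinct-mean") {
    catalog$total_occurrences / catalog$distinct_count
  } else {
    rep_counts <- catalog$counts[catalog$counts >= 2L]
    if (length(rep_counts) == 0L) rep_counts <- catalog$counts
    stats::median(rep_counts)
  }
}

#' Select frequent k-mers
#'
#' Returns the k-mers whose count is strictly greater than `f_K` times the
#' average k-mer frequency of the catalog ("over" the cutoff, so the
#' comparison is a strict inequality and boundary counts are excluded).
#'
#' @param catalog A `kmer_catalog`.
#' @param f_K Cutoff factor (default 10).
#' @param baseline Passed to [average_frequency()].
#' @return Named integer vector: counts indexed by frequent k-mer.
#' @export
select_frequent <- function(catalog, f_K = 10, baseline = "distinct-mean") {
  cutoff <- f_K * average_frequency(catalog, baseline)
  keep <- catalog$counts > cutoff
  stats::setNames(catalog$counts[keep], catalog$kmers[keep])
}

#' Partition frequent k-mers into overlapping frequency bins
#'
#' Target frequencies form a geometric sequence starting at the maximum
#' observed frequent count and decreasing by `bin_ratio` (default 2) until the
#' bin ceiling `bin_high_factor * f` would fall below the minimum frequent
#' count. Each bin with target `f` holds the k-mers whose count lies in
#' `[bin_low_factor * f, bin_high_factor * f]` (default `[0.2f, 5f]`);
#' consecutive bins overlap, so a k-mer may belong to several bins. Bins are
#' ordered from highest to lowest target frequency; k-mers from the same
#' repeat family tend to share a bin, which reduces chimeric assembly.
#'
#' @param frequent Named integer vector of counts (from [select_frequent()]).
#' @param config A [pipeline_config()] supplying the bin factors and ratio.
#' @return Object of class `frequency_bins`: list of bins, each a list with
#'   `target`, `low`, `high`, `members` (named counts).
#' @export
make_frequency_bins <- function(frequent, config = pipeline_config()) {
  if (length(frequent) == 0L)
    rf_stop("no frequent k-mers to bin", "degenerate_input_error")
  lo_f <- config$bin_low_factor
  hi_f <- config$bin_high_factor
  ratio <- config$bin_ratio
  cmin <- min(frequent)
  f <- max(frequent)
  bins <- list()
  repeat {
    lo <- lo_f * f
    hi <- hi_f * f
    members <- frequent[frequent >= lo & frequent <= hi]
    bins[[length(bins) + 1L]] <- list(target = f, low = lo, high = hi,
                                      members = members)
    f <- f / ratio
    if (f * hi_f < cmin) break
  }
  structure(bins, class = "frequency_bins")
}

#' @export
print.frequency_bins <- function(x, ...) {
  cat("frequency_bins:", length(x), "bins\n")
  for (b in x)
    cat(sprintf("  target %.1f  range [%.1f, %.1f]  %d k-mers\n",
                b$target, b$low, b$high, length(b$members)))
  invisible(x)
}

#' Export / import a k-mer count table
#'
#' Two-column tab-separated table `<kmer>\t<count>`, one k-mer per line —
#' the interchange format for pre-computed counts from an external k-mer
#' counter.
#'
#' @param catalog A `kmer_catalog` (for writing).
#' @param path File path.
#' @return `write_kmer_table()` returns `path` invisibly;
#'   `read_kmer_table()` returns a `kmer_catalog` (with `n_bases = NA`).
#' @export
write_kmer_table <- function(catalog, path) {
  utils::write.table(
    data.frame(kmer = catalog$kmers, count = catalog$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_table
#' @param canonical Whether the external counts are canonical.
#' @export
read_kmer_table <- function(path, canonical = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer"),
                           col.names = c("kmer", "count"))
  if (nrow(tab) == 0L) rf_stop("empty k-mer table", "degenerate_input_error")
  k <- unique(nchar(tab$kmer))
  if (length(k) != 1L)
    rf_stop("k-mer table mixes k-mer lengths", "parse_error")
  ord <- order(tab$kmer)
  structure(list(
    k = as.integer(k), kmers = tab$kmer[ord], counts = tab$count[ord],
    total_occurrences = sum(as.numeric(tab$count)),
    distinct_count = nrow(tab), canonical = canonical, n_bases = NA_real_
  ), class = "kmer_catalog")
}
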