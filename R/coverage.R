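## Coverage-based validation: re-map reads, discard low-coverage contigs,
## truncate unevenly covered ones.

#' Per-base coverage profile of one contig
#'
#' Depth at position i is the number of placements whose aligned span covers
#' i (1-based closed spans). Multi-mapping placements each contribute 1
#' (report-all semantics).
#'
#' @param placements Placement table rows for this contig.
#' @param contig A contig row (with `id` and `sequence` or `length`).
#' @return Object of class `coverage_profile`: list with `id`, `per_base`
#'   (integer vector) and `mean`.
#' @export
profile_coverage <- function(placements, contig) {
  len <- if (!is.null(contig$length)) contig$length[1] else nchar(contig$sequence[1])
  p <- placements[placements$contig == contig$id[1], , drop = FALSE]
  if (nrow(p) > 0L && (any(p$start < 1L) || any(p$end > len)))
    rf_stop("placement outside contig bounds", "internal_error")
  delta <- integer(len + 1L)
  if (nrow(p) > 0L) {
    st <- tabulate(p$start, len)
    en <- tabulate(p$end + 1L, len + 1L)
    delta[seq_len(len)] <- st
    delta <- delta - en
  }
  per_base <- cumsum(delta[seq_len(len)])
  structure(list(id = contig$id[1], per_base = as.integer(per_base),
                 mean = if (len > 0L) sum(per_base) / len else 0),
            class = "coverage_profile")
}

#' Coverage filter for one contig
#'
#' Applies the two coverage rules: a contig whose mean re-mapping coverage is
#' below `min_avg_coverage` is considered wrongly assembled and discarded;
#' otherwise, when coverage is uneven, only the high-coverage parts are kept
#' — each maximal run of positions with depth at least `min_avg_coverage`
#' and run length at least `min_run` is emitted as a (possibly truncated)
#' contig. A contig whose every position qualifies is kept unchanged.
#'
#' @param contig A contig row.
#' @param profile Its [profile_coverage()] profile.
#' @param config A [pipeline_config()].
#' @param min_run Minimum retained run length; defaults to the largest
#'   assembly k-mer length, so truncation never emits fragments shorter than
#'   the assembly k.
#' @return A data frame of retained (possibly truncated) contigs with
#'   `trunc_start`/`trunc_end` giving the retained span on the input contig;
#'   zero rows means discarded.
#' @export
filter_contig <- function(contig, profile, config = pipeline_config(),
                          min_run = max(config$kmer_lengths)) {
  len <- if (!is.null(contig$length)) contig$length[1] else nchar(contig$sequence[1])
  none <- cbind(contig[0, , drop = FALSE],
                data.frame(trunc_start = integer(0), trunc_end = integer(0)))
  if (profile$mean < config$min_avg_coverage) return(none)
  ok <- profile$per_base >= config$min_avg_coverage
  if (all(ok)) {
    out <- contig
    out$trunc_start <- 1L
    out$trunc_end <- len
    return(out)
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(none)
  starts <- starts[keep]; ends <- ends[keep]
  out <- contig[rep(1L, length(starts)), , drop = FALSE]
  out$sequence <- substring(contig$sequence[1], starts, ends)
  out$length <- nchar(out$sequence)
  if (length(starts) > 1L)
    out$id <- sprintf("%s.%d", contig$id[1], seq_along(starts))
  out$trunc_start <- starts
  out$trunc_end <- ends
  rownames(out) <- NULL
  out
}

#' Coverage-filter a whole contig set
#'
#' Maps the reads to the contigs, profiles per-base coverage, and applies
#' [filter_contig()] to each contig.
#'
#' @param contigs Raw-contig data frame.
#' @param reads A [read_set()].
#' @param config A [pipeline_config()].
#' @param placements Optional pre-computed placements on `contigs`.
#' @param min_run Passed to [filter_contig()].
#' @return Filtered contig data frame (with a `mean_coverage` column).
#' @export
filter_contigs <- function(contigs, reads, config = pipeline_config(),
                           placements = NULL,
                           min_run = max(config$kmer_lengths)) {
  if (nrow(contigs) == 0L) return(contigs)
  if (is.null(placements))
    placements <- map_reads_to_contigs(reads, contigs, config)
  pieces <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    row <- contigs[i, , drop = FALSE]
    prof <- profile_coverage(placements, row)
    kept <- filter_contig(row, prof, config, min_run)
    if (nrow(kept) > 0L) {
      kept$mean_coverage <- vapply(seq_len(nrow(kept)), function(j)
        mean(prof$per_base[kept$trunc_start[j]:kept$trunc_end[j]]),
        numeric(1))
    }
    kept$trunc_start <- NULL
    kept$trunc_end <- NULL
    pieces[[i]] <- kept
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Re-validate merged repeats by coverage
#'
#' Applies the same discard/truncate coverage rules to the merged repeats:
#' reads are re-mapped to the repeat sequences, repeats with mean coverage
#' below the threshold are dropped, unevenly covered repeats are truncated
#' (a chimeric merge whose junction attracts no reads is split there), and
#' `mean_coverage` is filled for the FASTA headers.
#'
#' @param repeats An `assembled_repeats` data frame.
#' @param reads A [read_set()].
#' @param config A [pipeline_config()].
#' @param min_run Minimum retained run length.
#' @return The surviving `assembled_repeats`, re-sorted and renumbered, with
#'   `mean_coverage` filled.
#' @export
annotate_repeats <- function(repeats, reads, config = pipeline_config(),
                             min_run = max(config$kmer_lengths)) {
  if (nrow(repeats) == 0L) return(repeats)
  ctg <- data.frame(id = repeats$id, sequence = repeats$sequence,
                    length = repeats$length, stringsAsFactors = FALSE)
  placements <- map_reads_to_contigs(reads, ctg, config)
  keep <- vector("list", nrow(repeats))
  for (i in seq_len(nrow(repeats))) {
    row <- repeats[i, , drop = FALSE]
    prof <- profile_coverage(placements,
                             data.frame(id = row$id, sequence = row$sequence,
                                        length = row$length))
    fc <- filter_contig(data.frame(id = row$id, sequence = row$sequence,
                                   length = row$length,
                                   stringsAsFactors = FALSE),
                        prof, config, min_run)
    if (nrow(fc) == 0L) next
    piece <- row[rep(1L, nrow(fc)), , drop = FALSE]
    piece$sequence <- fc$sequence
    piece$length <- fc$length
    piece$mean_coverage <- vapply(seq_len(nrow(fc)), function(j)
      mean(prof$per_base[fc$trunc_start[j]:fc$trunc_end[j]]),
      numeric(1))
    keep[[i]] <- piece
  }
  out <- do.call(rbind, keep[!vapply(keep, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    out <- repeats[0, , drop = FALSE]
    class(out) <- c("assembled_repeats", "data.frame")
    return(out)
  }
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  out$id <- sprintf("rep_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("assembled_repeats", "data.frame")
  out
}

#' Write a per-base coverage TSV
#'
#' `contig<TAB>pos<TAB>depth`, one line per base.
#'
#' @param profiles List of `coverage_profile` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(profiles, path) {
  tabs <- lapply(profiles, function(p)
    data.frame(contig = p$id, pos = seq_along(p$per_base), depth = p$per_base))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
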