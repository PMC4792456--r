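#' Assemble repeat consensus sequences from raw reads
#'
#' The full pipeline: (1) count k-mers for every configured k-mer length;
#' (2) select frequent k-mers (count strictly above `freq_cutoff_factor`
#' times the average k-mer frequency), partition them into overlapping
#' frequency bins and assemble each bin into raw contigs, combining all k
#' values and deduplicating; (3) validate raw contigs by re-mapping the
#' reads and discarding/truncating on coverage; (4) build the directed
#' contig graph (suffix-prefix overlaps with read-pair support); (5) merge
#' maximal paths into long repeats; (6) re-validate the merged repeats by
#' coverage and annotate their mean depth.
#'
#' @param reads A [read_set()].
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress with timings.
#' @return List of class `repeat_assembly` with elements `repeats`
#'   (an `assembled_repeats` data frame), `raw_contigs`, `filtered_contigs`,
#'   `graph`, and `config`.
#' @export
assemble_repeats <- function(reads, config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  stage <- function(what) {
    say("[%7.1fs] %s", proc.time()[3] - t0, what)
  }
  if (reads$read_length < max(config$kmer_lengths))
    rf_stop("reads are shorter than the largest assembly k-mer", "parse_error")
  set.seed(config$rng_seed)

  stage("counting k-mers")
  catalogs <- lapply(config$kmer_lengths, function(k)
    count_kmers(reads, k, canonical = config$canonical))

  stage("assembling frequent k-mers into raw contigs")
  raw <- assemble_all(catalogs, config)
  say("          %d raw contigs", nrow(raw))

  stage("coverage-filtering raw contigs")
  filtered <- if (nrow(raw) > 0L) filter_contigs(raw, reads, config) else raw
  say("          %d contigs after filtering", nrow(filtered))

  stage("building the contig graph")
  graph <- build_graph(filtered, reads, config)
  say("          %d nodes, %d edges", nrow(graph$contigs), nrow(graph$edges))

  stage("merging maximal paths into repeats")
  repeats <- merge_paths(graph)

  stage("re-validating merged repeats")
  repeats <- annotate_repeats(repeats, reads, config)
  say("          %d repeats", nrow(repeats))

  structure(list(repeats = repeats, raw_contigs = raw,
                 filtered_contigs = filtered, graph = graph, config = config),
            class = "repeat_assembly")
}

#' @export
print.repeat_assembly <- function(x, ...) {
  cat("repeat_assembly:\n")
  cat("  raw contigs:      ", nrow(x$raw_contigs), "\n")
  cat("  filtered contigs: ", nrow(x$filtered_contigs), "\n")
  cat("  graph:            ", nrow(x$graph$contigs), "nodes,",
      nrow(x$graph$edges), "edges\n")
  cat("  repeats:          ", nrow(x$repeats), "\n")
  if (nrow(x$repeats) > 0L)
    cat("  longest repeat:   ", max(x$repeats$length), "bp; N50",
        n50(x$repeats$length), "\n")
  invisible(x)
}
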