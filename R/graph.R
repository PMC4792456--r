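## Contig graph: candidate pairing by shared short substrings, suffix-prefix
## overlap verification by edit-distance DP, read-pair support, orientation
## assignment, and assembly of the directed graph over raw contigs.

#' Candidate contig pairs by shared short substrings
#'
#' Returns every ordered pair of distinct contigs sharing at least one exact
#' length-`k0` substring (reverse complements considered when `orientation`
#' is `TRUE`). Any overlap of at least 15 bp with under 5 percent mismatches
#' must contain an exact common 5-mer (pigeonhole over the mismatch
#' positions), so with the default thresholds this prefilter never excludes a
#' qualifying edge; it only prunes the all-pairs alignment work.
#'
#' @param contigs Raw-contig data frame (columns `id`, `sequence`).
#' @param k0 Shared-substring length (default 5).
#' @param orientation Also match against reverse complements.
#' @return Data frame with columns `source`, `target` (both orders present).
#' @export
candidate_pairs <- function(contigs, k0 = 5L, orientation = TRUE) {
  n <- nrow(contigs)
  empty <- data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k0) return(character(0))
    unique(substring(s, 1:(L - k0 + 1L), k0:L))
  }
  recs <- lapply(seq_len(n), function(i) {
    km <- kmers_of(contigs$sequence[i])
    if (orientation) km <- unique(c(km, kmers_of(revcomp(contigs$sequence[i]))))
    km
  })
  tab <- data.frame(kmer = unlist(recs),
                    idx = rep(seq_len(n), lengths(recs)),
                    stringsAsFactors = FALSE)
  m <- merge(tab, tab, by = "kmer")
  m <- m[m$idx.x != m$idx.y, c("idx.x", "idx.y")]
  m <- unique(m)
  if (nrow(m) == 0L) return(empty)
  out <- data.frame(source = contigs$id[m$idx.x],
                    target = contigs$id[m$idx.y],
                    stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}

## internal: sequence from a contig row / character
as_seq <- function(x) {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  if (!is.null(x$sequence)) return(toupper(x$sequence[1]))
  rf_stop("cannot interpret contig argument", "parameter_error")
}

#' Suffix-prefix overlap between two contigs
#'
#' Evaluates alignments of a suffix of `source` against a prefix of `target`
#' by edit-distance dynamic programming over all candidate overlap lengths.
#' An overlap qualifies when its length (bases of target prefix consumed) is
#' at least `min_overlap_bp` and its mismatch fraction (substitutions +
#' indels over the overlap length) is strictly below `max_mismatch_rate`.
#' Among qualifying overlaps the one with the lowest mismatch fraction wins,
#' longest first among ties — so an exact junction is never stretched by a
#' spurious indel that would still sit under the rate threshold. Ties between
#' orientations prefer fewer mismatches, then the forward orientation.
#'
#' @param source,target Contig sequences (character) or single contig rows.
#' @param config A [pipeline_config()].
#' @param orientation `"both"` (default) also tries the reverse complement of
#'   `target`; `"forward"` does not.
#' @return `NULL` when no overlap qualifies, otherwise a list with `length`,
#'   `mismatches`, `orientation` (`"forward"` or `"rc"`).
#' @examples
#' cfg <- pipeline_config(read_length = 100)
#' compute_overlap(paste0(strrep("T", 30), strrep("ACGTG", 4)),
#'                 paste0(strrep("ACGTG", 4), strrep("A", 30)), cfg)
#' @export
compute_overlap <- function(source, target, config = pipeline_config(),
                            orientation = c("both", "forward")) {
  orientation <- match.arg(orientation)
  a <- as_seq(source); b <- as_seq(target)
  fwd <- overlap_dp_cpp(a, b, config$min_overlap_bp, config$max_mismatch_rate)
  best <- NULL
  if (fwd[1] > 0L)
    best <- list(length = fwd[1], mismatches = fwd[2], orientation = "forward")
  if (orientation == "both") {
    rcv <- overlap_dp_cpp(a, revcomp(b), config$min_overlap_bp,
                          config$max_mismatch_rate)
    if (rcv[1] > 0L) {
      cand <- list(length = rcv[1], mismatches = rcv[2], orientation = "rc")
      if (is.null(best) ||
          cand$length > best$length ||
          (cand$length == best$length && cand$mismatches < best$mismatches))
        best <- cand
    }
  }
  best
}

## internal: is b (or its reverse complement) contained in a at < max_rate?
is_contained <- function(a, b, max_rate) {
  lb <- nchar(b)
  if (lb > nchar(a)) return(FALSE)
  f <- overlap_dp_cpp(a, b, 1L, 1)[3]
  r <- overlap_dp_cpp(a, revcomp(b), 1L, 1)[3]
  min(f, r) / lb < max_rate
}

#' Map reads to contigs with the built-in seed-and-extend mapper
#'
#' Exact seeds of `config$seed_length` bases are located via a substring
#' index over the contigs; each candidate (contig, diagonal, strand) is
#' extended by local alignment and kept when the aligned read span is at
#' least the seed length and the edit fraction over the aligned span is at
#' most `config$max_map_error_rate`. All placements are reported
#' (multi-mapping allowed); divergent reads may map with soft-clipped ends.
#'
#' @param reads A [read_set()].
#' @param contigs Raw-contig data frame.
#' @param config A [pipeline_config()].
#' @return Data frame of placements: `pair` (read-pair index), `mate` (1/2),
#'   `contig` (contig id), `start`, `end` (1-based closed, forward contig
#'   coordinates), `strand`, `edits`.
#' @export
map_reads_to_contigs <- function(reads, contigs, config = pipeline_config()) {
  empty <- data.frame(pair = integer(0), mate = integer(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      edits = integer(0), stringsAsFactors = FALSE)
  if (nrow(contigs) == 0L)
    rf_stop("contigs must be non-empty", "parameter_error")
  n <- length(reads)
  if (n == 0L) return(empty)
  pl <- map_reads_cpp(c(reads$fwd, reads$rev), contigs$sequence,
                      config$seed_length, config$max_map_error_rate,
                      config$seed_length)
  if (nrow(pl) == 0L) return(empty)
  out <- data.frame(pair = ((pl$read - 1L) %% n) + 1L,
                    mate = ifelse(pl$read <= n, 1L, 2L),
                    contig = contigs$id[pl$contig],
                    start = pl$start, end = pl$end,
                    strand = pl$strand, edits = pl$edits,
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read-pair support for a tentative contig junction
#'
#' Counts read pairs with one mate placed on `v1` and the other on `v2` whose
#' implied fragment span in the tentative merged layout (`v1` followed by
#' `v2` with `overlap$length` bases shared) falls within the insert-size
#' window `mean +/- 3 sd` with consistent forward/reverse orientation.
#' `expected` reports whether such a straddling placement is geometrically
#' possible at all: a fragment length inside the insert window must fit the
#' merged contig and reach across the junction with one full mate on each
#' side. The edge admission rule keeps a junction when straddling pairs are
#' not expected, or when `support >= min_read_pair_support`.
#'
#' @param v1,v2 Contig rows (id + sequence/length) from the graph node table.
#' @param overlap Overlap record joining `v1` to `v2` (list with `length`).
#' @param placements Placement table from [map_reads_to_contigs()].
#' @param config A [pipeline_config()].
#' @return List with `support` (integer) and `expected` (logical).
#' @export
pair_support <- function(v1, v2, overlap, placements, config = pipeline_config()) {
  l1 <- if (!is.null(v1$length)) v1$length[1] else nchar(as_seq(v1))
  l2 <- if (!is.null(v2$length)) v2$length[1] else nchar(as_seq(v2))
  id1 <- v1$id[1]; id2 <- v2$id[1]
  ov <- overlap$length
  rl <- config$read_length
  merged_len <- l1 + l2 - ov
  lo <- config$insert_size_mean - 3 * config$insert_size_sd
  hi <- config$insert_size_mean + 3 * config$insert_size_sd
  lo_eff <- max(lo, 2 * rl - ov, rl)
  expected <- lo_eff <= min(hi, merged_len)

  p1 <- placements[placements$contig == id1, , drop = FALSE]
  p2 <- placements[placements$contig == id2, , drop = FALSE]
  support <- 0L
  if (nrow(p1) > 0L && nrow(p2) > 0L) {
    m <- merge(p1, p2, by = "pair")
    m <- m[m$mate.x != m$mate.y, , drop = FALSE]
    if (nrow(m) > 0L) {
      b_start <- l1 - ov + m$start.y
      b_end <- l1 - ov + m$end.y
      left_first <- m$start.x <= b_start
      span <- pmax(m$end.x, b_end) - pmin(m$start.x, b_start) + 1L
      orient_ok <- ifelse(left_first,
                          m$strand.x == "+" & m$strand.y == "-",
                          m$strand.y == "+" & m$strand.x == "-")
      ok <- orient_ok & span >= lo & span <= hi
      support <- length(unique(m$pair[ok]))
    }
  }
  list(support = as.integer(support), expected = expected)
}

## internal: assign one orientation per connected component of the candidate
## overlap graph (repeats occur on both strands). Edges carry a parity: 0 if
## the best overlap keeps both contigs forward, 1 if one must be flipped.
## BFS two-colours each component; parity-violating edges are dropped with a
## warning.
assign_orientations <- function(ids, pair_parity) {
  sign <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  conflicts <- logical(nrow(pair_parity))
  if (nrow(pair_parity) > 0L) {
    adj <- split(seq_len(nrow(pair_parity)), pair_parity$a)
    adj2 <- split(seq_len(nrow(pair_parity)), pair_parity$b)
    for (root in ids) {
      if (!is.na(sign[root])) next
      sign[root] <- 0L
      queue <- root
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        rows <- c(adj[[u]], adj2[[u]])
        for (r in rows) {
          v <- if (pair_parity$a[r] == u) pair_parity$b[r] else pair_parity$a[r]
          want <- bitwXor(sign[u], pair_parity$parity[r])
          if (is.na(sign[v])) {
            sign[v] <- want
            queue <- c(queue, v)
          } else if (sign[v] != want) {
            conflicts[r] <- TRUE
          }
        }
      }
    }
  }
  sign[is.na(sign)] <- 0L
  list(sign = sign, conflicts = conflicts)
}

#' Build the directed contig graph
#'
#' The full edge-construction stage: candidate pairs by shared `k0`-mers,
#' containment removal (a contig lying entirely within another at low
#' divergence is discarded), per-component orientation assignment, overlap
#' verification on the oriented sequences, read re-mapping, and read-pair
#' admission ([pair_support()]).
#'
#' @param contigs Raw-contig data frame (typically coverage-filtered).
#' @param reads A [read_set()] (may be empty; edges then survive only where
#'   straddling pairs are not expected).
#' @param config A [pipeline_config()].
#' @param placements Optional pre-computed placements on `contigs` *as
#'   oriented here*; when `NULL` (recommended) reads are mapped after
#'   orientation assignment.
#' @return Object of class `contig_graph`: list with `contigs` (id, oriented
#'   sequence, orientation, length), `edges` (source, target, length,
#'   mismatches, support, expected), and `config`.
#' @export
build_graph <- function(contigs, reads, config = pipeline_config(),
                        placements = NULL) {
  graph <- function(ctg, edges) {
    structure(list(contigs = ctg, edges = edges, config = config),
              class = "contig_graph")
  }
  empty_edges <- data.frame(source = character(0), target = character(0),
                            length = integer(0), mismatches = integer(0),
                            support = integer(0), expected = logical(0),
                            stringsAsFactors = FALSE)
  ctg <- contigs[, c("id", "sequence"), drop = FALSE]
  ctg$orientation <- "+"
  ctg$length <- nchar(ctg$sequence)
  if (nrow(ctg) < 2L) return(graph(ctg, empty_edges))

  cand <- candidate_pairs(ctg, config$prefilter_substring_len,
                          orientation = TRUE)
  if (nrow(cand) == 0L) return(graph(ctg, empty_edges))
  unord <- unique(data.frame(
    a = pmin(cand$source, cand$target),
    b = pmax(cand$source, cand$target), stringsAsFactors = FALSE))

  ## containment: discard the contained contig rather than creating an edge
  seq_of <- stats::setNames(ctg$sequence, ctg$id)
  len_of <- stats::setNames(ctg$length, ctg$id)
  dropped <- character(0)
  for (i in seq_len(nrow(unord))) {
    a <- unord$a[i]; b <- unord$b[i]
    if (a %in% dropped || b %in% dropped) next
    long <- if (len_of[a] >= len_of[b]) a else b
    short <- if (long == a) b else a
    if (is_contained(seq_of[long], seq_of[short], config$max_mismatch_rate))
      dropped <- c(dropped, short)
  }
  if (length(dropped)) {
    ctg <- ctg[!ctg$id %in% dropped, , drop = FALSE]
    unord <- unord[!(unord$a %in% dropped | unord$b %in% dropped), , drop = FALSE]
    if (nrow(ctg) < 2L || nrow(unord) == 0L) return(graph(ctg, empty_edges))
  }

  ## orientation parity per candidate pair, from the best qualifying overlap
  par_rows <- data.frame(a = character(0), b = character(0),
                         parity = integer(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(unord))) {
    a <- seq_of[unord$a[i]]; b <- seq_of[unord$b[i]]
    fwd <- pmax(overlap_dp_cpp(a, b, config$min_overlap_bp, config$max_mismatch_rate)[1],
                overlap_dp_cpp(b, a, config$min_overlap_bp, config$max_mismatch_rate)[1])
    bc <- revcomp(b)
    rcb <- pmax(overlap_dp_cpp(a, bc, config$min_overlap_bp, config$max_mismatch_rate)[1],
                overlap_dp_cpp(bc, a, config$min_overlap_bp, config$max_mismatch_rate)[1])
    if (fwd == 0L && rcb == 0L) next
    par_rows <- rbind(par_rows, data.frame(
      a = unord$a[i], b = unord$b[i],
      parity = as.integer(rcb > fwd), stringsAsFactors = FALSE))
  }
  if (nrow(par_rows) == 0L) return(graph(ctg, empty_edges))
  ori <- assign_orientations(ctg$id, par_rows)
  if (any(ori$conflicts)) {
    warning(sum(ori$conflicts),
            " overlap(s) dropped due to inconsistent strand assignment")
    par_rows <- par_rows[!ori$conflicts, , drop = FALSE]
  }
  flip <- names(ori$sign)[ori$sign == 1L]
  ctg$orientation[ctg$id %in% flip] <- "-"
  ctg$sequence[ctg$id %in% flip] <- revcomp(ctg$sequence[ctg$id %in% flip])
  seq_of <- stats::setNames(ctg$sequence, ctg$id)

  ## directed edges on the oriented sequences (forward orientation only)
  edges <- empty_edges
  for (i in seq_len(nrow(par_rows))) {
    for (dir in 1:2) {
      s <- if (dir == 1L) par_rows$a[i] else par_rows$b[i]
      t <- if (dir == 1L) par_rows$b[i] else par_rows$a[i]
      ov <- overlap_dp_cpp(seq_of[s], seq_of[t],
                           config$min_overlap_bp, config$max_mismatch_rate)
      if (ov[1] > 0L && ov[1] < len_of[t]) # full-length hit is containment
        edges <- rbind(edges, data.frame(
          source = s, target = t, length = ov[1], mismatches = ov[2],
          support = NA_integer_, expected = NA, stringsAsFactors = FALSE))
    }
  }
  if (nrow(edges) == 0L) return(graph(ctg, edges))

  ## read-pair admission
  if (is.null(placements))
    placements <- map_reads_to_contigs(reads, ctg, config)
  keep_edge <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    v1 <- ctg[ctg$id == edges$source[i], , drop = FALSE]
    v2 <- ctg[ctg$id == edges$target[i], , drop = FALSE]
    ps <- pair_support(v1, v2, list(length = edges$length[i]),
                       placements, config)
    edges$support[i] <- ps$support
    edges$expected[i] <- ps$expected
    keep_edge[i] <- !ps$expected || ps$support >= config$min_read_pair_support
  }
  edges <- edges[keep_edge, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "placements") <- placements
  graph(ctg, edges)
}

#' @export
print.contig_graph <- function(x, ...) {
  cat("contig_graph:", nrow(x$contigs), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a contig graph edge list as TSV (and optionally GraphViz DOT)
#'
#' @param graph A `contig_graph`.
#' @param path Output TSV path (`source target overlap_len mismatches support`).
#' @param dot_path Optional DOT output path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path, dot_path = NULL) {
  e <- graph$edges
  utils::write.table(
    data.frame(source = e$source, target = e$target, overlap_len = e$length,
               mismatches = e$mismatches, support = e$support),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dot_path)) {
    lines <- c("digraph contigs {",
               sprintf("  \"%s\" -> \"%s\" [label=\"%d\"];",
                       e$source, e$target, e$length),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(path)
}
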