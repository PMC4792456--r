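## Raw-contig assembly: frequent k-mers -> unitigs of the de Bruijn graph.
## The inputs are exact k-mers (not error-bearing reads), so a deterministic
## unitig-only assembler is sufficient: nodes are (k-1)-mers, each k-mer is an
## edge, and every maximal non-branching path is spelled out as one contig.

empty_contigs <- function() {
  data.frame(id = character(0), sequence = character(0),
             source_k = integer(0), source_bin_target = numeric(0),
             length = integer(0), stringsAsFactors = FALSE)
}

#' Assemble one frequency bin of k-mers into unitigs
#'
#' Builds the de Bruijn graph whose nodes are (k-1)-mers and whose edges are
#' the member k-mers (each member and its reverse complement when
#' `canonical = TRUE`), then spells every maximal non-branching path. Node
#' traversal order is lexicographic, so the output is reproducible. With
#' canonical input each unitig and its mirror are spelled once and collapsed
#' to the lexicographically smaller orientation.
#'
#' @param members Character vector of k-mers (all of length `k`).
#' @param k K-mer length.
#' @param canonical Insert both orientations of every member.
#' @param bin_target Target frequency of the source bin (annotation only).
#' @return Data frame of raw contigs with columns `id`, `sequence`,
#'   `source_k`, `source_bin_target`, `length`.
#' @examples
#' assemble_bin(c("ACG", "CGT", "GTT"), 3, canonical = FALSE)$sequence
#' @export
assemble_bin <- function(members, k, canonical = TRUE, bin_target = NA_real_) {
  members <- unique(toupper(members))
  if (length(members) == 0L) return(empty_contigs())
  if (any(nchar(members) != k))
    rf_stop("all members must have length k", "parameter_error")
  edges <- if (canonical) sort(unique(c(members, revcomp(members)))) else sort(members)
  ## an edge and its reverse complement represent the same member; consuming
  ## one consumes the other, so every member is spelled exactly once
  rc_idx <- if (canonical) match(revcomp(edges), edges) else seq_along(edges)
  pref <- substr(edges, 1L, k - 1L)
  suf  <- substr(edges, 2L, k)
  nodes <- sort(unique(c(pref, suf)))
  pid <- match(pref, nodes)
  sid <- match(suf, nodes)
  n_nodes <- length(nodes)
  out_deg <- tabulate(pid, n_nodes)
  in_deg  <- tabulate(sid, n_nodes)
  out_edge <- integer(n_nodes) # the unique out-edge of degree-1 nodes
  adj <- split(seq_along(edges), pid)
  single <- lengths(adj) == 1L
  out_edge[as.integer(names(adj))[single]] <- unlist(adj[single], use.names = FALSE)
  through <- in_deg == 1L & out_deg == 1L

  used <- logical(length(edges))
  paths <- list()
  walk <- function(e0) {
    buf <- integer(64); n <- 0L; e <- e0
    repeat {
      used[e] <<- TRUE
      used[rc_idx[e]] <<- TRUE
      n <- n + 1L
      if (n > length(buf)) buf <- c(buf, integer(length(buf)))
      buf[n] <- e
      v <- sid[e]
      if (!through[v]) break
      e2 <- out_edge[v]
      if (e2 == 0L || used[e2]) break
      e <- e2
    }
    buf[seq_len(n)]
  }
  for (e in seq_along(edges))
    if (!used[e] && !through[pid[e]]) paths[[length(paths) + 1L]] <- walk(e)
  for (e in seq_along(edges))          # perfect cycles of through nodes
    if (!used[e]) paths[[length(paths) + 1L]] <- walk(e)

  spelled <- vapply(paths, function(p) {
    if (length(p) == 1L) edges[p] else
      paste0(edges[p[1L]], paste(substr(edges[p[-1L]], k, k), collapse = ""))
  }, character(1))
  if (canonical) {
    # orientation of a unitig is arbitrary: normalise for reproducibility
    rc <- revcomp(spelled)
    spelled <- ifelse(spelled <= rc, spelled, rc)
  }
  ord <- order(-nchar(spelled), spelled)
  spelled <- spelled[ord]
  data.frame(id = sprintf("k%d_b%s_%d", k,
                          ifelse(is.na(bin_target), "NA",
                                 formatC(bin_target, format = "fg")),
                          seq_along(spelled)),
             sequence = spelled, source_k = k,
             source_bin_target = bin_target, length = nchar(spelled),
             stringsAsFactors = FALSE)
}

#' Assemble raw contigs across all k-mer lengths and frequency bins
#'
#' For each catalog: select frequent k-mers, partition them into overlapping
#' frequency bins, and assemble each bin (highest target frequency first).
#' Results across bins and k values are concatenated, renumbered, and
#' deduplicated ([deduplicate_contigs()]).
#'
#' @param catalogs List of `kmer_catalog` objects (one per k-mer length).
#' @param config A [pipeline_config()].
#' @return Deduplicated raw-contig data frame.
#' @export
assemble_all <- function(catalogs, config = pipeline_config()) {
  if (length(catalogs) == 0L)
    rf_stop("at least one k-mer catalog is required", "parameter_error")
  pieces <- list()
  for (cat in catalogs) {
    frequent <- select_frequent(cat, config$freq_cutoff_factor, config$freq_baseline)
    if (length(frequent) == 0L) next
    bins <- make_frequency_bins(frequent, config)
    for (b in bins) {
      if (length(b$members) == 0L) next
      pieces[[length(pieces) + 1L]] <-
        assemble_bin(names(b$members), cat$k, canonical = cat$canonical,
                     bin_target = b$target)
    }
  }
  if (length(pieces) == 0L) return(empty_contigs())
  all <- do.call(rbind, pieces)
  all$id <- sprintf("ctg%05d", seq_len(nrow(all)))
  deduplicate_contigs(all)
}

#' Remove duplicate and contained raw contigs
#'
#' Drops any contig whose sequence — or its reverse complement — is a
#' substring of another retained contig (overlapping frequency bins and
#' multiple k values produce many exact duplicates and containments). Among
#' exact duplicates the contig with the smaller id is kept. Output order is
#' deterministic: length descending, then sequence.
#'
#' @param contigs Raw-contig data frame.
#' @return Filtered raw-contig data frame.
#' @export
deduplicate_contigs <- function(contigs) {
  if (nrow(contigs) <= 1L) return(contigs)
  ord <- order(-contigs$length, contigs$id)
  contigs <- contigs[ord, , drop = FALSE]
  kept_seq <- character(0)
  keep_idx <- integer(0)
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$sequence[i]
    r <- revcomp(s)
    contained <- length(kept_seq) > 0L &&
      (any(grepl(s, kept_seq, fixed = TRUE)) ||
       any(grepl(r, kept_seq, fixed = TRUE)))
    if (!contained) {
      keep_idx <- c(keep_idx, i)
      kept_seq <- c(kept_seq, s)
    }
  }
  out <- contigs[keep_idx, , drop = FALSE]
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
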