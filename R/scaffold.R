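## Merging raw contigs into long repeats: SCC condensation, linear ordering,
## greedy maximal-path traversal, and junction-aware sequence concatenation.

## internal: normalise graph input to (ids, edges df)
graph_parts <- function(graph) {
  if (inherits(graph, "contig_graph"))
    list(ids = graph$contigs$id, edges = graph$edges)
  else
    list(ids = graph$nodes, edges = graph$edges)
}

#' Strongly connected components of the contig graph
#'
#' Exact SCCs of the directed contig graph. Components are ordered (and
#' numbered) by their smallest member id, so the partition is deterministic.
#'
#' @param graph A `contig_graph`, or a list with `nodes` (character vector)
#'   and `edges` (data frame with `source`, `target`).
#' @return Object of class `scc_partition`: list with `components` (list of
#'   sorted id vectors) and `component_of` (named integer vector).
#' @export
find_sccs <- function(graph) {
  gp <- graph_parts(graph)
  if (length(gp$ids) == 0L)
    return(structure(list(components = list(),
                          component_of = stats::setNames(integer(0), character(0))),
                     class = "scc_partition"))
  ig <- igraph::graph_from_data_frame(
    gp$edges[, c("source", "target"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = gp$ids))
  memb <- igraph::components(ig, mode = "strong")$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1L))]
  names(comps) <- NULL
  component_of <- integer(length(gp$ids))
  names(component_of) <- gp$ids
  for (i in seq_along(comps)) component_of[comps[[i]]] <- i
  structure(list(components = comps, component_of = component_of),
            class = "scc_partition")
}

#' Condense a contig graph by its strongly connected components
#'
#' Contracts each SCC to a single node. The result is acyclic by
#' construction; a cycle in the condensation signals an internal error and
#' aborts.
#'
#' @param graph A `contig_graph` or `nodes`/`edges` list.
#' @param sccs The [find_sccs()] partition of `graph`.
#' @return List with `n` (number of components) and `edges` (data frame of
#'   component-index pairs `from`, `to`, no duplicates, no self-loops).
#' @export
condense <- function(graph, sccs) {
  gp <- graph_parts(graph)
  e <- gp$edges
  if (nrow(e) == 0L)
    return(list(n = length(sccs$components),
                edges = data.frame(from = integer(0), to = integer(0))))
  ce <- data.frame(from = sccs$component_of[e$source],
                   to = sccs$component_of[e$target])
  ce <- unique(ce[ce$from != ce$to, , drop = FALSE])
  rownames(ce) <- NULL
  if (nrow(ce) > 0L) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ce$from), to = as.character(ce$to)),
      directed = TRUE,
      vertices = data.frame(name = as.character(seq_along(sccs$components))))
    if (!igraph::is_dag(ig))
      rf_stop("condensation contains a cycle: SCC partition is inconsistent",
              "internal_error")
  }
  list(n = length(sccs$components), edges = ce)
}

#' Linear (near-topological) order of a node set
#'
#' Kahn's algorithm with deterministic tie-breaking: among zero-in-degree
#' candidates the smallest id is taken first. When every remaining node has
#' incoming edges (a cycle), the incoming edges of the smallest-id remaining
#' node are removed and the sort continues — so cyclic subgraphs still yield
#' a usable linear order, and acyclic ones yield a true topological order.
#'
#' @param nodes Character vector of node ids.
#' @param edges Data frame with `source`, `target` (restricted to `nodes`).
#' @return Character vector: the nodes in linear order.
#' @export
linear_order <- function(nodes, edges) {
  nodes <- sort(nodes)
  if (length(nodes) <= 1L) return(nodes)
  e <- edges[edges$source %in% nodes & edges$target %in% nodes, , drop = FALSE]
  e <- unique(e[e$source != e$target, c("source", "target"), drop = FALSE])
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tt <- table(e$target)
  indeg[names(tt)] <- as.integer(tt)
  out <- character(0)
  edge_alive <- rep(TRUE, nrow(e))
  while (any(alive)) {
    zero <- names(alive)[alive & indeg[names(alive)] == 0L]
    if (length(zero) == 0L) {
      ## blocked by a cycle: cut the incoming edges of the smallest remaining id
      u <- min(names(alive)[alive])
      cut <- edge_alive & e$target == u
      indeg[u] <- 0L
      edge_alive[cut] <- FALSE
      next
    }
    u <- min(zero)
    out <- c(out, u)
    alive[u] <- FALSE
    rows <- which(edge_alive & e$source == u)
    for (r in rows) {
      edge_alive[r] <- FALSE
      v <- e$target[r]
      if (alive[v]) indeg[v] <- indeg[v] - 1L
    }
  }
  out
}

#' Enumerate maximal paths through the contig graph
#'
#' Greedy heuristic path search: a global linear order is built from the
#' topological order of the SCC condensation with each component internally
#' ordered by [linear_order()]. Walks start from every in-degree-zero node;
#' any node still uncovered afterwards starts an additional walk (so every
#' node appears in at least one path). From the current node the walk follows
#' the out-edge that agrees with the linear order and leads to the nearest
#' subsequent node (falling back to the nearest preceding node when no
#' forward edge exists); ties prefer the smallest id. No node is revisited
#' within a path. Emitted paths that are contiguous subsequences of another
#' emitted path are removed.
#'
#' @param graph A `contig_graph` or `nodes`/`edges` list.
#' @param sccs Optional pre-computed [find_sccs()] partition.
#' @return List of character vectors (node-id paths), deterministic order.
#' @export
enumerate_paths <- function(graph, sccs = NULL) {
  gp <- graph_parts(graph)
  ids <- gp$ids
  if (length(ids) == 0L) return(list())
  e <- unique(gp$edges[, c("source", "target"), drop = FALSE])
  e <- e[e$source != e$target, , drop = FALSE]
  if (is.null(sccs)) sccs <- find_sccs(graph)
  cond <- condense(graph, sccs)
  comp_order <- linear_order(as.character(seq_len(cond$n)),
                             data.frame(source = as.character(cond$edges$from),
                                        target = as.character(cond$edges$to)))
  global <- character(0)
  for (ci in as.integer(comp_order)) {
    comp_nodes <- sccs$components[[ci]]
    global <- c(global, linear_order(comp_nodes, e))
  }
  rank <- stats::setNames(seq_along(global), global)

  adj <- split(e$target, e$source)
  indeg <- stats::setNames(integer(length(ids)), ids)
  tt <- table(e$target)
  indeg[names(tt)] <- as.integer(tt)

  walk_from <- function(start) {
    path <- start
    cur <- start
    repeat {
      nxt <- setdiff(adj[[cur]], path)
      if (length(nxt) == 0L) break
      fwd <- nxt[rank[nxt] > rank[cur]]
      cand <- if (length(fwd)) fwd[order(rank[fwd], fwd)] else
        nxt[order(-rank[nxt], nxt)]
      cur <- cand[1]
      path <- c(path, cur)
    }
    path
  }

  starts <- sort(names(indeg)[indeg == 0L])
  paths <- lapply(starts, walk_from)
  covered <- unique(unlist(paths))
  for (u in global) {
    if (!u %in% covered) {
      p <- walk_from(u)
      paths[[length(paths) + 1L]] <- p
      covered <- unique(c(covered, p))
    }
  }
  if (length(paths) == 0L) return(list())

  ## remove paths that are contiguous subsequences of another emitted path
  keys <- vapply(paths, function(p)
    paste0("\x01", paste(p, collapse = "\x01"), "\x01"), character(1))
  ord <- order(-lengths(paths), keys)
  paths <- paths[ord]; keys <- keys[ord]
  keep <- logical(length(paths))
  kept_keys <- character(0)
  for (i in seq_along(paths)) {
    if (!any(grepl(keys[i], kept_keys, fixed = TRUE))) {
      keep[i] <- TRUE
      kept_keys <- c(kept_keys, keys[i])
    }
  }
  paths[keep]
}

#' Merge an ordered contig path into one repeat sequence
#'
#' Concatenates oriented contig sequences along a path: the first contig is
#' taken whole, and each successor contributes its suffix beyond the aligned
#' prefix, so within a mismatching junction column the predecessor's base is
#' kept. For indel-free junctions the merged length is exactly the sum of
#' contig lengths minus the sum of junction overlap lengths.
#'
#' @param sequences Character vector of oriented contig sequences in path
#'   order.
#' @param overlap_lengths Integer vector (one per junction, length
#'   `length(sequences) - 1`): bases of successor prefix already aligned.
#' @return The merged sequence (character scalar).
#' @examples
#' merge_path(c("AAAACCCC", "CCCCGGGG"), 4)
#' @export
merge_path <- function(sequences, overlap_lengths = integer(0)) {
  if (length(sequences) == 0L)
    rf_stop("empty path", "degenerate_input_error")
  if (length(overlap_lengths) != length(sequences) - 1L)
    rf_stop("need one junction overlap per consecutive contig pair",
            "internal_error")
  out <- sequences[1]
  for (i in seq_along(overlap_lengths)) {
    s <- sequences[i + 1L]
    out <- paste0(out, substr(s, overlap_lengths[i] + 1L, nchar(s)))
  }
  out
}

#' Merge all maximal paths of a contig graph into assembled repeats
#'
#' Runs [enumerate_paths()] and [merge_path()] over a built contig graph and
#' returns the assembled repeats, largest first.
#'
#' @param graph A `contig_graph` from [build_graph()].
#' @param paths Optional pre-computed path list.
#' @return Object of class `assembled_repeats`: data frame with columns `id`,
#'   `sequence`, `length`, `n_contigs`, `path` (list column of contig ids),
#'   `junctions` (list column of overlap lengths), `mean_coverage` (`NA`
#'   until [annotate_repeats()]).
#' @export
merge_paths <- function(graph, paths = NULL) {
  if (is.null(paths)) paths <- enumerate_paths(graph)
  seq_of <- stats::setNames(graph$contigs$sequence, graph$contigs$id)
  ekey <- paste(graph$edges$source, graph$edges$target, sep = "\x01")
  elen <- stats::setNames(graph$edges$length, ekey)
  seqs <- character(length(paths))
  juncs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (length(p) > 1L) {
      k <- paste(p[-length(p)], p[-1L], sep = "\x01")
      if (anyNA(elen[k]))
        rf_stop("missing junction overlap record for a path edge",
                "internal_error")
      juncs[[i]] <- unname(elen[k])
    } else juncs[[i]] <- integer(0)
    seqs[i] <- merge_path(unname(seq_of[p]), juncs[[i]])
  }
  out <- data.frame(id = character(length(paths)), sequence = seqs,
                    length = nchar(seqs),
                    n_contigs = lengths(paths),
                    mean_coverage = NA_real_, stringsAsFactors = FALSE)
  out$path <- paths
  out$junctions <- juncs
  ord <- order(-out$length, out$sequence)
  out <- out[ord, , drop = FALSE]
  out$id <- sprintf("rep_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("assembled_repeats", "data.frame")
  out
}

#' Write the per-path report TSV
#'
#' One line per assembled repeat:
#' `repeat_id<TAB>num_contigs<TAB>contig_ids(comma)<TAB>merged_length`.
#'
#' @param repeats An `assembled_repeats` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paths_tsv <- function(repeats, path) {
  utils::write.table(
    data.frame(repeat_id = repeats$id,
               num_contigs = repeats$n_contigs,
               contig_ids = vapply(repeats$path, paste, character(1),
                                   collapse = ","),
               merged_length = repeats$length),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
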