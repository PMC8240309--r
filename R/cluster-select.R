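# Single-linkage clustering of candidate ORFs and greedy selection of
# representatives covering all long cluster edges.

#' Clustering parameters
#'
#' @param PI Percent-identity threshold for linking two sequences, default 90.
#' @param long_edge_min Edges longer than this many nucleotides are long
#'   cluster edges, default 1000.
#' @param literal_scan_order Scan members in the literal lexicographically
#'   non-decreasing triplet order (least reliable first) instead of the
#'   default descending-reliability order. Default `FALSE`.
#' @return A parameter list.
#' @export
cluster_params <- function(PI = 90, long_edge_min = 1000L,
                           literal_scan_order = FALSE) {
  stopifnot(PI > 0, PI <= 100, long_edge_min > 0)
  list(PI = PI, long_edge_min = as.integer(long_edge_min),
       literal_scan_order = isTRUE(literal_scan_order))
}

pair_linked <- function(a, b, PI) {
  if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) return(TRUE)
  hit <- exact_or_aligned_hit(if (nchar(a) <= nchar(b)) a else b,
                              if (nchar(a) <= nchar(b)) b else a)
  !is.null(hit) && hit$identity > PI
}

#' Single-linkage clustering of candidate ORFs
#'
#' Two ORFs are linked when one amino-acid sequence is a substring of the
#' other or their percent identity exceeds `PI`; clusters are the connected
#' components of this relation. Output is invariant to input order: members
#' are canonically ordered by `orf_id` and clusters by their smallest member.
#'
#' @param orfs Candidate tibble with `orf_id`, `aa_seq`, `path`.
#' @param params A [cluster_params()] list.
#' @return The tibble with a `cluster` integer column added.
#' @export
cluster_orfs <- function(orfs, params = cluster_params()) {
  n <- nrow(orfs)
  if (n == 0) { orfs$cluster <- integer(0); return(orfs) }
  ord <- order(orfs$orf_id)
  orfs <- orfs[ord, ]
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (pair_linked(orfs$aa_seq[i], orfs$aa_seq[j], params$PI))
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # renumber clusters by smallest member index
  first <- tapply(seq_len(n), comp, min)
  relabel <- rank(first, ties.method = "first")
  orfs$cluster <- as.integer(relabel[as.character(comp)])
  orfs[order(orfs$cluster, orfs$orf_id), ]
}

#' The reliability triplet of a candidate ORF
#'
#' Returns (start-distance likelihood, read coverage, path length); an ORF is
#' more reliable than another when its triplet is lexicographically larger.
#'
#' @param orf One-row candidate tibble (scored; see [score_candidates()]).
#' @return Numeric vector of length 3.
#' @export
rank_triplet <- function(orf) {
  c(likelihood = orf$likelihood[[1]], coverage = orf$coverage[[1]],
    length = as.numeric(orf$nt_len[[1]]))
}

# descending reliability; ties broken by orf_id for determinism
reliability_order <- function(orfs, decreasing = TRUE) {
  if (decreasing)
    order(-orfs$likelihood, -orfs$coverage, -orfs$nt_len, orfs$orf_id)
  else
    order(orfs$likelihood, orfs$coverage, orfs$nt_len, orfs$orf_id)
}

long_edges_of <- function(graph, paths, long_edge_min) {
  ids <- unique(unlist(lapply(paths, function(p) step_id(p$steps))))
  ids[vapply(ids, function(id) edge_len(graph, id) > long_edge_min, TRUE)]
}

#' Select representative ORFs for one cluster
#'
#' Members are scanned from most to least reliable (lexicographic triplet;
#' see [cluster_params()] for the literal ascending variant) and a member is
#' kept when its path contains a long cluster edge (> `long_edge_min` nt)
#' not present in previously kept members. The kept set therefore covers
#' every long cluster edge. A cluster without long edges contributes its
#' single most reliable member.
#'
#' @param cluster_orfs Candidate tibble of one cluster (scored).
#' @param graph An `asm_graph`.
#' @param params A [cluster_params()] list.
#' @return The representative rows, in selection order.
#' @export
select_representatives <- function(cluster_orfs, graph, params = cluster_params()) {
  stopifnot(nrow(cluster_orfs) > 0)
  ord <- reliability_order(cluster_orfs, decreasing = !params$literal_scan_order)
  members <- cluster_orfs[ord, ]
  long_edges <- long_edges_of(graph, members$path, params$long_edge_min)
  if (length(long_edges) == 0) {
    top <- cluster_orfs[reliability_order(cluster_orfs, decreasing = TRUE)[1], ]
    return(top)
  }
  covered <- character(0)
  keep <- logical(nrow(members))
  for (i in seq_len(nrow(members))) {
    ids <- intersect(step_id(members$path[[i]]$steps), long_edges)
    if (length(setdiff(ids, covered)) > 0) {
      keep[i] <- TRUE
      covered <- union(covered, ids)
    }
  }
  members[keep, ]
}

#' Cluster candidates and pick representatives
#'
#' Convenience wrapper: clusters the scored candidates, selects per-cluster
#' representatives, and returns both.
#'
#' @param orfs Scored candidate tibble.
#' @param graph An `asm_graph`.
#' @param params A [cluster_params()] list.
#' @return A list with `clusters` (the tibble with a `cluster` column and a
#'   `representative` flag) and `representatives` (the selected rows).
#' @export
cluster_and_select <- function(orfs, graph, params = cluster_params()) {
  cl <- cluster_orfs(orfs, params)
  if (nrow(cl) == 0) {
    cl$representative <- logical(0)
    return(list(clusters = cl, representatives = cl))
  }
  reps <- dplyr::bind_rows(lapply(split(cl, cl$cluster), function(sub) {
    r <- select_representatives(sub, graph, params)
    r
  }))
  cl$representative <- cl$orf_id %in% reps$orf_id
  list(clusters = cl, representatives = reps)
}
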