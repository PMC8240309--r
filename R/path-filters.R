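# Ranking and filtering of candidate ORFs: empirical start-distance
# likelihood, unique-edge identification, path compatibility, the
# contig-contradiction filter, and similarity classification against a
# database of known proteins.

#' Train the start-distance likelihood model
#'
#' Stores, per profile model (or query protein), the empirical multiset of
#' distances from the gene start to the start of a full model alignment. The
#' likelihood of a distance `d` is the fraction of stored distances within
#' `d +/- binSize`.
#'
#' @param model_hits Data frame with columns `model_id` and `distance`
#'   (nucleotides, >= 0); a `gene_id` column is allowed and ignored.
#' @param binSize Half-width of the likelihood window, default 150 nt.
#' @return An object of class `position_model`.
#' @export
train_position_model <- function(model_hits, binSize = 150L) {
  stopifnot(all(c("model_id", "distance") %in% names(model_hits)))
  if (any(model_hits$distance < 0)) stop("distances must be >= 0")
  structure(list(
    distances = split(as.numeric(model_hits$distance), model_hits$model_id),
    binSize = as.integer(binSize)
  ), class = "position_model")
}

#' @export
print.position_model <- function(x, ...) {
  cat("<position_model> ", length(x$distances), " models, binSize ",
      x$binSize, "\n", sep = "")
  invisible(x)
}

#' Likelihood of a start-to-anchor distance
#'
#' Fraction of the trained distances for `model_id` lying in
#' `[d - binSize, d + binSize]`. A model absent from the training data (or a
#' `NULL` model) yields 1: no evidence imposes no penalty.
#'
#' @param model A `position_model` (or `NULL`).
#' @param model_id Model identifier.
#' @param d Distance(s) in nucleotides, >= 0.
#' @return Numeric vector of likelihoods in `[0, 1]`.
#' @export
distance_likelihood <- function(model, model_id, d) {
  stopifnot(all(d >= 0))
  if (is.null(model)) return(rep(1, length(d)))
  xs <- model$distances[[model_id]]
  if (is.null(xs) || length(xs) == 0) return(rep(1, length(d)))
  vapply(d, function(di) mean(xs >= di - model$binSize & xs <= di + model$binSize), 0)
}

#' Unique-edge parameters
#' @param minLength Minimum edge length in nucleotides (exclusive), default 300.
#' @param degree_convention `"printed"` (default): an edge is unique when its
#'   start node has outdegree > 1 and its end node has indegree > 1.
#'   `"unitig"`: the inverse convention (outdegree of the start node and
#'   indegree of the end node both equal 1).
#' @return A parameter list.
#' @export
unique_edge_params <- function(minLength = 300L,
                               degree_convention = c("printed", "unitig")) {
  stopifnot(minLength > 0)
  list(minLength = as.integer(minLength),
       degree_convention = match.arg(degree_convention))
}

# Degrees of the implicit junction nodes flanking an edge, derived from the
# bidirected adjacency (a node is shared by an edge and its siblings).
edge_node_degrees <- function(graph, edge_id) {
  e <- paste0(edge_id, "+")
  preds <- graph_pred(graph, e)
  succs <- graph_succ(graph, e)
  out_start <- if (length(preds) == 0) 1L else
    max(vapply(preds, function(p) length(graph_succ(graph, p)), 0L))
  in_end <- if (length(succs) == 0) 1L else
    max(vapply(succs, function(s) length(graph_pred(graph, s)), 0L))
  list(out_start = out_start, in_end = in_end)
}

#' Is an edge unique?
#'
#' An edge is classified unique when its length exceeds `minLength`, its
#' start node has outdegree larger than 1, and its end node has indegree
#' larger than 1 (the printed convention; see [unique_edge_params()] for the
#' alternative). Unique edges are presumed traversed once by the genome path
#' and anchor the contig-contradiction filter.
#'
#' @param graph An `asm_graph`.
#' @param edge_id Edge identifier (unoriented).
#' @param params A [unique_edge_params()] list.
#' @return Logical scalar.
#' @export
is_unique_edge <- function(graph, edge_id, params = unique_edge_params()) {
  if (!edge_id %in% names(graph$seqs)) stop("unknown edge: ", edge_id)
  if (edge_len(graph, edge_id) <= params$minLength) return(FALSE)
  deg <- edge_node_degrees(graph, edge_id)
  if (params$degree_convention == "printed") {
    deg$out_start > 1L && deg$in_end > 1L
  } else {
    deg$out_start == 1L && deg$in_end == 1L
  }
}

path_edge_ids <- function(path) unique(step_id(path$steps))

#' Are two graph paths compatible?
#'
#' Two paths are compatible when one is contained within the other or a
#' suffix of one coincides with a prefix of the other, at the level of
#' oriented edge steps. The comparison is orientation-aware: a path is also
#' compared against the reverse complement of the other.
#'
#' @param p1,p2 `graph_path` objects (or character step vectors).
#' @return Logical scalar.
#' @export
paths_compatible <- function(p1, p2) {
  s1 <- if (inherits(p1, "graph_path")) p1$steps else as.character(p1)
  s2 <- if (inherits(p2, "graph_path")) p2$steps else as.character(p2)
  for (cand in list(s2, rc_steps(s2))) {
    if (steps_contain(s1, cand) || steps_contain(cand, s1)) return(TRUE)
    if (steps_overlap(s1, cand)) return(TRUE)
  }
  FALSE
}

#' Remove candidate ORFs that contradict contigs
#'
#' An ORF is removed when some contig path shares at least one unique edge
#' with it and the two paths are not compatible: two correct paths through
#' the same unique edge must agree, so disagreement marks the ORF as an
#' artefact of the graph rather than a genomic sequence.
#'
#' @param orfs Candidate tibble (with a `path` list-column).
#' @param contigs Contig paths: a list of `graph_path`/step vectors or a
#'   tibble with a `path` column.
#' @param graph An `asm_graph`.
#' @param params A [unique_edge_params()] list.
#' @return The candidate tibble with contradicting rows removed and a
#'   `contradicts` attribute-free report in columns `contradicted` /
#'   `contradicting_contig` available via `attr(, "report")`.
#' @export
filter_contradicting <- function(orfs, contigs, graph,
                                 params = unique_edge_params()) {
  contigs <- contig_paths_as_list(contigs)
  if (nrow(orfs) == 0 || length(contigs) == 0) {
    attr(orfs, "report") <- tibble::tibble(orf_id = orfs$orf_id,
                                           contradicting_contig = NA_character_)
    return(orfs)
  }
  uniq_cache <- new.env(parent = emptyenv())
  is_uniq <- function(id) {
    v <- uniq_cache[[id]]
    if (is.null(v)) { v <- is_unique_edge(graph, id, params); uniq_cache[[id]] <- v }
    v
  }
  contig_steps <- lapply(contigs, function(p) if (inherits(p, "graph_path")) p$steps else as.character(p))
  contig_uedges <- lapply(contig_steps, function(s) {
    ids <- unique(step_id(s)); ids[vapply(ids, is_uniq, TRUE)]
  })
  offender <- rep(NA_character_, nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    osteps <- orfs$path[[i]]$steps
    oids <- unique(step_id(osteps))
    for (j in seq_along(contig_steps)) {
      shared <- intersect(oids, contig_uedges[[j]])
      if (length(shared) == 0) next
      if (!paths_compatible(osteps, contig_steps[[j]])) {
        offender[i] <- paste(contig_steps[[j]], collapse = ",")
        break
      }
    }
  }
  report <- tibble::tibble(orf_id = orfs$orf_id, contradicting_contig = offender)
  out <- orfs[is.na(offender), ]
  attr(out, "report") <- report
  out
}

#' Similarity thresholds for classification
#'
#' @param retain_identity Percent identity below which an ORF is removed by
#'   the pipeline's retain filter (screens out look-alike families such as
#'   thioredoxins), default 80.
#' @param reliable_identity Boundary between candidate and reliable, default 80.
#' @param novel_low Lower (exclusive) bound of the reliable-novel band,
#'   default 90.
#' @return A threshold list.
#' @export
similarity_thresholds <- function(retain_identity = 80, reliable_identity = 80,
                                  novel_low = 90) {
  stopifnot(retain_identity > 0, retain_identity <= reliable_identity,
            reliable_identity <= novel_low, novel_low < 100)
  list(retain_identity = retain_identity, reliable_identity = reliable_identity,
       novel_low = novel_low)
}

best_db_identity <- function(aa, db) {
  best <- list(id = NA_character_, identity = 0)
  for (nm in names(db)) {
    hit <- exact_or_aligned_hit(aa, db[[nm]])
    idn <- if (is.null(hit)) 0 else hit$identity
    # full-length identical sequences score 100; an exact substring hit of a
    # longer db entry is still 100% identity over the aligned region
    if (idn > best$identity) best <- list(id = nm, identity = idn)
  }
  best
}

#' Classify candidate ORFs against a database of known proteins
#'
#' Computes, per ORF, the best local-alignment percent identity (BLOSUM62,
#' identity over aligned columns) against the database and assigns a verdict:
#' below the reliable threshold -> `"candidate"`; at or above it ->
#' `"reliable"`; within `(novel_low, 100)` -> `"reliable-novel"`; exactly
#' 100 -> `"reliable-known"`.
#'
#' @param orfs Candidate tibble with `aa_seq`.
#' @param db Named character vector of amino-acid sequences (or AAStringSet).
#' @param thresholds A [similarity_thresholds()] list.
#' @return The tibble with added columns `best_hit`, `best_identity`,
#'   `verdict`.
#' @export
similarity_classify <- function(orfs, db, thresholds = similarity_thresholds()) {
  if (inherits(db, "AAStringSet"))
    db <- stats::setNames(as.character(db), names(db))
  if (length(db) == 0) stop("empty protein database")
  hits <- lapply(orfs$aa_seq, best_db_identity, db = db)
  idn <- vapply(hits, `[[`, 0, "identity")
  verdict <- dplyr::case_when(
    idn == 100 ~ "reliable-known",
    idn > thresholds$novel_low ~ "reliable-novel",
    idn >= thresholds$reliable_identity ~ "reliable",
    TRUE ~ "candidate"
  )
  orfs$best_hit <- vapply(hits, `[[`, "", "id")
  orfs$best_identity <- idn
  orfs$verdict <- verdict
  orfs
}

#' Score candidate ORFs with the ranking triplet
#'
#' Attaches the (start-distance likelihood, read coverage, path length)
#' triplet used to order cluster members by reliability. Likelihood comes
#' from [distance_likelihood()] applied to the ORF's start-to-anchor
#' distance; coverage is the length-weighted mean of per-edge coverage from
#' the graph (0 when the graph carries none); length is the spelled
#' nucleotide length.
#'
#' @param orfs Candidate tibble.
#' @param graph An `asm_graph`.
#' @param model Optional `position_model`.
#' @return The tibble with `likelihood` and `coverage` columns added.
#' @export
score_candidates <- function(orfs, graph, model = NULL) {
  orfs$likelihood <- vapply(seq_len(nrow(orfs)), function(i) {
    distance_likelihood(model, orfs$query_id[i], orfs$start_distance[i])
  }, 0)
  orfs$coverage <- vapply(orfs$path, function(p) path_coverage(graph, p), 0)
  orfs
}

path_coverage <- function(graph, path) {
  if (is.null(graph$coverage)) return(0)
  ids <- step_id(path$steps)
  w <- nchar(vapply(path$steps, function(s) oseq(graph, s), "")) -
    c(0, rep(graph$overlap, length(ids) - 1L))
  covs <- graph$coverage[ids]
  covs[is.na(covs)] <- 0
  sum(covs * w) / sum(w)
}
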