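# Anchor acquisition: brute-force protein-to-graph alignment at desk scale,
# ingestion of externally computed alignments, and the redundant-subpath
# filter. An anchor-path is a partial gene hit in the graph, the seed that is
# later extended into a complete ORF.

#' Anchor retention thresholds
#'
#' Protein hits must span at least `min_protein_fraction` of the query;
#' profile-model hits must span at least `min_model_fraction` of the model and
#' (for ingested hits) have e-value at most `max_evalue`. `min_identity` is
#' the percent-identity floor used by the built-in aligner.
#'
#' @param min_protein_fraction Fraction of the protein length, default 0.8.
#' @param min_model_fraction Fraction of the model length, default 0.9.
#' @param max_evalue E-value cutoff for ingested model hits, default 1e-9.
#' @param min_identity Percent identity over the aligned span, default 80.
#' @param min_anchor_nt Anchors spelling fewer nucleotides are dropped,
#'   default 60.
#' @return A list of thresholds.
#' @export
anchor_thresholds <- function(min_protein_fraction = 0.8,
                              min_model_fraction = 0.9,
                              max_evalue = 1e-9,
                              min_identity = 80,
                              min_anchor_nt = 60L) {
  stopifnot(min_protein_fraction > 0, min_protein_fraction <= 1,
            min_model_fraction > 0, min_model_fraction <= 1,
            max_evalue > 0, min_identity > 0)
  list(min_protein_fraction = min_protein_fraction,
       min_model_fraction = min_model_fraction,
       max_evalue = max_evalue,
       min_identity = min_identity,
       min_anchor_nt = as.integer(min_anchor_nt))
}

# Normalise an anchor path to codon-aligned coordinates: drop the partial
# leading codon indicated by frame_tag, then any partial trailing codon.
codon_align_path <- function(graph, path, frame_tag = 0L) {
  lead <- (3L - frame_tag %% 3L) %% 3L
  len <- path_nt_length(graph, path)
  core <- len - lead
  core <- core - core %% 3L
  if (core < 3L) stop("anchor shorter than one codon after frame alignment")
  subpath_at(graph, path, lead, lead + core)
}

anchor_tibble <- function(rows) {
  tb <- tibble::tibble(
    anchor_id = vapply(rows, `[[`, "", "anchor_id"),
    query_id = vapply(rows, `[[`, "", "query_id"),
    kind = vapply(rows, `[[`, "", "kind"),
    query_len = vapply(rows, `[[`, 0L, "query_len"),
    query_start = vapply(rows, `[[`, 0L, "query_start"),
    query_end = vapply(rows, `[[`, 0L, "query_end"),
    fraction = vapply(rows, `[[`, 0, "fraction"),
    identity = vapply(rows, `[[`, 0, "identity"),
    frame_tag = vapply(rows, `[[`, 0L, "frame_tag"),
    nt_len = vapply(rows, `[[`, 0L, "nt_len"),
    path = lapply(rows, `[[`, "path")
  )
  tb[order(tb$query_id, vapply(tb$path, function(p) paste(p$steps, collapse = ","), ""),
           vapply(tb$path, function(p) p$start_offset, 0L)), ]
}

#' Build one anchor record
#'
#' Low-level constructor used by the aligners and the TSV loader; the path is
#' normalised to codon-aligned coordinates (its `frame_tag` becomes 0).
#'
#' @param graph An `asm_graph`.
#' @param path A `graph_path` covering the aligned region.
#' @param query_id Query protein/model id.
#' @param query_len Query length in residues.
#' @param query_start,query_end 0-based half-open aligned span on the query.
#' @param kind `"protein-hit"` or `"model-hit"`.
#' @param identity Percent identity of the alignment (informational).
#' @param frame_tag 0-2: position of the path start within its codon.
#' @return A one-row anchor tibble.
#' @export
anchor_path <- function(graph, path, query_id, query_len, query_start, query_end,
                        kind = "protein-hit", identity = NA_real_, frame_tag = 0L) {
  stopifnot(kind %in% c("protein-hit", "model-hit"))
  core <- codon_align_path(graph, path, frame_tag)
  validate_path(graph, core)
  anchor_tibble(list(list(
    anchor_id = NA_character_, query_id = query_id, kind = kind,
    query_len = as.integer(query_len),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    fraction = (query_end - query_start) / query_len,
    identity = identity, frame_tag = 0L,
    nt_len = path_nt_length(graph, core), path = core
  )))
}

number_anchors <- function(anchors) {
  if (nrow(anchors) > 0)
    anchors$anchor_id <- sprintf("anchor_%03d", seq_len(nrow(anchors)))
  anchors
}

# Enumerate maximal simple oriented-edge paths (no repeated oriented edge),
# starting from source edges, bounded by spelled length. Used only by the
# desk-scale built-in aligner.
maximal_simple_paths <- function(graph, max_path_len, max_paths = 10000L) {
  steps_all <- sort(names(graph$seqs))
  oriented <- c(paste0(steps_all, "+"), paste0(steps_all, "-"))
  sources <- oriented[vapply(oriented, function(s) length(graph_pred(graph, s)) == 0, TRUE)]
  if (length(sources) == 0) sources <- oriented
  paths <- list()
  covered <- character(0)
  emit <- function(steps) {
    if (length(paths) >= max_paths)
      stop("path budget exceeded during brute-force anchor search; ",
           "supply external anchors instead")
    paths[[length(paths) + 1]] <<- steps
    covered <<- union(covered, steps)
  }
  walk <- function(steps, len) {
    nxt <- setdiff(graph_succ(graph, steps[length(steps)]), steps)
    nxt <- nxt[vapply(nxt, function(s)
      len + edge_len(graph, step_id(s)) - graph$overlap <= max_path_len, TRUE)]
    if (length(nxt) == 0) {
      emit(steps)
      return()
    }
    for (s in sort(nxt)) walk(c(steps, s), len + edge_len(graph, step_id(s)) - graph$overlap)
  }
  for (s in sort(sources)) walk(s, edge_len(graph, step_id(s)))
  for (s in setdiff(oriented, covered)) walk(s, edge_len(graph, step_id(s)))
  paths
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

local_protein_alignment <- function(query_aa, subject_aa) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query_aa),
    subject = Biostrings::AAString(subject_aa),
    type = "local", substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5
  )
}

translate_frame <- function(nt, frame) {
  n <- nchar(nt) - frame
  n <- n - n %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, frame + 1L, frame + n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"
  ))
}

#' Brute-force protein-to-graph anchor search
#'
#' A desk-scale substitute for a sequence-to-graph aligner: enumerates maximal
#' simple-path spellings up to `max_path_len`, translates each in three frames
#' (both strands are covered because every oriented edge is enumerated),
#' locally aligns every query protein (BLOSUM62), and emits an anchor for
#' every alignment covering at least `min_protein_fraction` of the protein at
#' `min_identity` percent identity or better. Alignment coordinates are mapped
#' back to graph offsets.
#'
#' @param graph An `asm_graph`.
#' @param proteins Named character vector of amino-acid sequences, or an
#'   `AAStringSet`.
#' @param thresholds An [anchor_thresholds()] list.
#' @param max_path_len Longest spelled path considered, default 10000 nt.
#' @param max_paths Abort above this number of enumerated paths.
#' @return An anchor tibble (one row per hit, `path` list-column).
#' @export
find_anchors_bruteforce <- function(graph, proteins,
                                    thresholds = anchor_thresholds(),
                                    max_path_len = 10000L, max_paths = 10000L) {
  if (inherits(proteins, "AAStringSet"))
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  step_lists <- maximal_simple_paths(graph, max_path_len, max_paths)
  rows <- list()
  seen <- character(0)
  for (steps in step_lists) {
    p <- full_path(graph, steps)
    nt <- spell_path(graph, p)
    for (frame in 0:2) {
      aa <- translate_frame(nt, frame)
      if (aa == "") next
      for (qi in names(proteins)) {
        q <- proteins[[qi]]
        qlen <- nchar(q)
        hit <- exact_or_aligned_hit(q, aa)
        if (is.null(hit)) next
        if ((hit$qend - hit$qstart) / qlen < thresholds$min_protein_fraction) next
        if (hit$identity < thresholds$min_identity) next
        nt_from <- frame + 3L * hit$sstart
        nt_to <- frame + 3L * hit$send
        if (nt_to - nt_from < thresholds$min_anchor_nt) next
        sub <- subpath_at(graph, p, nt_from, nt_to)
        key <- paste(qi, paste(sub$steps, collapse = ","), sub$start_offset, sub$end_offset)
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1]] <- list(
          anchor_id = NA_character_, query_id = qi, kind = "protein-hit",
          query_len = qlen, query_start = hit$qstart, query_end = hit$qend,
          fraction = (hit$qend - hit$qstart) / qlen,
          identity = hit$identity, frame_tag = 0L,
          nt_len = path_nt_length(graph, sub), path = sub
        )
      }
    }
  }
  number_anchors(anchor_tibble(rows))
}

# 0-based half-open alignment coordinates; exact substring match short-circuits
# the dynamic programming.
exact_or_aligned_hit <- function(query_aa, subject_aa) {
  at <- regexpr(query_aa, subject_aa, fixed = TRUE)
  if (at > 0) {
    return(list(qstart = 0L, qend = nchar(query_aa),
                sstart = as.integer(at) - 1L,
                send = as.integer(at) - 1L + nchar(query_aa),
                identity = 100))
  }
  aln <- local_protein_alignment(query_aa, subject_aa)
  if (length(Biostrings::score(aln)) == 0 || Biostrings::score(aln) <= 0) return(NULL)
  pr <- methods::slot(Biostrings::pattern(aln), "range")
  sr <- methods::slot(Biostrings::subject(aln), "range")
  list(qstart = as.integer(BiocGenerics::start(pr)) - 1L,
       qend = as.integer(BiocGenerics::end(pr)),
       sstart = as.integer(BiocGenerics::start(sr)) - 1L,
       send = as.integer(BiocGenerics::end(sr)),
       identity = Biostrings::pid(aln, type = "PID1"))
}

#' Load externally computed anchor alignments
#'
#' Ingests a TSV of protein- or model-to-graph alignments (for example from a
#' sequence-to-graph or profile-HMM-to-graph aligner). Columns:
#' `query_id`, `kind` (`protein-hit`/`model-hit`), `query_len`, `query_start`,
#' `query_end` (0-based half-open, residues), `evalue` (number or `.`),
#' `path` (comma-separated oriented edge ids), `start_offset`, `end_offset`.
#' Rows failing the fraction/e-value thresholds are dropped; paths are
#' validated against the graph.
#'
#' @param path TSV file path.
#' @param graph An `asm_graph`.
#' @param thresholds An [anchor_thresholds()] list.
#' @return An anchor tibble.
#' @export
load_external_anchors <- function(path, graph, thresholds = anchor_thresholds()) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("query_id", "kind", "query_len", "query_start", "query_end",
            "evalue", "path", "start_offset", "end_offset")
  miss <- setdiff(need, names(tb))
  if (length(miss) > 0) stop("anchor TSV lacks columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(tb))) {
    r <- tb[i, ]
    if (!r$kind %in% c("protein-hit", "model-hit"))
      stop("malformed anchor row ", i, ": unknown kind '", r$kind, "'")
    qlen <- suppressWarnings(as.integer(r$query_len))
    qs <- suppressWarnings(as.integer(r$query_start))
    qe <- suppressWarnings(as.integer(r$query_end))
    if (anyNA(c(qlen, qs, qe)) || qe <= qs || qlen <= 0)
      stop("malformed anchor row ", i, ": bad query coordinates")
    frac <- (qe - qs) / qlen
    if (r$kind == "protein-hit" && frac < thresholds$min_protein_fraction) next
    if (r$kind == "model-hit") {
      if (frac < thresholds$min_model_fraction) next
      if (r$evalue != ".") {
        ev <- suppressWarnings(as.numeric(r$evalue))
        if (is.na(ev)) stop("malformed anchor row ", i, ": bad evalue")
        if (ev > thresholds$max_evalue) next
      }
    }
    steps <- trimws(strsplit(r$path, ",", fixed = TRUE)[[1]])
    gp <- graph_path(steps, as.integer(r$start_offset), as.integer(r$end_offset))
    validate_path(graph, gp)
    core <- codon_align_path(graph, gp, 0L)
    if (path_nt_length(graph, core) < thresholds$min_anchor_nt) next
    rows[[length(rows) + 1]] <- list(
      anchor_id = NA_character_, query_id = r$query_id, kind = r$kind,
      query_len = qlen, query_start = qs, query_end = qe,
      fraction = frac, identity = NA_real_, frame_tag = 0L,
      nt_len = path_nt_length(graph, core), path = core
    )
  }
  number_anchors(anchor_tibble(rows))
}

# Spelled coordinate of the start of `small` inside `big` when small's steps
# occur at index i of big's steps; NA when offsets fall outside big's span.
subpath_start_coord <- function(graph, big, small, i) {
  ov <- graph$overlap
  lens <- nchar(vapply(big$steps, function(s) oseq(graph, s), ""))
  contrib <- lens - c(big$start_offset, rep(ov, length(lens) - 1L))
  cum_before <- c(0, cumsum(contrib))[i]
  coord <- cum_before + small$start_offset - (if (i == 1) big$start_offset else ov)
  ns <- length(small$steps)
  end_coord <- coord + path_nt_length(graph, small)
  if (coord < 0 || end_coord > path_nt_length(graph, big)) return(NA_integer_)
  as.integer(coord)
}

# TRUE when anchor path `a` lies inside anchor path `b` in the same reading
# frame (both anchors are codon-aligned, so frames agree when the spelled
# offset of a's start within b is a multiple of 3).
anchor_subpath_same_frame <- function(graph, a, b) {
  hits <- steps_find(b$steps, a$steps)
  for (i in hits) {
    coord <- subpath_start_coord(graph, b, a, i)
    if (!is.na(coord) && coord %% 3L == 0L) return(TRUE)
  }
  FALSE
}

#' Drop anchors that are in-frame subpaths of other anchors
#'
#' An anchor is removed when its path (steps and offsets) is contained in
#' another anchor's path and the two read in the same frame over the shared
#' region. Exact duplicates are reduced to one. Output order is deterministic
#' (query id, then path).
#'
#' @param anchors An anchor tibble.
#' @param graph An `asm_graph`.
#' @return The filtered anchor tibble.
#' @export
filter_subpath_anchors <- function(anchors, graph) {
  n <- nrow(anchors)
  if (n <= 1) return(number_anchors(anchors))
  key <- vapply(seq_len(n), function(i) {
    p <- anchors$path[[i]]
    paste(paste(p$steps, collapse = ","), p$start_offset, p$end_offset)
  }, "")
  drop <- rep(FALSE, n)
  dup_seen <- character(0)
  for (i in seq_len(n)) {
    if (key[i] %in% dup_seen) { drop[i] <- TRUE; next }
    dup_seen <- c(dup_seen, key[i])
  }
  for (i in seq_len(n)) {
    if (drop[i]) next
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      a <- anchors$path[[i]]; b <- anchors$path[[j]]
      if (anchors$nt_len[i] > anchors$nt_len[j]) next
      if (key[i] == key[j]) next
      if (anchor_subpath_same_frame(graph, a, b)) { drop[i] <- TRUE; break }
    }
  }
  number_anchors(anchors[!drop, ])
}
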