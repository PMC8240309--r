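# Assembly-graph data model and GFA/FASTA I/O.
#
# The graph is bidirected: every edge has a + face (the stored sequence) and a
# - face (its reverse complement); adjacent edges share `overlap` bases
# (typically k-1 for a SPAdes graph). Oriented edges are written "id+"/"id-".

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`. Accepts A, C, G, T, N (case-sensitive, upper case).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

step_id <- function(step) substr(step, 1L, nchar(step) - 1L)
step_orient <- function(step) substr(step, nchar(step), nchar(step))

#' Flip the orientation of oriented edge labels
#' @param step Character vector like `"12+"` or `"3-"`.
#' @return Character vector with orientations flipped.
#' @export
step_flip <- function(step) {
  o <- step_orient(step)
  paste0(step_id(step), ifelse(o == "+", "-", "+"))
}

rc_steps <- function(steps) rev(step_flip(steps))

#' Construct an assembly graph
#'
#' @param segments Named character vector: edge id -> nucleotide sequence
#'   (the + face). Sequences may contain A, C, G, T, N only and must be
#'   longer than `overlap`.
#' @param links Optional data frame with columns `from`, `to` holding oriented
#'   edge labels (e.g. `"1+"`, `"2-"`); each link means the `to` edge follows
#'   the `from` edge sharing `overlap` bases. The reverse-complement mirror of
#'   every link is added automatically (bidirected symmetry).
#' @param overlap Integer >= 0, bases shared by adjacent edges.
#' @param coverage Optional named numeric vector of mean read coverage per edge.
#' @return An object of class `asm_graph`.
#' @export
asm_graph <- function(segments, links = NULL, overlap = 0L, coverage = NULL) {
  overlap <- as.integer(overlap)
  if (is.null(names(segments)) || anyNA(names(segments)) || any(names(segments) == ""))
    stop("segments must be a named character vector")
  if (anyDuplicated(names(segments)))
    stop("duplicated segment ids")
  bad <- grepl("[^ACGTN]", segments)
  if (any(bad))
    stop("segment sequences may contain only A,C,G,T,N: ", names(segments)[bad][1])
  if (any(nchar(segments) <= overlap))
    stop("every edge sequence must be longer than the overlap (", overlap, ")")

  succ <- new.env(parent = emptyenv())
  add_link <- function(a, b) {
    cur <- if (is.null(succ[[a]])) character(0) else succ[[a]]
    if (!b %in% cur) succ[[a]] <- sort(c(cur, b))
  }
  if (!is.null(links) && nrow(as.data.frame(links)) > 0) {
    links <- as.data.frame(links)
    ids <- unique(c(step_id(links$from), step_id(links$to)))
    miss <- setdiff(ids, names(segments))
    if (length(miss) > 0)
      stop("link references undeclared segment: ", miss[1])
    for (i in seq_len(nrow(links))) {
      add_link(links$from[i], links$to[i])
      add_link(step_flip(links$to[i]), step_flip(links$from[i]))
    }
  }
  if (!is.null(coverage)) {
    miss <- setdiff(names(coverage), names(segments))
    if (length(miss) > 0) stop("coverage references undeclared segment: ", miss[1])
  }

  oseq <- new.env(parent = emptyenv())
  for (id in names(segments)) {
    oseq[[paste0(id, "+")]] <- unname(segments[[id]])
    oseq[[paste0(id, "-")]] <- revcomp(segments[[id]])
  }

  structure(
    list(seqs = segments, overlap = overlap, succ = succ, oseq = oseq,
         coverage = coverage),
    class = "asm_graph"
  )
}

#' @export
print.asm_graph <- function(x, ...) {
  nl <- length(graph_links(x)$from)
  cat("<asm_graph> ", length(x$seqs), " edges, ", nl, " links, overlap ",
      x$overlap, "\n", sep = "")
  invisible(x)
}

edge_len <- function(graph, id) nchar(graph$seqs[[id]])
oseq <- function(graph, step) graph$oseq[[step]]

#' Successors / predecessors of an oriented edge
#' @param graph An `asm_graph`.
#' @param step Oriented edge label.
#' @return Character vector of oriented edge labels (sorted).
#' @export
graph_succ <- function(graph, step) {
  s <- graph$succ[[step]]
  if (is.null(s)) character(0) else s
}

#' @rdname graph_succ
#' @export
graph_pred <- function(graph, step) {
  sort(step_flip(graph_succ(graph, step_flip(step))))
}

# All links as a canonical (deduplicated) from/to list.
graph_links <- function(graph) {
  from <- character(0); to <- character(0)
  for (a in ls(graph$succ)) {
    for (b in graph$succ[[a]]) {
      mirror <- paste(step_flip(b), step_flip(a))
      if (paste(a, b) <= mirror) {
        from <- c(from, a); to <- c(to, b)
      }
    }
  }
  list(from = from, to = to)
}

#' Read a GFA 1.0 assembly graph
#'
#' Reads S-lines (sequences required) and L-lines (a single fixed-length
#' `<n>M` overlap across all links). Coverage is taken from `DP:f` tags, or
#' computed from `KC:i` tags as count / (length - overlap). The
#' reverse-complement mirror of each link is added if absent.
#'
#' @param path Path to a GFA 1.0 file.
#' @return An `asm_graph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  segs <- character(0)
  kc <- numeric(0); dp <- numeric(0)
  lfrom <- character(0); lto <- character(0); lov <- integer(0)

  for (ln in lines) {
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3 || f[3] == "*" || f[3] == "")
        stop("S-line without a sequence: segment ", if (length(f) >= 2) f[2] else "?")
      segs[[f[2]]] <- toupper(f[3])
      if (length(f) > 3) {
        for (tag in f[-(1:3)]) {
          if (startsWith(tag, "KC:i:")) kc[[f[2]]] <- as.numeric(sub("KC:i:", "", tag))
          if (startsWith(tag, "DP:f:") || startsWith(tag, "dp:f:"))
            dp[[f[2]]] <- as.numeric(sub("^..:f:", "", tag))
        }
      }
    } else if (f[1] == "L") {
      if (length(f) < 6) stop("malformed L-line: ", ln)
      m <- regmatches(f[6], regexec("^([0-9]+)M$", f[6]))[[1]]
      if (length(m) == 0) stop("L-line CIGAR must be a fixed-length match (<n>M): ", f[6])
      lfrom <- c(lfrom, paste0(f[2], f[3]))
      lto <- c(lto, paste0(f[4], f[5]))
      lov <- c(lov, as.integer(m[2]))
    }
  }
  overlap <- 0L
  if (length(lov) > 0) {
    if (length(unique(lov)) > 1)
      stop("inconsistent overlaps across L-lines: ", paste(unique(lov), collapse = ", "))
    overlap <- lov[1]
  }
  coverage <- NULL
  if (length(dp) > 0 || length(kc) > 0) {
    coverage <- stats::setNames(rep(NA_real_, length(segs)), names(segs))
    if (length(kc) > 0)
      coverage[names(kc)] <- kc / pmax(1, nchar(segs[names(kc)]) - overlap)
    if (length(dp) > 0) coverage[names(dp)] <- dp
  }
  g <- asm_graph(segs, links = data.frame(from = lfrom, to = lto), overlap = overlap,
                 coverage = coverage)
  check_overlap_consistency(g)
  g
}

check_overlap_consistency <- function(graph) {
  ov <- graph$overlap
  if (ov == 0) return(invisible(TRUE))
  for (a in ls(graph$succ)) {
    sa <- oseq(graph, a)
    for (b in graph$succ[[a]]) {
      sb <- oseq(graph, b)
      if (substr(sa, nchar(sa) - ov + 1L, nchar(sa)) != substr(sb, 1L, ov)) {
        warning("link ", a, " -> ", b, " has mismatching overlap sequence; ",
                "spelled paths across it will not match the genome")
        return(invisible(FALSE))
      }
    }
  }
  invisible(TRUE)
}

#' Write a GFA 1.0 assembly graph
#'
#' Inverse of [read_gfa()]: emits S-lines (with `DP:f` coverage tags when the
#' graph carries coverage) and one L-line per bidirected link.
#'
#' @param graph An `asm_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  out <- c("H\tVN:Z:1.0")
  for (id in names(graph$seqs)) {
    line <- paste("S", id, graph$seqs[[id]], sep = "\t")
    if (!is.null(graph$coverage) && !is.na(graph$coverage[id]))
      line <- paste0(line, "\tDP:f:", format(graph$coverage[[id]], scientific = FALSE))
    out <- c(out, line)
  }
  lk <- graph_links(graph)
  cig <- paste0(graph$overlap, "M")
  for (i in seq_along(lk$from)) {
    out <- c(out, paste("L", step_id(lk$from[i]), step_orient(lk$from[i]),
                        step_id(lk$to[i]), step_orient(lk$to[i]), cig, sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a graph path
#'
#' An ordered walk over oriented edges with 0-based half-open offsets into the
#' first and last edge: the path covers `[start_offset, ...)` of the first
#' edge through `[..., end_offset)` of the last edge.
#'
#' @param steps Character vector of oriented edge labels.
#' @param start_offset 0-based offset of the first covered base in the first edge.
#' @param end_offset Exclusive 0-based offset in the last edge.
#' @return An object of class `graph_path`.
#' @export
graph_path <- function(steps, start_offset = 0L, end_offset = NULL) {
  structure(list(steps = as.character(steps),
                 start_offset = as.integer(start_offset),
                 end_offset = if (is.null(end_offset)) NULL else as.integer(end_offset)),
            class = "graph_path")
}

#' @export
print.graph_path <- function(x, ...) {
  cat("<graph_path> ", paste(x$steps, collapse = ","),
      " [", x$start_offset, ", ", x$end_offset, ")\n", sep = "")
  invisible(x)
}

#' Full-span path over whole edges
#' @param graph An `asm_graph`.
#' @param steps Oriented edge labels.
#' @return A `graph_path` spanning the edges end to end.
#' @export
full_path <- function(graph, steps) {
  graph_path(steps, 0L, edge_len(graph, step_id(steps[length(steps)])))
}

#' Validate a graph path against a graph
#'
#' Checks that consecutive steps are linked, offsets are in range, and the
#' spelled length is positive.
#'
#' @param graph An `asm_graph`.
#' @param path A `graph_path`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_path <- function(graph, path) {
  n <- length(path$steps)
  if (n == 0) stop("empty path")
  miss <- setdiff(step_id(path$steps), names(graph$seqs))
  if (length(miss) > 0) stop("path references unknown edge: ", miss[1])
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!path$steps[i + 1] %in% graph_succ(graph, path$steps[i]))
        stop("disconnected steps: ", path$steps[i], " -> ", path$steps[i + 1])
    }
  }
  len1 <- edge_len(graph, step_id(path$steps[1]))
  lenn <- edge_len(graph, step_id(path$steps[n]))
  if (path$start_offset < 0 || path$start_offset >= len1)
    stop("start_offset out of range")
  if (is.null(path$end_offset) || path$end_offset <= 0 || path$end_offset > lenn)
    stop("end_offset out of range")
  if (path_nt_length(graph, path) <= 0) stop("path spells an empty sequence")
  invisible(TRUE)
}

#' Spelled length of a path, in nucleotides
#' @param graph An `asm_graph`.
#' @param path A `graph_path`.
#' @return Integer length of [spell_path()] output, computed arithmetically.
#' @export
path_nt_length <- function(graph, path) {
  lens <- nchar(vapply(path$steps, function(s) oseq(graph, s), ""))
  n <- length(lens)
  if (n == 1) return(path$end_offset - path$start_offset)
  sum(lens) - graph$overlap * (n - 1L) - path$start_offset - (lens[n] - path$end_offset)
}

# Move a path end that falls inside the final overlap onto the previous edge,
# so substring spelling stays well defined. No-op for single-step paths.
normalize_path <- function(graph, path) {
  ov <- graph$overlap
  while (length(path$steps) > 1 && path$end_offset <= ov) {
    n <- length(path$steps)
    prev_len <- edge_len(graph, step_id(path$steps[n - 1]))
    path$end_offset <- path$end_offset + prev_len - ov
    path$steps <- path$steps[-n]
  }
  path
}

#' Spell the nucleotide sequence of a path
#'
#' Concatenates the first edge from `start_offset`, then each subsequent
#' oriented edge minus its first `overlap` bases, truncated at `end_offset`
#' on the last edge. Orientation `-` spells the reverse complement of the
#' stored sequence.
#'
#' @param graph An `asm_graph`.
#' @param path A `graph_path`.
#' @return Nucleotide string.
#' @export
spell_path <- function(graph, path) {
  path <- normalize_path(graph, path)
  validate_path(graph, path)
  ov <- graph$overlap
  n <- length(path$steps)
  seqs <- unname(vapply(path$steps, function(s) oseq(graph, s), ""))
  if (n == 1) return(substr(seqs[1], path$start_offset + 1L, path$end_offset))
  parts <- character(n)
  parts[1] <- substr(seqs[1], path$start_offset + 1L, nchar(seqs[1]))
  if (n > 2)
    parts[2:(n - 1)] <- substr(seqs[2:(n - 1)], ov + 1L, nchar(seqs[2:(n - 1)]))
  parts[n] <- substr(seqs[n], ov + 1L, path$end_offset)
  paste(parts, collapse = "")
}

#' Reverse-complement a graph path
#' @param graph An `asm_graph`.
#' @param path A `graph_path`.
#' @return The `graph_path` spelling the reverse complement of `path`.
#' @export
rc_graph_path <- function(graph, path) {
  n <- length(path$steps)
  len1 <- edge_len(graph, step_id(path$steps[1]))
  lenn <- edge_len(graph, step_id(path$steps[n]))
  graph_path(rc_steps(path$steps),
             start_offset = lenn - path$end_offset,
             end_offset = len1 - path$start_offset)
}

#' Extract a sub-path by spelled coordinates
#'
#' @param graph An `asm_graph`.
#' @param path A `graph_path`.
#' @param from,to 0-based half-open interval in the spelled coordinates of
#'   `path` (`0 <= from < to <=` spelled length).
#' @return A `graph_path` spelling `substr(spell_path(graph, path), from+1, to)`.
#' @export
subpath_at <- function(graph, path, from, to) {
  total <- path_nt_length(graph, path)
  if (from < 0 || to > total || from >= to) stop("invalid subpath interval")
  ov <- graph$overlap
  lens <- nchar(vapply(path$steps, function(s) oseq(graph, s), ""))
  # cumulative spelled length after each step
  contrib <- lens - c(path$start_offset, rep(ov, length(lens) - 1L))
  cum <- cumsum(contrib)
  i <- which(cum > from)[1]
  j <- which(cum >= to)[1]
  off_of <- function(idx, coord) {
    prev <- if (idx == 1) 0 else cum[idx - 1]
    base <- coord - prev + (if (idx == 1) path$start_offset else ov)
    as.integer(base)
  }
  graph_path(path$steps[i:j], off_of(i, from), off_of(j, to - 1L) + 1L)
}

# ---- positions -------------------------------------------------------------
# A position is one base: list(step = "1+", off = 0-based offset).

pos <- function(step, off) list(step = step, off = as.integer(off))
pos_key <- function(p) paste0(p$step, ":", p$off)

pos_base <- function(graph, p) substr(oseq(graph, p$step), p$off + 1L, p$off + 1L)

# Positions holding the base immediately after p (branches at edge ends).
pos_next <- function(graph, p) {
  if (p$off + 1L < edge_len(graph, step_id(p$step)))
    return(list(pos(p$step, p$off + 1L)))
  lapply(graph_succ(graph, p$step), function(s) pos(s, graph$overlap))
}

# The same physical base on the opposite strand.
rc_pos <- function(graph, p) {
  pos(step_flip(p$step), edge_len(graph, step_id(p$step)) - 1L - p$off)
}

path_start_pos <- function(path) pos(path$steps[1], path$start_offset)
path_last_pos <- function(path) pos(path$steps[length(path$steps)], path$end_offset - 1L)

# ---- step-list predicates (contig_filter primitives) -----------------------

steps_find <- function(big, small) {
  nb <- length(big); ns <- length(small)
  if (ns > nb) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(nb - ns + 1)) {
    if (all(big[i:(i + ns - 1)] == small)) hits <- c(hits, i)
  }
  hits
}

#' Step-level containment and overlap predicates
#'
#' `steps_contain()` tests whether `small` occurs as a contiguous sub-list of
#' `big` (same orientation). `steps_overlap()` tests whether a suffix of `p`
#' equals a prefix of `q` (or vice versa). Both are primitives behind
#' [paths_compatible()].
#'
#' @param big,small,p,q Character vectors of oriented edge labels.
#' @return Logical scalar.
#' @export
steps_contain <- function(big, small) length(steps_find(big, small)) > 0

#' @rdname steps_contain
#' @export
steps_overlap <- function(p, q) {
  np <- length(p); nq <- length(q)
  for (k in seq_len(min(np, nq))) {
    if (all(p[(np - k + 1):np] == q[1:k])) return(TRUE)
    if (all(q[(nq - k + 1):nq] == p[1:k])) return(TRUE)
  }
  FALSE
}
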