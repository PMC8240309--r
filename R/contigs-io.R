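# Contig-path input: SPAdes-style `.paths` files and GFA P-lines.

#' Read SPAdes-style contig paths
#'
#' The `.paths` format alternates a contig name line with one line of
#' comma-separated oriented edge ids; `;` marks a gap in the path. Gapped
#' contig paths are split into gap-free sub-paths (suffixed `_1`, `_2`, ...),
#' since only gap-free runs constrain the compatibility filter.
#'
#' @param path Path to a `.paths` file.
#' @param graph Optional `asm_graph`; when given, each sub-path is validated
#'   and returned as a full-span [graph_path()].
#' @return A tibble with columns `contig`, `part`, `path` (list of
#'   `graph_path` when `graph` is given, else character vectors of steps).
#' @export
read_spades_paths <- function(path, graph = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  # a path line is a ;/, sequence of oriented edge ids; anything else names
  # a contig
  tok <- "[A-Za-z0-9_.]+[+-]"
  is_name <- !grepl(paste0("^", tok, "([,;]", tok, ")*[,;]?$"), lines)
  if (length(lines) == 0 || !is_name[1]) stop("malformed .paths file: ", path)
  name <- NA_character_
  out <- list()
  buf <- character(0)
  flush_buf <- function() {
    if (length(buf) == 0) return()
    segs <- strsplit(paste(buf, collapse = ";"), ";", fixed = TRUE)[[1]]
    segs <- segs[segs != ""]
    for (i in seq_along(segs)) {
      steps <- strsplit(gsub("[,; ]+$", "", segs[i]), ",", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <<- list(contig = name, part = i, steps = trimws(steps))
    }
    buf <<- character(0)
  }
  for (i in seq_along(lines)) {
    if (is_name[i]) {
      flush_buf()
      name <- lines[i]
    } else {
      buf <- c(buf, lines[i])
    }
  }
  flush_buf()
  finish_contig_tbl(out, graph)
}

#' Read contig paths from GFA P-lines
#'
#' @param path Path to a GFA 1.0 file containing P-lines.
#' @param graph Optional `asm_graph` for validation (see [read_spades_paths()]).
#' @return A tibble as for [read_spades_paths()].
#' @export
read_gfa_paths <- function(path, graph = NULL) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines[startsWith(lines, "P\t")]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed P-line: ", ln)
    segs <- strsplit(f[3], ";", fixed = TRUE)[[1]]
    for (i in seq_along(segs)) {
      steps <- strsplit(segs[i], ",", fixed = TRUE)[[1]]
      out[[length(out) + 1]] <- list(contig = f[2], part = i, steps = trimws(steps))
    }
  }
  finish_contig_tbl(out, graph)
}

finish_contig_tbl <- function(out, graph) {
  tb <- tibble::tibble(
    contig = vapply(out, `[[`, "", "contig"),
    part = vapply(out, `[[`, 0L, "part"),
    path = lapply(out, `[[`, "steps")
  )
  if (!is.null(graph)) {
    tb$path <- lapply(tb$path, function(steps) {
      p <- full_path(graph, steps)
      validate_path(graph, p)
      p
    })
  }
  tb
}

contig_paths_as_list <- function(contigs) {
  if (is.null(contigs)) return(list())
  if (inherits(contigs, "graph_path")) return(list(contigs))
  if (is.data.frame(contigs)) return(contigs$path)
  contigs
}
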