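# Deterministic synthetic fixtures: assembly graphs with known embedded
# genes, bubble and tangle structures, assembler-like unitig contigs, and a
# recorded truth table. The generator writes the graph directly (junction
# k-mers force the intended topology) instead of assembling reads, so every
# stage of the pipeline is testable without external tools.

DNA <- c("A", "C", "G", "T")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

all_codons <- function() {
  g <- expand.grid(DNA, DNA, DNA, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

SENSE_CODONS <- setdiff(all_codons(), c("TAA", "TAG", "TGA"))

#' Generate a random coding sequence
#'
#' ATG, `n_codons - 2` random sense codons, TAA.
#'
#' @param n_codons Total codon count including start and stop (>= 3).
#' @param seed RNG seed.
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 3)
  with_seed(seed, {
    paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
  })
}

#' Mutate a coding sequence without breaking it
#'
#' Replaces a fraction of internal codons with random different sense codons;
#' the start and stop codon and any codons overlapping `keep_region`
#' (0-based half-open, nt) are left untouched.
#'
#' @param cds A valid CDS (start..stop, length a multiple of 3).
#' @param rate Fraction of internal codons to replace.
#' @param keep_region Optional `c(from, to)` nucleotide interval to preserve.
#' @param seed RNG seed.
#' @return The mutated CDS.
#' @export
mutate_cds <- function(cds, rate = 0.05, keep_region = NULL, seed = 1L) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  idx <- seq(2L, length(codons) - 1L)
  if (!is.null(keep_region)) {
    from_c <- keep_region[1] %/% 3L + 1L
    to_c <- (keep_region[2] + 2L) %/% 3L
    idx <- setdiff(idx, seq(from_c, to_c))
  }
  with_seed(seed, {
    pick <- idx[stats::runif(length(idx)) < rate]
    for (i in pick) {
      codons[i] <- sample(setdiff(SENSE_CODONS, codons[i]), 1L)
    }
  })
  paste(codons, collapse = "")
}

#' A deterministic diverged relative of a coding sequence
#'
#' Replaces every `every`-th internal codon with a codon encoding a different
#' amino acid (alanine, or valine where the original already encodes
#' alanine), giving a relative at roughly `100 * (1 - 1/every)` percent
#' amino-acid identity regardless of the input.
#'
#' @param cds A valid CDS.
#' @param every Substitution period in codons, default 20 (~95% identity).
#' @return The mutated CDS.
#' @export
relative_cds <- function(cds, every = 20L) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  for (i in seq(2L, length(codons) - 1L, by = every)) {
    codons[i] <- if (substr(codons[i], 1L, 2L) == "GC") "GTT" else "GCT"
  }
  paste(codons, collapse = "")
}

# in-frame stop planted just upstream of the CDS so no longer ORF exists
make_flanks <- function(flank) {
  list(left = paste0(rand_dna(flank - 3L), "TAA"), right = rand_dna(flank))
}

#' Generate an assembly-graph fixture with embedded genes
#'
#' Each CDS is embedded in random flanking sequence (with an in-frame stop
#' immediately upstream), the region is split into edges overlapping by `k`,
#' and for each bubble an internal in-gene edge is duplicated with
#' `divergence` third-codon-position substitutions (a strain-level variant
#' branch). With `tangle = TRUE`, a second diverged copy of the first gene is
#' created that shares one central repeat edge with it, so neither gene lies
#' in a single contig. Deterministic under `seed`.
#'
#' @param genes Named character vector of CDS nucleotide sequences; default
#'   one random 300-codon gene.
#' @param n_bubbles Bubbles per gene (variant internal edges).
#' @param divergence Substitutions per bubble branch, default 3.
#' @param tangle Share a central repeat edge between two gene copies.
#' @param tangle_divergence Fraction of codons mutated in the second tangle
#'   copy (outside the shared repeat), default 0.4.
#' @param k Edge overlap (SPAdes-like k-1), default 55.
#' @param flank Flanking sequence length per side, default 300.
#' @param contig_policy `"unitigs"` (assembler-like, default), `"genome"`
#'   (one contig per gene region), or `"none"`.
#' @param true_coverage,variant_coverage Read-coverage tags for edges of the
#'   original path and of bubble branches.
#' @param seed RNG seed.
#' @return A list of class `orfgraph_fixture`: `graph` (`asm_graph`),
#'   `contigs` (tibble with `contig`, `part`, `path`), `truth` (tibble with
#'   `gene_id`, `nt`, `aa`, `path`), and the spec fields.
#' @export
generate_fixture <- function(genes = NULL, n_bubbles = 0L, divergence = 3L,
                             tangle = FALSE, tangle_divergence = 0.4,
                             k = 55L, flank = 300L,
                             contig_policy = c("unitigs", "genome", "none"),
                             true_coverage = 40, variant_coverage = 20,
                             seed = 1L) {
  contig_policy <- match.arg(contig_policy)
  k <- as.integer(k); n_bubbles <- as.integer(n_bubbles)
  if (is.null(genes))
    genes <- c(geneA = random_cds(300L, seed = seed + 7L))
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  for (g in genes) check_cds(g)
  if (tangle && n_bubbles > 0)
    stop("tangle fixtures are generated without bubbles")
  with_seed(seed, {
    segs <- character(0); links <- NULL; cov <- numeric(0)
    truth <- list()
    add_links <- function(df) {
      links <<- if (is.null(links)) df else rbind(links, df)
    }

    if (tangle) {
      cdsA <- genes[[1]]
      nA <- nchar(cdsA)
      r <- 3L * ((2L * k + 36L) %/% 3L)                 # shared repeat length
      s <- 3L * ((nA %/% 2L - r %/% 2L) %/% 3L)
      cdsB <- mutate_cds(cdsA, rate = tangle_divergence,
                         keep_region = c(s, s + r), seed = seed + 11L)
      regions <- list()
      for (nm in c("A", "B")) {
        cds <- if (nm == "A") cdsA else cdsB
        fl <- make_flanks(flank)
        regions[[nm]] <- paste0(fl$left, cds, fl$right)
      }
      q1 <- flank + s
      q2 <- flank + s + r - k
      ids <- list(A = c("tA_left", "rep", "tA_right"),
                  B = c("tB_left", "rep", "tB_right"))
      for (nm in c("A", "B")) {
        Rg <- regions[[nm]]
        segs[[ids[[nm]][1]]] <- substr(Rg, 1L, q1 + k)
        segs[["rep"]] <- substr(Rg, q1 + 1L, q2 + k)    # identical for A and B
        segs[[ids[[nm]][3]]] <- substr(Rg, q2 + 1L, nchar(Rg))
        add_links(data.frame(from = paste0(ids[[nm]][1], "+"), to = "rep+"))
        add_links(data.frame(from = "rep+", to = paste0(ids[[nm]][3], "+")))
        cov[ids[[nm]][c(1, 3)]] <- true_coverage
      }
      cov[["rep"]] <- 2 * true_coverage
      graph <- asm_graph(segs, links, overlap = k, coverage = cov)
      cds_list <- list(A = cdsA, B = cdsB)
      for (nm in c("A", "B")) {
        chain <- full_path(graph, paste0(ids[[nm]], "+"))
        tp <- subpath_at(graph, chain, flank, flank + nchar(cds_list[[nm]]))
        stopifnot(spell_path(graph, tp) == cds_list[[nm]])
        truth[[length(truth) + 1]] <- list(
          gene_id = paste0(names(genes)[1], "_", nm), nt = cds_list[[nm]],
          aa = translate_cds(cds_list[[nm]]), path = tp, chain = chain)
      }
    } else {
      for (gi in seq_along(genes)) {
        cds <- genes[[gi]]
        gid <- names(genes)[gi]
        fl <- make_flanks(flank)
        Rg <- paste0(fl$left, cds, fl$right)
        nC <- nchar(cds)
        m <- 2L * n_bubbles                       # interior cut count
        if (m > 0) {
          step <- nC %/% (m + 1L)
          if (step < k + 10L)
            stop("CDS too short for ", n_bubbles, " bubbles at k = ", k)
          cuts <- flank + step * seq_len(m)
        } else {
          # still split the gene across edges: two cuts inside the CDS
          cuts <- flank + c(nC %/% 3L, 2L * (nC %/% 3L))
        }
        bounds <- c(0L, cuts, nchar(Rg) - k)
        ids <- paste0(gid, "_e", seq_len(length(bounds) - 1L))
        for (i in seq_len(length(ids))) {
          segs[[ids[i]]] <- substr(Rg, bounds[i] + 1L, bounds[i + 1L] + k)
          cov[[ids[i]]] <- true_coverage
          if (i > 1)
            add_links(data.frame(from = paste0(ids[i - 1L], "+"),
                                 to = paste0(ids[i], "+")))
        }
        if (n_bubbles > 0) {
          bub_idx <- seq(2L, length(ids) - 1L, by = 2L)[seq_len(n_bubbles)]
          for (b in bub_idx) {
            vid <- paste0(ids[b], "v")
            segs[[vid]] <- mutate_edge_thirds(segs[[ids[b]]], bounds[b], flank,
                                              k, divergence)
            cov[[vid]] <- variant_coverage
            add_links(data.frame(from = paste0(ids[b - 1L], "+"),
                                 to = paste0(vid, "+")))
            add_links(data.frame(from = paste0(vid, "+"),
                                 to = paste0(ids[b + 1L], "+")))
          }
        }
        truth[[length(truth) + 1]] <- list(gene_id = gid, nt = cds,
                                           aa = translate_cds(cds),
                                           ids = ids, flank = flank)
      }
      graph <- asm_graph(segs, links, overlap = k, coverage = cov)
      truth <- lapply(truth, function(tr) {
        chain <- full_path(graph, paste0(tr$ids, "+"))
        tp <- subpath_at(graph, chain, tr$flank, tr$flank + nchar(tr$nt))
        stopifnot(spell_path(graph, tp) == tr$nt)
        list(gene_id = tr$gene_id, nt = tr$nt, aa = tr$aa, path = tp,
             chain = chain)
      })
    }

    contigs <- switch(contig_policy,
      none = tibble::tibble(contig = character(0), part = integer(0), path = list()),
      genome = tibble::tibble(
        contig = paste0("ctg_", vapply(truth, `[[`, "", "gene_id")),
        part = 1L,
        path = lapply(truth, `[[`, "chain")),
      unitigs = graph_unitigs(graph)
    )
    truth_tb <- tibble::tibble(
      gene_id = vapply(truth, `[[`, "", "gene_id"),
      nt = vapply(truth, `[[`, "", "nt"),
      aa = vapply(truth, `[[`, "", "aa"),
      path = lapply(truth, `[[`, "path"))
    structure(list(graph = graph, contigs = contigs, truth = truth_tb,
                   n_bubbles = n_bubbles, divergence = divergence,
                   tangle = tangle, k = k, flank = flank,
                   contig_policy = contig_policy, seed = seed),
              class = "orfgraph_fixture")
  })
}

check_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be a multiple of 3")
  if (!substr(cds, 1L, 3L) %in% START_CODONS) stop("CDS must begin with a start codon")
  if (!substr(cds, n - 2L, n) %in% STOP_CODONS) stop("CDS must end with a stop codon")
  if (has_internal_stop(cds)) stop("CDS has an internal in-frame stop")
  invisible(TRUE)
}

# Substitute `n_sub` third-codon positions in the novel interior of an edge,
# never creating a stop codon. `edge_start` is the edge's 0-based region
# coordinate; codon frame is taken relative to the CDS start at `flank`.
mutate_edge_thirds <- function(edge_seq, edge_start, flank, k, n_sub) {
  len <- nchar(edge_seq)
  offs <- seq(k + 1L, len - k)                 # 1-based positions free to change
  region_pos <- edge_start + offs - 1L         # 0-based region coordinate
  third <- offs[(region_pos - flank) %% 3L == 2L]
  third <- third[third >= k + 3L]              # keep whole codon inside the edge
  pick <- sample(third, min(n_sub, length(third)))
  out <- strsplit(edge_seq, "")[[1]]
  for (p in pick) {
    codon_from <- p - 2L
    for (b in sample(setdiff(DNA, out[p]))) {
      cand <- paste0(out[codon_from], out[codon_from + 1L], b)
      if (!cand %in% STOP_CODONS) { out[p] <- b; break }
    }
  }
  paste(out, collapse = "")
}

# Maximal unbranched runs of the graph, each reported once in canonical
# orientation: what a conservative assembler would emit as contigs.
graph_unitigs <- function(graph) {
  oriented <- c(paste0(names(graph$seqs), "+"), paste0(names(graph$seqs), "-"))
  interior <- function(a, b) {
    length(graph_succ(graph, a)) == 1L && length(graph_pred(graph, b)) == 1L
  }
  is_start <- vapply(oriented, function(s) {
    p <- graph_pred(graph, s)
    length(p) != 1L || length(graph_succ(graph, p)) != 1L
  }, TRUE)
  runs <- list()
  for (s in sort(oriented[is_start])) {
    run <- s
    repeat {
      nxt <- graph_succ(graph, run[length(run)])
      if (length(nxt) != 1L || length(graph_pred(graph, nxt)) != 1L) break
      run <- c(run, nxt)
    }
    runs[[length(runs) + 1]] <- run
  }
  keys <- vapply(runs, function(r) paste(r, collapse = ","), "")
  rc_keys <- vapply(runs, function(r) paste(rc_steps(r), collapse = ","), "")
  keep <- keys <= rc_keys
  runs <- runs[keep]
  ord <- order(vapply(runs, function(r) paste(r, collapse = ","), ""))
  runs <- runs[ord]
  tibble::tibble(
    contig = sprintf("unitig_%03d", seq_along(runs)),
    part = 1L,
    path = lapply(runs, function(r) full_path(graph, r)))
}

#' Write a fixture to disk
#'
#' Emits `graph.gfa`, `contigs.fasta`, `contigs.paths` (SPAdes style) and
#' `truth.json` into `dir`.
#'
#' @param fixture An `orfgraph_fixture`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gfa(fixture$graph, file.path(dir, "graph.gfa"))
  seqs <- vapply(fixture$contigs$path, function(p) spell_path(fixture$graph, p), "")
  names(seqs) <- paste0(fixture$contigs$contig, "_", fixture$contigs$part)
  if (length(seqs) > 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(dir, "contigs.fasta"))
  } else {
    file.create(file.path(dir, "contigs.fasta"))
  }
  plines <- unlist(lapply(seq_len(nrow(fixture$contigs)), function(i) {
    c(paste0(fixture$contigs$contig[i], "_", fixture$contigs$part[i]),
      paste(fixture$contigs$path[[i]]$steps, collapse = ","))
  }))
  writeLines(if (is.null(plines)) character(0) else plines,
             file.path(dir, "contigs.paths"))
  truth <- lapply(seq_len(nrow(fixture$truth)), function(i) {
    list(gene_id = fixture$truth$gene_id[i], nt = fixture$truth$nt[i],
         aa = fixture$truth$aa[i],
         steps = fixture$truth$path[[i]]$steps,
         start_offset = fixture$truth$path[[i]]$start_offset,
         end_offset = fixture$truth$path[[i]]$end_offset)
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' The Fig.-9-style conflict topology
#'
#' Builds the two-bulge graph A -> (B1|B2) -> C -> (D1|D2) -> E with long
#' branches B1, D1 (400 nt) and short branches B2, D2 (200 nt), plus the
#' labelled test paths: green (the contig path A,B1,C,D1,E, whose unique
#' edges are B1 and D1), red (B1,C,D2: shares unique B1 with the contig but
#' cannot be merged with it), blue (A,B2,C,D2: shares only non-unique
#' edges), yellow (B1,C,D1,E: contained in the contig). B1 and D1 are the
#' only unique edges at the default 300-nt threshold.
#'
#' @param seed RNG seed for the random edge sequences.
#' @return A list with `graph`, `contigs` (list of one `graph_path`), and
#'   `paths` (named list of `graph_path`s).
#' @export
generate_fig9_graph <- function(seed = 1L) {
  k <- 20L
  with_seed(seed, {
    z1 <- rand_dna(k); z2 <- rand_dna(k); z3 <- rand_dna(k); z4 <- rand_dna(k)
    segs <- c(
      A = paste0(rand_dna(380L), z1),
      B1 = paste0(z1, rand_dna(360L), z2),
      B2 = paste0(z1, rand_dna(160L), z2),
      C = paste0(z2, rand_dna(360L), z3),
      D1 = paste0(z3, rand_dna(360L), z4),
      D2 = paste0(z3, rand_dna(160L), z4),
      E = paste0(z4, rand_dna(380L)))
    links <- data.frame(
      from = c("A+", "A+", "B1+", "B2+", "C+", "C+", "D1+", "D2+"),
      to = c("B1+", "B2+", "C+", "C+", "D1+", "D2+", "E+", "E+"))
    graph <- asm_graph(segs, links, overlap = k)
    paths <- list(
      green = full_path(graph, c("A+", "B1+", "C+", "D1+", "E+")),
      red = full_path(graph, c("B1+", "C+", "D2+")),
      blue = full_path(graph, c("A+", "B2+", "C+", "D2+")),
      yellow = full_path(graph, c("B1+", "C+", "D1+", "E+")))
    list(graph = graph, contigs = list(paths$green), paths = paths)
  })
}

#' Random layered DAG with consistent overlaps
#'
#' Layers of 1-3 parallel edges joined all-to-all at shared junction k-mers;
#' every full path spells a valid sequence. Used for oracle-equivalence
#' testing of the codon search.
#'
#' @param n_layers Number of layers.
#' @param k Overlap length, default 4.
#' @param novel_range Range of per-edge novel lengths.
#' @param max_width Maximum edges per layer, default 3.
#' @param seed RNG seed.
#' @return An `asm_graph`.
#' @export
random_dag_graph <- function(n_layers = 5L, k = 4L, novel_range = c(6L, 20L),
                             max_width = 3L, seed = 1L) {
  with_seed(seed, {
    zs <- vapply(seq_len(n_layers + 1L), function(i) rand_dna(k), "")
    segs <- character(0)
    links <- NULL
    prev_ids <- character(0)
    for (l in seq_len(n_layers)) {
      w <- sample(seq_len(max_width), 1L)
      ids <- paste0("L", l, "E", seq_len(w))
      for (i in seq_along(ids)) {
        novel <- sample(seq(novel_range[1], novel_range[2]), 1L)
        segs[[ids[i]]] <- paste0(if (l > 1) zs[l] else rand_dna(k),
                                 rand_dna(novel), zs[l + 1L])
      }
      if (l > 1) {
        links <- rbind(links, expand.grid(from = paste0(prev_ids, "+"),
                                          to = paste0(ids, "+"),
                                          stringsAsFactors = FALSE))
      }
      prev_ids <- ids
    }
    asm_graph(segs, links, overlap = k)
  })
}
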