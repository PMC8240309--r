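# Graph model, GFA I/O, path spelling and orientation handling.

test_that("read_gfa builds the graph model and enforces its invariants", {
  f <- write_tmp_gfa(c("H\tVN:Z:1.0", "S\t1\tACGT"))
  g <- read_gfa(f)
  expect_length(g$seqs, 1)
  expect_identical(graph_succ(g, "1+"), character(0))

  f2 <- write_tmp_gfa(c("S\t1\tACGTA", "S\t2\tGTACC", "L\t1\t+\t2\t+\t3M"))
  g2 <- read_gfa(f2)
  expect_identical(graph_succ(g2, "1+"), "2+")
  expect_identical(graph_succ(g2, "2-"), "1-")  # bidirected mirror added

  expect_error(read_gfa(write_tmp_gfa(c("S\t1\t*"))), "without a sequence")
  expect_error(read_gfa(write_tmp_gfa(c(
    "S\t1\tACGTA", "S\t2\tGTACC", "S\t3\tACCGG",
    "L\t1\t+\t2\t+\t3M", "L\t2\t+\t3\t+\t4M"))), "inconsistent overlaps")
  expect_error(read_gfa(write_tmp_gfa(c(
    "S\t1\tACGTA", "L\t1\t+\t9\t+\t3M"))), "undeclared segment")
  expect_error(asm_graph(c(a = "ACGU")), "only A,C,G,T,N")
  expect_error(asm_graph(c(a = "ACG"), overlap = 3), "longer than the overlap")
})

test_that("coverage is read from DP and KC tags", {
  f <- write_tmp_gfa(c("S\t1\tACGTAACC\tDP:f:12.5",
                       "S\t2\tACCGTTTG\tKC:i:50",
                       "L\t1\t+\t2\t+\t3M"))
  g <- read_gfa(f)
  expect_equal(unname(g$coverage["1"]), 12.5)
  expect_equal(unname(g$coverage["2"]), 50 / (8 - 3))
})

test_that("gfa round trip is idempotent on the graph model", {
  g <- generate_fixture(n_bubbles = 2, seed = 11)$graph
  f <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, f)
  g2 <- read_gfa(f)
  f2 <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g2, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_identical(g$seqs, g2$seqs)
  expect_identical(g$overlap, g2$overlap)
  expect_equal(g$coverage, g2$coverage)
  for (s in c(paste0(names(g$seqs), "+"), paste0(names(g$seqs), "-")))
    expect_identical(graph_succ(g, s), graph_succ(g2, s))
})

test_that("spell_path follows the overlap-trimming concatenation rule", {
  g1 <- asm_graph(c(e = "ACGTACGT"))
  expect_identical(spell_path(g1, graph_path("e+", 2L, 6L)), "GTAC")

  g <- asm_graph(c(`1` = "ACGTA", `2` = "GTACC"),
                 data.frame(from = "1+", to = "2+"), overlap = 3)
  p <- full_path(g, c("1+", "2+"))
  expect_identical(spell_path(g, p), "ACGTACC")
  expect_identical(spell_path(g, rc_graph_path(g, p)), "GGTACGT")
  expect_error(spell_path(g, graph_path(c("2+", "1+"), 0L, 5L)), "disconnected")
})

test_that("spelling commutes with reverse complement on random paths", {
  cases <- 0
  for (seed in 1:25) {
    g <- random_dag_graph(n_layers = 3 + seed %% 3, seed = seed)
    set.seed(seed * 13)
    for (r in 1:5) {
      p <- random_walk_path(g)
      if (is.null(p)) next
      cases <- cases + 1
      expect_identical(spell_path(g, rc_graph_path(g, p)),
                       revcomp(spell_path(g, p)))
    }
  }
  expect_gte(cases, 100)
})

test_that("spelled length matches the offset arithmetic", {
  for (seed in 1:10) {
    g <- random_dag_graph(n_layers = 4, seed = seed)
    set.seed(seed)
    for (r in 1:5) {
      p <- random_walk_path(g)
      if (is.null(p)) next
      lens <- nchar(sapply(p$steps, function(s) g$seqs[[sub("[+-]$", "", s)]]))
      expected <- sum(lens) - g$overlap * (length(lens) - 1) -
        p$start_offset - (lens[length(lens)] - p$end_offset)
      expect_identical(nchar(spell_path(g, p)), as.integer(expected))
    }
  }
})

test_that("subpath_at returns the matching substring of the spelling", {
  g <- generate_fixture(n_bubbles = 1, seed = 3)$graph
  chain <- full_path(g, grep("v", c(paste0(sort(names(g$seqs)), "+")),
                             invert = TRUE, value = TRUE))
  full <- spell_path(g, chain)
  for (iv in list(c(0, 10), c(5, 300), c(297, 1000), c(0, nchar(full)))) {
    sub <- subpath_at(g, chain, iv[1], iv[2])
    expect_identical(spell_path(g, sub), substr(full, iv[1] + 1, iv[2]))
  }
})

test_that("contig paths are parsed from .paths files and P-lines, split at gaps", {
  g <- chain_graph(list("ACGTAACCG", "TTGCA", "GGAAC"), k = 3)
  f <- withr::local_tempfile()
  writeLines(c("NODE_1_length_19_cov_10", "e1+,e2+;", "e3+",
               "NODE_2_length_9_cov_5", "e1+"), f)
  tb <- read_spades_paths(f, g)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$part[tb$contig == "NODE_1_length_19_cov_10"], c(1L, 2L))
  expect_identical(tb$path[[1]]$steps, c("e1+", "e2+"))

  f2 <- write_tmp_gfa(c("S\t1\tACGTA", "S\t2\tGTACC", "L\t1\t+\t2\t+\t3M",
                        "P\tctg1\t1+,2+\t*"))
  tb2 <- read_gfa_paths(f2, read_gfa(f2))
  expect_identical(tb2$path[[1]]$steps, c("1+", "2+"))
})
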