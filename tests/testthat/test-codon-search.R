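# Frameshift-tracked BFS for start and stop codons.

test_that("stops adjacent to the anchor and across bubbles are found in frame", {
  # anchor ATG GCA on edge A; both branches carry an in-frame stop at
  # distance 6 (TAA on b1, TGA on b2)
  z1 <- "GGGG"
  g <- asm_graph(
    c(A = paste0("ATGGCA", z1),
      b1 = paste0(z1, "CCTAACCC"),
      b2 = paste0(z1, "CCTGACCC")),
    data.frame(from = c("A+", "A+"), to = c("b1+", "b2+")), overlap = 4)
  anchor <- graph_path("A+", 0L, 6L)
  st <- find_stop_codons(g, anchor, max_dist = 300)
  expect_equal(nrow(st), 2)
  expect_setequal(st$codon, c("TAA", "TGA"))
  expect_true(all(st$distance == 6))
  expect_true(all(st$distance %% 3 == 0))

  # a stop immediately after the anchor sits at distance 0
  g2 <- asm_graph(c(A = "ATGGCATAACCC"))
  st2 <- find_stop_codons(g2, graph_path("A+", 0L, 6L), max_dist = 300)
  expect_equal(st2$distance, 0L)
  expect_equal(st2$codon, "TAA")

  # the distance bound is respected: stop at max_dist + 3 is not returned
  expect_equal(nrow(find_stop_codons(g, anchor, max_dist = 3)), 0)
  expect_equal(nrow(find_stop_codons(g, anchor, max_dist = 6)), 2)
})

test_that("start search reports the anchor's own initiator at distance 0", {
  g <- asm_graph(c(A = "CCCTAACCCATGGCAGCATTT"))
  anchor <- graph_path("A+", 9L, 18L)
  st <- find_start_codons(g, anchor, max_dist = 30)
  d0 <- st[st$distance == 0, ]
  expect_equal(nrow(d0), 1)
  expect_equal(d0$codon, "ATG")
  expect_equal(d0$off, 9L)
  # the upstream in-frame TAA marks this start as after-stop
  expect_true(d0$after_stop)
})

test_that("upstream starts are found across branches with bacterial codons", {
  z <- "GGGG"
  f <- function(n) substr(strrep("CCA", ceiling(n / 3) + 1), 1, n)
  novelA <- paste0(f(6), "ATG", f(23))     # ATG ends 24 nt before the junction
  novelB <- paste0(f(6), "GTG", f(5))      # GTG ends 6 nt before the junction
  g <- asm_graph(
    c(PA = paste0(novelA, z), PB = paste0(novelB, z),
      E = paste0(z, "GCAGCAGCA")),
    data.frame(from = c("PA+", "PB+"), to = c("E+", "E+")), overlap = 4)
  anchor <- graph_path("E+", 4L, 13L)
  st <- find_start_codons(g, anchor, max_dist = 100)
  expect_setequal(st$codon, c("ATG", "GTG"))
  expect_setequal(st$distance, c(30L, 12L))
  # a restricted start set drops GTG
  st2 <- find_start_codons(g, anchor, max_dist = 100, start_set = "ATG")
  expect_equal(st2$codon, "ATG")
})

test_that("a Shine-Dalgarno-like motif upstream sets the has_sd flag", {
  g <- asm_graph(c(A = "TTAGGAGGTTTTTTTTATGGCAGCAGCA"))
  st <- find_start_codons(g, graph_path("A+", 16L, 25L), max_dist = 30)
  d0 <- st[st$distance == 0, ]
  expect_true(d0$has_sd)
  g2 <- asm_graph(c(A = "TTCTCTCCTTTTTTTTATGGCAGCAGCA"))
  st2 <- find_start_codons(g2, graph_path("A+", 16L, 25L), max_dist = 30)
  expect_false(st2[st2$distance == 0, ]$has_sd)
})

test_that("BFS codon sets equal the brute-force path-enumeration oracle", {
  checked <- 0
  for (seed in 1:40) {
    g <- random_dag_graph(n_layers = 3 + seed %% 5, seed = seed)
    a <- pick_dag_anchor(g)
    if (is.null(a)) next
    checked <- checked + 1
    md <- 60L
    expect_identical(site_keys(find_stop_codons(g, a, max_dist = md)),
                     oracle_stop_sites(g, a, md))
    sa <- find_start_codons(g, a, max_dist = md)
    expect_true(all(sa$distance %% 3 == 0))
    expect_identical(site_keys(sa[sa$distance > 0, ]),
                     oracle_start_sites(g, a, md))
  }
  expect_gte(checked, 30)
})

test_that("the search terminates on cyclic graphs", {
  segs <- c(X = paste0("ATGA", strrep("C", 20), "TTTT"),
            Y = paste0("TTTT", strrep("G", 18), "ATGA"))
  g <- asm_graph(segs, data.frame(from = c("X+", "Y+"), to = c("Y+", "X+")),
                 overlap = 4)
  anchor <- graph_path("X+", 0L, 12L)
  st <- find_stop_codons(g, anchor, max_dist = 3000)
  expect_true(nrow(st) >= 0)   # completion itself is the assertion
  sa <- find_start_codons(g, anchor, max_dist = 3000)
  expect_true(all(sa$distance %% 3 == 0))
})
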