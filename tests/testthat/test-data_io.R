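test_that("plain edge lists are read with self-loops dropped and duplicates collapsed", {
  f <- withr::local_tempfile()
  writeLines(c("A B", "B A", "A A", "B C"), f)
  g <- suppressMessages(read_network(f))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "B", "C"))

  # 10-line fixture with exactly one duplicate (P1 P2 / P2 P1) and one
  # self-loop (P5 P5): 10 - 2 = 8 edges survive
  f2 <- withr::local_tempfile()
  writeLines(c("# comment", "P1 P2", "P2 P1", "P5 P5", "P2 P3", "P3 P4",
               "P4 P5", "P5 P6", "P6 P1", "P1 P3", "P2 P6"), f2)
  g2 <- suppressMessages(read_network(f2))
  expect_equal(igraph::ecount(g2), 8)
  expect_equal(igraph::vcount(g2), 6)
})

test_that("malformed or empty edge lists are rejected with line context", {
  f <- withr::local_tempfile()
  writeLines(c("A B", "A B C"), f)
  expect_error(read_network(f), "line 2")

  f2 <- withr::local_tempfile()
  writeLines(c("# only a comment"), f2)
  expect_error(suppressMessages(read_network(f2)), "empty network")

  f3 <- withr::local_tempfile()
  writeLines("A A", f3)
  expect_error(suppressMessages(read_network(f3)), "empty network")
})

test_that("the BioGRID TAB dialect extracts systematic names and can restrict to physical edges", {
  row <- function(a, b, type) {
    paste(c("1", "100", "200", "10", "20", a, b, "SYMA", "SYMB", "-", "-",
            "Two-hybrid", type), collapse = "\t")
  }
  f <- withr::local_tempfile()
  writeLines(c("#BioGRID header line", row("YAL001C", "YBR001C", "physical"),
               row("YAL001C", "YCR001C", "genetic"),
               row("-", "YDR001C", "physical")), f)
  g <- suppressMessages(read_network(f, dialect = "biogrid_tab"))
  expect_equal(igraph::ecount(g), 2)  # placeholder row skipped
  g_phys <- suppressMessages(
    read_network(f, dialect = "biogrid_tab", physical_only = TRUE))
  expect_equal(igraph::ecount(g_phys), 1)
  expect_setequal(igraph::V(g_phys)$name, c("YAL001C", "YBR001C"))
})

test_that("network writing round-trips the edge set", {
  g <- random_graph(10, 0.3, seed = 11)
  f <- withr::local_tempfile()
  write_network(g, f)
  g2 <- suppressMessages(read_network(f))
  key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(key(g2), key(g))
})

test_that("expression files parse and reject ragged or non-numeric bodies", {
  f <- withr::local_tempfile()
  writeLines(c("protein\tS1\tS2\tS3\tS4",
               "A\t1\t2\t3\t4", "B\t5\t6\t7\t8", "C\t1\t1\t2\t2"), f)
  rec <- read_expression(f)
  expect_equal(rec$ids, c("A", "B", "C"))
  expect_equal(dim(rec$values), c(3L, 4L))
  expect_equal(rec$values[2L, ], c(S1 = 5, S2 = 6, S3 = 7, S4 = 8))

  f2 <- withr::local_tempfile()
  writeLines(c("protein\tS1\tS2", "A\t1"), f2)
  expect_error(read_expression(f2), "ragged")

  f3 <- withr::local_tempfile()
  writeLines(c("protein\tS1\tS2", "A\t1\t2", "B\tx\t3"), f3)
  expect_error(read_expression(f3), "row 3")

  f4 <- withr::local_tempfile()
  writeLines("protein\tS1\tS2", f4)
  expect_error(read_expression(f4), "no profiles")

  f5 <- withr::local_tempfile()
  writeLines(c("protein\tS1", "A\t1"), f5)
  expect_error(read_expression(f5), "at least 2 samples")
})

test_that("profile selection keeps the maximal-mean row, first occurrence on ties", {
  rec <- list(ids = c("P", "P", "Q", "R", "R"),
              values = rbind(c(1, 2, 3), c(4, 5, 6),     # P: means 2 and 5
                             c(0, 0, 0),                 # Q: single row
                             c(2, 2, 2), c(1, 2, 3)))    # R: tied means 2, 2
  expr <- select_profile(rec)
  expect_equal(rownames(expr), c("P", "Q", "R"))
  expect_equal(unname(expr["P", ]), c(4, 5, 6))   # maximal mean wins
  expect_equal(unname(expr["Q", ]), c(0, 0, 0))   # identity for singletons
  expect_equal(unname(expr["R", ]), c(2, 2, 2))   # first row wins the tie
})

test_that("orthology tables validate counts against n_reference", {
  f <- withr::local_tempfile()
  writeLines(c("#n_reference=99", "P1\t99", "P2\t33", "P3\t0", "P4\t12",
               "P5\t7"), f)
  orth <- read_orthology(f)
  expect_s3_class(orth, "orthology_table")
  expect_equal(orth$n_reference, 99L)
  expect_length(orth$counts, 5L)
  expect_equal(unname(orth$counts[c("P1", "P4")]), c(99L, 12L))

  f2 <- withr::local_tempfile()
  writeLines(c("#n_reference=99", "P2\t120"), f2)
  expect_error(read_orthology(f2), "exceeds n_reference")
  expect_error(read_orthology(f2, n_reference = 200), NA)

  f3 <- withr::local_tempfile()
  writeLines(c("#n_reference=10", "P1\t-2"), f3)
  expect_error(read_orthology(f3), "negative")

  f4 <- withr::local_tempfile()
  writeLines("P1\t5", f4)
  expect_error(read_orthology(f4), "n_reference not given")
})

test_that("the analysis universe is the sorted network-expression intersection", {
  g <- igraph::make_graph(~ A - B, B - C, C - A, C - D)
  expr <- matrix(rnorm(12), 4, 3,
                 dimnames = list(c("B", "C", "D", "E"), paste0("S", 1:3)))
  orth <- orthology_table(c(B = 3L, E = 5L), 10L)
  u <- suppressMessages(build_universe(g, expr, orth))
  expect_equal(u$proteins, c("B", "C", "D"))
  expect_equal(igraph::V(u$graph)$name, u$proteins)
  # induced edges: B-C, C-D survive; A's edges drop
  expect_equal(igraph::ecount(u$graph), 2)
  expect_equal(unname(u$orth_counts), c(3L, 0L, 0L))  # absent proteins get 0

  # idempotence: rebuilding from the restricted parts changes nothing
  u2 <- suppressMessages(build_universe(u$graph, u$expression,
                                        orthology_table(u$orth_counts,
                                                        u$n_reference)))
  expect_equal(u2$proteins, u$proteins)
  expect_equal(igraph::ecount(u2$graph), igraph::ecount(u$graph))
  expect_equal(u2$expression, u$expression)

  expect_error(suppressMessages(build_universe(
    g, matrix(0, 1, 2, dimnames = list("Z", NULL)), orth)), "empty universe")
})

test_that("a larger shared fixture induces the hand-counted universe", {
  # 12 network nodes, 9 shared with expression; induced edges counted by hand:
  # among shared nodes N01..N09 the generator wiring below keeps exactly the
  # edges with both endpoints <= N09
  set.seed(42)
  g <- random_graph(12, 0.35, seed = 42)
  shared <- sprintf("N%02d", 1:9)
  expr <- matrix(rnorm(9 * 4), 9, 4, dimnames = list(shared, paste0("S", 1:4)))
  el <- igraph::as_edgelist(g)
  expected_edges <- sum(el[, 1] %in% shared & el[, 2] %in% shared)
  u <- suppressMessages(build_universe(g, expr, orthology_table(
    stats::setNames(integer(0), character(0)), 5L)))
  expect_equal(u$proteins, shared)
  expect_equal(igraph::ecount(u$graph), expected_edges)
  expect_lte(igraph::ecount(u$graph), igraph::ecount(g))
})
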