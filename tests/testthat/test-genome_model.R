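# Signed gene-order model, marker view and gapped adjacency multisets.

test_that("marker expansion follows the head/tail convention", {
  expect_equal(marker_sequence("a"), c("a_t", "a_h", "O_t", "O_h"))
  expect_equal(marker_sequence(c("1", "-2")),
               c("1_t", "1_h", "2_h", "2_t", "O_t", "O_h"))
  expect_equal(marker_sequence(c("a", "b"), circular = TRUE),
               c("a_t", "a_h", "b_t", "b_h"))
  expect_error(marker_sequence(character(0)), "empty")
})

test_that("genome constructor enforces the reserved telomere symbol", {
  g <- genome(list(c("+1", "-2", "3")), name = "A")
  expect_equal(g$chrom[[1]], c("1", "-2", "3"))
  expect_error(genome(list(c("a", "O"))), "reserved")
  expect_error(genome(list(character(0))), "empty")
  expect_equal(mult("O", genome(list("a", "b"))), 2L)
  expect_equal(mult("O", genome(list("a"), circular = TRUE)), 0L)
})

test_that("gapped adjacency multisets reproduce the worked tandem-array case", {
  g <- genome(list(c("a", "a", "b", "a", "a", "c")), name = "G")
  expect_equal(alpha_adjacencies(g, "a", "left", 1),
               sort(c("O", "a", "b", "a")))
  expect_equal(alpha_adjacencies(g, "a", "right", 2),
               sort(c("a", "b", "a", "c", "-a", "-b", "-a", "-c")))
})

test_that("direct adjacencies of a signed permutation read both sides", {
  g <- genome(list(c("1", "-2", "3", "-4")), name = "H")
  expect_equal(alpha_adjacencies(g, "1", "right", 1), "-2")
  expect_equal(alpha_adjacencies(g, "2", "right", 1), "-1")
  expect_equal(alpha_adjacencies(g, "2", "left", 1), "-3")
  expect_equal(alpha_adjacencies(g, "3", "left", 1), "-2")
})

test_that("a lone gene on a linear chromosome neighbours only the telomere", {
  g <- genome(list("g"), name = "K")
  expect_equal(alpha_adjacencies(g, "g", "left", 1), "O")
  expect_equal(alpha_adjacencies(g, "g", "right", 1), "O")
  expect_error(alpha_adjacencies(g, "zz", "left", 1), "unknown")
  expect_error(alpha_adjacencies(g, "g", "left", 0), "alpha")
})

test_that("multiset intersection takes the minimum of counts", {
  expect_equal(multiset_intersection_size(c("a", "a", "b"), c("a", "b", "b")), 2L)
  x <- c("a", "-a", "b", "b")
  expect_equal(multiset_intersection_size(x, x), length(x))
  expect_equal(multiset_intersection_size("a", "-a"), 0L)
  expect_equal(multiset_intersection_size(character(0), "a"), 0L)
})

test_that("per-gene and per-genome conservation counts match hand values", {
  ab <- genome(list(c("a", "b")), name = "A")
  ba <- genome(list(c("b", "a")), name = "B")
  expect_equal(adj_cons_gene("a", 1, ab, ab), 2L)
  expect_equal(adj_cons_gene("a", 1, ab, ba), 0L)
  expect_equal(adj_cons_genomes(1, ab, ab), 6L)  # 2 per gene, genes O a b
  g1 <- genome(list(c("x", "y")), name = "X")
  expect_equal(adj_cons_genomes(1, ab, g1), 0L)  # only O shared, ends differ
  expect_equal(adj_cons_genomes(2, ab, ba), adj_cons_genomes(2, ba, ab))
})

test_that("self-intersection doubles the one-sided multiset size", {
  set.seed(41)
  for (i in 1:5) {
    g <- random_test_genome(8L, 4L, n_chrom = 2L)
    gene <- sample(setdiff(gene_set(g), "O"), 1L)
    la <- alpha_adjacencies(g, gene, "left", 2)
    expect_equal(adj_cons_gene(gene, 2, g, g),
                 length(la) + length(alpha_adjacencies(g, gene, "right", 2)))
  }
})

test_that("adjacency extraction agrees with the substring-rule oracle", {
  set.seed(7)
  for (i in 1:25) {
    g <- random_test_genome(sample(4:10, 1), sample(2:5, 1),
                            n_chrom = sample(1:2, 1),
                            circular = sample(c(TRUE, FALSE), 1))
    alpha <- sample(1:5, 1)
    for (gene in setdiff(gene_set(g), "O")) {
      expect_equal(alpha_adjacencies(g, gene, "left", alpha),
                   oracle_left_adjacencies(g, gene, alpha),
                   info = sprintf("left i=%d gene=%s alpha=%d", i, gene, alpha))
      expect_equal(alpha_adjacencies(g, gene, "right", alpha),
                   oracle_right_adjacencies(g, gene, alpha),
                   info = sprintf("right i=%d gene=%s alpha=%d", i, gene, alpha))
    }
  }
})

test_that("multiset size obeys the alpha * multiplicity law", {
  # circular chromosome of distinct genes: equality without exclusion
  g <- genome(list(letters[1:9]), circular = TRUE, name = "C")
  for (alpha in 1:5)
    expect_length(alpha_adjacencies(g, "e", "left", alpha,
                                    strict_gap_exclusion = FALSE), alpha)
  # never above alpha * mult, with or without exclusion
  set.seed(11)
  for (i in 1:10) {
    g <- random_test_genome(sample(3:9, 1), sample(2:4, 1))
    alpha <- sample(1:4, 1)
    for (gene in setdiff(gene_set(g), "O")) {
      for (strict in c(TRUE, FALSE))
        expect_lte(length(alpha_adjacencies(g, gene, "left", alpha, strict)),
                   alpha * mult(gene, g))
    }
  }
})

test_that("adjacency multisets are intrinsic to the physical genome", {
  # rewriting a chromosome in the opposite direction (reverse + sign
  # flip) describes the same molecule, so left and right multisets are
  # unchanged; negating signs without reversing swaps every occurrence's
  # reading direction, turning right multisets into left ones
  set.seed(13)
  for (i in 1:10) {
    g <- random_test_genome(sample(4:9, 1), sample(2:4, 1), n_chrom = 2L)
    rw <- g
    rw$chrom <- lapply(g$chrom, function(ch) rev(neg_tok(ch)))
    fl <- g
    fl$chrom <- lapply(g$chrom, neg_tok)
    alpha <- sample(1:4, 1)
    for (gene in setdiff(gene_set(g), "O")) {
      la <- alpha_adjacencies(g, gene, "left", alpha)
      expect_equal(alpha_adjacencies(rw, gene, "left", alpha), la,
                   info = sprintf("rewrite i=%d gene=%s alpha=%d", i, gene, alpha))
      expect_equal(alpha_adjacencies(fl, gene, "left", alpha),
                   alpha_adjacencies(g, gene, "right", alpha),
                   info = sprintf("flip i=%d gene=%s alpha=%d", i, gene, alpha))
    }
  }
})

test_that("adjacency multisets grow monotonically with the gap bound", {
  set.seed(17)
  for (i in 1:8) {
    g <- random_test_genome(sample(4:10, 1), sample(2:5, 1))
    gene <- sample(setdiff(gene_set(g), "O"), 1)
    prev <- character(0)
    for (alpha in 1:5) {
      cur <- alpha_adjacencies(g, gene, "left", alpha,
                               strict_gap_exclusion = FALSE)
      expect_equal(multiset_intersection_size(prev, cur), length(prev),
                   info = sprintf("i=%d alpha=%d", i, alpha))
      prev <- cur
    }
  }
})

test_that("each conserved junction is counted twice at direct gap", {
  set.seed(19)
  for (i in 1:10) {
    ga <- random_test_genome(sample(4:9, 1), 4L)
    gb <- random_test_genome(sample(4:9, 1), 4L, name = "H")
    expect_identical(adj_cons_genomes(1, ga, gb) %% 2L, 0L)
  }
})
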