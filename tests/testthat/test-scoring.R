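# Conservation scoring: branch matches, the inside-outside DP against an
# exhaustive oracle, and the adjacency-specific singleton scores.

test_that("branch match doubles parent counts across WGD branches", {
  expect_equal(branch_match(c("a", "a"), c("a", "b")), 1L)
  expect_equal(branch_match("a", c("a", "a"), parent_is_wgd = TRUE), 2L)
  expect_equal(branch_match(bottom_token, c("a", "b")), 0L)
  expect_equal(branch_match(c(bottom_token, bottom_token),
                            c(bottom_token, bottom_token)), 0L)
  expect_equal(branch_match(c("a", "b"), c("b", "a", "c")), 2L)
})

two_leaf_tree <- function(gA, gB) {
  assign_gene_content(read_species_tree("(A,B)R;", list(gA, gB)))
}

test_that("two identical leaves give root score 2 for the shared adjacency", {
  st <- two_leaf_tree(genome(list(c("a", "b")), name = "A"),
                      genome(list(c("a", "b")), name = "B"))
  tabs <- compute_score_tables("b", "left", 1, st)
  i <- which(vapply(tabs$candidates$R, identical, logical(1), y = "a"))
  expect_equal(tabs$total$R[i], 2)
  j <- which(vapply(tabs$candidates$R, identical, logical(1), y = bottom_token))
  expect_equal(tabs$total$R[j], 0)
  sc <- score_tables_at_node("R", 1, c("a", "b"), st, method = "total")
  expect_equal(unname(sc$L$b["a"]), 2)
  expect_equal(unname(sc$R$a["b"]), 2)
  expect_equal(unname(sc$L$a[bottom_token]), 0)
})

test_that("a gene confined to one leaf scores zero everywhere", {
  st <- two_leaf_tree(genome(list(c("a", "g")), name = "A"),
                      genome(list("a"), name = "B"))
  sc <- score_tables_at_node("R", 1, "a", st, method = "total")
  expect_true(all(sc$L$a >= 0))
  # g is absent at R: scoring it there must fail
  expect_error(score_tables_at_node("R", 1, "g", st), "mult != 1|absent")
})

test_that("the DP equals exhaustive maximisation on small instances", {
  checked <- 0L
  for (seed in 1:12) {
    st <- random_score_instance(seed)
    if (is.null(st)) next
    genes <- setdiff(rownames(st$content), "O")
    genes <- genes[st$content[genes, st$root] >= 1L &
                   apply(st$content[genes, , drop = FALSE], 1, max) <= 2L]
    for (gene in head(genes, 2)) {
      for (side in c("left", "right")) {
        alpha <- sample(1:2, 1)
        tabs <- compute_score_tables(gene, side, alpha, st)
        oracle <- oracle_score_totals(st, gene, side, alpha, "R")
        expect_equal(tabs$total$R, oracle,
                     info = sprintf("seed=%d gene=%s side=%s", seed, gene, side))
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 8L)
})

test_that("the compiled kernel matches the reference DP at singleton queries", {
  for (seed in 13:20) {
    st <- random_score_instance(seed)
    if (is.null(st)) next
    ctx <- gapadj:::make_score_context(st)
    genes <- setdiff(rownames(st$content), "O")
    genes <- genes[st$content[genes, st$root] == 1L]
    for (gene in head(genes, 2)) {
      alpha <- sample(1:3, 1)
      tabs <- compute_score_tables(gene, "left", alpha, st)
      fast <- gapadj:::score_gene_at(ctx, gene, "left", alpha, st$root, "total")
      ref <- vapply(seq_along(tabs$candidates$R), function(i) {
        x <- tabs$candidates$R[[i]]
        if (length(x) == 1L) tabs$total$R[i] else NA_real_
      }, numeric(1))
      names(ref) <- vapply(tabs$candidates$R, function(x)
        if (length(x) == 1L) x else NA_character_, character(1))
      ref <- ref[!is.na(ref)]
      expect_equal(fast[names(ref)], ref[names(ref)],
                   info = sprintf("seed=%d gene=%s", seed, gene))
    }
  }
})

test_that("scores are invariant to chromosome rewriting and mirror sides", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 12, rmax = 2, seed = 31)
  st <- assign_gene_content(st)
  rw <- st  # same molecules written in the opposite direction
  for (i in which(rw$kind == "leaf"))
    rw$genomes[[i]]$chrom <- lapply(rw$genomes[[i]]$chrom,
                                    function(ch) rev(neg_tok(ch)))
  rw <- assign_gene_content(rw)
  fl <- st  # signs negated without reversal: left and right swap
  for (i in which(fl$kind == "leaf"))
    fl$genomes[[i]]$chrom <- lapply(fl$genomes[[i]]$chrom, neg_tok)
  fl <- assign_gene_content(fl)
  for (gene in c("3", "7")) {
    for (method in c("adjacency", "total")) {
      l1 <- score_tables_at_node("SIGMA", 2, gene, st, method = method)$L[[gene]]
      l_rw <- score_tables_at_node("SIGMA", 2, gene, rw, method = method)$L[[gene]]
      expect_equal(l1, l_rw, info = paste("rewrite", gene, method))
      r_fl <- score_tables_at_node("SIGMA", 2, gene, fl, method = method)$R[[gene]]
      expect_equal(l1, r_fl, info = paste("flip", gene, method))
    }
  }
})

test_that("singleton scores never exceed the conservation capacity", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 15, rmax = 3, seed = 37)
  st <- assign_gene_content(st)
  sc <- score_tables_at_node("SIGMA", 3, c("2", "9", "O"), st)
  for (g in names(sc$L)) {
    cap <- conservation_capacity(g, st)
    expect_true(all(sc$L[[g]] <= cap), info = g)
    expect_true(all(sc$R[[g]] <= cap), info = g)
  }
})

test_that("adjacency-specific scores count free internal carriage", {
  # identical leaves: the true adjacency reaches capacity, the wildcard
  # only the internal branches
  gs <- lapply(c("A", "B", "C", "D", "E", "F"), function(n)
    genome(list(c("a", "b", "c")), name = n))
  st <- assign_gene_content(read_species_tree(
    "((((A,B)AB,C)ABC,(D,E)DE)SIGMA,F)RHO;", gs))
  sc <- score_tables_at_node("SIGMA", 1, "b", st)
  expect_equal(unname(sc$L$b["a"]), conservation_capacity("b", st))  # 10
  expect_equal(unname(sc$L$b[bottom_token]), 4)  # internal branches only
  expect_equal(unname(sc$R$b["c"]), 10)
})

test_that("labeled-tree conservation is bounded by summed best scores", {
  # the displayed decomposition bounds direct-adjacency conservation:
  # candidate multisets hold mult(g, u) elements, the size of LA(g, 1, .)
  for (seed in c(43, 47)) {
    st <- simulate_evolution(six_leaf_fixture(), n_genes = 8, rmax = 1,
                             seed = seed)
    st <- assign_gene_content(st)
    total <- adj_cons_tree(1, st)
    bound <- 0
    for (gene in rownames(st$content)) {
      if (st$content[gene, st$root] == 0L) next
      tabs_l <- compute_score_tables(gene, "left", 1, st)
      tabs_r <- compute_score_tables(gene, "right", 1, st)
      nm <- st$name[st$root]
      bound <- bound + max(tabs_l$total[[nm]]) + max(tabs_r$total[[nm]])
    }
    expect_lte(total, bound)
  }
})

test_that("multiplicities above the cap are rejected with the gene named", {
  g16 <- genome(list(rep("a", 16)), name = "A")
  st <- assign_gene_content(read_species_tree(
    "(A,B)R;", list(g16, genome(list(rep("a", 16)), name = "B"))))
  expect_error(compute_score_tables("a", "left", 1, st, mult_cap = 4),
               "cap")
})
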