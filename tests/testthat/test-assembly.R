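# Junction graph, TSP assembly, threshold cutting and the main loop.

identical_six_leaf <- function(genes = c("1", "2", "3", "4", "5")) {
  gs <- lapply(c("A", "B", "C", "D", "E", "F"), function(n)
    genome(list(genes), name = n))
  assign_gene_content(read_species_tree(
    "((((A,B)AB,C)ABC,(D,E)DE)SIGMA,F)RHO;", gs))
}

test_that("junction weights follow the capacity-normalised formula", {
  st <- identical_six_leaf(c("g", "h"))
  cars <- car_set(list("g", "h"))
  # hand-made score maps: L(g,h)=4, R(h,g)=4 against capacity 10 each
  mk <- function(v) stats::setNames(c(v, 0), c("x", bottom_token))
  scores <- list(
    L = list(g = stats::setNames(c(4, 0), c("h", bottom_token)),
             h = mk(0), O = mk(0)),
    R = list(h = stats::setNames(c(4, 0), c("g", bottom_token)),
             g = mk(0), O = mk(0)))
  gr <- build_junction_graph(cars, scores, st)
  # the scored junction places h before g: exit CAR2 end, enter CAR1 start
  expect_equal(gr$M[4, 1], (4 + 4) / (10 + 10))
  expect_equal(gr$M[1, 4], gr$M[4, 1])  # symmetric
  # the reverse placement (g before h) is unsupported: wildcard fallback 0
  expect_equal(gr$M[2, 3], 0)
  expect_error(build_junction_graph(car_set(list()), scores, st), "empty")
})

test_that("conservation capacity counts carrier branches with WGD doubling", {
  st <- identical_six_leaf()
  expect_equal(conservation_capacity("3", st), 10L)  # 10 branches, mult 1
  expect_equal(conservation_capacity("3", st), max_adj("3", st) - 1L)
  gA <- genome(list(c("a", "b", "a", "b")), name = "A")
  gB <- genome(list(c("a", "b", "a", "b")), name = "B")
  gC <- genome(list(c("a", "b", "a", "b")), name = "C")
  stw <- assign_gene_content(read_species_tree("(A,(B,C)BC)R3_WGD;",
                                               list(gA, gB, gC)))
  # branches: wgd->R3 doubles (2), R3->A, R3->BC, BC->B, BC->C carry 2 each
  expect_equal(conservation_capacity("a", stw), 10L)
  expect_equal(conservation_capacity("a", stw, wgd_double_match = FALSE), 9L)
})

test_that("perfectly conserved junctions weigh 1 and assemble the genome", {
  st <- identical_six_leaf()
  res <- gapadj(st, "SIGMA", seed = 5)
  expect_equal(length(res$cars), 1L)
  car <- res$cars[[1]]
  if (car[1] == "-5") car <- rev(gapadj:::negate_tok(car))
  expect_equal(car, c("1", "2", "3", "4", "5"))
  expect_true(all(attr(res$cars[[1]], "join_alpha") == 1L))
  expect_true(all(res$junctions$weight >= res$tau))
})

test_that("the exact solver matches exhaustive permutation search", {
  set.seed(61)
  for (i in 1:6) {
    K <- sample(2:4, 1)
    E <- 2L * K + 1L
    M <- matrix(stats::runif(E * E), E, E)
    M <- (M + t(M)) / 2; diag(M) <- 0
    graph <- structure(list(M = M, cars = as.list(letters[1:K]),
                            fac = rep("x", E)), class = "junction_graph")
    tour <- solve_tsp(graph, seed = i)
    expect_true(tour$exact)
    expect_equal(tour$weight, oracle_best_tour_weight(graph), tolerance = 1e-9)
    expect_setequal(tour$order, seq_len(K))
  }
})

test_that("the heuristic matches the exact optimum on small instances", {
  set.seed(67)
  for (i in 1:4) {
    K <- sample(5:6, 1)
    E <- 2L * K + 1L
    M <- matrix(stats::runif(E * E), E, E)
    M <- (M + t(M)) / 2; diag(M) <- 0
    graph <- structure(list(M = M, cars = as.list(letters[1:K]),
                            fac = rep("x", E)), class = "junction_graph")
    exact <- solve_tsp(graph, seed = i, exact_limit = 9L)
    heur <- solve_tsp(graph, seed = i, exact_limit = 0L, restarts = 6L)
    expect_false(heur$exact)
    expect_gte(heur$weight + 1e-9, 0.97 * exact$weight)
  }
})

test_that("cutting keeps strong junctions and concatenates runs", {
  st <- identical_six_leaf(c("a", "b", "c"))
  cars <- car_set(list(c("a", "b"), "c"))
  ctx_scores <- score_tables_at_node("SIGMA", 1, c("a", "b", "c", "O"), st)
  graph <- build_junction_graph(cars, ctx_scores, st)
  tour <- solve_tsp(graph, seed = 2)
  out_all <- cut_tour(tour, graph, tau = 0.7, alpha = 1L)
  expect_equal(length(out_all), 1L)
  car <- out_all[[1]]
  if (car[1] == "-c") car <- rev(gapadj:::negate_tok(car))
  expect_equal(car, c("a", "b", "c"))
  # an impossible threshold keeps the CAR set (up to orientation)
  out_none <- cut_tour(tour, graph, tau = 1.01, alpha = 1L)
  expect_equal(length(out_none), length(cars))
  norm <- function(car) {
    s <- paste(car, collapse = " ")
    r <- paste(rev(gapadj:::negate_tok(car)), collapse = " ")
    min(s, r)
  }
  expect_setequal(vapply(out_none, norm, character(1)),
                  vapply(list(c("a", "b"), "c"), norm, character(1)))
})

test_that("no rearrangements means perfect recovery of the ancestor", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 40, n_chromosomes = 2,
                           rmax = 0, seed = 71)
  truth <- st$genomes[[match("SIGMA", st$name)]]
  res <- gapadj(st, "SIGMA", seed = 71)
  expect_equal(length(res$cars), length(truth$chrom))
  expect_equal(error_rate(res, truth, max_alpha = 5)$error_rate, 0)
  norm <- function(car) {
    s <- paste(car, collapse = " ")
    r <- paste(rev(gapadj:::negate_tok(car)), collapse = " ")
    min(s, r)
  }
  expect_setequal(vapply(res$cars, norm, character(1)),
                  vapply(truth$chrom, norm, character(1)))
})

test_that("CAR counts never increase over iterations", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 40, rmax = 6,
                           seed = 73)
  res <- gapadj(st, "SIGMA", seed = 73, max_alpha = 12)
  expect_true(all(diff(res$log$n_cars) <= 0))
  expect_true(all(res$junctions$weight >= res$tau))
})

test_that("reversing all inputs yields the same CARs up to reversal", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 25, rmax = 4,
                           seed = 79)
  rt <- st
  for (i in which(rt$kind == "leaf"))
    rt$genomes[[i]]$chrom <- lapply(rt$genomes[[i]]$chrom,
                                    function(ch) rev(neg_tok(ch)))
  res1 <- gapadj(st, "SIGMA", seed = 79, max_alpha = 8)
  res2 <- gapadj(rt, "SIGMA", seed = 79, max_alpha = 8)
  norm <- function(car) {
    s <- paste(car, collapse = " ")
    r <- paste(rev(gapadj:::negate_tok(car)), collapse = " ")
    min(s, r)
  }
  expect_setequal(vapply(res1$cars, norm, character(1)),
                  vapply(res2$cars, norm, character(1)))
})

test_that("the loop is deterministic for a fixed seed", {
  st <- simulate_evolution(six_leaf_fixture(), n_genes = 30, rmax = 5,
                           seed = 83)
  r1 <- gapadj(st, "SIGMA", seed = 83, max_alpha = 6)
  r2 <- gapadj(st, "SIGMA", seed = 83, max_alpha = 6)
  expect_identical(lapply(r1$cars, as.vector), lapply(r2$cars, as.vector))
  expect_identical(r1$log, r2$log)
})
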