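# CAR assembly: junction graph over CAR extremities, heaviest Hamiltonian
# cycle, threshold cut, iterated over increasing gap bounds.

#' Construct a CAR set
#'
#' @param cars list of character vectors of signed gene tokens
#'   (Contiguous Ancestral Regions; never contain `O`).
#' @return object of class `car_set`.
#' @export
car_set <- function(cars) {
  cars <- lapply(cars, function(x) {
    a <- attr(x, "join_alpha")  # junction provenance survives cleaning
    y <- sub("^\\+", "", as.character(x))
    if (!is.null(a)) attr(y, "join_alpha") <- a
    y
  })
  if (any(vapply(cars, function(x) length(x) == 0L, logical(1))))
    stop("empty CAR")
  if (any(vapply(cars, function(x) any(gene_of(x) == "O"), logical(1))))
    stop("a CAR may not contain the telomeric gene O")
  structure(cars, class = "car_set")
}

#' @export
print.car_set <- function(x, ...) {
  cat(sprintf("<car_set> %d CAR(s), %d genes\n", length(x), sum(lengths(x))))
  for (i in seq_along(x))
    cat(sprintf("  CAR%d: %s\n", i, paste(x[[i]], collapse = " ")))
  invisible(x)
}

# out-facing signed token of each extremity: CAR i contributes extremity
# 2i-1 (start; facing token is the negated first gene) and 2i (end; the
# last gene); the O vertex is extremity 2K+1.
extremity_tokens <- function(cars) {
  fac <- character(2L * length(cars) + 1L)
  for (i in seq_along(cars)) {
    fac[2L * i - 1L] <- negate_tok(cars[[i]][1L])
    fac[2L * i] <- cars[[i]][length(cars[[i]])]
  }
  fac[2L * length(cars) + 1L] <- "O"
  fac
}

# score lookup with wildcard fallback for tokens never observed
score_lookup <- function(map, token) {
  v <- map[token]
  v[is.na(v)] <- map[[bottom_token]]
  unname(v)
}

#' Conservation capacity of a gene over the tree
#'
#' The largest side-adjacency conservation score any labeling can reach
#' for the gene: the sum over carrier branches (u, v) of
#' `min((1 + [u is WGD]) * mult(g, u), mult(g, v))` (the telomeric gene
#' `O` is scored per copy, so its multiplicities are capped at 1). On a
#' tree without WGD nodes and single-copy genes this is the carrier
#' subtree's branch count, `max_adj(g) - 1`; junction weights divided by
#' it lie in [0, 1] and the cut threshold reads as the conserved
#' fraction of achievable adjacencies.
#'
#' @param gene unsigned gene symbol.
#' @param st a `species_tree` with content assigned.
#' @param wgd_double_match count WGD branches with doubled parent copies.
#' @return non-negative integer.
#' @export
conservation_capacity <- function(gene, st, wgd_double_match = TRUE) {
  stopifnot(!is.null(st$content))
  if (!gene %in% rownames(st$content)) return(0L)
  m <- st$content[gene, ]
  if (gene == "O") m <- pmin(m, 1L)
  total <- 0L
  for (v in seq_len(n_nodes(st))) {
    u <- st$parent[v]
    if (is.na(u) || m[u] == 0L || m[v] == 0L) next
    w <- if (st$kind[u] == "wgd" && wgd_double_match) 2L else 1L
    total <- total + min(w * m[u], m[v])
  }
  total
}

#' Build the junction graph over CAR extremities
#'
#' Vertices are the two extremities of each CAR plus one O vertex. The
#' junction placing signed gene a immediately before signed gene b is
#' weighted `(score_right(a -> b) + score_left(b <- a)) / (C(|a|) +
#' C(|b|))`, where the two scores are the tree-wide conservation values
#' of the corresponding singleton adjacency at the target node (genes
#' facing out of a reversed CAR are read with flipped signs) and C is
#' [conservation_capacity()]. The symmetric capacity normalisation keeps
#' weights in [0, 1] on any tree (including WGD branches, which can
#' conserve two copies of an adjacency), so the cut threshold reads as
#' the conserved fraction of achievable adjacencies;
#' `literal_normalization` instead divides by the node count
#' `MaxAdj(g, S)` of the downstream gene alone.
#'
#' @param cars a `car_set`.
#' @param scores output of [score_tables_at_node()] for the genes at CAR
#'   extremities (and `"O"`).
#' @param st the `species_tree` (content assigned), used for the
#'   normalising capacities.
#' @param literal_normalization divide by the downstream gene's node
#'   count `MaxAdj` only.
#' @param wgd_double_match passed to [conservation_capacity()].
#' @return object of class `junction_graph`: the weight matrix over
#'   extremities, the CAR set and the facing tokens.
#' @export
build_junction_graph <- function(cars, scores, st,
                                 literal_normalization = FALSE,
                                 wgd_double_match = TRUE) {
  if (length(cars) == 0L) stop("empty CAR set")
  fac <- extremity_tokens(cars)
  E <- length(fac)
  genes <- gene_of(fac)
  sgn <- sign_of(fac)
  norm <- if (literal_normalization)
    vapply(unique(genes), max_adj, numeric(1), st = st)[genes]
  else
    pmax(1, vapply(unique(genes), conservation_capacity, numeric(1),
                   st = st, wgd_double_match = wgd_double_match)[genes])
  enter <- negate_tok(fac)  # the gene read when entering at an extremity
  # junction (exit e, enter f) places x = fac[e] before y = enter[f];
  # its weight sums the conservation score seen from x's right side and
  # from y's left side (a gene facing out of a reversed CAR is read with
  # flipped sign, swapping its left and right score tables)
  SR <- matrix(0, E, E)  # SR[e, f]: score of pair (fac[e] -> enter[f]), x's side
  SL <- matrix(0, E, E)  # SL[e, f]: same pair seen from enter[f]'s side
  for (e in seq_len(E)) {
    g <- genes[e]
    SR[e, ] <- if (sgn[e] > 0) score_lookup(scores$R[[g]], enter)
               else score_lookup(scores$L[[g]], negate_tok(enter))
  }
  for (f in seq_len(E)) {
    g <- genes[f]  # gene_of(enter[f]) == genes[f]
    SL[, f] <- if (sgn[f] > 0) score_lookup(scores$R[[g]], negate_tok(fac))
               else score_lookup(scores$L[[g]], fac)
  }
  denom <- if (literal_normalization) matrix(norm, E, E, byrow = TRUE)
           else outer(norm, norm, "+")
  M <- (SR + SL) / denom
  M <- (M + t(M)) / 2  # junction weights are orientation-symmetric
  diag(M) <- 0
  for (i in seq_along(cars)) M[2L * i - 1L, 2L * i] <- M[2L * i, 2L * i - 1L] <- 0
  structure(list(M = M, cars = cars, fac = fac), class = "junction_graph")
}

#' @export
print.junction_graph <- function(x, ...) {
  cat(sprintf("<junction_graph> %d CARs, %d vertices\n",
              length(x$cars), length(x$fac)))
  invisible(x)
}

#' Heaviest Hamiltonian cycle through the junction graph
#'
#' Each CAR is entered at one extremity and exited at the other (internal
#' pairings are mandatory); the cycle passes once through the O vertex.
#' Instances with at most `exact_limit` CARs are solved exactly by
#' dynamic programming over subsets; larger ones by seeded greedy
#' construction with 2-opt improvement and randomized restarts.
#'
#' @param graph a `junction_graph`.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param exact_limit largest CAR count solved exactly.
#' @param restarts randomized restarts of the heuristic.
#' @return list with `order` (CAR indices), `orient` (0 forward,
#'   1 reversed), `weight` (total), `exact` (logical).
#' @export
solve_tsp <- function(graph, seed = NULL, exact_limit = 9L, restarts = 3L) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(graph$cars)
  res <- tsp_solve_cpp(graph$M, K, as.integer(exact_limit),
                       as.integer(restarts))
  res$order <- res$order + 1L
  res
}

# weights of the K+1 junctions along a tour (O-in, between cities, O-out)
tour_junction_weights <- function(tour, graph) {
  K <- length(tour$order)
  Ov <- 2L * K + 1L
  inx <- function(c, o) 2L * (c - 1L) + o + 1L
  outx <- function(c, o) 2L * (c - 1L) + 2L - o
  w <- numeric(K + 1L)
  w[1L] <- graph$M[Ov, inx(tour$order[1L], tour$orient[1L])]
  if (K > 1L) for (i in seq_len(K - 1L))
    w[i + 1L] <- graph$M[outx(tour$order[i], tour$orient[i]),
                         inx(tour$order[i + 1L], tour$orient[i + 1L])]
  w[K + 1L] <- graph$M[outx(tour$order[K], tour$orient[K]), Ov]
  w
}

#' Cut weak junctions and concatenate the survivors
#'
#' The O vertex is always cut; every junction of weight below `tau` is
#' cut; maximal surviving runs of CARs are concatenated (reversing CARs
#' traversed backwards, with sign flips) into the new CAR set.
#'
#' @param tour result of [solve_tsp()].
#' @param graph the `junction_graph` the tour was computed on.
#' @param tau cut threshold in [0, 1].
#' @param alpha gap bound recorded on the junctions created by this cut
#'   (provenance used by [error_rate()]).
#' @return a `car_set`; each CAR carries a `join_alpha` attribute (the
#'   iteration that created each internal junction) and the set carries a
#'   `seams` attribute describing the junctions kept by this cut.
#' @export
cut_tour <- function(tour, graph, tau, alpha = NA_integer_) {
  K <- length(tour$order)
  w <- tour_junction_weights(tour, graph)
  oriented <- vector("list", K)
  jalpha <- vector("list", K)
  for (i in seq_len(K)) {
    g <- graph$cars[[tour$order[i]]]
    a <- attr(g, "join_alpha")
    if (is.null(a)) a <- rep(NA_integer_, max(0L, length(g) - 1L))
    if (tour$orient[i] == 1L) { g <- rev(negate_tok(as.vector(g))); a <- rev(a) }
    oriented[[i]] <- as.vector(g)
    jalpha[[i]] <- a
  }
  keep <- w >= tau
  keep[c(1L, K + 1L)] <- FALSE  # junctions at O
  out <- list()
  seams <- data.frame(left = character(0), right = character(0),
                      weight = numeric(0))
  run <- oriented[[1L]]
  run_a <- jalpha[[1L]]
  if (K > 1L) for (i in seq_len(K - 1L)) {
    if (keep[i + 1L]) {
      seams <- rbind(seams, data.frame(left = run[length(run)],
                                       right = oriented[[i + 1L]][1L],
                                       weight = w[i + 1L]))
      run <- c(run, oriented[[i + 1L]])
      run_a <- c(run_a, alpha, jalpha[[i + 1L]])
    } else {
      out <- c(out, list(structure(run, join_alpha = run_a)))
      run <- oriented[[i + 1L]]
      run_a <- jalpha[[i + 1L]]
    }
  }
  out <- c(out, list(structure(run, join_alpha = run_a)))
  res <- car_set(out)
  attr(res, "seams") <- seams
  res
}

#' Iterative gapped-adjacency ancestral genome inference
#'
#' Initialises one CAR per gene of the target node's content, then for
#' `alpha = 1, ..., max_alpha`: scores the singleton gapped adjacencies of
#' the genes at current CAR extremities, builds the junction graph,
#' solves the heaviest-Hamiltonian-cycle instance and cuts junctions below
#' `tau`. The CAR count never increases; the loop stops early once a
#' single CAR remains.
#'
#' @param st a `species_tree` with leaf genomes attached (content is
#'   assigned if missing).
#' @param nu name of the target (pre-duplication) node.
#' @param tau junction cut threshold in [0, 1]; roughly the fraction of
#'   tree branches on which a kept adjacency must be conservable.
#' @param max_alpha largest gap bound.
#' @param seed integer seed controlling the TSP heuristic.
#' @param wgd_double_match double parent multisets across WGD branches in
#'   the scoring DP.
#' @param strict_gap_exclusion gap windows may not contain the focal or
#'   contributed gene.
#' @param literal_normalization see [build_junction_graph()].
#' @param mult_cap complexity guard on per-node gene multiplicity.
#' @param snapshot_alphas record the CAR set after these iterations.
#' @param verbose print one line per iteration.
#' @return list of class `gapadj_result`: `cars` (a `car_set`), `log`
#'   (data.frame: alpha, n_cars, tour_weight), `snapshots` (named list of
#'   `car_set`), `junctions` (data.frame of kept junctions: alpha at
#'   join, genes, weight).
#' @export
gapadj <- function(st, nu, tau = 0.70, max_alpha = 50L, seed = 1L,
                   wgd_double_match = TRUE, strict_gap_exclusion = TRUE,
                   literal_normalization = FALSE, mult_cap = 4L,
                   snapshot_alphas = integer(0), verbose = FALSE) {
  stopifnot(inherits(st, "species_tree"))
  if (is.null(st$content)) st <- assign_gene_content(st)
  nu_id <- node_id(st, nu)
  if (!is.null(seed)) set.seed(seed)
  ctx <- make_score_context(st, wgd_double_match = wgd_double_match,
                            strict_gap_exclusion = strict_gap_exclusion,
                            mult_cap = mult_cap)
  sigma_nu <- rownames(st$content)[st$content[, nu_id] > 0L]
  genes0 <- setdiff(sigma_nu, "O")
  bad <- genes0[st$content[genes0, nu_id] != 1L]
  if (length(bad) > 0L)
    stop(sprintf("mult != 1 at '%s' for gene(s) %s: not a valid pre-duplication node",
                 nu, paste(head(bad, 5L), collapse = ", ")))
  cars <- car_set(as.list(genes0))
  log <- data.frame(alpha = integer(0), n_cars = integer(0),
                    tour_weight = numeric(0))
  snapshots <- list()
  junctions <- data.frame(alpha = integer(0), left = character(0),
                          right = character(0), weight = numeric(0))
  for (alpha in seq_len(max_alpha)) {
    if (length(cars) <= 1L) break
    ext_genes <- unique(c(gene_of(extremity_tokens(cars)), "O"))
    scores <- list(
      L = stats::setNames(lapply(ext_genes, score_gene_at, ctx = ctx,
                                 side = "left", alpha = alpha,
                                 query = nu_id), ext_genes),
      R = stats::setNames(lapply(ext_genes, score_gene_at, ctx = ctx,
                                 side = "right", alpha = alpha,
                                 query = nu_id), ext_genes))
    graph <- build_junction_graph(cars, scores, st,
                                  literal_normalization = literal_normalization,
                                  wgd_double_match = wgd_double_match)
    tour <- solve_tsp(graph, seed = NULL)
    new_cars <- cut_tour(tour, graph, tau, alpha = alpha)
    if (length(new_cars) > length(cars))
      stop("internal error: CAR count increased")  # cut can only merge
    seams <- attr(new_cars, "seams")
    if (nrow(seams) > 0L)
      junctions <- rbind(junctions, cbind(alpha = alpha, seams))
    cars <- new_cars
    log <- rbind(log, data.frame(alpha = alpha, n_cars = length(cars),
                                 tour_weight = tour$weight))
    if (alpha %in% snapshot_alphas)
      snapshots[[as.character(alpha)]] <- cars
    if (verbose)
      message(sprintf("alpha=%2d  CARs=%4d  tour weight=%.2f",
                      alpha, length(cars), tour$weight))
  }
  structure(list(cars = cars, log = log, snapshots = snapshots,
                 junctions = junctions, nu = nu, tau = tau,
                 max_alpha = max_alpha),
            class = "gapadj_result")
}

#' @export
print.gapadj_result <- function(x, ...) {
  cat(sprintf("<gapadj_result> node '%s': %d CAR(s) after %d iteration(s) (tau=%.2f)\n",
              x$nu, length(x$cars), nrow(x$log), x$tau))
  invisible(x)
}
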