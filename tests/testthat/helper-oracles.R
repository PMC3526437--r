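# Independent oracles used by the test suite.  These re-derive expected
# values from first principles (substring characterisation, exhaustive
# labeling enumeration, permutation enumeration) and deliberately share
# no code with the implementation paths they check.

neg_tok <- function(tok) {
  out <- ifelse(startsWith(tok, "-"), substring(tok, 2L), paste0("-", tok))
  out[sub("^-", "", tok) == "O"] <- "O"
  out
}

# circular token rings of a genome (O appended to linear chromosomes)
genome_rings <- function(g) {
  lapply(seq_along(g$chrom), function(i)
    if (g$circular[i]) g$chrom[[i]] else c(g$chrom[[i]], "O"))
}

# Left gapped-adjacency multiset by the substring characterisation:
# value v is counted once per position pair matching
#   "v x a" or "-a x -v"  with |x| <= floor((alpha-1)/2)   (trailing
#   extremity), or
#   "-v x a" or "-a x v"  with |x| <= floor((alpha-2)/2)   (leading
#   extremity),
# where x runs over signed genes excluding copies of |a| and |v|.  The
# telomeric gene O is orientation-free: it is counted positively via its
# nearest extremity (gap floor((alpha-1)/2)) and never negatively.
oracle_left_adjacencies <- function(g, gene, alpha, strict = TRUE) {
  out <- character(0)
  k1 <- (alpha - 1) %/% 2   # trailing-extremity gap bound
  k2 <- (alpha - 2) %/% 2   # leading-extremity gap bound (alpha >= 2)
  for (ring in genome_rings(g)) {
    n <- length(ring)
    if (n < 2) next
    for (q in seq_len(n)) {            # position of the focal-side token
      for (k in 0:min(max(k1, k2), n - 2L)) {
        p <- ((q - 1L - (k + 1L)) %% n) + 1L   # k genes strictly between
        x <- if (k > 0) ring[((q - 1L - seq_len(k)) %% n) + 1L] else character(0)
        xg <- sub("^-", "", x)
        pair_hits <- function(vtok, kmax) {
          if (k > kmax) return(FALSE)
          if (strict && any(xg %in% c(gene, sub("^-", "", vtok)))) return(FALSE)
          TRUE
        }
        w <- ring[p]
        if (ring[q] == gene) {          # "... v x a ..." and "... -v x a ..."
          if (sub("^-", "", w) == "O") {
            if (pair_hits("O", k1)) out <- c(out, "O")
          } else {
            if (pair_hits(w, k1)) out <- c(out, w)
            if (alpha >= 2 && pair_hits(neg_tok(w), k2)) out <- c(out, neg_tok(w))
          }
        }
        if (ring[p] == paste0("-", gene)) {  # "-a x -v" / "-a x v", focal at p
          # the region right of the focal -a occurrence, read reversed
          xr <- if (k > 0) ring[((p - 1L + seq_len(k)) %% n) + 1L] else character(0)
          xgr <- sub("^-", "", xr)
          wq <- ring[((p - 1L + (k + 1L)) %% n) + 1L]
          hits_r <- function(vtok, kmax) {
            if (k > kmax) return(FALSE)
            if (strict && any(xgr %in% c(gene, sub("^-", "", vtok)))) return(FALSE)
            TRUE
          }
          if (sub("^-", "", wq) == "O") {
            if (hits_r("O", k1)) out <- c(out, "O")
          } else {
            v1 <- neg_tok(wq)           # "-a x -v" counts v at trailing gap
            if (hits_r(v1, k1)) out <- c(out, v1)
            if (alpha >= 2 && hits_r(wq, k2)) out <- c(out, wq)
          }
        }
      }
    }
  }
  sort(out)
}

# right side via the sign-flip identity: negating every written token
# (without reversing) swaps each occurrence's reading direction, so
# RA(g, G) = LA(g, signflip(G)) element for element
oracle_right_adjacencies <- function(g, gene, alpha, strict = TRUE) {
  fg <- g
  fg$chrom <- lapply(g$chrom, neg_tok)
  oracle_left_adjacencies(fg, gene, alpha, strict)
}

# exhaustive maximisation over all joint candidate-multiset assignments
# at internal carrier nodes (leaves clamped to their observations);
# returns the totals for every candidate at `query`
oracle_score_totals <- function(st, gene, side, alpha, query_name,
                                wgd_double = TRUE) {
  tabs <- compute_score_tables(gene, side, alpha, st,
                               wgd_double_match = wgd_double)
  cand <- tabs$candidates
  nodes <- names(cand)
  kindof <- st$kind[match(nodes, st$name)]
  internal <- nodes[kindof != "leaf"]
  stopifnot(query_name %in% nodes)
  bm <- function(x, y, wgd) branch_match(x, y, wgd)
  branches <- list()
  for (v in nodes) {
    p <- st$parent[match(v, st$name)]
    if (is.na(p) || !(st$name[p] %in% nodes)) next
    branches[[length(branches) + 1L]] <-
      list(u = st$name[p], v = v, wgd = st$kind[p] == "wgd" && wgd_double)
  }
  score_assign <- function(assign) {
    tot <- 0
    for (b in branches)
      tot <- tot + bm(assign[[b$u]], assign[[b$v]], b$wgd)
    tot
  }
  out <- numeric(length(cand[[query_name]]))
  others <- setdiff(internal, query_name)
  idx <- lapply(others, function(u) seq_along(cand[[u]]))
  grid <- if (length(others) == 0L) list(integer(0)) else
    split(as.matrix(do.call(expand.grid, idx)), seq_len(prod(lengths(idx))))
  assign0 <- lapply(cand, function(x) x[[1L]])
  for (v in nodes[kindof == "leaf"]) assign0[[v]] <- cand[[v]][[1L]]
  for (qi in seq_along(cand[[query_name]])) {
    best <- -Inf
    for (g_row in grid) {
      assign <- assign0
      assign[[query_name]] <- cand[[query_name]][[qi]]
      if (length(others) > 0L)
        for (j in seq_along(others))
          assign[[others[j]]] <- cand[[others[j]]][[g_row[j]]]
      best <- max(best, score_assign(assign))
    }
    out[qi] <- best
  }
  out
}

# exhaustive heaviest Hamiltonian cycle over CAR permutations and
# orientations (O anchored), on a junction_graph
oracle_best_tour_weight <- function(graph) {
  K <- length(graph$cars)
  M <- graph$M
  Ov <- 2L * K + 1L
  inx <- function(c, o) 2L * (c - 1L) + o + 1L
  outx <- function(c, o) 2L * (c - 1L) + 2L - o
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- -Inf
  for (ord in perms(seq_len(K))) {
    oris <- expand.grid(rep(list(0:1), K))
    for (r in seq_len(nrow(oris))) {
      o <- as.integer(oris[r, ])
      w <- M[Ov, inx(ord[1L], o[1L])]
      if (K > 1L) for (i in seq_len(K - 1L))
        w <- w + M[outx(ord[i], o[i]), inx(ord[i + 1L], o[i + 1L])]
      w <- w + M[outx(ord[K], o[K]), Ov]
      best <- max(best, w)
    }
  }
  best
}

# random small scoring instance: three random leaf genomes over a tiny
# alphabet on a random 3-leaf topology (possibly with a WGD node)
random_score_instance <- function(seed) {
  set.seed(seed)
  syms <- c("a", "b", "c")
  rg <- function(name, n_occ) {
    toks <- paste0(sample(c("", "-"), n_occ, TRUE), sample(syms, n_occ, TRUE))
    genome(list(toks), name = name)
  }
  nwk <- sample(c("((A,B)X,C)R;", "((A,B)X_WGD,C)R;", "(A,(B,C)Y)R;"), 1)
  gs <- lapply(c("A", "B", "C"), rg, n_occ = sample(3:5, 1))
  st <- try(assign_gene_content(read_species_tree(nwk, gs)), silent = TRUE)
  if (inherits(st, "try-error")) return(NULL)
  st
}

# small random genome with duplicated genes for property tests
random_test_genome <- function(n_occ, n_sym, n_chrom = 1L, circular = FALSE,
                               name = "G") {
  syms <- letters[seq_len(n_sym)]
  toks <- paste0(sample(c("", "-"), n_occ, replace = TRUE),
                 sample(syms, n_occ, replace = TRUE))
  cuts <- sort(sample(seq_len(n_occ - 1L), n_chrom - 1L))
  bounds <- c(0L, cuts, n_occ)
  chrom <- lapply(seq_len(n_chrom), function(i)
    toks[(bounds[i] + 1L):bounds[i + 1L]])
  genome(chrom, circular = circular, name = name)
}
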