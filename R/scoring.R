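# Tree dynamic program for gapped-adjacency conservation scores.
#
# For a focal gene g, a side and a gap bound alpha, and every candidate
# multiset X of mult(g, u) potential adjacencies at a node u, the DP
# computes the maximum number of side-alpha-adjacencies of g conservable
# over the whole tree by any ancestral labeling constrained to X at u.
# Leaves are clamped to their observed adjacency multisets; the inside
# (leaves-to-root) and outside (root-to-leaves) passes exchange messages
# max_Y [ branch_match(X, Y) + score(Y) ] along branches.  Candidate
# symbols never observed at any leaf cannot raise a match and are
# collapsed into one wildcard that matches nothing.

#' Wildcard adjacency token
#'
#' Stands for "any never-observed adjacency"; matches nothing in
#' [branch_match()]. The token (`"."`) is reserved and may not be used as
#' a gene symbol.
#' @export
bottom_token <- "."

# multisets of size m over symbols, as a list of sorted character vectors
comb_rep <- function(symbols, m) {
  if (m == 0L) return(list(character(0)))
  rec <- function(start, m) {
    if (m == 0L) return(list(character(0)))
    out <- list()
    for (i in start:length(symbols))
      out <- c(out, lapply(rec(i, m - 1L), function(r) c(symbols[i], r)))
    out
  }
  rec(1L, m)
}

#' Branch match between two candidate adjacency multisets
#'
#' Multiset intersection size, with every count of the parent-side
#' multiset doubled when the branch descends from a WGD node (a doubling
#' duplicates every adjacency). The wildcard [bottom_token] matches
#' nothing.
#'
#' @param x parent-side multiset (character vector of signed tokens).
#' @param y child-side multiset.
#' @param parent_is_wgd double the parent multiset's counts?
#' @return non-negative integer.
#' @examples
#' branch_match(c("a", "a"), c("a", "b"))          # 1
#' branch_match("a", c("a", "a"), parent_is_wgd = TRUE)  # 2
#' @export
branch_match <- function(x, y, parent_is_wgd = FALSE) {
  x <- x[x != bottom_token]
  y <- y[y != bottom_token]
  if (parent_is_wgd) x <- rep(x, each = 2L)
  multiset_intersection_size(x, y)
}

# observed side-alpha-adjacency multiset of `gene` at a carrier leaf
observed_adjacencies <- function(st, leaf, gene, side, alpha, strict) {
  alpha_adjacencies(st$genomes[[leaf]], gene, side, alpha, strict)
}

#' Conservation score tables for one gene
#'
#' Runs the inside-outside dynamic program for `gene` on `side` at gap
#' `alpha` and returns, for every carrier node, the score of each
#' candidate adjacency multiset: the maximum number of conserved
#' side-alpha-adjacencies of the gene over the whole tree when the node is
#' constrained to that multiset.  Candidate multisets have size
#' `mult(gene, node)` and draw from the symbols observed adjacent to the
#' gene at the leaves, plus `"O"` and the wildcard [bottom_token]
#' (`mult("O", .)` is capped at 1: the telomeric gene is scored
#' per-copy).  This reference implementation enumerates candidates
#' directly; the inference loop uses an equivalent compiled kernel for
#' multiplicities up to 2.
#'
#' @param gene unsigned focal gene symbol.
#' @param side `"left"` or `"right"`.
#' @param alpha positive integer gap bound.
#' @param st a `species_tree` with content assigned and leaf genomes.
#' @param wgd_double_match double parent multisets across WGD branches?
#' @param strict_gap_exclusion passed to adjacency extraction.
#' @param mult_cap error when `mult(gene, node)` exceeds this bound.
#' @return list with `alphabet`, and per carrier node `candidates`
#'   (list of multisets), `inside`, `outside` and `total` score vectors.
#' @export
compute_score_tables <- function(gene, side = c("left", "right"), alpha, st,
                                 wgd_double_match = TRUE,
                                 strict_gap_exclusion = TRUE, mult_cap = 4L) {
  side <- match.arg(side)
  stopifnot(inherits(st, "species_tree"), !is.null(st$content))
  if (!gene %in% rownames(st$content)) stop(sprintf("gene '%s' not in tree content", gene))
  m <- st$content[gene, ]
  if (gene == "O") m <- pmin(m, 1L)
  if (any(m > mult_cap))
    stop(sprintf("mult(%s) exceeds the complexity cap %d", gene, mult_cap))
  carriers <- which(m > 0L)
  lv <- intersect(carriers, tree_leaves(st))
  obs <- stats::setNames(
    lapply(lv, observed_adjacencies, st = st, gene = gene, side = side,
           alpha = alpha, strict = strict_gap_exclusion), st$name[lv])
  alphabet <- sort(unique(c(unlist(obs, use.names = FALSE), "O")))
  alphabet <- c(alphabet, bottom_token)
  po <- tree_postorder(st)
  po <- po[po %in% carriers]
  cand <- vector("list", n_nodes(st))
  for (u in carriers) {
    cand[[u]] <- if (st$kind[u] == "leaf") list(sort(obs[[st$name[u]]]))
                 else comb_rep(alphabet, m[u])
  }
  is_wgd <- st$kind == "wgd" & wgd_double_match
  D <- vector("list", n_nodes(st))
  msg <- vector("list", n_nodes(st))  # message from node to its parent
  for (u in po) {
    ch <- intersect(st$children[[u]], carriers)
    D[[u]] <- numeric(length(cand[[u]]))
    for (v in ch) {
      dv <- if (st$kind[v] == "leaf") 0 else D[[v]]
      msg[[v]] <- vapply(cand[[u]], function(X)
        max(vapply(seq_along(cand[[v]]), function(iy)
          branch_match(X, cand[[v]][[iy]], is_wgd[u]) + dv[iy], numeric(1))),
        numeric(1))
      D[[u]] <- D[[u]] + msg[[v]]
    }
  }
  U <- vector("list", n_nodes(st))
  for (u in rev(po)) {
    p <- st$parent[u]
    if (is.na(p) || !(p %in% carriers)) U[[u]] <- numeric(length(cand[[u]]))
    for (v in intersect(st$children[[u]], carriers)) {
      tvec <- U[[u]] + D[[u]] - msg[[v]]
      U[[v]] <- vapply(cand[[v]], function(Y)
        max(vapply(seq_along(cand[[u]]), function(ix)
          branch_match(cand[[u]][[ix]], Y, is_wgd[u]) + tvec[ix], numeric(1))),
        numeric(1))
    }
  }
  total <- vector("list", n_nodes(st))
  for (u in po) total[[u]] <- D[[u]] + U[[u]]
  names(total) <- names(cand) <- names(D) <- names(U) <- st$name
  list(gene = gene, side = side, alpha = alpha, alphabet = alphabet,
       candidates = cand[carriers], inside = D[carriers],
       outside = U[carriers], total = total[carriers])
}

#' Singleton adjacency scores at the target node
#'
#' For each queried gene g (which must have multiplicity 1 at `nu`: the
#' node precedes all duplications) returns `L(g, h)` and `R(g, h)`: the
#' conservation score with the gene's left (right) adjacency at `nu`
#' clamped to the single signed token h, for h over the gene's candidate
#' alphabet plus the wildcard.
#'
#' Two scores are available. `method = "adjacency"` (the default, used
#' by the assembly) is the maximum number of times the specific gapped
#' adjacency (g, h) can be conserved along branches over all ancestral
#' labelings: internal carrier nodes may carry the adjacency freely, a
#' leaf contributes the number of copies of h in its observed window
#' (capped at the gene's multiplicity), and a WGD branch doubles the
#' parent side. `method = "total"` is the inside-outside dynamic program
#' of [compute_score_tables()], which pools the conservation of all of
#' the gene's side-adjacencies under the clamp.
#'
#' @param nu name of the target node.
#' @param alpha positive integer gap bound.
#' @param genes unsigned gene symbols to score.
#' @param st a `species_tree` with content assigned and leaf genomes.
#' @param method `"adjacency"` or `"total"`.
#' @param ... scoring options (`wgd_double_match`,
#'   `strict_gap_exclusion`, `mult_cap`).
#' @return list with elements `L` and `R`: per-gene named numeric vectors
#'   over signed tokens (the wildcard entry gives the score of any
#'   unobserved adjacency).
#' @export
score_tables_at_node <- function(nu, alpha, genes, st,
                                 method = c("adjacency", "total"), ...) {
  method <- match.arg(method)
  stopifnot(!is.null(st$content))
  nu_id <- node_id(st, nu)
  ctx <- make_score_context(st, ...)
  bad <- genes[genes != "O" & st$content[genes, nu_id] != 1L]
  if (length(bad) > 0L)
    stop(sprintf("mult != 1 at node '%s' for gene(s) %s: not a valid pre-duplication node",
                 nu, paste(bad, collapse = ", ")))
  L <- lapply(genes, function(g) score_gene_at(ctx, g, "left", alpha, nu_id, method))
  R <- lapply(genes, function(g) score_gene_at(ctx, g, "right", alpha, nu_id, method))
  list(L = stats::setNames(L, genes), R = stats::setNames(R, genes))
}

## ---- integer-encoded scoring context used by the inference loop ----

make_score_context <- function(st, wgd_double_match = TRUE,
                               strict_gap_exclusion = TRUE, mult_cap = 4L) {
  stopifnot(!is.null(st$content))
  lv <- tree_leaves(st)
  symtab <- make_symtab(st$genomes[lv])
  symtab <- union(symtab, rownames(st$content))  # keep "O" last otherwise
  if (symtab[length(symtab)] != "O") symtab <- c(setdiff(symtab, "O"), "O")
  enc <- vector("list", n_nodes(st))
  for (i in lv) enc[[i]] <- encode_genome(st$genomes[[i]], symtab)
  list(st = st, symtab = symtab, o_id = length(symtab), enc = enc,
       leaves = lv, wgd_double = wgd_double_match,
       strict = strict_gap_exclusion, mult_cap = mult_cap,
       content = st$content[, , drop = FALSE])
}

# observed multisets (signed ids) of several genes at one leaf
ctx_observed <- function(ctx, leaf, gene_ids, side, alpha) {
  adj_multisets_cpp(ctx$enc[[leaf]], ctx$st$genomes[[leaf]]$circular,
                    as.integer(gene_ids), as.integer(side == "right"),
                    as.integer(alpha), ctx$strict, ctx$o_id)
}

# Score one gene at `query`; returns a named numeric vector over signed
# tokens plus the wildcard (names are decoded tokens; last is bottom).
# method "adjacency": closed-form maximum conservation of each specific
# adjacency value; "total": inside-outside DP pooling all values.
score_gene_at <- function(ctx, gene, side, alpha, query,
                          method = "adjacency") {
  st <- ctx$st
  gid <- match(gene, ctx$symtab)
  m <- ctx$content[gene, ]
  if (gene == "O") m <- pmin(m, 1L)
  if (any(m > ctx$mult_cap))
    stop(sprintf("mult(%s) exceeds the complexity cap %d", gene, ctx$mult_cap))
  if (m[query] == 0L) stop(sprintf("gene '%s' absent at query node", gene))
  carriers <- which(m > 0L)
  lvs <- intersect(carriers, ctx$leaves)
  obs <- if (gene == "O") {
    # O is orientation-free, so telomeric evidence is symmetrised over
    # chromosome writing direction: a junction (x, O) shows up as x in
    # LA(O) or as -x in RA(O) depending on how the leaf chromosome is
    # written; both spellings are folded into the queried side
    other <- if (side == "left") "right" else "left"
    lapply(lvs, function(leaf) {
      a <- ctx_observed(ctx, leaf, gid, side, alpha)[[1L]]
      b <- ctx_observed(ctx, leaf, gid, other, alpha)[[1L]]
      c(a, ifelse(abs(b) == ctx$o_id, ctx$o_id, -b))
    })
  } else {
    lapply(lvs, function(leaf) ctx_observed(ctx, leaf, gid, side, alpha)[[1L]])
  }
  syms <- sort(unique(c(unlist(obs, use.names = FALSE), ctx$o_id)))
  A <- length(syms)
  obs_cnt <- matrix(0L, A + 1L, n_nodes(st))
  for (k in seq_along(lvs))
    obs_cnt[, lvs[k]] <- tabulate(match(obs[[k]], syms), nbins = A + 1L)
  toks_all <- c(decode_tokens(syms, ctx$symtab), bottom_token)
  if (method == "adjacency") {
    vals <- numeric(A + 1L)
    for (v in seq_len(n_nodes(st))) {
      u <- st$parent[v]
      if (is.na(u) || m[u] == 0L || m[v] == 0L) next
      w <- if (st$kind[u] == "wgd" && ctx$wgd_double) 2L else 1L
      av <- if (st$kind[v] == "leaf") pmin(obs_cnt[, v], m[v]) else m[v]
      vals <- vals + pmin(w * m[u], av)
    }
    return(stats::setNames(vals, toks_all))
  }
  if (max(m) <= 2L) {
    tot <- score_gene_cpp(st$parent - 1L, tree_postorder(st) - 1L,
                          match(st$kind, c("leaf", "spec", "wgd")) - 1L,
                          as.integer(m), obs_cnt, A,
                          query - 1L, ctx$wgd_double)
  } else {
    tot <- score_gene_generic(st, m, obs_cnt, A, query, ctx$wgd_double)
  }
  if (m[query] == 1L) stats::setNames(as.numeric(tot), toks_all)
  else structure(as.numeric(tot), symbols = toks_all)
}

# R fallback for multiplicities above 2 (stacked WGDs); enumerates
# candidate multisets as integer index vectors over 1..A+1.
score_gene_generic <- function(st, m, obs_cnt, A, query, wgd_double) {
  Aq <- A + 1L
  carriers <- which(m > 0L)
  po <- tree_postorder(st); po <- po[po %in% carriers]
  combs <- function(mm) {
    if (mm == 1L) return(as.list(seq_len(Aq)))
    rec <- function(start, mm) {
      if (mm == 0L) return(list(integer(0)))
      out <- list()
      for (i in start:Aq) out <- c(out, lapply(rec(i, mm - 1L), function(r) c(i, r)))
      out
    }
    rec(1L, mm)
  }
  bm <- function(X, Y, wgd) {
    cx <- tabulate(X, Aq); if (wgd) cx <- cx * 2L
    cy <- tabulate(Y, Aq)
    sum(pmin(cx, cy)[seq_len(A)])
  }
  bm_obs <- function(X, cnt, wgd) {
    cx <- tabulate(X, Aq); if (wgd) cx <- cx * 2L
    sum(pmin(cx, cnt)[seq_len(A)])
  }
  cand <- vector("list", n_nodes(st))
  for (u in carriers)
    cand[[u]] <- if (st$kind[u] == "leaf") NULL else combs(m[u])
  is_wgd <- (st$kind == "wgd") & wgd_double
  D <- vector("list", n_nodes(st)); msg <- vector("list", n_nodes(st))
  for (u in po) {
    if (st$kind[u] == "leaf") next
    D[[u]] <- numeric(length(cand[[u]]))
    for (v in intersect(st$children[[u]], carriers)) {
      msg[[v]] <- if (st$kind[v] == "leaf")
        vapply(cand[[u]], bm_obs, numeric(1), cnt = obs_cnt[, v], wgd = is_wgd[u])
      else vapply(cand[[u]], function(X)
        max(vapply(seq_along(cand[[v]]), function(iy)
          bm(X, cand[[v]][[iy]], is_wgd[u]) + D[[v]][iy], numeric(1))),
        numeric(1))
      D[[u]] <- D[[u]] + msg[[v]]
    }
  }
  U <- vector("list", n_nodes(st))
  for (u in rev(po)) {
    if (st$kind[u] == "leaf") next
    p <- st$parent[u]
    if (is.na(p) || !(p %in% carriers)) U[[u]] <- numeric(length(cand[[u]]))
    for (v in intersect(st$children[[u]], carriers)) {
      if (st$kind[v] == "leaf") next
      tvec <- U[[u]] + D[[u]] - msg[[v]]
      U[[v]] <- vapply(cand[[v]], function(Y)
        max(vapply(seq_along(cand[[u]]), function(ix)
          bm(cand[[u]][[ix]], Y, is_wgd[u]) + tvec[ix], numeric(1))),
        numeric(1))
    }
  }
  if (st$kind[query] == "leaf") stop("query node must be internal")
  D[[query]] + U[[query]]
}
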