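# Species trees with speciation nodes (2 children), WGD nodes (1 child)
# and leaves.  Stored as flat parallel vectors indexed by node id; gene
# content is an integer matrix (genes x nodes) filled by
# assign_gene_content().

new_species_tree <- function(kind, name, parent, children, root,
                             genomes = NULL, content = NULL) {
  n <- length(kind)
  if (is.null(genomes)) genomes <- vector("list", n)
  structure(list(kind = kind, name = name, parent = parent,
                 children = children, root = root, genomes = genomes,
                 content = content),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d nodes (%d leaves, %d speciation, %d WGD)%s\n",
              length(x$kind), sum(x$kind == "leaf"), sum(x$kind == "spec"),
              sum(x$kind == "wgd"),
              if (is.null(x$content)) "" else ", content assigned"))
  rec <- function(i, ind) {
    lab <- switch(x$kind[i], leaf = x$name[i],
                  spec = paste0(x$name[i], " (*)"),
                  wgd = paste0(x$name[i], " [WGD]"))
    cat(strrep("  ", ind), lab, "\n", sep = "")
    for (ch in x$children[[i]]) rec(ch, ind + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}

n_nodes <- function(st) length(st$kind)
tree_leaves <- function(st) which(st$kind == "leaf")

# children-before-parents ordering
tree_postorder <- function(st) {
  out <- integer(0)
  rec <- function(i) {
    for (ch in st$children[[i]]) rec(ch)
    out <<- c(out, i)
  }
  rec(st$root)
  out
}

node_depths <- function(st) {
  d <- integer(n_nodes(st))
  for (i in rev(tree_postorder(st)))
    d[i] <- if (is.na(st$parent[i])) 0L else d[st$parent[i]] + 1L
  d
}

node_id <- function(st, name) {
  i <- match(name, st$name)
  if (is.na(i))
    stop(sprintf("no node named '%s'; valid names: %s", name,
                 paste(st$name, collapse = ", ")))
  i
}

tree_lca <- function(st, ids) {
  d <- node_depths(st)
  ids <- unique(ids)
  a <- ids[1L]
  for (b in ids[-1L]) {
    while (d[a] > d[b]) a <- st$parent[a]
    while (d[b] > d[a]) b <- st$parent[b]
    while (a != b) { a <- st$parent[a]; b <- st$parent[b] }
  }
  a
}

# leaves at or below each node
leaves_below <- function(st, i) {
  if (st$kind[i] == "leaf") return(i)
  unlist(lapply(st$children[[i]], leaves_below, st = st), use.names = FALSE)
}

# splice a single-child WGD node on the edge above node i
splice_wgd_above <- function(st, i, name) {
  n <- n_nodes(st) + 1L
  st$kind <- c(st$kind, "wgd")
  st$name <- c(st$name, name)
  st$parent <- c(st$parent, st$parent[i])
  st$children <- c(st$children, list(i))
  if (!is.na(st$parent[i])) {
    p <- st$parent[i]
    st$children[[p]][st$children[[p]] == i] <- n
  } else {
    st$root <- n
  }
  st$parent[i] <- n
  st$genomes <- c(st$genomes, list(NULL))
  st
}

#' Read a species tree from Newick text
#'
#' Internal nodes must be binary; the literal token `WGD` in a node label
#' marks a whole-genome duplication. A label on a single-child node makes
#' that node the WGD node; on a two-child node (or a leaf, or the root) a
#' WGD node is spliced in on the edge above it. Unlabeled internal nodes
#' receive auto-generated names.
#'
#' @param newick_text a Newick string.
#' @param genomes optional list of `genome` objects whose names must match
#'   the leaf labels 1:1; attached to the leaves.
#' @return A `species_tree`.
#' @examples
#' read_species_tree("((A,B)X,C)R;")
#' @export
read_species_tree <- function(newick_text, genomes = NULL) {
  ph <- tryCatch(ape::read.tree(text = newick_text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(ph)) stop("malformed Newick text")
  m <- length(ph$tip.label)
  nn <- ph$Nnode
  kind <- c(rep("leaf", m), rep("spec", nn))
  labs <- ph$node.label
  if (is.null(labs)) labs <- rep("", nn)
  labs[is.na(labs)] <- ""
  auto <- paste0("n", seq_len(nn))
  name <- c(ph$tip.label, ifelse(labs == "", auto, labs))
  parent <- rep(NA_integer_, m + nn)
  children <- rep(list(integer(0)), m + nn)
  for (e in seq_len(nrow(ph$edge))) {
    p <- ph$edge[e, 1L]; v <- ph$edge[e, 2L]
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
  }
  root <- which(is.na(parent) & seq_along(parent) > m)
  if (length(root) != 1L) stop("malformed Newick: no unique root")
  st <- new_species_tree(kind, name, parent, children, root)
  # classify WGD annotations
  wgd_marked <- which(grepl("WGD", st$name, fixed = TRUE))
  for (i in wgd_marked) {
    nch <- length(st$children[[i]])
    if (st$kind[i] != "leaf" && nch == 1L) {
      st$kind[i] <- "wgd"
      base <- gsub("^_+|_+$", "", gsub("WGD", "", st$name[i], fixed = TRUE))
      if (base != "") st$name[i] <- base
    } else {
      base <- gsub("WGD", "", st$name[i], fixed = TRUE)
      base <- gsub("^_+|_+$", "", base)
      if (st$kind[i] != "leaf") st$name[i] <- if (base != "") base else paste0("n", i)
      st <- splice_wgd_above(st, i, paste0("wgd_", st$name[i]))
    }
  }
  bad <- which(st$kind == "spec" & lengths(st$children) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("non-binary speciation node(s): %s",
                 paste(st$name[bad], collapse = ", ")))
  if (!is.null(genomes)) st <- attach_genomes(st, genomes)
  st
}

attach_genomes <- function(st, genomes) {
  gnames <- vapply(genomes, function(g) g$name, character(1))
  lv <- tree_leaves(st)
  if (anyDuplicated(gnames)) stop("duplicate genome names")
  if (!setequal(gnames, st$name[lv]) || length(gnames) != length(lv))
    stop("leaf names and genome names do not match 1:1")
  for (g in genomes) st$genomes[[node_id(st, g$name)]] <- g
  st
}

#' Insert WGD nodes from leaf gene multiplicities
#'
#' Each leaf requires `ceiling(log2(max multiplicity))` WGD events on its
#' root path (multiplicities below 2 require none). Shared WGD nodes are
#' placed as high as possible: the event required by a set of leaves is
#' inserted immediately above their LCA (above the root when all leaves
#' require one). Errors when no placement gives every root-to-leaf path
#' exactly the required number of WGD crossings.
#'
#' @param st a `species_tree` with leaf genomes attached and no WGD nodes.
#' @return The tree with WGD nodes spliced in.
#' @export
insert_wgd_nodes <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  if (any(st$kind == "wgd")) stop("tree already has WGD nodes")
  lv <- tree_leaves(st)
  need <- vapply(lv, function(i) {
    g <- st$genomes[[i]]
    if (is.null(g)) stop("leaf genomes must be attached")
    tab <- mult_table(g)
    tab <- tab[names(tab) != "O"]
    mx <- if (length(tab)) max(tab) else 1L
    if (mx < 2L) 0L else as.integer(ceiling(log2(mx)))
  }, integer(1))
  if (all(need == 0L)) return(st)
  for (lev in seq_len(max(need))) {
    sel <- lv[need >= lev]
    anc <- tree_lca(st, sel)
    under <- intersect(leaves_below(st, anc), lv)
    if (!setequal(under, sel))
      stop("leaf WGD requirements admit no shared placement; ",
           "annotate WGD nodes explicitly in the Newick input")
    st <- splice_wgd_above(st, anc, sprintf("wgd%d", lev))
    lv <- tree_leaves(st)  # ids unchanged, but recompute for clarity
  }
  st
}

#' Assign ancestral gene content and multiplicity
#'
#' Two bottom-up passes. Pass 1 (WGD nodes): a gene is assigned to a WGD
#' node when its maximum multiplicity over the node's direct descendants
#' (nearest leaves/WGD nodes with no intervening WGD) is at least 2, with
#' pre-duplication multiplicity `ceiling(max/2)`. Pass 2: a gene is
#' assigned to every node on a path from the LCA of its carriers (leaves
#' or WGD nodes) to a carrying leaf; multiplicities not set by pass 1 are
#' the maximum over the node's children.
#'
#' @param st a `species_tree` with leaf genomes attached.
#' @return The tree with its `content` matrix (genes x nodes) filled.
#' @export
assign_gene_content <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  lv <- tree_leaves(st)
  if (any(vapply(st$genomes[lv], is.null, logical(1))))
    stop("leaf genomes must be attached")
  genes <- sort(unique(unlist(lapply(st$genomes[lv], gene_set), use.names = FALSE)))
  M <- matrix(0L, length(genes), n_nodes(st),
              dimnames = list(genes, st$name))
  for (i in lv) {
    tab <- mult_table(st$genomes[[i]])
    M[names(tab), i] <- as.integer(tab)
  }
  po <- tree_postorder(st)
  # pass 1: WGD nodes, children before parents
  direct_desc <- function(u) {
    out <- integer(0)
    rec <- function(v) {
      if (st$kind[v] %in% c("leaf", "wgd")) { out <<- c(out, v); return() }
      for (ch in st$children[[v]]) rec(ch)
    }
    rec(st$children[[u]][1L])
    out
  }
  for (u in po[st$kind[po] == "wgd"]) {
    dd <- direct_desc(u)
    mx <- apply(M[, dd, drop = FALSE], 1L, max)
    M[, u] <- ifelse(mx >= 2L, as.integer(ceiling(mx / 2)), 0L)
  }
  # pass 2: span from carrier LCA to carrying leaves
  set_in_p1 <- st$kind == "wgd"
  for (g in genes) {
    carriers <- which(M[g, ] > 0L & (st$kind == "leaf" | st$kind == "wgd"))
    if (length(carriers) == 0L) next
    anc <- tree_lca(st, carriers)
    span <- integer(0)
    for (leaf in intersect(carriers, lv)) {
      v <- leaf
      repeat {
        span <- c(span, v)
        if (v == anc) break
        v <- st$parent[v]
        if (is.na(v)) break
      }
    }
    span <- unique(span)
    for (u in po[po %in% span]) {
      if (st$kind[u] == "leaf") next
      if (set_in_p1[u] && M[g, u] > 0L) next
      ch <- st$children[[u]]
      M[g, u] <- max(M[g, ch])
    }
  }
  st$content <- M
  st
}

#' Number of tree nodes carrying a gene
#'
#' Counts nodes (leaves and internal, any kind) whose assigned content
#' includes the gene; the normaliser of junction weights.
#'
#' @param gene unsigned gene symbol.
#' @param st a `species_tree` with content assigned.
#' @return non-negative integer.
#' @export
max_adj <- function(gene, st) {
  stopifnot(!is.null(st$content))
  if (!gene %in% rownames(st$content)) return(0L)
  sum(st$content[gene, ] >= 1L)
}

#' Conserved gapped adjacencies over a fully labeled tree
#'
#' Sum of [adj_cons_genomes()] over all parent-child branches; every node
#' must carry a genome label.
#'
#' @param alpha positive integer gap bound.
#' @param st a `species_tree` with a genome at every node.
#' @inheritParams alpha_adjacencies
#' @return non-negative integer.
#' @export
adj_cons_tree <- function(alpha, st, strict_gap_exclusion = TRUE) {
  if (any(vapply(st$genomes, is.null, logical(1))))
    stop("adj_cons_tree needs a genome label at every node")
  total <- 0L
  for (v in seq_len(n_nodes(st))) {
    u <- st$parent[v]
    if (is.na(u)) next
    total <- total + adj_cons_genomes(alpha, st$genomes[[u]], st$genomes[[v]],
                                      strict_gap_exclusion)
  }
  total
}

#' Per-branch gene gain and loss counts
#'
#' For a branch (u, v) the expected copy number below u is
#' `2 * mult(g, u)` when u is a WGD node and `mult(g, u)` otherwise;
#' losses are the summed shortfalls of v, gains the genes appearing at v
#' with no copy at u.
#'
#' @param st a `species_tree` with content assigned.
#' @return data.frame with columns parent, child, gains, losses.
#' @export
infer_events <- function(st) {
  stopifnot(!is.null(st$content))
  M <- st$content[rownames(st$content) != "O", , drop = FALSE]
  rows <- lapply(seq_len(n_nodes(st)), function(v) {
    u <- st$parent[v]
    if (is.na(u)) return(NULL)
    e <- M[, u] * (if (st$kind[u] == "wgd") 2L else 1L)
    data.frame(parent = st$name[u], child = st$name[v],
               gains = sum(M[, u] == 0L & M[, v] >= 1L),
               losses = sum(pmax(0L, e - M[, v])))
  })
  do.call(rbind, rows)
}

#' Write a species tree as Newick text
#'
#' WGD nodes are emitted as single-child nodes whose label carries the
#' `WGD` token, the convention [read_species_tree()] understands.
#'
#' @param st a `species_tree`.
#' @return a Newick string.
#' @export
write_species_tree <- function(st) {
  rec <- function(i) {
    if (st$kind[i] == "leaf") return(st$name[i])
    lab <- st$name[i]
    if (st$kind[i] == "wgd" && !grepl("WGD", lab, fixed = TRUE))
      lab <- paste0(lab, "_WGD")
    paste0("(", paste(vapply(st$children[[i]], rec, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(rec(st$root), ";")
}
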