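# Genome evolution simulator: inversions, translocations, fusions,
# fissions, gene losses and whole-genome duplications along a species
# tree, storing the true genome at every node so inferences can be scored
# against a known ancestor.

#' Identity root genome
#'
#' Genes `1..n_genes`, all positive, in identity order, split into
#' `n_chromosomes` near-equal linear chromosomes.
#'
#' @param n_genes number of genes (>= `n_chromosomes`).
#' @param n_chromosomes number of linear chromosomes.
#' @param name genome identifier.
#' @return a `genome`.
#' @export
random_root <- function(n_genes, n_chromosomes = 1L, name = "root") {
  if (n_genes < n_chromosomes || n_chromosomes < 1L)
    stop("need n_genes >= n_chromosomes >= 1")
  cuts <- round(seq(0L, n_genes, length.out = n_chromosomes + 1L))
  chrom <- lapply(seq_len(n_chromosomes), function(i)
    as.character((cuts[i] + 1L):cuts[i + 1L]))
  genome(chrom, circular = FALSE, name = name)
}

# locate the idx-th gene occurrence (chromosome, offset)
locate_occurrence <- function(g, idx) {
  lens <- lengths(g$chrom)
  ch <- findInterval(idx - 1L, cumsum(c(0L, lens)), rightmost.closed = FALSE)
  list(chrom = ch, pos = idx - c(0L, cumsum(lens))[ch])
}

#' Apply one random inversion
#'
#' A uniform start position is drawn over all gene positions; the
#' inverted segment length is geometric (`p`, support >= 1), truncated at
#' the chromosome end; the segment is reversed with all signs flipped.
#'
#' @param g a `genome`.
#' @param p geometric parameter for segment length (mean `1/p`).
#' @return the rearranged `genome`.
#' @export
apply_inversion <- function(g, p = 0.5) {
  n <- sum(lengths(g$chrom))
  if (n < 1L) stop("empty genome")
  loc <- locate_occurrence(g, sample.int(n, 1L))
  ch <- g$chrom[[loc$chrom]]
  len <- 1L + stats::rgeom(1L, p)
  seg <- loc$pos:min(loc$pos + len - 1L, length(ch))
  ch[seg] <- rev(negate_tok(ch[seg]))
  g$chrom[[loc$chrom]] <- ch
  g
}

#' Apply one inter-chromosomal rearrangement
#'
#' Translocation: reciprocal exchange of uniform-random suffixes of two
#' distinct chromosomes (orientations preserved). Fusion: concatenation
#' of two chromosomes, the second reversed with probability 1/2.
#' Fission: split of one chromosome at a uniform internal boundary.
#' Chromosomes emptied by a translocation are removed.
#'
#' @param g a `genome` (linear chromosomes).
#' @param kind `"translocation"`, `"fusion"` or `"fission"`.
#' @return the rearranged `genome`.
#' @export
apply_interchromosomal <- function(g, kind = c("translocation", "fusion",
                                               "fission")) {
  kind <- match.arg(kind)
  nc <- length(g$chrom)
  if (kind %in% c("translocation", "fusion")) {
    if (nc < 2L) stop(sprintf("%s needs at least 2 chromosomes", kind))
    ij <- sample.int(nc, 2L)
    a <- g$chrom[[ij[1L]]]; b <- g$chrom[[ij[2L]]]
    if (kind == "fusion") {
      if (stats::runif(1L) < 0.5) b <- rev(negate_tok(b))
      g$chrom[[ij[1L]]] <- c(a, b)
      g$chrom <- g$chrom[-ij[2L]]
      g$circular <- g$circular[-ij[2L]]
    } else {
      ca <- sample.int(length(a) + 1L, 1L) - 1L  # keep prefix of length ca
      cb <- sample.int(length(b) + 1L, 1L) - 1L
      na <- c(a[seq_len(ca)], b[seq_len(length(b) - cb) + cb])
      nb <- c(b[seq_len(cb)], a[seq_len(length(a) - ca) + ca])
      g$chrom[[ij[1L]]] <- na
      g$chrom[[ij[2L]]] <- nb
      keep <- lengths(g$chrom) > 0L
      g$chrom <- g$chrom[keep]
      g$circular <- g$circular[keep]
    }
  } else {
    ok <- which(lengths(g$chrom) >= 2L)
    if (length(ok) == 0L) stop("fission needs a chromosome with >= 2 genes")
    i <- if (length(ok) == 1L) ok else sample(ok, 1L)
    ch <- g$chrom[[i]]
    cut <- sample.int(length(ch) - 1L, 1L)
    g$chrom[[i]] <- ch[seq_len(cut)]
    g$chrom <- c(g$chrom, list(ch[(cut + 1L):length(ch)]))
    g$circular <- c(g$circular, FALSE)
  }
  g
}

#' Remove one uniformly chosen gene occurrence
#'
#' @param g a `genome` with at least one gene.
#' @return the `genome` after the loss; emptied chromosomes are deleted.
#' @export
apply_loss <- function(g) {
  n <- sum(lengths(g$chrom))
  if (n < 1L) stop("empty genome")
  loc <- locate_occurrence(g, sample.int(n, 1L))
  g$chrom[[loc$chrom]] <- g$chrom[[loc$chrom]][-loc$pos]
  keep <- lengths(g$chrom) > 0L
  g$chrom <- g$chrom[keep]
  g$circular <- g$circular[keep]
  g
}

#' Whole-genome duplication
#'
#' Every chromosome is duplicated; every gene multiplicity doubles.
#'
#' @param g a `genome`.
#' @return the doubled `genome`.
#' @export
apply_wgd <- function(g) {
  g$chrom <- c(g$chrom, g$chrom)
  g$circular <- c(g$circular, g$circular)
  g
}

# one rearrangement with kind drawn from the Inv:Transloc:(Fus+Fiss) mix,
# resampling (up to a limit) when the drawn kind's precondition fails
random_rearrangement <- function(g, op_mix, p) {
  probs <- op_mix / sum(op_mix)
  for (try in 1:100) {
    cls <- sample.int(3L, 1L, prob = probs)
    res <- tryCatch(switch(cls,
      apply_inversion(g, p),
      apply_interchromosomal(g, "translocation"),
      apply_interchromosomal(g, if (stats::runif(1L) < 0.5) "fusion" else "fission")),
      error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  g  # nothing applicable (degenerate genome)
}

#' Simulate genome evolution along a species tree
#'
#' Places an identity root genome at the root and evolves it along every
#' branch: the branch's gene losses are applied first, then `r`
#' rearrangements with `r` uniform in `[ceiling(rmax/2), rmax]` and kinds
#' drawn from `op_mix`. Crossing a WGD node doubles the genome and then
#' applies `wgd_losses` losses (the burst between duplication and the
#' next speciation) before the branch's own events. True genomes are
#' stored at every node.
#'
#' @param st a `species_tree` (may contain WGD nodes); leaf genomes need
#'   not be attached.
#' @param n_genes,n_chromosomes root genome size.
#' @param rmax maximum rearrangements per branch (0 = none).
#' @param geometric_p inversion segment length parameter.
#' @param op_mix length-3 ratio Inv : Transloc : (Fus+Fiss).
#' @param branch_losses losses per branch: a single count applied to
#'   every branch, or a named vector keyed by child node name.
#' @param wgd_losses losses applied immediately after each WGD.
#' @param seed integer seed; the same seed reproduces the labeled tree
#'   exactly.
#' @return the `species_tree` with a true genome at every node (leaf
#'   genomes attached) and content unassigned.
#' @export
simulate_evolution <- function(st, n_genes = 200L, n_chromosomes = 1L,
                               rmax = 0L, geometric_p = 0.5,
                               op_mix = c(5, 4, 1), branch_losses = 0L,
                               wgd_losses = 0L, seed = 1L) {
  stopifnot(inherits(st, "species_tree"))
  if (!is.null(seed)) set.seed(seed)
  losses_for <- function(v) {
    if (length(branch_losses) == 1L && is.null(names(branch_losses)))
      return(as.integer(branch_losses))
    out <- branch_losses[st$name[v]]
    if (is.na(out)) 0L else as.integer(out)
  }
  g0 <- random_root(n_genes, n_chromosomes, name = st$name[st$root])
  st$genomes[[st$root]] <- g0
  for (v in rev(tree_postorder(st))) {
    u <- st$parent[v]
    if (is.na(u)) next
    g <- st$genomes[[u]]
    if (st$kind[u] == "wgd") {
      g <- apply_wgd(g)
      for (i in seq_len(wgd_losses)) g <- apply_loss(g)
    }
    for (i in seq_len(losses_for(v))) g <- apply_loss(g)
    if (rmax > 0L) {
      lo <- as.integer(ceiling(rmax / 2))
      r <- if (lo == rmax) rmax else sample(lo:rmax, 1L)
      for (i in seq_len(r)) g <- random_rearrangement(g, op_mix, geometric_p)
    }
    g$name <- st$name[v]
    st$genomes[[v]] <- g
  }
  st
}

#' Six-leaf simulation tree
#'
#' The non-duplicated study topology `((((A,B),C),(D,E)),F)` with the
#' target node `SIGMA` (ancestor of A..E, child of the root `RHO`).
#'
#' @return a `species_tree`.
#' @export
six_leaf_fixture <- function() {
  read_species_tree("((((A,B)AB,C)ABC,(D,E)DE)SIGMA,F)RHO;")
}

#' Three-leaf WGD simulation tree
#'
#' A cereal-style topology `(A,(B,C))` with one WGD above the root: the
#' pre-duplication target node is `wgd_R3`.
#'
#' @return a `species_tree`.
#' @export
cereal_fixture <- function() {
  read_species_tree("(A,(B,C)BC)R3_WGD;")
}
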