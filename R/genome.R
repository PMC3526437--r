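# Signed gene-order genomes.
#
# A chromosome is a character vector of signed gene tokens ("a", "-a"); a
# genome is a set of chromosomes, each flagged linear or circular.  Linear
# chromosomes never contain the artificial telomeric gene "O": it is
# appended only in the circularised marker view, and by convention is
# always read positively (its two extremities are interchangeable).

#' Construct a genome
#'
#' @param chromosomes list of character vectors of signed gene tokens; a
#'   leading `-` marks reverse orientation, an optional leading `+` is
#'   stripped.
#' @param circular logical vector (recycled) flagging circular chromosomes.
#' @param name genome identifier.
#' @return An object of class `genome`.
#' @examples
#' genome(list(c("1", "-2", "3")), name = "A")
#' @export
genome <- function(chromosomes, circular = FALSE, name = "genome") {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, function(ch) {
    ch <- as.character(ch)
    if (length(ch) == 0L) stop("empty chromosome")
    sub("^\\+", "", ch)
  })
  if (any(vapply(chromosomes, function(ch) any(gene_of(ch) == "O"), logical(1))))
    stop("gene symbol 'O' is reserved for the artificial telomere")
  circular <- rep_len(as.logical(circular), length(chromosomes))
  structure(list(name = name, chrom = chromosomes, circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d chromosome(s), %d gene occurrence(s)\n",
              x$name, length(x$chrom), sum(lengths(x$chrom))))
  for (i in seq_along(x$chrom)) {
    cat(sprintf("  [%d%s] %s\n", i, if (x$circular[i]) ", circ" else "",
                paste(x$chrom[[i]], collapse = " ")))
  }
  invisible(x)
}

# unsigned symbol of a signed token
gene_of <- function(tok) sub("^-", "", tok)
# sign of a signed token as +1/-1
sign_of <- function(tok) ifelse(startsWith(tok, "-"), -1L, 1L)
# negate signed tokens; O stays positive by convention
negate_tok <- function(tok) {
  out <- ifelse(startsWith(tok, "-"), substring(tok, 2L), paste0("-", tok))
  out[gene_of(tok) == "O"] <- "O"
  out
}

#' Gene set of a genome
#'
#' Unsigned symbols present in the genome, including the artificial gene
#' `O` when the genome has at least one linear chromosome.
#'
#' @param g a `genome`.
#' @return character vector of unsigned gene symbols.
#' @export
gene_set <- function(g) {
  s <- unique(gene_of(unlist(g$chrom, use.names = FALSE)))
  if (any(!g$circular)) s <- c(s, "O")
  sort(s)
}

#' Gene multiplicity
#'
#' Number of copies of `gene` (in either orientation) in genome `g`.
#' `mult("O", g)` equals the number of linear chromosomes.
#'
#' @param gene unsigned gene symbol.
#' @param g a `genome`.
#' @return non-negative integer.
#' @export
mult <- function(gene, g) {
  if (gene == "O") return(sum(!g$circular))
  sum(gene_of(unlist(g$chrom, use.names = FALSE)) == gene)
}

# named multiplicity table over the whole gene set
mult_table <- function(g) {
  occ <- gene_of(unlist(g$chrom, use.names = FALSE))
  tab <- table(occ)
  out <- stats::setNames(as.integer(tab), names(tab))
  nlin <- sum(!g$circular)
  if (nlin > 0L) out["O"] <- nlin
  out
}

#' Marker sequence of a chromosome
#'
#' Expands a chromosome into its circular ring of unsigned markers: `+g`
#' becomes `(g_t, g_h)`, `-g` becomes `(g_h, g_t)`. A linear chromosome
#' receives the two markers of the artificial telomeric gene `O` at its
#' end and the result is read circularly.
#'
#' @param chromosome character vector of signed gene tokens.
#' @param circular is the chromosome circular (no `O` appended)?
#' @return character vector of markers, e.g. `c("a_t","a_h","O_t","O_h")`.
#' @examples
#' marker_sequence(c("1", "-2"))
#' @export
marker_sequence <- function(chromosome, circular = FALSE) {
  chromosome <- sub("^\\+", "", as.character(chromosome))
  if (length(chromosome) == 0L) stop("empty chromosome")
  toks <- if (circular) chromosome else c(chromosome, "O")
  g <- gene_of(toks)
  neg <- startsWith(toks, "-")
  first <- ifelse(neg, paste0(g, "_h"), paste0(g, "_t"))
  second <- ifelse(neg, paste0(g, "_t"), paste0(g, "_h"))
  as.vector(rbind(first, second))
}

## ---- integer encoding used by the compiled kernels ----

# symbol table: character vector with "O" guaranteed present; id = index
make_symtab <- function(genomes) {
  syms <- sort(unique(unlist(lapply(genomes, function(g)
    gene_of(unlist(g$chrom, use.names = FALSE))), use.names = FALSE)))
  c(syms, "O")
}

# encode one genome's chromosomes as signed integer vectors
encode_genome <- function(g, symtab) {
  lapply(g$chrom, function(ch) {
    ids <- match(gene_of(ch), symtab)
    if (anyNA(ids)) stop("gene symbol missing from symbol table")
    ids * sign_of(ch)
  })
}

decode_tokens <- function(ids, symtab) {
  s <- symtab[abs(ids)]
  ifelse(ids < 0, paste0("-", s), s)
}

## ---- adjacency multisets ----

#' Gapped adjacency multiset of a gene
#'
#' Returns the multiset of signed genes that are left (or right)
#' \eqn{\alpha}-adjacent to `gene` in genome `g`: each occurrence of the
#' focal gene (occurrences in reverse orientation are read reversed with
#' all signs flipped) is scanned outward on the requested side of the
#' circular marker ring, and a neighbouring gene contributes once per
#' qualifying extremity at marker gap `d < alpha` (markers strictly
#' between), signed so that the extremity at that gap is the gene's
#' trailing marker. The artificial gene `O` participates like any gene but
#' is always contributed positively.
#'
#' With `strict_gap_exclusion` (the default) a contribution is suppressed
#' when the genes strictly inside its gap window include a copy of the
#' focal or of the contributed gene, matching the substring
#' characterisation of gapped adjacencies over \eqn{\pm\Sigma - \{a, b\}}.
#'
#' @param g a `genome`.
#' @param gene unsigned focal gene symbol (must occur in `g`; `"O"` allowed
#'   when `g` has linear chromosomes).
#' @param side `"left"` or `"right"`.
#' @param alpha positive integer gap bound (`alpha = 1` is direct
#'   adjacency).
#' @param strict_gap_exclusion suppress contributions whose gap window
#'   contains the focal or contributed gene?
#' @return sorted character vector of signed tokens (a multiset).
#' @examples
#' g <- genome(list(c("a", "a", "b", "a", "a", "c")), name = "G")
#' alpha_adjacencies(g, "a", "left", 1)   # O a a b
#' alpha_adjacencies(g, "a", "right", 2)  # a a b c -a -a -b -c
#' @export
alpha_adjacencies <- function(g, gene, side = c("left", "right"), alpha = 1L,
                              strict_gap_exclusion = TRUE) {
  side <- match.arg(side)
  stopifnot(inherits(g, "genome"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1)
    stop("alpha must be a positive integer")
  if (!gene %in% gene_set(g)) stop(sprintf("unknown gene symbol '%s'", gene))
  symtab <- make_symtab(list(g))
  enc <- encode_genome(g, symtab)
  res <- adj_multisets_cpp(enc, g$circular, match(gene, symtab),
                           as.integer(side == "right"), as.integer(alpha),
                           strict_gap_exclusion, length(symtab))
  sort(decode_tokens(res[[1L]], symtab))
}

#' Multiset intersection size
#'
#' Sum over distinct signed tokens of the minimum of the two counts.
#'
#' @param a,b character vectors interpreted as multisets of signed tokens.
#' @return non-negative integer.
#' @export
multiset_intersection_size <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (length(common) == 0L) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Conserved gapped adjacencies of one gene between two genomes
#'
#' `|LA(g, a, Gu) ∩ LA(g, a, Gv)| + |RA(g, a, Gu) ∩ RA(g, a, Gv)|`; returns
#' 0 when the gene is absent from either genome.
#'
#' The telomeric gene `O` is orientation-free (its two extremities are
#' interchangeable and it is always read positively), so its left and
#' right sides are not intrinsic: they swap with the arbitrary writing
#' direction of a chromosome. Its conservation is therefore counted once
#' over the orientation-folded multiset `LA(O) + negate(RA(O))`, which
#' holds one element per telomeric junction; together with the count
#' seen from the partner gene's side this preserves the rule that every
#' conserved junction contributes exactly 2.
#'
#' @param gene unsigned gene symbol.
#' @param alpha positive integer gap bound.
#' @param gu,gv `genome` objects.
#' @inheritParams alpha_adjacencies
#' @return non-negative integer.
#' @export
adj_cons_gene <- function(gene, alpha, gu, gv, strict_gap_exclusion = TRUE) {
  if (!gene %in% gene_set(gu) || !gene %in% gene_set(gv)) return(0L)
  if (gene == "O") {
    folded <- function(g) c(
      alpha_adjacencies(g, "O", "left", alpha, strict_gap_exclusion),
      negate_tok(alpha_adjacencies(g, "O", "right", alpha,
                                   strict_gap_exclusion)))
    return(multiset_intersection_size(folded(gu), folded(gv)))
  }
  multiset_intersection_size(
    alpha_adjacencies(gu, gene, "left", alpha, strict_gap_exclusion),
    alpha_adjacencies(gv, gene, "left", alpha, strict_gap_exclusion)) +
  multiset_intersection_size(
    alpha_adjacencies(gu, gene, "right", alpha, strict_gap_exclusion),
    alpha_adjacencies(gv, gene, "right", alpha, strict_gap_exclusion))
}

#' Conserved gapped adjacencies between two genomes
#'
#' Sum of [adj_cons_gene()] over genes present in both genomes (including
#' `O`). Each conserved physical junction is counted twice (once from each
#' incident gene's side).
#'
#' @inheritParams adj_cons_gene
#' @return non-negative integer.
#' @export
adj_cons_genomes <- function(alpha, gu, gv, strict_gap_exclusion = TRUE) {
  shared <- intersect(gene_set(gu), gene_set(gv))
  if (length(shared) == 0L) return(0L)
  sum(vapply(shared, adj_cons_gene, integer(1), alpha = alpha, gu = gu,
             gv = gv, strict_gap_exclusion = strict_gap_exclusion))
}
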