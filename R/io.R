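# GRIMM-style gene-order files and the end-to-end inference wrapper.
#
# Format: a line ">name" opens a genome; each following non-empty,
# non-comment line is one chromosome of whitespace-separated signed gene
# tokens terminated by "$" (linear) or "@" (circular); "#" starts a
# comment; the symbol "O" is reserved.

#' Read genomes from a GRIMM-style file
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of lines instead of a file.
#' @return named list of `genome` objects.
#' @examples
#' read_genomes(text = c(">A", "1 -2 $", "3 @"))
#' @export
read_genomes <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  out <- list()
  cur <- NULL; chrom <- list(); circ <- logical(0)
  flush <- function() {
    if (is.null(cur)) return()
    if (length(chrom) == 0L) stop(sprintf("genome '%s' has no chromosomes", cur))
    if (cur %in% names(out)) stop(sprintf("duplicate genome name '%s'", cur))
    out[[cur]] <<- genome(chrom, circular = circ, name = cur)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur <- trimws(substring(ln, 2L))
      if (cur == "") stop("empty genome name")
      chrom <- list(); circ <- logical(0)
    } else {
      if (is.null(cur)) stop("chromosome line before any '>' header")
      toks <- strsplit(ln, "\\s+")[[1L]]
      term <- toks[length(toks)]
      if (!term %in% c("$", "@"))
        stop(sprintf("chromosome line must end with '$' or '@': %s", ln))
      toks <- toks[-length(toks)]
      if (length(toks) == 0L) stop("empty chromosome")
      chrom <- c(chrom, list(toks))
      circ <- c(circ, term == "@")
    }
  }
  flush()
  if (length(out) == 0L) stop("no genomes in input")
  out
}

#' Write genomes in the GRIMM-style dialect
#'
#' @param genomes list of `genome` objects.
#' @param path output file.
#' @export
write_genomes <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  lines <- unlist(lapply(genomes, function(g) {
    c(paste0(">", g$name),
      vapply(seq_along(g$chrom), function(i)
        paste(c(g$chrom[[i]], if (g$circular[i]) "@" else "$"),
              collapse = " "), character(1)))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a CAR set (one linear chromosome per CAR)
#'
#' @param cars a `car_set` or `gapadj_result`.
#' @param path output file.
#' @param name genome header to use.
#' @export
write_cars <- function(cars, path, name = "ancestor") {
  if (inherits(cars, "gapadj_result")) cars <- cars$cars
  write_genomes(cars_as_genome(cars, name), path)
}

#' Write the junction report of a run
#'
#' Tab-separated table of the junctions kept at each iteration: the gap
#' bound at which the junction was made, the signed genes joined and the
#' junction weight.
#'
#' @param result a `gapadj_result`.
#' @param path output file.
#' @export
write_junction_report <- function(result, path) {
  stopifnot(inherits(result, "gapadj_result"))
  utils::write.table(result$junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' End-to-end ancestral inference
#'
#' Reads inputs, places WGD nodes when leaf multiplicities require them
#' and the tree carries no annotation, assigns ancestral gene content,
#' runs the iterative gapped-adjacency loop at the target node, and
#' optionally evaluates against a known ancestor and writes outputs.
#'
#' @param genomes GRIMM-style file path or a list of `genome` objects.
#' @param tree Newick file path, Newick string or `species_tree`.
#' @param node name of the target node.
#' @param truth optional true ancestral `genome` for evaluation.
#' @param out_dir optional directory for CARs, junction report and log.
#' @param ... passed to [gapadj()] (tau, max_alpha, seed, flags).
#' @return list with `result` (a `gapadj_result`) and `report` (an
#'   `evaluation_report` or NULL).
#' @export
run_infer <- function(genomes, tree, node, truth = NULL, out_dir = NULL,
                      ...) {
  if (is.character(genomes)) genomes <- read_genomes(genomes)
  genomes <- unname(genomes)
  if (is.character(tree)) {
    txt <- if (file.exists(tree)) paste(readLines(tree, warn = FALSE),
                                        collapse = "") else tree
    st <- read_species_tree(txt, genomes)
  } else {
    st <- tree
    if (all(vapply(st$genomes[tree_leaves(st)], is.null, logical(1))))
      st <- attach_genomes(st, genomes)
  }
  needs_wgd <- any(vapply(st$genomes[tree_leaves(st)], function(g) {
    tab <- mult_table(g); any(tab[names(tab) != "O"] >= 2L)
  }, logical(1)))
  if (needs_wgd && !any(st$kind == "wgd")) st <- insert_wgd_nodes(st)
  st <- assign_gene_content(st)
  result <- gapadj(st, node, ...)
  report <- if (!is.null(truth))
    error_rate(result, truth, max_alpha = result$max_alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cars(result, file.path(out_dir, "cars.txt"))
    write_junction_report(result, file.path(out_dir, "junctions.tsv"))
    utils::write.table(result$log, file.path(out_dir, "log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(result = result, report = report)
}
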