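# Evaluation of an inferred CAR set against a known ancestral genome.
#
# The error rate is the fraction of inferred adjacencies -- the chained
# junctions inside CARs -- that are contradicted by the true genome: a
# junction joining signed genes (x, y) at iteration alpha is correct when
# y lies within the alpha-gap window of x in the truth.  Junctions keep
# the gap bound that created them (the `join_alpha` attribute written by
# the assembly); a bare CAR set without provenance is checked at
# `max_alpha` throughout.

cars_as_genome <- function(cars, name = "inferred") {
  genome(lapply(cars, as.vector), circular = FALSE, name = name)
}

# junction table of a CAR set: left token, right token, creation alpha
car_junctions <- function(cars, default_alpha) {
  rows <- lapply(seq_along(cars), function(i) {
    g <- cars[[i]]
    if (length(g) < 2L) return(NULL)
    a <- attr(g, "join_alpha")
    if (is.null(a)) a <- rep(default_alpha, length(g) - 1L)
    a[is.na(a)] <- default_alpha
    data.frame(left = g[-length(g)], right = g[-1L], alpha = as.integer(a))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(left = character(0), right = character(0),
                               alpha = integer(0))
  else out
}

# is each junction's right gene inside the left gene's alpha window of
# `truth`? (checked from the left gene's side; the relation is symmetric)
junctions_supported <- function(junc, truth, strict = TRUE) {
  if (nrow(junc) == 0L) return(logical(0))
  ok <- logical(nrow(junc))
  tgenes <- gene_set(truth)
  for (a in unique(junc$alpha)) {
    sel <- which(junc$alpha == a)
    for (k in sel) {
      x <- junc$left[k]; y <- junc$right[k]
      g <- gene_of(x)
      if (!g %in% tgenes) { ok[k] <- FALSE; next }
      ok[k] <- if (sign_of(x) > 0)
        y %in% alpha_adjacencies(truth, g, "right", a, strict)
      else
        negate_tok(y) %in% alpha_adjacencies(truth, g, "left", a, strict)
    }
  }
  ok
}

#' Adjacency error rate of an inferred CAR set
#'
#' The fraction of inferred adjacencies -- the junctions chaining
#' consecutive signed genes inside CARs -- that are not gapped
#' adjacencies of the true ancestor. A junction made at gap bound
#' `alpha` is correct when its downstream gene lies within the upstream
#' gene's alpha-gap window in the truth; junctions carry the iteration
#' that created them when `inferred` comes from [gapadj()], and are
#' checked at `max_alpha` otherwise. Telomere (`O`) adjacencies are CAR
#' ends and take no part.
#'
#' @param inferred a `gapadj_result` or `car_set`.
#' @param truth the true ancestral `genome`.
#' @param max_alpha gap bound used for junctions without provenance (and
#'   upper bound of the per-alpha breakdown).
#' @param strict_gap_exclusion passed to adjacency extraction.
#' @return object of class `evaluation_report`: `error_rate` in [0, 1],
#'   `n_cars`, `n_true_chromosomes`, and `per_alpha` (junctions grouped
#'   by the iteration that created them).
#' @export
error_rate <- function(inferred, truth, max_alpha = 1L,
                       strict_gap_exclusion = TRUE) {
  if (inherits(inferred, "gapadj_result")) inferred <- inferred$cars
  if (length(inferred) == 0L) stop("empty inferred CAR set")
  stopifnot(inherits(truth, "genome"))
  junc <- car_junctions(inferred, default_alpha = max_alpha)
  ok <- junctions_supported(junc, truth, strict_gap_exclusion)
  per <- data.frame(alpha = seq_len(max_alpha), errors = 0L, total = 0L)
  if (nrow(junc) > 0L) {
    tab_tot <- table(factor(junc$alpha, levels = seq_len(max_alpha)))
    tab_err <- table(factor(junc$alpha[!ok], levels = seq_len(max_alpha)))
    per$total <- as.integer(tab_tot)
    per$errors <- as.integer(tab_err)
  }
  structure(list(error_rate = if (nrow(junc) == 0L) 0
                 else sum(!ok) / nrow(junc),
                 n_cars = length(inferred),
                 n_true_chromosomes = length(truth$chrom),
                 per_alpha = per),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> error rate %.3f (%d/%d junctions), %d CAR(s), %d true chromosome(s)\n",
              x$error_rate, sum(x$per_alpha$errors), sum(x$per_alpha$total),
              x$n_cars, x$n_true_chromosomes))
  invisible(x)
}

#' Fraction of inferred adjacencies contradicted by another CAR set
#'
#' The fraction of the first CAR set's junctions whose gene pair is not
#' an alpha-gapped adjacency of the second CAR set (read as a genome),
#' at one fixed gap bound.
#'
#' @param cars_a,cars_b `car_set` objects (or `gapadj_result`s).
#' @param alpha the gap bound.
#' @inheritParams error_rate
#' @return fraction in [0, 1] (0 when the first set has no junctions).
#' @export
disagreement_fraction <- function(cars_a, cars_b, alpha = 1L,
                                  strict_gap_exclusion = TRUE) {
  if (inherits(cars_a, "gapadj_result")) cars_a <- cars_a$cars
  if (inherits(cars_b, "gapadj_result")) cars_b <- cars_b$cars
  junc <- car_junctions(cars_a, default_alpha = alpha)
  if (nrow(junc) == 0L) return(0)
  junc$alpha <- as.integer(alpha)
  ok <- junctions_supported(junc, cars_as_genome(cars_b, "B"),
                            strict_gap_exclusion)
  sum(!ok) / nrow(junc)
}

#' Aggregate evaluation reports over replicates
#'
#' @param replicates list of `evaluation_report` objects.
#' @return data.frame with mean and standard error of the error rate and
#'   CAR count.
#' @export
summarize_reports <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  er <- vapply(replicates, function(r) r$error_rate, numeric(1))
  nc <- vapply(replicates, function(r) as.numeric(r$n_cars), numeric(1))
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  data.frame(metric = c("error_rate", "n_cars"),
             mean = c(mean(er), mean(nc)),
             se = c(se(er), se(nc)),
             n = length(replicates))
}
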