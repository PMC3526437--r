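# Shared simulation-protocol runners for the acceptance tests, memoised
# so criteria drawing on the same protocol reuse one set of replicates.

.protocol_cache <- new.env(parent = emptyenv())

# inversion-only protocol on the six-leaf tree; per-replicate statistics
inversion_protocol <- function(rmax, reps = 20L) {
  key <- sprintf("inv_%d_%d", rmax, reps)
  if (!is.null(.protocol_cache[[key]])) return(.protocol_cache[[key]])
  out <- lapply(seq_len(reps), function(rep) {
    st <- simulate_evolution(six_leaf_fixture(), n_genes = 200,
                            n_chromosomes = 1, rmax = rmax, seed = rep)
    truth <- st$genomes[[match("SIGMA", st$name)]]
    res <- gapadj(st, "SIGMA", seed = rep, snapshot_alphas = 1L)
    first <- res$snapshots[["1"]]
    list(cars1 = length(first), fin = length(res$cars),
         err1 = error_rate(first, truth, max_alpha = 1)$error_rate,
         err50 = error_rate(res, truth, max_alpha = 50)$error_rate)
  })
  .protocol_cache[[key]] <- out
  out
}

multichrom_protocol <- function(rmax, reps = 20L) {
  key <- sprintf("mc_%d_%d", rmax, reps)
  if (!is.null(.protocol_cache[[key]])) return(.protocol_cache[[key]])
  out <- lapply(seq_len(reps), function(rep) {
    st <- simulate_evolution(six_leaf_fixture(), n_genes = 200,
                            n_chromosomes = 2, rmax = rmax,
                            branch_losses = 5, seed = rep)
    truth <- st$genomes[[match("SIGMA", st$name)]]
    res <- gapadj(st, "SIGMA", seed = rep)
    list(fin = length(res$cars),
         err50 = error_rate(res, truth, max_alpha = 50)$error_rate)
  })
  .protocol_cache[[key]] <- out
  out
}

wgd_protocol <- function(reps = 20L, wgd_losses = 50L, rmax = 10L) {
  key <- sprintf("wgd_%d_%d_%d", reps, wgd_losses, rmax)
  if (!is.null(.protocol_cache[[key]])) return(.protocol_cache[[key]])
  out <- lapply(seq_len(reps), function(rep) {
    st <- simulate_evolution(cereal_fixture(), n_genes = 200,
                            n_chromosomes = 2, rmax = rmax,
                            branch_losses = 5, wgd_losses = wgd_losses,
                            seed = rep)
    truth <- st$genomes[[match("wgd_R3", st$name)]]
    res <- gapadj(st, "wgd_R3", seed = rep)
    list(fin = length(res$cars),
         err50 = error_rate(res, truth, max_alpha = 50)$error_rate)
  })
  .protocol_cache[[key]] <- out
  out
}

stat_of <- function(runs, field) vapply(runs, `[[`, numeric(1), field)
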