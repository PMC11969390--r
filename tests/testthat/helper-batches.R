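# 50-replicate default-size batches of the four scenarios, computed once and
# shared by the acceptance tests (they are the expensive part of the suite).

.batch_cache <- new.env(parent = emptyenv())

acceptance_batches <- function(replicates = 50, base_seed = 20260920) {
  key <- sprintf("b%d_%d", replicates, base_seed)
  if (is.null(.batch_cache[[key]])) {
    scen <- c("i", "ii", "iii", "iv")
    .batch_cache[[key]] <- lapply(stats::setNames(scen, scen), function(sc) {
      run_batch(sc, base_seed = base_seed + 101 * match(sc, scen),
                replicates = replicates)
    })
  }
  .batch_cache[[key]]
}

batch_mean <- function(batch, metric) {
  batch$aggregate$mean[batch$aggregate$metric == metric]
}
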