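# Shared small simulation used by several test files. Built once per test
# run; deterministic in the config seed.
small_cfg <- function(seed = 42, ...) {
  args <- list(n_chromosomes_per_subgenome = 4, genes_per_chromosome = 12,
               chrom_length = 6e4, depth_per_copy = 100,
               n_hybrid_chromosomes = 1, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_cfg()
      sim <- simulate_hybrid_genome(cfg)
      des <- sim_design(strains = "W", conditions = c("minimal", "day2"),
                        n_replicates = 3)
      cts <- simulate_counts(sim$genes, sim$truth, des, cfg)
      cache <<- list(cfg = cfg, sim = sim, des = des, cts = cts)
    }
    cache
  }
})

# genes with true copy numbers attached, for pairing tests
genes_with_truth_cn <- function(sim) {
  dplyr::left_join(sim$genes, sim$truth$gene_cn[, c("gene_id", "cn_true")],
                   by = "gene_id") |>
    dplyr::rename(cn = "cn_true")
}
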