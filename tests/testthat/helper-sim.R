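# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

tiny_config <- function(n_genes = 40, n_proteins = 8, seed = 1, ...) {
  sim_config(n_genes = n_genes, n_proteins = n_proteins,
             depth_per_event = 200, targets_per_protein = 5, seed = seed,
             ...)
}

# models + counts for a small screen
tiny_screen <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  models <- generate_gene_models(cfg)
  counts <- simulate_counts(models, cfg)
  list(cfg = cfg, models = models, counts = counts)
}

# run quantification + differential testing on simulated counts
quantify_and_test <- function(models, counts, min_total = 20, fdr = 0.05,
                              dpsi_min = 10) {
  ev <- truth_events(models$truth)
  ic <- count_isoform_reads(ev, counts$junction_counts,
                            counts$region_counts)
  pooled <- pool_replicates(ic, counts$metadata)
  vref <- build_virtual_reference(pooled, ev, min_total = min_total)
  calls <- diff_splice(pooled, ev, vref, min_total = min_total, fdr = fdr,
                       dpsi_min = dpsi_min)
  psi <- splicescreen:::event_psi_table(pooled, ev)
  list(events = ev, counts = pooled, psi = psi, vref = vref, calls = calls)
}

# independent textbook BH step-up reimplementation (oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  i <- m:1L
  q <- pmin(1, cummin(m / i * p[o]))
  q[ro]
}

# exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins, probability of each via choose(), sum those <= observed
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  tot <- choose(m + n, k)
  pr <- choose(m, support) * choose(n, k - support) / tot
  pobs <- choose(m, a) * choose(n, k - a) / tot
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# brute-force junction grouping oracle for the index
group_oracle <- function(jn, field) {
  split(seq_len(nrow(jn)), paste(jn$chrom, jn$strand, jn[[field]], sep = "|"))
}
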