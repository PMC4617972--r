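test_that("config validation catches bad proportions and ranges", {
  expect_error(sim_config(event_type_mix = c(SE = 0.5)), "sum to 1")
  expect_error(sim_config(dispersion = 1), "dispersion")
  expect_error(sim_config(depth_per_event = 0), "depth")
  expect_error(sim_config(psi_range = c(0.9, 0.1)), "psi_range")
  expect_error(sim_config(cross_links = list(
    list(regulator = "P01", target = "P02", delta_psi = 0.05))), ">= 0.10")
})

test_that("one gene per event type is planted when the mix forces it", {
  mix <- setNames(rep(1 / 8, 8), event_types())
  cfg <- sim_config(n_genes = 8, event_type_mix = mix, n_proteins = 2,
                    seed = 1)
  models <- generate_gene_models(cfg)
  ev <- models$truth$events
  expect_equal(length(unique(ev$event_id)), 8)
  expect_setequal(unique(ev$event_type), event_types())
})

test_that("an empty simulation yields empty models and truth", {
  cfg <- sim_config(n_genes = 0, n_proteins = 3, seed = 1)
  models <- generate_gene_models(cfg)
  expect_equal(nrow(models$exons), 0)
  expect_equal(nrow(models$junctions), 0)
  expect_equal(nrow(models$truth$events), 0)
  expect_equal(nrow(models$truth$effects), 0)
})

test_that("discovery on an SE-only simulation recovers all planted events", {
  cfg <- sim_config(n_genes = 200, event_type_mix = c(SE = 1),
                    n_proteins = 4, seed = 7)
  models <- generate_gene_models(cfg)
  disc <- discover_events(models$junctions, models$exons)
  expect_equal(length(unique(disc$event_id)), 200)
  expect_true(all(disc$event_type == "SE"))
  expect_setequal(event_signatures(disc),
                  event_signatures(truth_events(models$truth)))
})

test_that("identical config and seed give bit-identical simulations", {
  s1 <- tiny_screen(seed = 42)
  s2 <- tiny_screen(seed = 42)
  expect_identical(s1$models, s2$models)
  expect_identical(s1$counts, s2$counts)
  s3 <- tiny_screen(seed = 43)
  expect_false(identical(s1$counts$junction_counts,
                         s3$counts$junction_counts))
})

test_that("planted effects shift the empirical PSI as configured", {
  # near-zero dispersion, very high depth: abundance PSI converges on the
  # planted effective PSI in affected samples and the baseline elsewhere
  cfg <- sim_config(n_genes = 6, event_type_mix = c(SE = 1), n_proteins = 2,
                    n_replicates = 1, depth_per_event = 100000,
                    dispersion = 0, targets_per_protein = 0, seed = 11)
  models <- generate_gene_models(cfg)
  ev1 <- models$truth$events[models$truth$events$isoform_index ==
                               models$truth$events$inclusion_index, ]
  models$truth$effects <- data.frame(
    event_id = ev1$event_id[1], protein = "P01",
    affected_isoform = ev1$inclusion_index[1], delta_psi = 0.30,
    tier = "moderate", source = "fixed", stringsAsFactors = FALSE)
  # keep the shift feasible for this baseline
  expect_lte(ev1$iso_psi[1] + 0.30, 1)
  counts <- simulate_counts(models, cfg)
  ic <- count_isoform_reads(truth_events(models$truth),
                            counts$junction_counts, counts$region_counts)
  psi <- splicescreen:::event_psi_table(ic, truth_events(models$truth))
  aff <- psi[psi$event_id == ev1$event_id[1] & psi$sample_id == "P01_rep1", ]
  un <- psi[psi$event_id == ev1$event_id[1] &
              psi$sample_id == "untreated", ]
  expect_equal(aff$psi, ev1$iso_psi[1] + 0.30, tolerance = 0.01)
  expect_equal(un$psi, ev1$iso_psi[1], tolerance = 0.01)
})

test_that("an infeasible effective PSI is a hard error", {
  cfg <- sim_config(n_genes = 2, event_type_mix = c(SE = 1), n_proteins = 1,
                    seed = 1, targets_per_protein = 0)
  models <- generate_gene_models(cfg)
  ev1 <- models$truth$events[models$truth$events$isoform_index ==
                               models$truth$events$inclusion_index, ]
  models$truth$effects <- data.frame(
    event_id = ev1$event_id[1], protein = "P01",
    affected_isoform = ev1$inclusion_index[1], delta_psi = 0.95,
    tier = "strong", source = "fixed", stringsAsFactors = FALSE)
  expect_error(simulate_counts(models, cfg), "outside")
})

test_that("inclusion count variance matches the beta-binomial model", {
  # one cassette exon observed across many independent libraries
  rho <- 0.05
  cfg <- sim_config(n_genes = 1, event_type_mix = c(SE = 1),
                    n_proteins = 1500, n_replicates = 1,
                    depth_per_event = 200, dispersion = rho,
                    targets_per_protein = 0, seed = 5)
  models <- generate_gene_models(cfg)
  counts <- simulate_counts(models, cfg)
  ev <- truth_events(models$truth)
  ic <- count_isoform_reads(ev, counts$junction_counts,
                            counts$region_counts)
  inc_idx <- ev$inclusion_index[1]
  x <- ic$count[ic$isoform_index == inc_idx]
  psi <- models$truth$events$iso_psi[
    models$truth$events$isoform_index == inc_idx]
  lens <- ev$iso_length
  q <- psi * lens[inc_idx] /
    (psi * lens[inc_idx] + (1 - psi) * lens[-inc_idx])
  lam <- 200
  # X | N ~ BetaBin(N, q, rho), N ~ Poisson(lam):
  # Var(X) = q^2 lam + q(1-q) lam + q(1-q) rho lam^2
  v_theory <- q^2 * lam + q * (1 - q) * lam + q * (1 - q) * rho * lam^2
  expect_equal(stats::var(x), v_theory, tolerance = 0.12)
  expect_equal(mean(x), q * lam, tolerance = 0.02)
})

test_that("read-offset histograms behave as specified", {
  h <- simulate_read_offsets(400, n_offsets = 4)
  expect_equal(h$count, rep(100L, 4))
  expect_equal(shannon_entropy(h$count), 2.0)
  h1 <- simulate_read_offsets(400, n_offsets = 4, mode = "single")
  expect_equal(sum(h1$count), 400L)
  expect_equal(shannon_entropy(h1$count), 0)
  h2 <- simulate_read_offsets(0, n_offsets = 3)
  expect_equal(sum(h2$count), 0L)
})

test_that("fixtures round-trip through the readers", {
  s <- tiny_screen(seed = 9, n_proteins = 5)
  d <- withr::local_tempdir()
  write_fixtures(s$models, s$counts, d)
  # 5 proteins x 2 replicates + untreated
  expect_length(list.files(file.path(d, "junctions")), 11)

  meta <- splicescreen:::read_tsv(file.path(d, "metadata.tsv"))
  expect_equal(meta[, names(s$counts$metadata)], s$counts$metadata)

  exons <- read_exon_gtf(file.path(d, "annotation.gtf"))
  expect_equal(exons[, c("chrom", "start", "end", "strand", "gene_id")],
               s$models$exons[order(s$models$exons$chrom,
                                    s$models$exons$start,
                                    s$models$exons$end,
                                    s$models$exons$gene_id),
                              c("chrom", "start", "end", "strand",
                                "gene_id")],
               ignore_attr = TRUE)
  expect_equal(sum(exons$is_first_exon), sum(s$models$exons$is_first_exon))
  expect_equal(sum(exons$cage_supported), sum(s$models$exons$cage_supported))

  one <- read_junction_bed(file.path(d, "junctions", "P01_rep1.bed"))
  want <- s$counts$junction_counts[
    s$counts$junction_counts$sample_id == "P01_rep1" &
      s$counts$junction_counts$count > 0, ]
  got_key <- junction_key(one$chrom, one$donor, one$acceptor, one$strand)
  expect_setequal(got_key, want$junction)
  expect_equal(one$count[match(want$junction, got_key)], want$count)

  tr <- splicescreen:::read_tsv(file.path(d, "truth_events.tsv"))
  expect_setequal(event_signatures(tr),
                  event_signatures(s$models$truth$events))
})
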