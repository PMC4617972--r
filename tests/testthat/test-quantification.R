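# helper: assemble a 2-isoform SE-style event table directly
mk_event <- function(eid = "SE@g1", incl_jn = c("c:100-200:+", "c:250-400:+"),
                     excl_jn = "c:100-400:+", incl_len = 2, excl_len = 1) {
  data.frame(event_id = eid, gene_id = "g1", event_type = "SE", chrom = "c",
             strand = "+", isoform_index = 1:2, n_isoforms = 2L,
             inclusion_index = 1L,
             junctions = c(paste(incl_jn, collapse = ";"),
                           paste(excl_jn, collapse = ";")),
             region = NA_character_, iso_length = c(incl_len, excl_len),
             stringsAsFactors = FALSE)
}

mk_counts <- function(jn_counts, sample = "s1") {
  data.frame(sample_id = sample, junction = names(jn_counts),
             count = as.integer(jn_counts), stringsAsFactors = FALSE)
}

test_that("isoform counts sum junction support; shared junctions count for
           neither isoform", {
  ev <- mk_event()
  jc <- mk_counts(c("c:100-200:+" = 30, "c:250-400:+" = 50,
                    "c:100-400:+" = 20))
  ic <- count_isoform_reads(ev, jc)
  expect_equal(ic$count[ic$isoform_index == 1], 80L)
  expect_equal(ic$count[ic$isoform_index == 2], 20L)

  jc0 <- mk_counts(c("c:100-200:+" = 0, "c:250-400:+" = 0,
                     "c:100-400:+" = 0))
  ic0 <- count_isoform_reads(ev, jc0)
  expect_equal(sum(ic0$count), 0L)

  # a junction listed in both isoforms is ambiguous support
  ev2 <- mk_event(incl_jn = c("c:100-200:+", "c:900-950:+"),
                  excl_jn = c("c:100-400:+", "c:900-950:+"))
  jc2 <- mk_counts(c("c:100-200:+" = 10, "c:900-950:+" = 99,
                     "c:100-400:+" = 5))
  ic2 <- count_isoform_reads(ev2, jc2)
  expect_equal(ic2$count[ic2$isoform_index == 1], 10L)
  expect_equal(ic2$count[ic2$isoform_index == 2], 5L)
})

test_that("missing junctions count as zero with a warning", {
  ev <- mk_event()
  jc <- mk_counts(c("c:100-200:+" = 30, "c:100-400:+" = 20))
  expect_warning(ic <- count_isoform_reads(ev, jc), "absent")
  expect_equal(ic$count[ic$isoform_index == 1], 30L)
})

test_that("simulated per-isoform counts match the simulator's bookkeeping", {
  s <- tiny_screen(seed = 21, n_genes = 60)
  ev <- truth_events(s$models$truth)
  ic <- count_isoform_reads(ev, s$counts$junction_counts,
                            s$counts$region_counts)
  # every junction read lands in exactly one isoform of one event, and every
  # region read in one isoform: totals must agree
  expect_equal(sum(ic$count),
               sum(s$counts$junction_counts$count) +
                 sum(s$counts$region_counts$count))
  # per-sample totals agree too
  by_sample <- tapply(ic$count, ic$sample_id, sum)
  want <- tapply(s$counts$junction_counts$count,
                 s$counts$junction_counts$sample_id, sum) +
    tapply(s$counts$region_counts$count,
           s$counts$region_counts$sample_id, sum)
  expect_equal(by_sample[names(want)], want)
})

test_that("abundance is count over length and rejects bad lengths", {
  expect_equal(isoform_abundance(80, 2), 40)
  expect_equal(isoform_abundance(0, 5), 0)
  expect_error(isoform_abundance(10, 0), "positive")
  expect_error(isoform_abundance(10, -1), "positive")
})

test_that("PSI follows the abundance formula with boundary conventions", {
  expect_equal(compute_psi(40, 20), 2 / 3)
  expect_equal(compute_psi(0, 20), 0)
  expect_equal(compute_psi(40, 0), 1)
  expect_true(is.na(compute_psi(0, 0)))
  # SE asymmetry: counts (80, 20) with lengths (2, 1)
  expect_equal(compute_psi(isoform_abundance(80, 2),
                           isoform_abundance(20, 1)), 2 / 3)
})

test_that("PSI is invariant to scaling all counts of an event", {
  for (sc in c(2, 10, 137)) {
    expect_equal(compute_psi(isoform_abundance(80 * sc, 2),
                             isoform_abundance(20 * sc, 1)),
                 compute_psi(isoform_abundance(80, 2),
                             isoform_abundance(20, 1)))
  }
})

test_that("the 20-read expression cutoff is inclusive", {
  rows <- data.frame(event_id = c("e1", "e2"), sample_id = "s",
                     total = c(19L, 20L))
  out <- apply_expression_cutoff(rows, min_total = 20)
  expect_equal(out$event_id, "e2")
  rep <- attr(out, "cutoff_report")
  expect_equal(rep$rows_testable, 1)

  # surviving set equals a brute-force filter on a random matrix
  set.seed(4)
  rows2 <- data.frame(event_id = sprintf("e%03d", 1:200),
                      sample_id = "s", total = rpois(200, 20))
  out2 <- apply_expression_cutoff(rows2, min_total = 20)
  expect_setequal(out2$event_id, rows2$event_id[rows2$total >= 20])
})

test_that("virtual reference equals median total times median ratios", {
  ev <- mk_event()
  counts <- rbind(
    data.frame(event_id = "SE@g1", sample_id = "c1", isoform_index = 1:2,
               count = c(50L, 50L)),
    data.frame(event_id = "SE@g1", sample_id = "c2", isoform_index = 1:2,
               count = c(120L, 80L)),
    data.frame(event_id = "SE@g1", sample_id = "c3", isoform_index = 1:2,
               count = c(210L, 90L)))
  vr <- build_virtual_reference(counts, ev)
  expect_equal(vr$median_total[1], 200)
  expect_equal(vr$vref_count, c(120, 80))
  expect_equal(vr$vref_rounded, c(120L, 80L))
})

test_that("identical samples are a virtual-reference fixed point", {
  ev <- mk_event()
  counts <- do.call(rbind, lapply(sprintf("c%d", 1:5), function(s)
    data.frame(event_id = "SE@g1", sample_id = s, isoform_index = 1:2,
               count = c(60L, 40L))))
  vr <- build_virtual_reference(counts, ev)
  expect_equal(vr$vref_count, c(60, 40))
  calls <- diff_splice(counts, ev, vr)
  expect_equal(calls$delta_psi, rep(0, 5))
  expect_equal(calls$raw_p, rep(1, 5))
  expect_false(any(calls$significant))
})

test_that("even sample counts use the mean of the central pair", {
  ev <- mk_event()
  counts <- rbind(
    data.frame(event_id = "SE@g1", sample_id = "c1", isoform_index = 1:2,
               count = c(50L, 50L)),
    data.frame(event_id = "SE@g1", sample_id = "c2", isoform_index = 1:2,
               count = c(100L, 100L)),
    data.frame(event_id = "SE@g1", sample_id = "c3", isoform_index = 1:2,
               count = c(30L, 30L)),
    data.frame(event_id = "SE@g1", sample_id = "c4", isoform_index = 1:2,
               count = c(60L, 60L)))
  vr <- build_virtual_reference(counts, ev, min_total = 20)
  # totals 100, 200, 60, 120 -> median (100 + 120) / 2 = 110
  expect_equal(vr$median_total[1], 110)
})

test_that("events testable in fewer than three RNAi samples get no
           reference", {
  ev <- mk_event()
  counts <- rbind(
    data.frame(event_id = "SE@g1", sample_id = "c1", isoform_index = 1:2,
               count = c(60L, 40L)),
    data.frame(event_id = "SE@g1", sample_id = "c2", isoform_index = 1:2,
               count = c(60L, 40L)),
    data.frame(event_id = "SE@g1", sample_id = "c3", isoform_index = 1:2,
               count = c(5L, 4L)),
    data.frame(event_id = "SE@g1", sample_id = "untreated",
               isoform_index = 1:2, count = c(60L, 40L)))
  vr <- build_virtual_reference(counts, ev)
  expect_equal(nrow(vr), 0)
})

test_that("replicate pooling sums counts per condition", {
  s <- tiny_screen(seed = 2, n_genes = 10)
  ev <- truth_events(s$models$truth)
  ic <- count_isoform_reads(ev, s$counts$junction_counts,
                            s$counts$region_counts)
  pooled <- pool_replicates(ic, s$counts$metadata)
  one <- ev$event_id[1]
  want <- sum(ic$count[ic$event_id == one &
                         ic$sample_id %in% c("P01_rep1", "P01_rep2")])
  expect_equal(sum(pooled$count[pooled$event_id == one &
                                  pooled$sample_id == "P01"]), want)
  expect_setequal(unique(pooled$sample_id),
                  unique(s$counts$metadata$protein))
})
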