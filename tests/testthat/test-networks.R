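mk_calls <- function(conds, event_ids, dpsi, sig = TRUE, type = "SE",
                     gene = "gX") {
  data.frame(event_id = event_ids, gene_id = gene, event_type = type,
             condition = conds, tested_isoform = 1L, raw_p = 0.001,
             psi_sample = 0.5, psi_vref = 0.5, delta_psi = dpsi,
             corrected_p = 0.001, significant = sig,
             magnitude = ifelse(abs(dpsi) > 50, "strong",
                         ifelse(abs(dpsi) > 25, "moderate", "weak")),
             direction = ifelse(dpsi < 0, "activated", "repressed"),
             stringsAsFactors = FALSE)
}

binom_oracle <- function(x, n, p = 0.5) {
  pr <- stats::dbinom(0:n, n, p)
  sum(pr[pr <= pr[x + 1] * (1 + 1e-7)])
}

test_that("bias test matches closed forms and exhaustive enumeration", {
  calls <- mk_calls(rep("P01", 16), sprintf("e%d", 1:16), dpsi = -30)
  b <- regulator_bias(calls)
  expect_equal(b$n_activated, 16)
  expect_equal(b$binomial_p, 2 * 0.5^16, tolerance = 1e-9)
  expect_equal(b$bias_label, "activator")

  bal <- mk_calls(rep("P02", 20), sprintf("e%d", 1:20),
                  dpsi = rep(c(-30, 30), 10))
  b2 <- regulator_bias(bal)
  expect_equal(b2$binomial_p, 1)
  expect_equal(b2$bias_label, "none")

  for (n in c(5, 12, 30)) for (x in c(0, 2, n %/% 2, n)) {
    expect_equal(binom_two_sided(x, n), binom_oracle(x, n),
                 tolerance = 1e-9)
  }
})

test_that("a simulated strong activator is flagged at the Bonferroni level
           and a balanced regulator is not", {
  set.seed(19)
  flagged_act <- flagged_bal <- 0L
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    n_act <- rbinom(1, 50, 0.9)
    calls <- rbind(
      mk_calls(rep("PA", 50), sprintf("a%d", 1:50),
               dpsi = c(rep(-30, n_act), rep(30, 50 - n_act))),
      mk_calls(rep("PB", 50), sprintf("b%d", 1:50),
               dpsi = ifelse(rbinom(50, 1, 0.5) == 1, -30, 30)))
    # Bonferroni over the 56 proteins of a full screen
    b <- regulator_bias(calls)
    b$bonferroni_p <- pmin(1, b$binomial_p * 56)
    flagged_act <- flagged_act + (b$bonferroni_p[b$protein == "PA"] < 0.05)
    flagged_bal <- flagged_bal + (b$bonferroni_p[b$protein == "PB"] < 0.05)
  }
  expect_gte(flagged_act / n_rep, 0.95)
  expect_lte(flagged_bal / n_rep, 0.05)
})

test_that("pair overlap matches the Fisher oracle and labels direction
           agreement", {
  universe <- sprintf("e%03d", 1:100)
  testable <- expand.grid(event_id = universe, condition = c("A", "B"),
                          stringsAsFactors = FALSE)
  shared <- universe[1:10]
  calls <- rbind(mk_calls(rep("A", 10), shared, dpsi = -30),
                 mk_calls(rep("B", 10), shared,
                          dpsi = c(rep(-30, 7), rep(30, 3))))
  po <- pairwise_overlap(calls, testable)
  expect_equal(nrow(po), 1)
  expect_equal(po$shared_events, 10)
  expect_equal(po$coordinated, 7)
  expect_equal(po$antagonistic, 3)
  expect_equal(po$fisher_p, fisher_oracle(10, 0, 0, 90), tolerance = 1e-9)
  expect_true(po$significant_overlap)
  expect_equal(po$pair_label, "coordinated")
  # symmetric in the pair: relabeling proteins swaps nothing material
  calls2 <- calls
  calls2$condition <- ifelse(calls$condition == "A", "B", "A")
  po2 <- pairwise_overlap(calls2, testable)
  expect_equal(po2[, c("universe", "shared_events", "fisher_p")],
               po[, c("universe", "shared_events", "fisher_p")])

  # disjoint call sets in a large universe are not significant
  big <- sprintf("e%04d", 1:1000)
  tst <- expand.grid(event_id = big, condition = c("A", "B"),
                     stringsAsFactors = FALSE)
  calls3 <- rbind(mk_calls(rep("A", 10), big[1:10], dpsi = -30),
                  mk_calls(rep("B", 10), big[11:20], dpsi = -30))
  po3 <- pairwise_overlap(calls3, tst)
  expect_false(po3$significant_overlap)

  # 14 of 16 shared events in the same direction: coordinated
  sh <- big[1:16]
  calls4 <- rbind(mk_calls(rep("A", 16), sh, dpsi = -30),
                  mk_calls(rep("B", 16), sh,
                           dpsi = c(rep(-30, 14), rep(30, 2))))
  po4 <- pairwise_overlap(calls4, tst)
  expect_equal(po4$coordinated, 14)
  expect_equal(po4$pair_label, "coordinated")
})

test_that("cross-regulation matrix records planted links under the
           magnitude filter", {
  pg <- data.frame(protein = c("P01", "P02", "P03"),
                   gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  no_calls <- mk_calls("P01", "e0", 40)[0, ]
  expect_true(all(cross_regulation_matrix(no_calls, pg) == 0))
  calls <- rbind(mk_calls("P01", "e1", dpsi = 40, gene = "g2"),
                 mk_calls("P01", "e2", dpsi = 15, gene = "g3"),
                 mk_calls("P02", "e3", dpsi = -60, gene = "g2"))
  M <- cross_regulation_matrix(calls, pg)
  expect_equal(M["P01", "P02"], 1L)
  expect_equal(M["P01", "P03"], 0L)  # weak excluded by default
  expect_equal(attr(M, "self_targeting"), 1L)  # P02 on its own gene
  Mw <- cross_regulation_matrix(calls, pg, min_magnitude = "weak")
  expect_equal(Mw["P01", "P03"], 1L)
})

test_that("confounded pairs are flagged from the cross matrix", {
  pg <- data.frame(protein = c("A", "B"), gene_id = c("gA", "gB"),
                   stringsAsFactors = FALSE)
  pairs <- data.frame(protein_a = "A", protein_b = "B",
                      significant_overlap = TRUE, stringsAsFactors = FALSE)
  M0 <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_false(confounded_overlap_screen(pairs, M0)$confounded)
  M1 <- M0; M1["A", "B"] <- 2L
  expect_true(confounded_overlap_screen(pairs, M1)$confounded)
})

test_that("promoter-window TFBS scores equal brute-force base counting", {
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
  tss <- data.frame(gene_id = "g1", chrom = "chr1", pos = 5000L,
                    strand = "+", stringsAsFactors = FALSE)
  expect_equal(tf_promoter_targets(peaks, tss)$score, 2100)
  far <- data.frame(gene_id = "g2", chrom = "chr1", pos = 50000L,
                    strand = "+", stringsAsFactors = FALSE)
  expect_equal(tf_promoter_targets(peaks, far)$score, 0)
  expect_false(tf_promoter_targets(peaks, far)$is_target)

  set.seed(23)
  pk <- data.frame(chrom = "chr1",
                   start = sort(sample(0:100000, 60)) )
  pk$end <- pk$start + sample(50:800, 60, TRUE)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50), chrom = "chr1",
                      pos = sample(2000:98000, 50),
                      strand = sample(c("+", "-"), 50, TRUE),
                      stringsAsFactors = FALSE)
  got <- tf_promoter_targets(pk, genes)
  # oracle: per-base membership count
  covered <- rep(FALSE, 110001)
  for (i in seq_len(nrow(pk)))
    covered[(pk$start[i] + 1):min(pk$end[i], 110000)] <- TRUE
  want <- vapply(seq_len(50), function(i) {
    w <- if (genes$strand[i] == "+")
      c(genes$pos[i] - 2000, genes$pos[i] + 100)
    else c(genes$pos[i] - 100, genes$pos[i] + 2000)
    sum(covered[(w[1] + 1):w[2]])
  }, 0)
  expect_equal(got$score, want)

  # unknown strand is skipped with a warning
  bad <- rbind(genes, data.frame(gene_id = "gu", chrom = "chr1",
                                 pos = 5000L, strand = "*"))
  expect_warning(out <- tf_promoter_targets(pk, bad), "unknown strand")
  expect_false("gu" %in% out$gene_id)
})
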