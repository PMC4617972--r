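# Downstream statistics on the differential-splicing call matrix:
# activation/repression bias per protein, coordination/antagonism between
# protein pairs, cross-regulation among the assayed regulator genes, and
# promoter-window TF-target scoring.

#' Two-sided exact binomial test (point-probability convention)
#'
#' Sums the binomial point probabilities not exceeding that of the observed
#' count, the same convention as [stats::binom.test()]. Exposed separately
#' because the doubling-the-smaller-tail convention differs on asymmetric
#' counts.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param p Null success probability.
#' @return Two-sided p-value.
#' @export
binom_two_sided <- function(x, n, p = 0.5) {
  if (n == 0) return(1)
  stats::binom.test(x, n, p, alternative = "two.sided")$p.value
}

#' Activation/repression bias of each splicing regulator
#'
#' When depletion of a protein decreases inclusion of an exon (dPSI < 0) the
#' protein is inferred to activate that exon's splicing; increased inclusion
#' implies repression. Per protein, the counts of activated versus repressed
#' cassette exons are compared by a two-sided exact binomial test at p0 =
#' 0.5; Bonferroni correction is over the number of proteins with at least
#' one qualifying call. A bias label is assigned only at the corrected
#' threshold.
#'
#' @param calls Calls data frame from [diff_splice()].
#' @param event_type Event type whose calls enter the test (cassette exons).
#' @param alpha Significance threshold for the Bonferroni-corrected label.
#' @return Data frame, one row per protein, with `n_activated`,
#'   `n_repressed`, `binomial_p`, `bonferroni_p`, `bias_label`.
#' @export
regulator_bias <- function(calls, event_type = "SE", alpha = 0.05) {
  sig <- calls[calls$significant & calls$event_type == event_type, ,
               drop = FALSE]
  prots <- sort(unique(sig$condition))
  if (!length(prots))
    return(data.frame(protein = character(0), n_activated = integer(0),
                      n_repressed = integer(0), binomial_p = numeric(0),
                      bonferroni_p = numeric(0), bias_label = character(0),
                      stringsAsFactors = FALSE))
  m <- length(prots)
  out <- do.call(rbind, lapply(prots, function(p) {
    s <- sig[sig$condition == p, ]
    na <- sum(s$direction == "activated")
    nr <- sum(s$direction == "repressed")
    pb <- binom_two_sided(na, na + nr)
    data.frame(protein = p, n_activated = na, n_repressed = nr,
               binomial_p = pb, bonferroni_p = min(1, pb * m),
               stringsAsFactors = FALSE)
  }))
  out$bias_label <- ifelse(out$bonferroni_p >= alpha, "none",
                    ifelse(out$n_activated > out$n_repressed, "activator",
                           "repressor"))
  out
}

#' Coordinated and antagonistic regulator pairs
#'
#' For each unordered pair of proteins, the set of events testable in both
#' conditions forms the universe; a 2x2 table (affected by A x affected by
#' B) over that universe gives a two-sided Fisher's exact p-value for the
#' overlap, Bonferroni-corrected over the number of pairs with a non-empty
#' shared universe. Shared affected events are partitioned by whether both
#' knockdowns shift PSI in the same direction (coordinated) or opposite
#' directions (antagonistic); the pair is labeled by the majority, with ties
#' labeled mixed.
#'
#' @param calls Calls data frame.
#' @param testable Data frame (`event_id`, `condition`) of pairs that were
#'   testable (post-cutoff, with a virtual reference).
#' @param event_type Event type considered (cassette exons).
#' @param alpha Threshold on the Bonferroni-corrected p-value.
#' @return Data frame with one row per pair: `shared_events`, `coordinated`,
#'   `antagonistic`, `fisher_p`, `bonferroni_p`, `significant_overlap`,
#'   `pair_label`.
#' @export
pairwise_overlap <- function(calls, testable, event_type = "SE",
                             alpha = 0.05) {
  cl <- calls[calls$event_type == event_type, , drop = FALSE]
  tst <- if ("event_type" %in% names(testable))
    testable[testable$event_type == event_type, , drop = FALSE]
  else testable
  prots <- sort(unique(cl$condition))
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      universe = integer(0), shared_events = integer(0),
                      coordinated = integer(0), antagonistic = integer(0),
                      fisher_p = numeric(0), bonferroni_p = numeric(0),
                      significant_overlap = logical(0),
                      pair_label = character(0), stringsAsFactors = FALSE)
  if (length(prots) < 2) return(empty)
  tst_by <- split(tst$event_id, tst$condition)
  sig <- cl[cl$significant, ]
  sig_by <- split(sig$event_id, sig$condition)
  sgn_by <- split(sign(sig$delta_psi), sig$condition)
  rows <- list()
  for (i in seq_along(prots)) for (j in seq_along(prots)) {
    if (j <= i) next
    a <- prots[i]; b <- prots[j]
    uni <- intersect(tst_by[[a]], tst_by[[b]])
    if (!length(uni)) next
    sa <- intersect(sig_by[[a]] %||% character(0), uni)
    sb <- intersect(sig_by[[b]] %||% character(0), uni)
    both <- intersect(sa, sb)
    n11 <- length(both); n10 <- length(sa) - n11; n01 <- length(sb) - n11
    n00 <- length(uni) - n11 - n10 - n01
    pv <- fisher_exact_two_sided(n11, n10, n01, n00)
    if (length(both)) {
      da <- (sgn_by[[a]])[match(both, sig_by[[a]])]
      db <- (sgn_by[[b]])[match(both, sig_by[[b]])]
      coord <- sum(da == db); antag <- sum(da != db)
    } else coord <- antag <- 0L
    rows[[length(rows) + 1L]] <- data.frame(
      protein_a = a, protein_b = b, universe = length(uni),
      shared_events = n11, coordinated = coord, antagonistic = antag,
      fisher_p = pv, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$bonferroni_p <- pmin(1, out$fisher_p * m)
  out$significant_overlap <- out$bonferroni_p < alpha
  out$pair_label <- ifelse(out$coordinated > out$antagonistic, "coordinated",
                    ifelse(out$antagonistic > out$coordinated, "antagonistic",
                           "mixed"))
  out
}

magnitude_rank <- function(x) {
  match(x, c("none", "weak", "moderate", "strong")) - 1L
}

#' Cross-regulation matrix among the assayed regulator genes
#'
#' Counts, for each (regulator, target-protein) pair, the significant
#' splicing events on the target protein's own pre-mRNA upon depletion of
#' the regulator, restricted by default to moderate or strong magnitude
#' changes. Self-targeting (a regulator affecting its own gene) is excluded
#' from the matrix and reported in the `self_targeting` attribute.
#'
#' @param calls Calls data frame.
#' @param protein_gene Data frame mapping `protein` to `gene_id`.
#' @param min_magnitude Weakest magnitude tier admitted
#'   (`"weak"`, `"moderate"` or `"strong"`).
#' @return Integer matrix, regulators x target proteins.
#' @export
cross_regulation_matrix <- function(calls, protein_gene,
                                    min_magnitude = "moderate") {
  prots <- protein_gene$protein
  M <- matrix(0L, length(prots), length(prots),
              dimnames = list(regulator = prots, target = prots))
  sig <- calls[calls$significant &
                 magnitude_rank(calls$magnitude) >=
                   magnitude_rank(min_magnitude), , drop = FALSE]
  selfs <- 0L
  if (nrow(sig)) {
    tgt <- protein_gene$protein[match(sig$gene_id, protein_gene$gene_id)]
    hit <- !is.na(tgt) & sig$condition %in% prots
    for (i in which(hit)) {
      if (sig$condition[i] == tgt[i]) { selfs <- selfs + 1L; next }
      M[sig$condition[i], tgt[i]] <- M[sig$condition[i], tgt[i]] + 1L
    }
  }
  attr(M, "self_targeting") <- selfs
  M
}

#' Flag regulator pairs whose overlap could be a secondary effect
#'
#' A significant pair (A, B) is potentially confounded when depletion of A
#' alters the splicing of B's own gene (per the cross-regulation matrix) or
#' its expression (per an optional differential-expression table), in either
#' direction of the pair.
#'
#' @param pairs Data frame from [pairwise_overlap()].
#' @param cross_matrix Matrix from [cross_regulation_matrix()].
#' @param de_table Optional data frame (`condition`, `gene_id`,
#'   `significant`) of differential-expression calls.
#' @param protein_gene Mapping of proteins to their genes (needed with
#'   `de_table`).
#' @return `pairs` with a `confounded` flag column.
#' @export
confounded_overlap_screen <- function(pairs, cross_matrix, de_table = NULL,
                                      protein_gene = NULL) {
  link <- function(a, b) {
    x <- a %in% rownames(cross_matrix) && b %in% colnames(cross_matrix) &&
      cross_matrix[a, b] > 0
    if (!x && !is.null(de_table) && !is.null(protein_gene)) {
      gb <- protein_gene$gene_id[protein_gene$protein == b]
      x <- any(de_table$condition == a & de_table$gene_id %in% gb &
                 de_table$significant)
    }
    x
  }
  conf <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$protein_a[i]; b <- pairs$protein_b[i]
    link(a, b) || link(b, a)
  }, TRUE)
  pairs$confounded <- conf
  if (is.null(de_table))
    attr(pairs, "note") <- "no DE table supplied; splicing cross-matrix only"
  pairs
}

#' Transcription-factor target genes from promoter-window peak coverage
#'
#' Scores each gene by the number of bases covered by ChIP-seq peaks within
#' the strand-oriented window from `window_upstream` bp upstream to
#' `window_downstream` bp downstream of its transcription start; genes
#' scoring in the top `1 - cutoff_quantile` fraction of nonzero scores are
#' targets.
#'
#' @param peaks Data frame (`chrom`, `start`, `end`) of peak intervals
#'   (0-based half-open).
#' @param tss Data frame (`gene_id`, `chrom`, `pos`, `strand`) of
#'   transcription starts.
#' @param window_upstream,window_downstream Window extent in bp.
#' @param cutoff_quantile Quantile of nonzero scores defining targets
#'   (default 0.9: top 10%).
#' @return Data frame (`gene_id`, `score`, `is_target`); genes of unknown
#'   strand are skipped with a warning.
#' @export
tf_promoter_targets <- function(peaks, tss, window_upstream = 2000,
                                window_downstream = 100,
                                cutoff_quantile = 0.9) {
  unknown <- !tss$strand %in% c("+", "-")
  if (any(unknown)) {
    warnf("%d gene(s) with unknown strand skipped", sum(unknown))
    tss <- tss[!unknown, , drop = FALSE]
  }
  merged <- lapply(split(peaks, peaks$chrom), function(p) {
    r <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  })
  score <- vapply(seq_len(nrow(tss)), function(i) {
    w <- if (tss$strand[i] == "+")
      c(tss$pos[i] - window_upstream, tss$pos[i] + window_downstream)
    else c(tss$pos[i] - window_downstream, tss$pos[i] + window_upstream)
    m <- merged[[tss$chrom[i]]]
    if (is.null(m)) return(0)
    sum(pmax(0, pmin(m$end, w[2]) - pmax(m$start, w[1])))
  }, 0)
  nz <- score[score > 0]
  cut <- if (length(nz)) stats::quantile(nz, cutoff_quantile) else Inf
  data.frame(gene_id = tss$gene_id, score = score,
             is_target = score > 0 & score >= cut,
             stringsAsFactors = FALSE)
}
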