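# Per-condition differential splicing against the virtual reference:
# exact Fisher tests on inclusion/exclusion counts, Benjamini-Hochberg
# correction per (condition, event type), dPSI thresholding and magnitude
# tiers.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by log-space hypergeometric summation: the sum of
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a relative
#' tolerance of 1e-7, the usual convention for this test). A table with any
#' zero margin is uninformative and returns p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, laid out as
#'   rows = (sample, reference) and columns = (inclusion, exclusion).
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)    # 1
#' fisher_exact_two_sided(10, 0, 0, 10)  # ~1.08e-5
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0))
    stopf("Fisher table cells must be non-negative")
  vapply(seq_len(n), function(i)
    fisher_p_scalar(a[i], b[i], c[i], d[i]), 0)
}

fisher_p_scalar <- function(a, b, c, d) {
  m <- a + b; nn <- c + d; k <- a + c
  if (m == 0 || nn == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  logp <- stats::dhyper(support, m, nn, k, log = TRUE)
  lobs <- stats::dhyper(a, m, nn, k, log = TRUE)
  incl <- logp <= lobs + log(1 + 1e-7)
  if (all(incl)) return(1)
  min(1, sum(exp(logp[incl])))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment; within the pipeline it is applied separately
#' per (condition, event type) group.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_correct <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Test one event in one sample against its virtual reference
#'
#' @param sample_inclusion,sample_exclusion Observed counts.
#' @param vref_inclusion,vref_exclusion Rounded virtual-reference counts.
#' @param inclusion_len,exclusion_len Isoform lengths for the abundance
#'   normalization.
#' @param vref_inclusion_real,vref_exclusion_real Real-valued reference
#'   counts used for the reference PSI (default: the rounded ones).
#' @return List with `raw_p`, `delta_psi` (percentage points,
#'   sample minus reference), `psi_sample`, `psi_vref`.
#' @export
test_event <- function(sample_inclusion, sample_exclusion,
                       vref_inclusion, vref_exclusion,
                       inclusion_len = 1, exclusion_len = 1,
                       vref_inclusion_real = vref_inclusion,
                       vref_exclusion_real = vref_exclusion) {
  psi_s <- compute_psi(isoform_abundance(sample_inclusion, inclusion_len),
                       isoform_abundance(sample_exclusion, exclusion_len))
  psi_v <- compute_psi(isoform_abundance(vref_inclusion_real, inclusion_len),
                       isoform_abundance(vref_exclusion_real, exclusion_len))
  list(raw_p = fisher_exact_two_sided(sample_inclusion, sample_exclusion,
                                      vref_inclusion, vref_exclusion),
       delta_psi = 100 * (psi_s - psi_v),
       psi_sample = psi_s, psi_vref = psi_v)
}

#' Differential splicing calls against the virtual reference
#'
#' For every testable (event, condition) pair, compares the
#' inclusion/exclusion counts with the rounded virtual-reference counts by a
#' two-sided Fisher's exact test. Events with more than two isoforms are
#' tested once per isoform (that isoform versus all others combined, lengths
#' summed accordingly); all candidate tests enter the per-(condition, event
#' type) Benjamini-Hochberg correction, and the isoform with the lowest
#' corrected p-value is reported per event (ties broken by larger |dPSI|,
#' then lower isoform index). The untreated condition is never tested.
#'
#' @param counts Long per-condition isoform count table.
#' @param events Long event table.
#' @param vref Virtual reference from [build_virtual_reference()].
#' @param min_total Expression cutoff on the per-condition total.
#' @param fdr FDR threshold for [call_significant()].
#' @param dpsi_min Minimum |dPSI| (percentage points) for a call.
#' @param exclude Conditions excluded from testing.
#' @return Calls data frame, one row per (event, condition), with
#'   `raw_p`, `corrected_p`, `delta_psi`, `significant`, `magnitude`,
#'   `direction`.
#' @export
diff_splice <- function(counts, events, vref, min_total = 20, fdr = 0.05,
                        dpsi_min = 10, exclude = "untreated") {
  cx <- counts[!counts$sample_id %in% exclude, , drop = FALSE]
  cx <- cx[cx$event_id %in% unique(vref$event_id), , drop = FALSE]
  if (nrow(cx) == 0) return(empty_calls())

  ev1 <- events[!duplicated(events$event_id),
                c("event_id", "gene_id", "event_type", "inclusion_index",
                  "n_isoforms")]
  lens <- events[, c("event_id", "isoform_index", "iso_length")]

  # wide per-event matrices for speed
  cand <- list()
  for (grp in split(seq_len(nrow(cx)), cx$event_id)) {
    g <- cx[grp, ]
    eid <- g$event_id[1]
    meta <- ev1[ev1$event_id == eid, ]
    ln <- lens$iso_length[lens$event_id == eid][
      order(lens$isoform_index[lens$event_id == eid])]
    wide <- stats::xtabs(count ~ isoform_index + sample_id, data = g)
    tot <- colSums(wide)
    ok <- tot >= min_total
    if (!any(ok)) next
    wide <- wide[, ok, drop = FALSE]
    tot <- tot[ok]
    vr <- vref[vref$event_id == eid, ]
    vr <- vr[order(vr$isoform_index), ]
    vtot_real <- sum(vr$vref_count)
    k <- nrow(vr)
    iso_set <- if (k > 2) seq_len(k) else meta$inclusion_index
    for (ii in iso_set) {
      a <- as.integer(wide[ii, ])
      bcnt <- as.integer(tot - a)
      c_ <- vr$vref_rounded[ii]
      d_ <- as.integer(round_half_up(vtot_real - vr$vref_count[ii]))
      li <- ln[ii]; le <- sum(ln[-ii])
      psi_s <- compute_psi(a / li, bcnt / le)
      psi_v <- compute_psi(vr$vref_count[ii] / li,
                           (vtot_real - vr$vref_count[ii]) / le)
      cand[[length(cand) + 1L]] <- data.frame(
        event_id = eid, gene_id = meta$gene_id,
        event_type = meta$event_type, sample_id = colnames(wide),
        tested_isoform = ii,
        raw_p = fisher_exact_two_sided(a, bcnt, c_, d_),
        psi_sample = psi_s, psi_vref = psi_v,
        delta_psi = 100 * (psi_s - psi_v),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty_calls())
  cand <- do.call(rbind, cand)

  grp_key <- paste(cand$sample_id, cand$event_type, sep = "|")
  cand$corrected_p <- NA_real_
  for (g in split(seq_len(nrow(cand)), grp_key))
    cand$corrected_p[g] <- bh_correct(cand$raw_p[g])

  # per (event, condition): keep the isoform with the lowest corrected p
  sel_key <- paste(cand$event_id, cand$sample_id, sep = "|")
  picked <- vapply(split(seq_len(nrow(cand)), sel_key), function(ix) {
    o <- order(cand$corrected_p[ix], -abs(cand$delta_psi[ix]),
               cand$tested_isoform[ix])
    ix[o[1]]
  }, 1L)
  calls <- cand[sort(picked), , drop = FALSE]
  rownames(calls) <- NULL
  names(calls)[names(calls) == "sample_id"] <- "condition"
  call_significant(calls, fdr = fdr, dpsi_min = dpsi_min)
}

empty_calls <- function() {
  data.frame(event_id = character(0), gene_id = character(0),
             event_type = character(0), condition = character(0),
             tested_isoform = integer(0), raw_p = numeric(0),
             psi_sample = numeric(0), psi_vref = numeric(0),
             delta_psi = numeric(0), corrected_p = numeric(0),
             significant = logical(0), magnitude = character(0),
             direction = character(0), stringsAsFactors = FALSE)
}

#' Finalize significance, magnitude tier and direction of calls
#'
#' A call is significant iff its corrected p-value is below `fdr` AND
#' |dPSI| exceeds `dpsi_min` percentage points. Magnitude tiers: weak
#' (10, 25], moderate (25, 50], strong (50, 100] (boundary values fall in
#' the lower tier). Direction encodes the depleted protein's inferred action
#' on the inclusion isoform: decreased inclusion upon knockdown (dPSI < 0)
#' means the protein activated inclusion; increased inclusion means it
#' repressed it.
#'
#' @param calls Calls data frame with `corrected_p` and `delta_psi`.
#' @param fdr FDR threshold (default 0.05).
#' @param dpsi_min Minimum |dPSI| in percentage points (default 10).
#' @return `calls` with `significant`, `magnitude` and `direction` columns.
#' @export
call_significant <- function(calls, fdr = 0.05, dpsi_min = 10) {
  adp <- abs(calls$delta_psi)
  calls$significant <- !is.na(calls$corrected_p) & !is.na(adp) &
    calls$corrected_p < fdr & adp > dpsi_min
  calls$magnitude <- ifelse(!calls$significant, "none",
                     ifelse(adp > 50, "strong",
                     ifelse(adp > 25, "moderate", "weak")))
  calls$direction <- ifelse(!calls$significant, "none",
                     ifelse(calls$delta_psi < 0, "activated", "repressed"))
  calls
}

#' Per-condition summary of significant calls
#'
#' @param calls Calls data frame.
#' @return Data frame of significant-call counts by condition, event type
#'   and magnitude tier.
#' @export
summarize_calls <- function(calls) {
  sig <- calls[calls$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(condition = character(0), event_type = character(0),
                      magnitude = character(0), n = integer(0)))
  out <- stats::aggregate(
    n ~ condition + event_type + magnitude,
    data = cbind(sig[, c("condition", "event_type", "magnitude")], n = 1L),
    FUN = sum)
  out[order(out$condition, out$event_type, out$magnitude), ]
}
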