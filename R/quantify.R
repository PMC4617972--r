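# Read counting per isoform, PSI computation, expression cutoff and the
# virtual reference.

#' Count reads supporting each isoform of each event
#'
#' An isoform's count is the sum of read counts over its junctions plus, for
#' region-bearing isoforms (retained introns), the supplied intron-body
#' region count. Junctions shared between two isoforms of the same event are
#' ambiguous support and contribute to neither. Junctions absent from the
#' count table count as zero (with a single warning).
#'
#' @param events Long event data frame from [discover_events()].
#' @param junction_counts Long data frame (`sample_id`, `junction`, `count`).
#' @param region_counts Optional long data frame (`sample_id`, `region`,
#'   `count`).
#' @return Long data frame (`event_id`, `sample_id`, `isoform_index`,
#'   `count`).
#' @export
count_isoform_reads <- function(events, junction_counts,
                                region_counts = NULL) {
  samples <- sort(unique(junction_counts$sample_id))
  if (!length(samples)) samples <- character(0)
  jmap <- new.env(parent = emptyenv())
  if (nrow(junction_counts)) {
    ok <- order(junction_counts$junction, junction_counts$sample_id)
    jc <- junction_counts[ok, ]
    for (grp in split(seq_len(nrow(jc)), jc$junction)) {
      v <- integer(length(samples))
      names(v) <- samples
      v[jc$sample_id[grp]] <- jc$count[grp]
      jmap[[jc$junction[grp[1]]]] <- v
    }
  }
  rmap <- new.env(parent = emptyenv())
  if (!is.null(region_counts) && nrow(region_counts)) {
    for (grp in split(seq_len(nrow(region_counts)), region_counts$region)) {
      v <- integer(length(samples))
      names(v) <- samples
      v[region_counts$sample_id[grp]] <- region_counts$count[grp]
      rmap[[region_counts$region[grp[1]]]] <- v
    }
  }
  missing_jn <- character(0)
  out <- vector("list", nrow(events))
  for (grp in split(seq_len(nrow(events)), events$event_id)) {
    jl <- split_tokens(events$junctions[grp])
    shared <- unlist(jl)[duplicated(unlist(jl))]
    for (i in seq_along(grp)) {
      r <- grp[i]
      v <- numeric(length(samples))
      for (key in setdiff(jl[[i]], shared)) {
        jv <- jmap[[key]]
        if (is.null(jv)) missing_jn <- c(missing_jn, key) else v <- v + jv
      }
      if (!is.na(events$region[r])) {
        for (key in split_tokens(events$region[r])[[1]]) {
          rv <- rmap[[key]]
          if (!is.null(rv)) v <- v + rv
        }
      }
      out[[r]] <- data.frame(event_id = events$event_id[r],
                             sample_id = samples,
                             isoform_index = events$isoform_index[r],
                             count = as.integer(v),
                             stringsAsFactors = FALSE)
    }
  }
  if (length(missing_jn))
    warnf("%d event junction(s) absent from the count table; counted as 0",
          length(unique(missing_jn)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pool replicate libraries into per-condition counts
#'
#' Replicate counts are summed per knockdown condition before PSI
#' computation, virtual-reference construction and testing; the untreated
#' sample maps to the condition `"untreated"`.
#'
#' @param counts Long isoform count table from [count_isoform_reads()].
#' @param metadata Sample table with `sample_id` and `protein`.
#' @return Counts with `sample_id` replaced by the condition name.
#' @export
pool_replicates <- function(counts, metadata) {
  cond <- metadata$protein[match(counts$sample_id, metadata$sample_id)]
  if (anyNA(cond)) stopf("samples missing from metadata: %s",
                         paste(unique(counts$sample_id[is.na(cond)]),
                               collapse = ", "))
  agg <- stats::aggregate(count ~ event_id + isoform_index + cond,
                          data = cbind(counts, cond = cond), FUN = sum)
  names(agg)[names(agg) == "cond"] <- "sample_id"
  agg[order(agg$event_id, agg$sample_id, agg$isoform_index),
      c("event_id", "sample_id", "isoform_index", "count")]
}

#' Length-normalized isoform abundance
#'
#' @param count Read count (non-negative).
#' @param length Isoform length in normalization units (positive).
#' @return `count / length`.
#' @export
isoform_abundance <- function(count, length) {
  if (any(length <= 0)) stopf("isoform length must be positive")
  count / length
}

#' Percent spliced in from isoform abundances
#'
#' \deqn{\Psi = \frac{a_{incl}}{a_{incl} + a_{excl}}}
#' where the abundances are length-normalized read counts. When both
#' abundances are zero the event is unquantifiable in that sample and PSI is
#' `NA` (distinct from 0).
#'
#' @param inclusion_abundance,exclusion_abundance Non-negative abundances.
#' @return PSI in `[0, 1]`, or `NA` when both abundances are zero.
#' @export
compute_psi <- function(inclusion_abundance, exclusion_abundance) {
  tot <- inclusion_abundance + exclusion_abundance
  ifelse(tot == 0, NA_real_, inclusion_abundance / tot)
}

# Per-(event, sample) inclusion/exclusion counts and PSI using the
# designated inclusion isoform; exclusion pools all other isoforms.
event_psi_table <- function(counts, events) {
  ev1 <- events[!duplicated(events$event_id),
                c("event_id", "gene_id", "event_type", "inclusion_index",
                  "n_isoforms")]
  lens <- events[, c("event_id", "isoform_index", "iso_length")]
  x <- merge(counts, lens, by = c("event_id", "isoform_index"))
  x <- merge(x, ev1, by = "event_id")
  x$is_inc <- x$isoform_index == x$inclusion_index
  inc <- stats::aggregate(cbind(count = count, len = iso_length) ~
                            event_id + sample_id,
                          data = x[x$is_inc, ], FUN = sum)
  exc <- stats::aggregate(cbind(count = count, len = iso_length) ~
                            event_id + sample_id,
                          data = x[!x$is_inc, ], FUN = sum)
  names(inc)[3:4] <- c("inclusion_count", "inclusion_len")
  names(exc)[3:4] <- c("exclusion_count", "exclusion_len")
  out <- merge(inc, exc, by = c("event_id", "sample_id"))
  out <- merge(out, ev1[, c("event_id", "gene_id", "event_type")],
               by = "event_id")
  out$psi <- compute_psi(
    isoform_abundance(out$inclusion_count, out$inclusion_len),
    isoform_abundance(out$exclusion_count, out$exclusion_len))
  out$total <- out$inclusion_count + out$exclusion_count
  out[order(out$event_id, out$sample_id), ]
}

#' Apply the per-event expression cutoff
#'
#' An (event, sample) pair is testable iff the total of reads supporting the
#' inclusion and exclusion isoforms reaches `min_total` (inclusive; default
#' 20 reads).
#'
#' @param psi_rows Table from the quantification step with a `total` column.
#' @param min_total Read-count cutoff.
#' @return The testable rows, with a `cutoff_report` attribute giving the
#'   number of events expressed in at least one sample.
#' @export
apply_expression_cutoff <- function(psi_rows, min_total = 20) {
  keep <- psi_rows$total >= min_total
  out <- psi_rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff_report") <- data.frame(
    rows_in = nrow(psi_rows), rows_testable = nrow(out),
    events_expressed = length(unique(out$event_id)))
  out
}

#' Build the virtual reference for each event
#'
#' The virtual reference synthesizes a control library from the RNAi samples
#' themselves, under the assumption that any given splicing event is
#' affected by only a few of the depleted proteins so that cross-sample
#' medians reflect the unperturbed state. Per event:
#' `median_total` is the median of per-sample total counts, and each
#' isoform's reference count is `median_total` times the median of its
#' per-sample count ratio (ratios renormalized to sum to one; for two
#' isoforms the medians already do). Counts are additionally rounded half-up
#' to integers for the exact test, while the real-valued counts are retained
#' for PSI. Events testable in fewer than `min_samples` RNAi conditions get
#' no reference and become untestable.
#'
#' @param counts Long per-condition isoform count table.
#' @param events Long event table.
#' @param min_total Expression cutoff applied to each sample's total.
#' @param exclude Conditions excluded from the medians (the untreated
#'   sample).
#' @param min_samples Minimum number of contributing RNAi conditions.
#' @return Long data frame (`event_id`, `isoform_index`, `vref_count`,
#'   `vref_rounded`, `median_total`, `n_samples`).
#' @export
build_virtual_reference <- function(counts, events, min_total = 20,
                                    exclude = "untreated", min_samples = 3) {
  cx <- counts[!counts$sample_id %in% exclude, , drop = FALSE]
  out <- list()
  for (grp in split(seq_len(nrow(cx)), cx$event_id)) {
    g <- cx[grp, ]
    wide <- stats::xtabs(count ~ isoform_index + sample_id, data = g)
    tot <- colSums(wide)
    ok <- tot >= min_total
    if (sum(ok) < min_samples) next
    wide <- wide[, ok, drop = FALSE]
    tot <- tot[ok]
    med_tot <- stats::median(tot)
    ratios <- sweep(wide, 2, tot, "/")
    med_r <- apply(ratios, 1, stats::median)
    if (sum(med_r) == 0) next
    med_r <- med_r / sum(med_r)
    vref <- med_tot * med_r
    out[[length(out) + 1L]] <- data.frame(
      event_id = g$event_id[1],
      isoform_index = as.integer(rownames(wide)),
      vref_count = as.numeric(vref),
      vref_rounded = as.integer(round_half_up(vref)),
      median_total = med_tot,
      n_samples = sum(ok),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(event_id = character(0), isoform_index = integer(0),
                      vref_count = numeric(0), vref_rounded = integer(0),
                      median_total = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
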