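# End-to-end orchestration: junctions -> events -> quantification ->
# virtual reference -> differential calls -> network statistics, with a
# machine-readable run manifest. Every stage is a pure function of its
# declared inputs, so identical inputs and configuration reproduce
# byte-identical outputs.

#' Run the full splicing-screen analysis pipeline
#'
#' @param paths List of input/output paths: `junction_dir` (one
#'   `<sample_id>.bed` per sample), `annotation_gtf`,
#'   `annotation_junctions` (BED of annotated junctions), `metadata`
#'   (TSV with `sample_id`, `protein`, `replicate`, optionally `gene_id`),
#'   optional `offsets` (novel-junction read-start histograms TSV), optional
#'   `region_counts` (intron-body coverage TSV) and `outdir`.
#' @param config A [run_config()].
#' @param verbose Print per-stage progress to stderr.
#' @return Invisible list with all stage outputs (`events`, `psi`,
#'   `testable`, `vref`, `calls`, `bias`, `pairs`, `cross_matrix`,
#'   `manifest`).
#' @export
run_pipeline <- function(paths, config = run_config(), verbose = FALSE) {
  op <- options(splicescreen.verbose = verbose); on.exit(options(op))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) ss_message(sprintf("[%s] %.1fs", name,
                                             proc.time()[["elapsed"]] - t0))

  meta <- read_tsv(paths$metadata)
  bed_files <- file.path(paths$junction_dir, paste0(meta$sample_id, ".bed"))
  missing <- !file.exists(bed_files)
  if (any(missing))
    stopf("stage junctions: no junction file for sample(s): %s",
          paste(meta$sample_id[missing], collapse = ", "))

  per_sample <- lapply(seq_along(bed_files), function(i) {
    df <- read_junction_bed(bed_files[i])
    if (nrow(df)) df$sample_id <- meta$sample_id[i] else df$sample_id <-
        character(0)
    df
  })
  expressed <- do.call(rbind, per_sample)
  stage("junctions")

  ann_jn <- read_junction_bed(paths$annotation_junctions)
  if (all(is.na(ann_jn$status)) && nrow(ann_jn)) ann_jn$status <- "reference"
  # pooled junction table across samples
  pooled <- if (nrow(expressed)) {
    key <- junction_key(expressed$chrom, expressed$donor, expressed$acceptor,
                        expressed$strand)
    agg <- tapply(expressed$count, key, sum)
    first <- !duplicated(key)
    p <- expressed[first, c("chrom", "donor", "acceptor", "strand", "name",
                            "count", "status")]
    p$count <- as.integer(agg[key[first]])
    p
  } else expressed[, c("chrom", "donor", "acceptor", "strand", "name",
                       "count", "status")]
  if (all(is.na(pooled$status)) && nrow(pooled))
    pooled <- annotate_status(pooled,
                              ann_jn[ann_jn$status == "reference", ],
                              ann_jn[ann_jn$status == "secondary", ])

  offsets <- if (!is.null(paths$offsets) && file.exists(paths$offsets))
    read_tsv(paths$offsets)
  else data.frame(junction = character(0), offset = integer(0),
                  count = integer(0))
  confident <- filter_novel_junctions(pooled, offsets,
                                      entropy_min = config$entropy_min,
                                      count_min = config$count_min)
  filter_report <- attr(confident, "filter_report")
  universe <- augment_with_annotated(confident, ann_jn)
  stage("filter/augment")

  exons <- read_exon_gtf(paths$annotation_gtf)
  events <- discover_events(universe, exons,
                            require_cage = config$require_cage,
                            read_length = config$read_length)
  stage("events")

  kept_keys <- junction_key(confident$chrom, confident$donor,
                            confident$acceptor, confident$strand)
  jc <- expressed[junction_key(expressed$chrom, expressed$donor,
                               expressed$acceptor, expressed$strand) %in%
                    c(kept_keys,
                      junction_key(universe$chrom, universe$donor,
                                   universe$acceptor, universe$strand)), ]
  jlong <- data.frame(sample_id = jc$sample_id,
                      junction = junction_key(jc$chrom, jc$donor,
                                              jc$acceptor, jc$strand),
                      count = jc$count, stringsAsFactors = FALSE)
  rlong <- if (!is.null(paths$region_counts) &&
               file.exists(paths$region_counts))
    read_tsv(paths$region_counts) else NULL

  counts_rep <- count_isoform_reads(events, jlong, rlong)
  stage("count")

  analyse <- function(counts_cond) {
    psi <- event_psi_table(counts_cond, events)
    testable <- apply_expression_cutoff(psi, min_total = config$min_total)
    vref <- build_virtual_reference(counts_cond, events,
                                    min_total = config$min_total,
                                    min_samples = 3)
    calls <- diff_splice(counts_cond, events, vref,
                         min_total = config$min_total, fdr = config$fdr,
                         dpsi_min = config$dpsi_min)
    list(psi = psi, testable = testable, vref = vref, calls = calls)
  }

  if (config$replicate_mode == "pooled") {
    res <- analyse(pool_replicates(counts_rep, meta))
  } else {
    reps <- sort(unique(meta$replicate))
    parts <- lapply(reps, function(r) {
      m <- meta[meta$replicate == r | meta$protein == "untreated", ]
      cc <- counts_rep[counts_rep$sample_id %in% m$sample_id, ]
      analyse(pool_replicates(cc, m))
    })
    res <- parts[[1]]
    if (length(parts) > 1) {
      keys <- lapply(parts, function(p)
        with(p$calls[p$calls$significant, ],
             paste(event_id, condition)))
      common <- Reduce(intersect, keys)
      res$calls$significant <- paste(res$calls$event_id,
                                     res$calls$condition) %in% common
      res$calls <- call_significant(res$calls, fdr = config$fdr,
                                    dpsi_min = config$dpsi_min)
      res$calls$significant <- res$calls$significant &
        paste(res$calls$event_id, res$calls$condition) %in% common
    }
  }
  stage("quantify/test")

  testable_pairs <- unique(res$testable[
    res$testable$event_id %in% unique(res$vref$event_id) &
      res$testable$sample_id != "untreated",
    c("event_id", "sample_id", "event_type")])
  names(testable_pairs) <- c("event_id", "condition", "event_type")
  bias <- regulator_bias(res$calls)
  pairs <- pairwise_overlap(res$calls, testable_pairs)
  pg <- if ("gene_id" %in% names(meta)) {
    x <- unique(meta[meta$protein != "untreated",
                     c("protein", "gene_id")])
    x[!is.na(x$gene_id), ]
  } else NULL
  cross <- if (!is.null(pg) && nrow(pg))
    cross_regulation_matrix(res$calls, pg,
                            min_magnitude = config$min_magnitude)
  else NULL
  if (!is.null(cross) && nrow(pairs))
    pairs <- confounded_overlap_screen(pairs, cross, protein_gene = pg)
  stage("networks")

  manifest <- list(
    package = "splicescreen",
    version = as.character(utils::packageVersion("splicescreen")),
    config = unclass(config),
    config_hash = config_hash(config),
    stages = list(
      samples = nrow(meta),
      junctions_expressed = nrow(pooled),
      junctions_confident = nrow(confident),
      junction_universe = nrow(universe),
      novel_dropped = filter_report$novel_dropped,
      events_discovered = length(unique(events$event_id)),
      events_expressed = length(unique(res$testable$event_id)),
      events_with_vref = length(unique(res$vref$event_id)),
      calls_tested = nrow(res$calls),
      calls_significant = sum(res$calls$significant),
      events_affected = length(unique(
        res$calls$event_id[res$calls$significant]))))

  out <- list(events = events, psi = res$psi, testable = res$testable,
              vref = res$vref, calls = res$calls, bias = bias,
              pairs = pairs, cross_matrix = cross, manifest = manifest)
  if (!is.null(paths$outdir)) write_pipeline_outputs(out, paths$outdir)
  stage("write")
  invisible(out)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(unclass(config), NULL, version = 2), f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(out$events, file.path(outdir, "events.tsv"))
  write_events_bed(out$events, file.path(outdir, "events.bed"))
  write_tsv(out$psi, file.path(outdir, "psi.tsv"))
  write_tsv(out$vref, file.path(outdir, "vref.tsv"))
  write_tsv(out$calls, file.path(outdir, "calls.tsv"))
  write_tsv(summarize_calls(out$calls), file.path(outdir, "summary.tsv"))
  write_tsv(out$bias, file.path(outdir, "bias.tsv"))
  write_tsv(out$pairs, file.path(outdir, "pairs.tsv"))
  if (!is.null(out$cross_matrix)) {
    m <- as.data.frame(unclass(out$cross_matrix))
    m <- cbind(regulator = rownames(m), m)
    write_tsv(m, file.path(outdir, "cross_matrix.tsv"))
  }
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

# BED track of event spans for genome-browser inspection.
write_events_bed <- function(events, path) {
  ids <- unique(events$event_id)
  lines <- vapply(ids, function(eid) {
    e <- events[events$event_id == eid, ]
    keys <- unlist(split_tokens(e$junctions))
    sp <- if (length(keys)) {
      k <- parse_junction_key(keys)
      c(min(k$donor), max(k$acceptor))
    } else c(0L, 1L)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", e$chrom[1], sp[1], sp[2], eid,
            e$strand[1])
  }, "")
  writeLines(lines, path)
  invisible(path)
}
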