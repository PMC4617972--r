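#' Simulation configuration for the synthetic RNAi splicing screen
#'
#' Builds and validates the configuration object consumed by
#' [generate_gene_models()] and [simulate_counts()]. The defaults emulate the
#' design of an RNAi depletion screen in which 56 candidate splicing
#' regulators are each knocked down in two biological replicates alongside
#' one untreated sample, and splicing outcomes are read out as splice-junction
#' counts.
#'
#' @param n_genes Number of synthetic genes; each gene carries exactly one
#'   alternative-splicing event.
#' @param event_type_mix Named numeric vector of proportions over the eight
#'   event types `SE`, `A5SS`, `A3SS`, `MXE`, `CSE`, `AFE`, `ALE`, `RI`;
#'   must sum to 1.
#' @param n_proteins Number of RNAi-targeted proteins (default 56). The first
#'   `n_proteins` genes double as the genes encoding the assayed proteins, so
#'   cross-regulation can be planted.
#' @param n_replicates Biological replicates per knockdown condition
#'   (default 2). One untreated sample is always added.
#' @param depth_per_event Mean total read count per event per library
#'   (Poisson-distributed around this mean).
#' @param dispersion Beta-binomial overdispersion rho in (0, 1) for the
#'   inclusion/exclusion read split. Values below 1e-12 are treated as pure
#'   binomial sampling.
#' @param targets_per_protein Expected number of events carrying a planted
#'   effect for each depleted protein.
#' @param effect_tiers Proportions of planted effect magnitudes:
#'   `weak` |dPSI| in (0.10, 0.25], `moderate` (0.25, 0.50], `strong`
#'   (0.50, 1]; must sum to 1.
#' @param psi_range Range from which baseline PSI values are drawn uniformly.
#' @param status_mix Proportions of junction annotation tiers
#'   (`reference`, `secondary`, `novel`); must sum to 1.
#' @param coregulated_pairs List of planted regulator pairs; each element is
#'   `list(pair = c("P01","P02"), shared_fraction = 0.5,
#'   mode = "coordinated")` (or `"antagonistic"`).
#' @param cross_links List of planted cross-regulatory links; each element is
#'   `list(regulator = "P01", target = "P05", delta_psi = 0.4)` meaning
#'   depletion of the regulator shifts PSI of the event on the target
#'   protein's gene by `delta_psi`.
#' @param read_length Read length used to express retained-intron isoform
#'   lengths in junction-equivalent units.
#' @param seed Integer RNG seed; identical configurations and seeds yield
#'   bit-identical simulations.
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 8, n_proteins = 4, seed = 1)
sim_config <- function(n_genes = 200,
                       event_type_mix = c(SE = 0.35, A5SS = 0.10, A3SS = 0.10,
                                          MXE = 0.05, CSE = 0.05, AFE = 0.15,
                                          ALE = 0.10, RI = 0.10),
                       n_proteins = 56,
                       n_replicates = 2,
                       depth_per_event = 200,
                       dispersion = 0.01,
                       targets_per_protein = 20,
                       effect_tiers = c(weak = 0.55, moderate = 0.42,
                                        strong = 0.03),
                       psi_range = c(0.2, 0.8),
                       status_mix = c(reference = 0.35, secondary = 0.55,
                                      novel = 0.10),
                       coregulated_pairs = list(),
                       cross_links = list(),
                       read_length = 75,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    event_type_mix = event_type_mix,
    n_proteins = as.integer(n_proteins),
    n_replicates = as.integer(n_replicates),
    depth_per_event = as.integer(depth_per_event),
    dispersion = dispersion,
    targets_per_protein = targets_per_protein,
    effect_tiers = effect_tiers,
    psi_range = psi_range,
    status_mix = status_mix,
    coregulated_pairs = coregulated_pairs,
    cross_links = cross_links,
    read_length = as.integer(read_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  types <- event_types()
  if (cfg$n_genes < 0) stopf("n_genes must be >= 0")
  if (is.null(names(cfg$event_type_mix)) ||
      !all(names(cfg$event_type_mix) %in% types))
    stopf("event_type_mix must be named with event types %s",
          paste(types, collapse = ", "))
  if (abs(sum(cfg$event_type_mix) - 1) > 1e-9)
    stopf("event_type_mix must sum to 1")
  if (any(cfg$event_type_mix < 0)) stopf("event_type_mix must be non-negative")
  if (abs(sum(cfg$effect_tiers) - 1) > 1e-9)
    stopf("effect_tiers must sum to 1")
  if (!all(c("weak", "moderate", "strong") %in% names(cfg$effect_tiers)))
    stopf("effect_tiers needs names weak, moderate, strong")
  if (abs(sum(cfg$status_mix) - 1) > 1e-9)
    stopf("status_mix must sum to 1")
  if (cfg$depth_per_event < 1) stopf("depth_per_event must be >= 1")
  if (cfg$dispersion < 0 || cfg$dispersion >= 1)
    stopf("dispersion must be in [0, 1)")
  if (cfg$n_replicates < 1) stopf("n_replicates must be >= 1")
  if (length(cfg$psi_range) != 2 || cfg$psi_range[1] >= cfg$psi_range[2] ||
      cfg$psi_range[1] < 0 || cfg$psi_range[2] > 1)
    stopf("psi_range must be an increasing pair within [0, 1]")
  for (cl in cfg$cross_links) {
    if (!all(c("regulator", "target", "delta_psi") %in% names(cl)))
      stopf("cross_links entries need regulator, target, delta_psi")
    if (abs(cl$delta_psi) < 0.10)
      stopf("planted cross-link |delta_psi| must be >= 0.10")
  }
  for (cp in cfg$coregulated_pairs) {
    if (!all(c("pair", "shared_fraction", "mode") %in% names(cp)))
      stopf("coregulated_pairs entries need pair, shared_fraction, mode")
    if (!cp$mode %in% c("coordinated", "antagonistic"))
      stopf("coregulated pair mode must be coordinated or antagonistic")
  }
  invisible(cfg)
}

#' The eight alternative-splicing event types
#'
#' @return Character vector of the canonical event-type labels.
#' @export
event_types <- function() {
  c("SE", "A5SS", "A3SS", "MXE", "CSE", "AFE", "ALE", "RI")
}

#' Analysis thresholds and modes for a pipeline run
#'
#' @param min_total Expression cutoff: an (event, sample) pair is testable iff
#'   inclusion + exclusion read counts reach this total (inclusive; default
#'   20 reads).
#' @param fdr Benjamini-Hochberg FDR threshold for differential calls
#'   (default 0.05, applied per condition and per event type).
#' @param dpsi_min Minimum |dPSI| in percentage points for a significant call
#'   (strict inequality; default 10).
#' @param entropy_min Minimum Shannon entropy (bits) of the read-start offset
#'   distribution for a novel junction to be retained (default 2).
#' @param count_min Minimum read count for a novel junction (default 2).
#' @param min_magnitude Magnitude filter for the cross-regulation matrix:
#'   `"weak"`, `"moderate"` or `"strong"` (default `"moderate"`).
#' @param require_cage Whether alternative-first-exon discovery requires
#'   CAGE-supported first exons (default TRUE).
#' @param replicate_mode `"pooled"` (replicate counts summed per condition
#'   before testing) or `"per-replicate"` (calls computed per replicate and
#'   intersected).
#' @param read_length Read length for retained-intron length units.
#' @param seed Seed recorded in the run manifest (the analysis itself is
#'   deterministic).
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(min_total = 20, fdr = 0.05, dpsi_min = 10,
                       entropy_min = 2.0, count_min = 2,
                       min_magnitude = "moderate", require_cage = TRUE,
                       replicate_mode = c("pooled", "per-replicate"),
                       read_length = 75, seed = 1L) {
  replicate_mode <- match.arg(replicate_mode)
  cfg <- list(min_total = min_total, fdr = fdr, dpsi_min = dpsi_min,
              entropy_min = entropy_min, count_min = count_min,
              min_magnitude = min_magnitude, require_cage = require_cage,
              replicate_mode = replicate_mode,
              read_length = as.integer(read_length), seed = as.integer(seed))
  if (cfg$min_total < 0 || cfg$fdr < 0 || cfg$fdr > 1 ||
      cfg$dpsi_min < 0 || cfg$dpsi_min > 100)
    stopf("run_config thresholds out of range")
  if (!cfg$min_magnitude %in% c("weak", "moderate", "strong"))
    stopf("min_magnitude must be weak, moderate or strong")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline run configuration from a YAML file
#'
#' The YAML file may contain any subset of the [run_config()] fields plus the
#' input paths used by [run_pipeline()] (`junction_dir`, `annotation_gtf`,
#' `annotation_junctions`, `metadata`, `offsets`, `outdir`).
#'
#' @param path Path to a YAML file.
#' @return List with `config` (a `run_config`) and `paths`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  cfg <- do.call(run_config, raw[intersect(names(raw), known)])
  paths <- raw[setdiff(names(raw), known)]
  list(config = cfg, paths = paths)
}
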