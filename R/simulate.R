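# Synthetic RNAi splicing-screen generator.
#
# Each synthetic gene occupies its own 10-kb block on chromosomes
# chrS1, chrS2, ... and carries exactly one alternative-splicing event of a
# configured type. Gene geometries are laid out so that junction donors and
# acceptors coincide exactly with exon boundaries, as the event classifier
# assumes for real annotations.

GENES_PER_CHROM <- 25L
GENE_BLOCK <- 10000L

gene_coords <- function(i) {
  chrom <- sprintf("chrS%d", ((i - 1L) %/% GENES_PER_CHROM) + 1L)
  base <- ((i - 1L) %% GENES_PER_CHROM) * GENE_BLOCK + 1000L
  list(chrom = chrom, base = base)
}

exon_row <- function(chrom, start, end, strand, gene_id,
                     first = FALSE, last = FALSE, cage = FALSE,
                     source = "primary") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, gene_id = gene_id,
             is_first_exon = first, is_last_exon = last,
             cage_supported = cage, source = source,
             stringsAsFactors = FALSE)
}

junction_row <- function(chrom, donor, acceptor, strand) {
  data.frame(chrom = chrom, donor = as.integer(donor),
             acceptor = as.integer(acceptor), strand = strand,
             stringsAsFactors = FALSE)
}

# Isoform constructor: junction keys, optional region keys, and length in
# normalization units (number of junctions; retained introns use
# intron_length / read_length, floored, minimum 1).
iso <- function(junctions = character(), regions = character(), length) {
  list(junctions = junctions, regions = regions, length = length)
}

iso_token <- function(isoform) {
  paste(sort(c(isoform$junctions, isoform$regions)), collapse = ",")
}

# Canonical event form shared by the generator and the classifier: isoforms
# sorted by token; the inclusion isoform is the exon/intron-containing one
# for SE/CSE/RI and the first isoform otherwise.
canonicalize_event <- function(isoforms, type) {
  ord <- order(vapply(isoforms, iso_token, ""))
  isoforms <- isoforms[ord]
  inclusion <- 1L
  if (type %in% c("SE", "CSE")) {
    nj <- vapply(isoforms, function(x) length(x$junctions), 1L)
    inclusion <- which.max(nj)
  } else if (type == "RI") {
    nr <- vapply(isoforms, function(x) length(x$regions), 1L)
    inclusion <- which.max(nr)
  }
  list(isoforms = isoforms, inclusion_index = as.integer(inclusion))
}

event_rows <- function(event_id, gene_id, type, chrom, strand, isoforms,
                       inclusion_index, iso_psi = NA_real_) {
  k <- length(isoforms)
  data.frame(
    event_id = event_id, gene_id = gene_id, event_type = type,
    chrom = chrom, strand = strand,
    isoform_index = seq_len(k), n_isoforms = k,
    inclusion_index = inclusion_index,
    junctions = vapply(isoforms, function(x) join_tokens(x$junctions), ""),
    region = vapply(isoforms, function(x)
      if (length(x$regions)) join_tokens(x$regions) else NA_character_, ""),
    iso_length = vapply(isoforms, function(x) x$length, 1),
    iso_psi = iso_psi,
    stringsAsFactors = FALSE
  )
}

# ---- per-type gene builders -------------------------------------------------
# Each returns list(exons, junctions, isoforms, type, strand).

build_SE <- function(chrom, g, gid) {
  ex <- rbind(
    exon_row(chrom, g, g + 200L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 300L, g + 400L, "+", gid),
    exon_row(chrom, g + 500L, g + 700L, "+", gid, last = TRUE))
  jup <- junction_key(chrom, g + 200L, g + 300L, "+")
  jdn <- junction_key(chrom, g + 400L, g + 500L, "+")
  jsk <- junction_key(chrom, g + 200L, g + 500L, "+")
  jn <- rbind(junction_row(chrom, g + 200L, g + 300L, "+"),
              junction_row(chrom, g + 400L, g + 500L, "+"),
              junction_row(chrom, g + 200L, g + 500L, "+"))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(c(jup, jdn), length = 2), iso(jsk, length = 1)))
}

build_CSE <- function(chrom, g, gid) {
  ex <- rbind(
    exon_row(chrom, g, g + 200L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 300L, g + 400L, "+", gid),
    exon_row(chrom, g + 500L, g + 600L, "+", gid),
    exon_row(chrom, g + 700L, g + 900L, "+", gid, last = TRUE))
  j1 <- junction_key(chrom, g + 200L, g + 300L, "+")
  j2 <- junction_key(chrom, g + 400L, g + 500L, "+")
  j3 <- junction_key(chrom, g + 600L, g + 700L, "+")
  jsk <- junction_key(chrom, g + 200L, g + 700L, "+")
  jn <- rbind(junction_row(chrom, g + 200L, g + 300L, "+"),
              junction_row(chrom, g + 400L, g + 500L, "+"),
              junction_row(chrom, g + 600L, g + 700L, "+"),
              junction_row(chrom, g + 200L, g + 700L, "+"))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(c(j1, j2, j3), length = 3), iso(jsk, length = 1)))
}

build_MXE <- function(chrom, g, gid) {
  ex <- rbind(
    exon_row(chrom, g, g + 200L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 300L, g + 400L, "+", gid),
    exon_row(chrom, g + 500L, g + 600L, "+", gid),
    exon_row(chrom, g + 700L, g + 900L, "+", gid, last = TRUE))
  a1 <- junction_key(chrom, g + 200L, g + 300L, "+")
  a2 <- junction_key(chrom, g + 400L, g + 700L, "+")
  b1 <- junction_key(chrom, g + 200L, g + 500L, "+")
  b2 <- junction_key(chrom, g + 600L, g + 700L, "+")
  jn <- rbind(junction_row(chrom, g + 200L, g + 300L, "+"),
              junction_row(chrom, g + 400L, g + 700L, "+"),
              junction_row(chrom, g + 200L, g + 500L, "+"),
              junction_row(chrom, g + 600L, g + 700L, "+"))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(c(a1, a2), length = 2), iso(c(b1, b2), length = 2)))
}

build_A5SS <- function(chrom, g, gid) {
  # Alternative donors of the intron between the internal exon (two 3'-end
  # variants) and the terminal exon; the gene's true first exon is upstream
  # so alternative-first-exon logic never competes for these junctions.
  ex <- rbind(
    exon_row(chrom, g, g + 100L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 300L, g + 400L, "+", gid),
    exon_row(chrom, g + 300L, g + 450L, "+", gid),
    exon_row(chrom, g + 600L, g + 800L, "+", gid, last = TRUE))
  jc <- junction_row(chrom, g + 100L, g + 300L, "+")
  ja <- junction_key(chrom, g + 400L, g + 600L, "+")
  jb <- junction_key(chrom, g + 450L, g + 600L, "+")
  jn <- rbind(jc,
              junction_row(chrom, g + 400L, g + 600L, "+"),
              junction_row(chrom, g + 450L, g + 600L, "+"))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(ja, length = 1), iso(jb, length = 1)))
}

build_A3SS <- function(chrom, g, gid) {
  # Alternative acceptors: two 5'-end variants of the downstream exon.
  ex <- rbind(
    exon_row(chrom, g, g + 100L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 300L, g + 400L, "+", gid),
    exon_row(chrom, g + 600L, g + 800L, "+", gid),
    exon_row(chrom, g + 650L, g + 800L, "+", gid))
  ja <- junction_key(chrom, g + 400L, g + 600L, "+")
  jb <- junction_key(chrom, g + 400L, g + 650L, "+")
  jn <- rbind(junction_row(chrom, g + 100L, g + 300L, "+"),
              junction_row(chrom, g + 400L, g + 600L, "+"),
              junction_row(chrom, g + 400L, g + 650L, "+"))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(ja, length = 1), iso(jb, length = 1)))
}

build_RI <- function(chrom, g, gid, read_length = 75L) {
  ex <- rbind(
    exon_row(chrom, g, g + 300L, "+", gid, first = TRUE, cage = TRUE),
    exon_row(chrom, g + 500L, g + 800L, "+", gid, last = TRUE),
    # single-exon form of the unspliced transcript, spanning the intron
    exon_row(chrom, g, g + 800L, "+", gid))
  jx <- junction_key(chrom, g + 300L, g + 500L, "+")
  rg <- region_key(chrom, g + 300L, g + 500L)
  jn <- junction_row(chrom, g + 300L, g + 500L, "+")
  rlen <- max(1, floor(200L / read_length))
  list(exons = ex, junctions = jn, strand = "+",
       isoforms = list(iso(regions = rg, length = rlen), iso(jx, length = 1)))
}

build_AFE <- function(chrom, g, gid, minus = FALSE, n_first = 2L) {
  if (!minus) {
    fe_starts <- c(g, g + 200L, g + 350L)[seq_len(n_first)]
    fe_ends <- c(g + 100L, g + 300L, g + 400L)[seq_len(n_first)]
    ex <- exon_row(chrom, g + 500L, g + 700L, "+", gid, last = TRUE)
    for (i in seq_len(n_first))
      ex <- rbind(ex, exon_row(chrom, fe_starts[i], fe_ends[i], "+", gid,
                               first = TRUE, cage = TRUE))
    jn <- do.call(rbind, lapply(fe_ends, function(e)
      junction_row(chrom, e, g + 500L, "+")))
    isoforms <- lapply(fe_ends, function(e)
      iso(junction_key(chrom, e, g + 500L, "+"), length = 1))
    strand <- "+"
  } else {
    fe_starts <- c(g + 600L, g + 400L, g + 250L)[seq_len(n_first)]
    fe_ends <- c(g + 700L, g + 500L, g + 300L)[seq_len(n_first)]
    ex <- exon_row(chrom, g, g + 200L, "-", gid, last = TRUE)
    for (i in seq_len(n_first))
      ex <- rbind(ex, exon_row(chrom, fe_starts[i], fe_ends[i], "-", gid,
                               first = TRUE, cage = TRUE))
    jn <- do.call(rbind, lapply(fe_starts, function(s)
      junction_row(chrom, g + 200L, s, "-")))
    isoforms <- lapply(fe_starts, function(s)
      iso(junction_key(chrom, g + 200L, s, "-"), length = 1))
    strand <- "-"
  }
  list(exons = ex, junctions = jn, strand = strand, isoforms = isoforms)
}

build_ALE <- function(chrom, g, gid, minus = FALSE) {
  if (!minus) {
    ex <- rbind(
      exon_row(chrom, g, g + 200L, "+", gid, first = TRUE, cage = TRUE),
      exon_row(chrom, g + 400L, g + 500L, "+", gid, last = TRUE),
      exon_row(chrom, g + 600L, g + 800L, "+", gid, last = TRUE))
    jn <- rbind(junction_row(chrom, g + 200L, g + 400L, "+"),
                junction_row(chrom, g + 200L, g + 600L, "+"))
    isoforms <- list(iso(junction_key(chrom, g + 200L, g + 400L, "+"), length = 1),
                     iso(junction_key(chrom, g + 200L, g + 600L, "+"), length = 1))
    strand <- "+"
  } else {
    ex <- rbind(
      exon_row(chrom, g + 600L, g + 800L, "-", gid, first = TRUE, cage = TRUE),
      exon_row(chrom, g + 300L, g + 400L, "-", gid, last = TRUE),
      exon_row(chrom, g + 100L, g + 200L, "-", gid, last = TRUE))
    jn <- rbind(junction_row(chrom, g + 400L, g + 600L, "-"),
                junction_row(chrom, g + 200L, g + 600L, "-"))
    isoforms <- list(iso(junction_key(chrom, g + 400L, g + 600L, "-"), length = 1),
                     iso(junction_key(chrom, g + 200L, g + 600L, "-"), length = 1))
    strand <- "-"
  }
  list(exons = ex, junctions = jn, strand = strand, isoforms = isoforms)
}

# Largest-remainder allocation of n_genes across event types.
allocate_types <- function(n, mix) {
  mix <- mix[mix > 0]
  raw <- n * mix / sum(mix)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base[base > 0]
}

#' Generate synthetic gene models with planted splicing events
#'
#' Lays out `n_genes` synthetic genes (one alternative-splicing event each,
#' type drawn from `event_type_mix`), builds the exon annotation and the
#' junction universe they imply, and records the ground truth: every planted
#' event with its isoform junction sets, baseline PSI values, per-junction
#' annotation tiers, and all planted knockdown effects (screen targets,
#' coregulated pairs, cross-regulatory links).
#'
#' @param config A [sim_config()].
#' @return List with `exons` (exon annotation data frame), `junctions`
#'   (junction universe with annotation `status`), and `truth` (list of
#'   `events`, `effects`, `protein_gene`, `proteins`).
#' @export
generate_gene_models <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, generate_gene_models_impl(config))
}

generate_gene_models_impl <- function(config) {
  n <- config$n_genes
  proteins <- sprintf("P%02d", seq_len(config$n_proteins))
  empty <- list(
    exons = exon_row("x", 0, 1, "+", "x")[0, ],
    junctions = cbind(junction_row("x", 0, 1, "+"),
                      name = "x", status = "novel")[0, ],
    truth = list(events = event_rows("x", "x", "SE", "x", "+",
                                     list(iso("k", length = 1),
                                          iso("k2", length = 1)), 1L)[0, ],
                 effects = data.frame(event_id = character(0),
                                      protein = character(0),
                                      affected_isoform = integer(0),
                                      delta_psi = numeric(0),
                                      tier = character(0),
                                      source = character(0),
                                      stringsAsFactors = FALSE),
                 protein_gene = data.frame(protein = proteins,
                                           gene_id = NA_character_,
                                           stringsAsFactors = FALSE),
                 proteins = proteins))
  if (n == 0) return(empty)

  alloc <- allocate_types(n, config$event_type_mix)
  # shuffle so the protein-encoding genes (the first n_proteins) span types
  types <- sample(rep(names(alloc), alloc))

  exons_list <- vector("list", n)
  jn_list <- vector("list", n)
  ev_list <- vector("list", n)
  afe_i <- 0L; ale_i <- 0L
  for (i in seq_len(n)) {
    gc <- gene_coords(i)
    gid <- sprintf("gS%04d", i)
    ty <- types[i]
    m <- switch(ty,
      SE = build_SE(gc$chrom, gc$base, gid),
      CSE = build_CSE(gc$chrom, gc$base, gid),
      MXE = build_MXE(gc$chrom, gc$base, gid),
      A5SS = build_A5SS(gc$chrom, gc$base, gid),
      A3SS = build_A3SS(gc$chrom, gc$base, gid),
      RI = build_RI(gc$chrom, gc$base, gid, config$read_length),
      AFE = {
        afe_i <- afe_i + 1L
        build_AFE(gc$chrom, gc$base, gid, minus = afe_i %% 2L == 0L,
                  n_first = if (afe_i %% 3L == 0L) 3L else 2L)
      },
      ALE = {
        ale_i <- ale_i + 1L
        build_ALE(gc$chrom, gc$base, gid, minus = ale_i %% 2L == 0L)
      })
    can <- canonicalize_event(m$isoforms, ty)
    k <- length(can$isoforms)
    psi_inc <- runif(1, config$psi_range[1], config$psi_range[2])
    iso_psi <- rep((1 - psi_inc) / (k - 1), k)
    if (k > 2) {
      w <- runif(k - 1)
      iso_psi[-can$inclusion_index] <- (1 - psi_inc) * w / sum(w)
    }
    iso_psi[can$inclusion_index] <- psi_inc
    ev_list[[i]] <- event_rows(paste0(ty, "@", gid), gid, ty, gc$chrom,
                               m$strand, can$isoforms, can$inclusion_index,
                               iso_psi)
    exons_list[[i]] <- m$exons
    jn_list[[i]] <- m$junctions
  }
  exons <- do.call(rbind, exons_list)
  junctions <- do.call(rbind, jn_list)
  junctions$name <- sprintf("j%06d", seq_len(nrow(junctions)))
  junctions$status <- sample(names(config$status_mix), nrow(junctions),
                             replace = TRUE, prob = config$status_mix)
  events <- do.call(rbind, ev_list)

  pg <- data.frame(protein = proteins,
                   gene_id = ifelse(seq_along(proteins) <= n,
                                    sprintf("gS%04d", seq_along(proteins)),
                                    NA_character_),
                   stringsAsFactors = FALSE)

  # Cross-links may need a feasible baseline PSI on the target gene's event.
  for (cl in config$cross_links) {
    gid <- pg$gene_id[pg$protein == cl$target]
    if (is.na(gid)) stopf("cross-link target %s has no gene", cl$target)
    idx <- which(events$gene_id == gid)
    inc <- idx[events$isoform_index[idx] == events$inclusion_index[idx]]
    psi <- events$iso_psi[inc]
    lo <- 0.02 + max(0, -cl$delta_psi)
    hi <- 0.98 - max(0, cl$delta_psi)
    if (lo > hi) stopf("cross-link delta_psi %.2f infeasible", cl$delta_psi)
    if (psi < lo || psi > hi) {
      new_psi <- runif(1, lo, hi)
      sc <- (1 - new_psi) / (1 - psi)
      events$iso_psi[idx] <- events$iso_psi[idx] * sc
      events$iso_psi[inc] <- new_psi
    }
  }

  effects <- plant_effects(events, pg, config)
  list(exons = exons, junctions = junctions,
       truth = list(events = events, effects = effects, protein_gene = pg,
                    proteins = proteins))
}

tier_range <- function(tier) {
  switch(tier, weak = c(0.10, 0.25), moderate = c(0.25, 0.50),
         strong = c(0.50, 1.00))
}

tier_of <- function(mag) {
  ifelse(mag > 0.50, "strong", ifelse(mag > 0.25, "moderate", "weak"))
}

# Draw a feasible signed effect for an event with baseline inclusion PSI.
draw_effect <- function(psi, tier) {
  for (t in switch(tier, strong = c("strong", "moderate", "weak"),
                   moderate = c("moderate", "weak"), weak = "weak")) {
    r <- tier_range(t)
    head_plus <- 0.98 - psi
    head_minus <- psi - 0.02
    ok <- c(`+` = head_plus > r[1], `-` = head_minus > r[1])
    if (!any(ok)) next
    sgn <- if (all(ok)) sample(c(1, -1), 1) else if (ok[["+"]]) 1 else -1
    head <- if (sgn > 0) head_plus else head_minus
    mag <- runif(1, r[1], min(r[2], head))
    return(list(delta = sgn * mag, tier = t))
  }
  stopf("no feasible effect for baseline PSI %.3f", psi)
}

plant_effects <- function(events, pg, config) {
  ev1 <- events[events$isoform_index == events$inclusion_index, ]
  eff <- list()
  add <- function(event_id, protein, delta, tier, source) {
    inc <- ev1$inclusion_index[ev1$event_id == event_id]
    data.frame(event_id = event_id, protein = protein,
               affected_isoform = inc, delta_psi = delta, tier = tier,
               source = source, stringsAsFactors = FALSE)
  }
  if (nrow(ev1) == 0 || config$targets_per_protein <= 0)
    n_t <- 0
  else
    n_t <- min(config$targets_per_protein, nrow(ev1))
  for (p in sprintf("P%02d", seq_len(config$n_proteins))) {
    if (n_t == 0) break
    tgt <- sample(ev1$event_id, n_t)
    for (e in tgt) {
      psi <- ev1$iso_psi[ev1$event_id == e]
      tier <- sample(names(config$effect_tiers), 1,
                     prob = config$effect_tiers)
      d <- draw_effect(psi, tier)
      eff[[length(eff) + 1L]] <- add(e, p, d$delta, d$tier, "screen")
    }
  }
  eff <- if (length(eff)) do.call(rbind, eff) else
    data.frame(event_id = character(0), protein = character(0),
               affected_isoform = integer(0), delta_psi = numeric(0),
               tier = character(0), source = character(0),
               stringsAsFactors = FALSE)

  # Coregulated pairs: a fraction of A's cassette-exon targets are shared
  # with B, shifted in the same (coordinated) or opposite (antagonistic)
  # direction.
  for (cp in config$coregulated_pairs) {
    a <- cp$pair[1]; b <- cp$pair[2]
    a_eff <- eff[eff$protein == a, ]
    se_ids <- ev1$event_id[ev1$event_type == "SE"]
    pool <- a_eff[a_eff$event_id %in% se_ids, ]
    if (nrow(pool) == 0) pool <- a_eff
    n_sh <- ceiling(cp$shared_fraction * nrow(pool))
    if (n_sh == 0) next
    shared <- pool[sample(nrow(pool), n_sh), ]
    for (i in seq_len(nrow(shared))) {
      e <- shared$event_id[i]
      psi <- ev1$iso_psi[ev1$event_id == e]
      sgn <- sign(shared$delta_psi[i]) *
        if (cp$mode == "coordinated") 1 else -1
      head <- if (sgn > 0) 0.98 - psi else psi - 0.02
      mag <- min(abs(shared$delta_psi[i]), head * 0.99)
      if (mag < 0.10) mag <- min(0.12, head * 0.99)
      eff <- eff[!(eff$protein == b & eff$event_id == e), ]
      eff <- rbind(eff, add(e, b, sgn * mag, tier_of(mag), "coreg"))
    }
  }

  for (cl in config$cross_links) {
    gid <- pg$gene_id[pg$protein == cl$target]
    e <- ev1$event_id[ev1$gene_id == gid]
    eff <- eff[!(eff$protein == cl$regulator & eff$event_id == e), ]
    eff <- rbind(eff, add(e, cl$regulator, cl$delta_psi,
                          tier_of(abs(cl$delta_psi)), "cross"))
  }
  rownames(eff) <- NULL
  stopifnot(all(abs(eff$delta_psi) >= 0.10))
  eff
}

#' Simulate junction read counts for every library in the screen
#'
#' For each sample and event, the total event read count is Poisson around
#' `depth_per_event`; the split across isoforms follows a beta-binomial (two
#' isoforms) or Dirichlet-multinomial (more) distribution whose mean is the
#' length-weighted count probability implied by the effective PSI
#' (baseline + planted effect for the sample's depleted protein). Reads
#' assigned to an isoform are divided uniformly among its junctions;
#' retained-intron isoforms deposit their reads as intron-body region counts.
#'
#' @param models Output of [generate_gene_models()].
#' @param config The same [sim_config()].
#' @return List with `junction_counts` (long data frame: sample_id, junction,
#'   count), `region_counts`, `metadata` (sample table), and `offsets`
#'   (read-start offset histograms for novel junctions).
#' @export
simulate_counts <- function(models, config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 1L), simulate_counts_impl(models, config))
}

simulate_counts_impl <- function(models, config) {
  truth <- models$truth
  events <- truth$events
  proteins <- truth$proteins
  meta <- build_metadata(proteins, config$n_replicates)
  ns <- nrow(meta)
  rho <- config$dispersion

  jc <- new.env(parent = emptyenv())  # junction key -> count vector
  rc <- list()

  ev_ids <- unique(events$event_id)
  for (eid in ev_ids) {
    ev <- events[events$event_id == eid, ]
    k <- nrow(ev)
    lens <- ev$iso_length
    base_psi <- ev$iso_psi
    inc <- ev$inclusion_index[1]
    effs <- truth$effects[truth$effects$event_id == eid, ]

    # effective inclusion PSI per sample
    psi_mat <- matrix(rep(base_psi, ns), nrow = k)
    if (nrow(effs)) {
      for (i in seq_len(nrow(effs))) {
        s_idx <- which(meta$protein == effs$protein[i])
        new_inc <- base_psi[inc] + effs$delta_psi[i]
        if (new_inc < 0 || new_inc > 1)
          stopf("effective PSI %.3f outside [0,1] for event %s", new_inc, eid)
        sc <- if (base_psi[inc] < 1) (1 - new_inc) / (1 - base_psi[inc]) else 0
        psi_mat[, s_idx] <- base_psi * sc
        psi_mat[inc, s_idx] <- new_inc
      }
    }
    w <- psi_mat * lens
    q <- sweep(w, 2, colSums(w), "/")

    total <- rpois(ns, config$depth_per_event)
    if (k == 2) {
      p <- if (rho < 1e-12) q[inc, ] else {
        a <- q[inc, ] * (1 - rho) / rho
        b <- (1 - q[inc, ]) * (1 - rho) / rho
        rbeta(ns, a, b)
      }
      x_inc <- rbinom(ns, total, p)
      cnt <- rbind(x_inc, total - x_inc)
      cnt <- cnt[order(c(inc, setdiff(1:2, inc))), , drop = FALSE]
    } else {
      alpha0 <- if (rho < 1e-12) Inf else (1 - rho) / rho
      cnt <- matrix(0L, nrow = k, ncol = ns)
      for (s in seq_len(ns)) {
        pr <- if (is.finite(alpha0)) {
          gm <- rgamma(k, shape = alpha0 * q[, s])
          if (sum(gm) == 0) q[, s] else gm / sum(gm)
        } else q[, s]
        cnt[, s] <- rmultinom(1, total[s], pr)
      }
    }

    for (j in seq_len(k)) {
      keys <- split_tokens(ev$junctions[j])[[1]]
      regs <- if (is.na(ev$region[j])) character() else
        split_tokens(ev$region[j])[[1]]
      nj <- length(keys)
      if (nj > 0) {
        if (nj == 1) {
          per <- matrix(cnt[j, ], nrow = 1)
        } else {
          per <- vapply(seq_len(ns), function(s)
            as.integer(rmultinom(1, cnt[j, s], rep(1 / nj, nj))),
            integer(nj))
          per <- matrix(per, nrow = nj)
        }
        for (ji in seq_len(nj)) {
          key <- keys[ji]
          cur <- if (!is.null(jc[[key]])) jc[[key]] else integer(ns)
          jc[[key]] <- cur + per[ji, ]
        }
      }
      for (rg in regs) {
        cur <- rc[[rg]]
        rc[[rg]] <- (if (is.null(cur)) integer(ns) else cur) + cnt[j, ]
      }
    }
  }

  keys <- sort(ls(jc))
  jlong <- if (length(keys)) {
    do.call(rbind, lapply(keys, function(key) {
      v <- jc[[key]]
      data.frame(sample_id = meta$sample_id, junction = key, count = v,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(sample_id = character(0), junction = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  rkeys <- sort(names(rc))
  rlong <- if (length(rkeys)) {
    do.call(rbind, lapply(rkeys, function(key) {
      data.frame(sample_id = meta$sample_id, region = key, count = rc[[key]],
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(sample_id = character(0), region = character(0),
                    count = integer(0), stringsAsFactors = FALSE)
  rownames(jlong) <- NULL; rownames(rlong) <- NULL

  offsets <- novel_offsets(models, jlong)
  list(junction_counts = jlong, region_counts = rlong, metadata = meta,
       offsets = offsets)
}

build_metadata <- function(proteins, n_replicates) {
  cats <- rep_len(c("SR", "hnRNP", "Core", "EJC", "other", "novel"),
                  length(proteins))
  meta <- do.call(rbind, lapply(seq_along(proteins), function(i) {
    data.frame(sample_id = sprintf("%s_rep%d", proteins[i],
                                   seq_len(n_replicates)),
               protein = proteins[i], replicate = seq_len(n_replicates),
               category = cats[i], stringsAsFactors = FALSE)
  }))
  rbind(meta, data.frame(sample_id = "untreated", protein = "untreated",
                         replicate = 1L, category = "untreated",
                         stringsAsFactors = FALSE))
}

# Offset histograms for novel junctions: evenly spread read starts, so a
# genuinely expressed novel junction passes the entropy filter.
novel_offsets <- function(models, jlong) {
  jn <- models$junctions
  novel <- jn[jn$status == "novel", , drop = FALSE]
  if (nrow(novel) == 0 || nrow(jlong) == 0)
    return(data.frame(junction = character(0), offset = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  keys <- junction_key(novel$chrom, novel$donor, novel$acceptor, novel$strand)
  tot <- tapply(jlong$count, jlong$junction, sum)
  out <- lapply(keys, function(key) {
    n <- if (key %in% names(tot)) as.integer(tot[[key]]) else 0L
    h <- simulate_read_offsets(n, n_offsets = 8L, mode = "uniform")
    cbind(junction = key, h)
  })
  do.call(rbind, out)
}

#' Read-start offset histogram for a splice junction
#'
#' @param n_reads Total reads crossing the junction.
#' @param n_offsets Number of distinct alignment start offsets available.
#' @param mode `"uniform"` spreads reads evenly over the offsets (remainder
#'   assigned to the lowest offsets); `"single"` stacks all reads at one
#'   offset, giving zero Shannon entropy.
#' @param position Offset used in `"single"` mode.
#' @return Data frame with `offset` and `count`.
#' @export
#' @examples
#' h <- simulate_read_offsets(400, n_offsets = 4)
#' shannon_entropy(h$count)  # 2 bits
simulate_read_offsets <- function(n_reads, n_offsets = 8L,
                                  mode = c("uniform", "single"),
                                  position = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_reads >= 0, n_offsets >= 1)
  counts <- integer(n_offsets)
  if (mode == "uniform") {
    counts <- rep(n_reads %/% n_offsets, n_offsets)
    rem <- n_reads %% n_offsets
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  } else {
    counts[position] <- n_reads
  }
  data.frame(offset = seq_len(n_offsets), count = as.integer(counts))
}

#' Write a simulated screen to disk as plain-text fixtures
#'
#' Emits one junction BED6+1 file per sample (score = read count, column 7 =
#' annotation status), the exon annotation GTF, the annotated-junction BED,
#' intron-body region counts, novel-junction offset histograms, the sample
#' metadata table and the ground-truth tables. Re-reading the files through
#' the package's readers reproduces the in-memory objects.
#'
#' @param models Output of [generate_gene_models()].
#' @param counts Output of [simulate_counts()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_fixtures <- function(models, counts, outdir) {
  dir.create(file.path(outdir, "junctions"), recursive = TRUE,
             showWarnings = FALSE)
  jn <- models$junctions
  jkey <- if (nrow(jn)) junction_key(jn$chrom, jn$donor, jn$acceptor,
                                     jn$strand) else character(0)
  for (s in counts$metadata$sample_id) {
    sc <- counts$junction_counts[counts$junction_counts$sample_id == s &
                                   counts$junction_counts$count > 0, ,
                                 drop = FALSE]
    idx <- match(sc$junction, jkey)
    df <- if (nrow(sc)) data.frame(
      chrom = jn$chrom[idx], donor = jn$donor[idx],
      acceptor = jn$acceptor[idx], strand = jn$strand[idx],
      name = jn$name[idx], count = sc$count, status = jn$status[idx],
      stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), donor = integer(0),
                    acceptor = integer(0), strand = character(0),
                    name = character(0), count = integer(0),
                    status = character(0), stringsAsFactors = FALSE)
    write_junction_bed(df, file.path(outdir, "junctions", paste0(s, ".bed")))
  }
  write_exon_gtf(models$exons, file.path(outdir, "annotation.gtf"))
  ann <- jn[jn$status %in% c("reference", "secondary"), , drop = FALSE]
  ann$count <- 0L
  write_junction_bed(ann, file.path(outdir, "annotation_junctions.bed"))
  write_tsv(counts$offsets, file.path(outdir, "offsets.tsv"))
  write_tsv(counts$region_counts, file.path(outdir, "region_counts.tsv"))
  meta <- counts$metadata
  meta$gene_id <- models$truth$protein_gene$gene_id[
    match(meta$protein, models$truth$protein_gene$protein)]
  write_tsv(meta, file.path(outdir, "metadata.tsv"))
  write_tsv(models$truth$events, file.path(outdir, "truth_events.tsv"))
  write_tsv(models$truth$effects, file.path(outdir, "truth_effects.tsv"))
  write_tsv(models$truth$protein_gene, file.path(outdir, "protein_gene.tsv"))
  invisible(outdir)
}

#' Events implied by a truth table
#'
#' Reshapes the generator's ground-truth event records into the same long
#' event table that [discover_events()] produces, for use when the
#' downstream stages are exercised without rerunning discovery.
#'
#' @param truth Truth list from [generate_gene_models()].
#' @return Long event data frame.
#' @export
truth_events <- function(truth) {
  ev <- truth$events
  ev$iso_psi <- NULL
  ev
}

#' Replace planted effects with fixed-magnitude knockdown effects
#'
#' Utility for power analysis: overwrites the truth's effect table so that
#' each protein shifts `per_protein` randomly chosen events by exactly
#' `delta` PSI units (sign chosen toward the feasible side of the baseline).
#'
#' @param models Output of [generate_gene_models()].
#' @param delta Absolute planted PSI shift (0-1 scale).
#' @param per_protein Number of affected events per protein.
#' @param seed RNG seed for the event assignment.
#' @return `models` with `truth$effects` replaced.
#' @export
plant_fixed_effects <- function(models, delta = 0.30, per_protein = 10,
                                seed = 1L) {
  ev1 <- models$truth$events[models$truth$events$isoform_index ==
                               models$truth$events$inclusion_index, ]
  with_seed(seed, {
    eff <- do.call(rbind, lapply(models$truth$proteins, function(p) {
      idx <- sample(nrow(ev1), min(per_protein, nrow(ev1)))
      psi <- ev1$iso_psi[idx]
      sgn <- ifelse(psi <= 0.5, 1, -1)
      data.frame(event_id = ev1$event_id[idx], protein = p,
                 affected_isoform = ev1$inclusion_index[idx],
                 delta_psi = sgn * delta, tier = tier_of(delta),
                 source = "fixed", stringsAsFactors = FALSE)
    }))
    models$truth$effects <- eff
    models
  })
}
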