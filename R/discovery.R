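# Classification of alternative-splicing events from a junction universe
# plus exon coordinates.
#
# Event-type naming is strand-aware and follows transcript coordinates: a
# group of junctions sharing their genomic-RIGHT end with differing LEFT
# ends is an A5SS (alternative donors) on the plus strand but an A3SS
# (alternative acceptors) on the minus strand, where the genomic-left shared
# point is the biological acceptor. Junctions of unknown strand are named by
# the plus-strand convention and are excluded from first/last-exon (AFE/ALE)
# discovery, which is inherently strand-dependent.
#
# Classification precedence: SE, CSE and MXE are detected first; AFE/ALE
# discovery claims junction groups whose varying ends abut annotated
# first/last exons; only the remaining shared-end groups are considered for
# A5SS/A3SS. Retained introns are detected independently by
# annotation containment (the intron interval strictly inside a single
# annotated exon).

jn_keys <- function(jn) junction_key(jn$chrom, jn$donor, jn$acceptor, jn$strand)

#' Index junctions by shared donor-side and acceptor-side coordinates
#'
#' @param junctions Junction data frame.
#' @return List of two lists: `donor` maps `"chrom|strand|donor"` to row
#'   indices sorted by acceptor; `acceptor` maps `"chrom|strand|acceptor"`
#'   to row indices sorted by donor.
#' @export
index_junctions <- function(junctions) {
  n <- nrow(junctions)
  if (n == 0) return(list(donor = list(), acceptor = list()))
  dkey <- paste(junctions$chrom, junctions$strand, junctions$donor, sep = "|")
  akey <- paste(junctions$chrom, junctions$strand, junctions$acceptor,
                sep = "|")
  dn <- split(seq_len(n), dkey)
  ac <- split(seq_len(n), akey)
  dn <- lapply(dn, function(i) i[order(junctions$acceptor[i])])
  ac <- lapply(ac, function(i) i[order(junctions$donor[i])])
  list(donor = dn, acceptor = ac)
}

#' Augment expressed junctions with annotated alternative junctions
#'
#' An annotated-but-unexpressed junction is added (with count 0) iff it
#' shares a donor-side or acceptor-side coordinate with an expressed junction
#' while differing at the other end: such a junction certifies that the
#' expressed junction can be alternatively spliced even when the alternative
#' form is not observed in the current libraries.
#'
#' @param expressed Junction data frame of expressed junctions.
#' @param annotation Junction data frame of annotated junctions.
#' @return Combined junction universe.
#' @export
augment_with_annotated <- function(expressed, annotation) {
  if (nrow(annotation) == 0 || nrow(expressed) == 0) return(expressed)
  ekey <- jn_keys(expressed)
  akey <- jn_keys(annotation)
  new <- annotation[!(akey %in% ekey), , drop = FALSE]
  if (nrow(new) == 0) return(expressed)
  ed <- paste(expressed$chrom, expressed$strand, expressed$donor, sep = "|")
  ea <- paste(expressed$chrom, expressed$strand, expressed$acceptor, sep = "|")
  nd <- paste(new$chrom, new$strand, new$donor, sep = "|")
  na_ <- paste(new$chrom, new$strand, new$acceptor, sep = "|")
  # shares one end with an expressed junction but is itself a new interval
  qualifies <- (nd %in% ed) | (na_ %in% ea)
  add <- new[qualifies, , drop = FALSE]
  if (nrow(add) == 0) return(expressed)
  add$count <- 0L
  if (!"name" %in% names(add) || all(is.na(add$name)))
    add$name <- sprintf("aug%05d", seq_len(nrow(add)))
  out <- rbind(expressed[, c("chrom", "donor", "acceptor", "strand", "name",
                             "count", "status")],
               add[, c("chrom", "donor", "acceptor", "strand", "name",
                       "count", "status")])
  out <- out[order(out$chrom, out$donor, out$acceptor, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- internal lookup tables -------------------------------------------------

exon_tables <- function(exons) {
  list(
    exact = paste(exons$chrom, exons$start, exons$end, sep = "|"),
    by_end = split(seq_len(nrow(exons)),
                   paste(exons$chrom, exons$end, sep = "|")),
    by_start = split(seq_len(nrow(exons)),
                     paste(exons$chrom, exons$start, sep = "|")),
    exons = exons)
}

strand_compatible <- function(jstrand, estrand) {
  jstrand == "*" | estrand == "*" | jstrand == estrand
}

exon_exists <- function(et, chrom, start, end) {
  paste(chrom, start, end, sep = "|") %in% et$exact
}

# exon rows abutting a coordinate on the given side, strand-compatible
abutting_exons <- function(et, chrom, coord, side, jstrand) {
  idx <- if (side == "end") et$by_end[[paste(chrom, coord, sep = "|")]]
         else et$by_start[[paste(chrom, coord, sep = "|")]]
  if (is.null(idx)) return(integer(0))
  idx[strand_compatible(jstrand, et$exons$strand[idx])]
}

new_event <- function(type, chrom, strand, isoforms) {
  can <- canonicalize_event(isoforms, type)
  list(type = type, chrom = chrom, strand = strand,
       isoforms = can$isoforms, inclusion_index = can$inclusion_index)
}

event_used_keys <- function(ev) {
  unlist(lapply(ev$isoforms, function(x) x$junctions), use.names = FALSE)
}

event_signature <- function(ev) {
  toks <- sort(vapply(ev$isoforms, iso_token, ""))
  paste0(ev$type, "|", paste(toks, collapse = "|"))
}

# ---- SE / CSE / MXE ---------------------------------------------------------

find_se_cse <- function(jn, idx, et) {
  out <- list()
  for (s in seq_len(nrow(jn))) {
    d0 <- jn$donor[s]; a2 <- jn$acceptor[s]
    chrom <- jn$chrom[s]; strand <- jn$strand[s]
    dgrp <- idx$donor[[paste(chrom, strand, d0, sep = "|")]]
    agrp <- idx$acceptor[[paste(chrom, strand, a2, sep = "|")]]
    ups <- setdiff(dgrp[jn$acceptor[dgrp] < a2], s)
    if (!length(ups)) next
    # single cassette exon
    for (u in ups) {
      a1 <- jn$acceptor[u]
      downs <- setdiff(agrp[jn$donor[agrp] > a1 & jn$donor[agrp] < a2], s)
      for (dn in downs) {
        d1 <- jn$donor[dn]
        if (exon_exists(et, chrom, a1, d1)) {
          key <- function(i) junction_key(chrom, jn$donor[i], jn$acceptor[i],
                                          strand)
          out[[length(out) + 1L]] <- new_event("SE", chrom, strand, list(
            iso(c(key(u), key(dn)), length = 2),
            iso(key(s), length = 1)))
        }
      }
    }
    # chains of >= 2 coordinately included exons
    chains <- cse_chains(jn, idx, et, s)
    for (ch in chains) {
      keys <- junction_key(jn$chrom[ch], jn$donor[ch], jn$acceptor[ch],
                           jn$strand[ch])
      out[[length(out) + 1L]] <- new_event("CSE", jn$chrom[s], jn$strand[s],
        list(iso(keys, length = length(keys)),
             iso(junction_key(jn$chrom[s], d0, a2, strand), length = 1)))
    }
  }
  out
}

# Depth-first search for exon chains realizing the skipped interval of
# junction s; returns junction index vectors for chains with >= 2 exons.
cse_chains <- function(jn, idx, et, s, max_exons = 8L) {
  chrom <- jn$chrom[s]; strand <- jn$strand[s]
  d0 <- jn$donor[s]; a2 <- jn$acceptor[s]
  res <- list()
  walk <- function(donor, path, n_exons) {
    if (n_exons > max_exons) return(invisible(NULL))
    grp <- idx$donor[[paste(chrom, strand, donor, sep = "|")]]
    grp <- setdiff(grp[jn$acceptor[grp] <= a2], s)
    for (j in grp) {
      a <- jn$acceptor[j]
      if (a == a2) {
        if (n_exons >= 2) res[[length(res) + 1L]] <<- c(path, j)
      } else {
        nx <- abutting_exons(et, chrom, a, "start", strand)
        for (e in nx) {
          ed <- et$exons$end[e]
          if (ed < a2) walk(ed, c(path, j), n_exons + 1L)
        }
      }
    }
  }
  walk(d0, integer(0), 0L)
  res
}

find_mxe <- function(jn, idx, et) {
  out <- list()
  n <- nrow(jn)
  if (n == 0) return(out)
  jkey <- jn_keys(jn)
  # candidate paths: J_in = (d0, x), exon [x, y), J_out = (y, a2)
  paths <- list()
  for (i in seq_len(n)) {
    chrom <- jn$chrom[i]; strand <- jn$strand[i]
    x <- jn$acceptor[i]
    for (e in abutting_exons(et, chrom, x, "start", strand)) {
      y <- et$exons$end[e]
      grp <- idx$donor[[paste(chrom, strand, y, sep = "|")]]
      for (j in grp) {
        paths[[length(paths) + 1L]] <- list(
          chrom = chrom, strand = strand,
          d0 = jn$donor[i], a2 = jn$acceptor[j],
          ex_start = x, ex_end = y, jin = i, jout = j)
      }
    }
  }
  if (!length(paths)) return(out)
  gkey <- vapply(paths, function(p)
    paste(p$chrom, p$strand, p$d0, p$a2, sep = "|"), "")
  for (grp in split(paths, gkey)) {
    if (length(grp) < 2) next
    exo <- vapply(grp, function(p) paste(p$ex_start, p$ex_end), "")
    grp <- grp[!duplicated(exo)]
    if (length(grp) < 2) next
    # mutually exclusive paths must not share junctions: exon variants
    # reached through a common junction are alternative splice sites, not
    # alternative exons
    sel <- list()
    for (p in grp) {
      clash <- any(vapply(sel, function(q)
        q$jin == p$jin || q$jout == p$jout, TRUE))
      if (!clash) sel[[length(sel) + 1L]] <- p
    }
    grp <- sel
    if (length(grp) < 2) next
    p1 <- grp[[1]]
    # no direct junction joining the outer boundaries (that is an SE/CSE)
    if (junction_key(p1$chrom, p1$d0, p1$a2, p1$strand) %in% jkey) next
    # no junction connecting any two of the candidate internal exons
    connected <- FALSE
    for (a in seq_along(grp)) for (b in seq_along(grp)) {
      if (a == b) next
      if (junction_key(p1$chrom, grp[[a]]$ex_end, grp[[b]]$ex_start,
                       p1$strand) %in% jkey) connected <- TRUE
    }
    if (connected) next
    isoforms <- lapply(grp, function(p)
      iso(c(junction_key(p$chrom, jn$donor[p$jin], jn$acceptor[p$jin],
                         p$strand),
            junction_key(p$chrom, jn$donor[p$jout], jn$acceptor[p$jout],
                         p$strand)), length = 2))
    out[[length(out) + 1L]] <- new_event("MXE", p1$chrom, p1$strand, isoforms)
  }
  out
}

# ---- AFE / ALE --------------------------------------------------------------

#' Discover alternative first- and last-exon events
#'
#' AFE: two or more annotated first exons of a gene (optionally required to
#' be CAGE-supported, confirming genuine transcription starts), each joined
#' by a junction to a common downstream point; one isoform per first exon.
#' ALE is the mirror case at the 3' end, without the CAGE requirement.
#' Junctions of unknown strand never enter AFE/ALE events.
#'
#' @param junctions Junction universe data frame.
#' @param exons Exon data frame with `is_first_exon`, `is_last_exon`,
#'   `cage_supported` flags.
#' @param require_cage Require CAGE support on first exons (default TRUE).
#' @return List of internal event objects (see [discover_events()] for the
#'   user-facing wrapper returning a data frame).
#' @export
discover_afe_ale <- function(junctions, exons, require_cage = TRUE) {
  jn <- junctions
  et <- exon_tables(exons)
  out <- list()
  grab <- function(shared_side, strand, flag, cage, type) {
    # shared_side: which junction end is shared within a group
    skey <- if (shared_side == "right")
      paste(jn$chrom, jn$strand, jn$acceptor, sep = "|")
    else paste(jn$chrom, jn$strand, jn$donor, sep = "|")
    sel <- which(jn$strand == strand)
    for (grp in split(sel, skey[sel])) {
      if (length(grp) < 2) next
      hits <- list()
      for (i in grp) {
        # varying end must abut the terminal exon
        side <- if (shared_side == "right") "end" else "start"
        coord <- if (shared_side == "right") jn$donor[i] else jn$acceptor[i]
        ex <- abutting_exons(et, jn$chrom[i], coord, side, strand)
        ex <- ex[et$exons[[flag]][ex] & et$exons$strand[ex] == strand]
        if (cage) ex <- ex[et$exons$cage_supported[ex]]
        if (length(ex)) hits[[length(hits) + 1L]] <- i
      }
      if (length(hits) >= 2) {
        isoforms <- lapply(hits, function(i)
          iso(junction_key(jn$chrom[i], jn$donor[i], jn$acceptor[i], strand),
              length = 1))
        out[[length(out) + 1L]] <<- new_event(type, jn$chrom[grp[1]], strand,
                                              isoforms)
      }
    }
  }
  # first exons: upstream in transcript coordinates
  grab("right", "+", "is_first_exon", require_cage, "AFE")
  grab("left", "-", "is_first_exon", require_cage, "AFE")
  # last exons
  grab("left", "+", "is_last_exon", FALSE, "ALE")
  grab("right", "-", "is_last_exon", FALSE, "ALE")
  out
}

# ---- A5SS / A3SS / RI -------------------------------------------------------

find_alt_ss <- function(jn, et, used_keys) {
  out <- list()
  key <- jn_keys(jn)
  for (shared_side in c("right", "left")) {
    skey <- if (shared_side == "right")
      paste(jn$chrom, jn$strand, jn$acceptor, sep = "|")
    else paste(jn$chrom, jn$strand, jn$donor, sep = "|")
    for (grp in split(seq_len(nrow(jn)), skey)) {
      if (length(grp) < 2) next
      if (any(key[grp] %in% used_keys)) next
      strand <- jn$strand[grp[1]]; chrom <- jn$chrom[grp[1]]
      side <- if (shared_side == "right") "end" else "start"
      coords <- if (shared_side == "right") jn$donor[grp] else jn$acceptor[grp]
      abut <- lapply(coords, function(co)
        abutting_exons(et, chrom, co, side, strand))
      # groups explained by first/last-exon choice belong to AFE/ALE
      if (strand %in% c("+", "-")) {
        term_flag <- if ((shared_side == "right") == (strand == "+"))
          "is_first_exon" else "is_last_exon"
        term <- unlist(lapply(abut, function(ix)
          ix[et$exons[[term_flag]][ix]]))
        if (length(unique(term)) >= 2) next
      }
      ok <- vapply(seq_along(grp), function(i)
        length(abut[[i]]) > 0 || jn$status[grp[i]] == "secondary", TRUE)
      keep <- grp[ok]
      if (length(keep) < 2) next
      type <- if ((shared_side == "right") == (strand != "-")) "A5SS"
              else "A3SS"
      isoforms <- lapply(keep, function(i)
        iso(key[i], length = 1))
      out[[length(out) + 1L]] <- new_event(type, chrom, strand, isoforms)
    }
  }
  out
}

find_ri <- function(jn, et, read_length = 75L) {
  out <- list()
  ex <- et$exons
  for (i in seq_len(nrow(jn))) {
    d <- jn$donor[i]; a <- jn$acceptor[i]
    cand <- which(ex$chrom == jn$chrom[i] & ex$start < d & ex$end > a &
                    strand_compatible(jn$strand[i], ex$strand))
    if (!length(cand)) next
    rlen <- max(1, floor((a - d) / read_length))
    out[[length(out) + 1L]] <- new_event("RI", jn$chrom[i], jn$strand[i], list(
      iso(regions = region_key(jn$chrom[i], d, a), length = rlen),
      iso(junction_key(jn$chrom[i], d, a, jn$strand[i]), length = 1)))
  }
  out
}

#' Classify junction-driven alternative-splicing events
#'
#' Detects SE, CSE, MXE, A5SS, A3SS and RI events from the junction universe
#' and exon coordinates (AFE/ALE discovery is separate, see
#' [discover_afe_ale()]). A5SS/A3SS classification is restricted to
#' junctions whose varying splice site abuts an annotated exon boundary,
#' except when the alternative junction itself carries a secondary-annotation
#' status.
#'
#' @param junctions Junction universe data frame.
#' @param exons Exon data frame.
#' @param read_length Read length used for retained-intron length units.
#' @param used_keys Junction keys already claimed by other events (typically
#'   AFE/ALE); shared-end groups touching them are not considered for
#'   A5SS/A3SS.
#' @return List of internal event objects.
#' @export
classify_events <- function(junctions, exons, read_length = 75L,
                            used_keys = character(0)) {
  jn <- junctions
  if (nrow(jn) == 0) return(list())
  idx <- index_junctions(jn)
  et <- exon_tables(exons)
  ev <- c(find_se_cse(jn, idx, et), find_mxe(jn, idx, et))
  used <- unique(c(used_keys,
                   unlist(lapply(ev, event_used_keys), use.names = FALSE)))
  ev <- c(ev, find_alt_ss(jn, et, used), find_ri(jn, et, read_length))
  ev[!duplicated(vapply(ev, event_signature, ""))]
}

# ---- gene assignment and user-facing wrapper --------------------------------

event_span <- function(ev) {
  keys <- unlist(lapply(ev$isoforms, function(x) x$junctions))
  coords <- if (length(keys)) parse_junction_key(keys) else NULL
  regs <- unlist(lapply(ev$isoforms, function(x) x$regions))
  lo <- hi <- integer(0)
  if (!is.null(coords)) { lo <- coords$donor; hi <- coords$acceptor }
  if (length(regs)) {
    m <- regmatches(regs, regexec("^(.+):([0-9]+)-([0-9]+)$", regs))
    lo <- c(lo, as.integer(vapply(m, `[`, "", 3L)))
    hi <- c(hi, as.integer(vapply(m, `[`, "", 4L)))
  }
  c(min(lo), max(hi))
}

assign_gene <- function(ev, gene_spans) {
  sp <- event_span(ev)
  g <- gene_spans[gene_spans$chrom == ev$chrom, , drop = FALSE]
  if (nrow(g) == 0) return(NA_character_)
  ov <- pmax(0, pmin(g$end, sp[2]) - pmax(g$start, sp[1]))
  if (all(ov == 0)) return(NA_character_)
  top <- which(ov == max(ov))
  if (length(top) > 1) {
    g <- g[top, , drop = FALSE]
    return(paste0("AMBIG:", g$gene_id[order(g$gene_id)][1]))
  }
  g$gene_id[top]
}

#' Discover and classify all alternative-splicing events
#'
#' Runs AFE/ALE discovery followed by junction-pattern classification of the
#' remaining six event types, assigns each event to the gene whose exon span
#' it overlaps most (ties are ambiguous and excluded with a message), and
#' returns events in canonical coordinate order as a long data frame with
#' one row per isoform.
#'
#' @param junctions Junction universe data frame.
#' @param exons Exon data frame.
#' @param require_cage Require CAGE support for AFE first exons.
#' @param read_length Read length for retained-intron length units.
#' @return Data frame with columns `event_id`, `gene_id`, `event_type`,
#'   `chrom`, `strand`, `isoform_index`, `n_isoforms`, `inclusion_index`,
#'   `junctions` (semicolon-joined keys), `region`, `iso_length`.
#' @export
discover_events <- function(junctions, exons, require_cage = TRUE,
                            read_length = 75L) {
  afe <- discover_afe_ale(junctions, exons, require_cage)
  used <- unlist(lapply(afe, event_used_keys), use.names = FALSE)
  rest <- classify_events(junctions, exons, read_length, used_keys = used)
  ev <- c(afe, rest)
  if (!length(ev)) {
    out <- event_rows("x", "x", "SE", "x", "+",
                      list(iso("k", length = 1), iso("k2", length = 1)),
                      1L)[0, ]
    out$iso_psi <- NULL
    return(out)
  }
  spans <- t(vapply(ev, event_span, c(0, 0)))
  ord <- order(vapply(ev, function(e) e$chrom, ""), spans[, 1], spans[, 2],
               vapply(ev, function(e) e$type, ""))
  ev <- ev[ord]; spans <- spans[ord, , drop = FALSE]

  gene_spans <- data.frame(chrom = exons$chrom, gene_id = exons$gene_id,
                           start = exons$start, end = exons$end,
                           stringsAsFactors = FALSE)
  gene_spans <- do.call(rbind, lapply(split(gene_spans,
                                            gene_spans$gene_id), function(g)
    data.frame(chrom = g$chrom[1], gene_id = g$gene_id[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)))

  genes <- vapply(ev, assign_gene, "", gene_spans = gene_spans)
  ambig <- grepl("^AMBIG:", genes)
  if (any(ambig))
    ss_message(sprintf("%d event(s) with ambiguous gene assignment excluded",
                       sum(ambig)))
  ev <- ev[!ambig]; genes <- genes[!ambig]; spans <- spans[!ambig, ,
                                                           drop = FALSE]
  if (!length(ev)) {
    out <- event_rows("x", "x", "SE", "x", "+",
                      list(iso("k", length = 1), iso("k2", length = 1)),
                      1L)[0, ]
    out$iso_psi <- NULL
    return(out)
  }
  rows <- lapply(seq_along(ev), function(i) {
    e <- ev[[i]]
    eid <- sprintf("%s@%s:%d-%d:%s", e$type, e$chrom, spans[i, 1],
                   spans[i, 2], e$strand)
    event_rows(eid, genes[i], e$type, e$chrom, e$strand, e$isoforms,
               e$inclusion_index)
  })
  out <- do.call(rbind, rows)
  out$iso_psi <- NULL
  rownames(out) <- NULL
  out
}

#' Signatures of a set of events
#'
#' A signature is the event type plus the sorted isoform token sets; two
#' event tables describe the same events iff their signature sets are equal.
#'
#' @param events Long event data frame (one row per isoform).
#' @return Character vector, one signature per event.
#' @export
event_signatures <- function(events) {
  sp <- split(events, events$event_id)
  sig <- vapply(sp, function(e) {
    toks <- vapply(seq_len(nrow(e)), function(i) {
      parts <- c(split_tokens(e$junctions[i])[[1]],
                 if (!is.na(e$region[i])) split_tokens(e$region[i])[[1]])
      paste(sort(parts), collapse = ",")
    }, "")
    paste0(e$event_type[1], "|", paste(sort(toks), collapse = "|"))
  }, "")
  unname(sig)
}
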