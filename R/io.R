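# Reading and writing junction BED files, exon annotations and the
# tab-separated tables exchanged between pipeline stages.
#
# Coordinate convention: BED 0-based half-open throughout; a junction's
# interval is the intron, so the `donor` field is the genomic-left boundary
# and `acceptor` the genomic-right (half-open) boundary regardless of strand.
# On the minus strand the biological donor (5' splice site) is the
# genomic-right end; all strand-aware logic lives in the event classifier.

#' Read splice junctions from a BED6(+1) file
#'
#' Column 5 (score) holds the junction read count; an optional seventh column
#' carries the annotation status (`reference`, `secondary`, `novel`).
#' Duplicate junction lines (same interval and strand) are merged by summing
#' their counts, with a warning.
#'
#' @param path Path to a BED file with at least 6 columns.
#' @param strip_chr_prefix If TRUE, a leading `"chr"` is removed from
#'   chromosome names so sources with mismatched prefixes can be combined.
#' @return Data frame with columns `chrom`, `donor`, `acceptor`, `strand`,
#'   `name`, `count`, `status`.
#' @export
read_junction_bed <- function(path, strip_chr_prefix = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  empty <- data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      name = character(0), count = integer(0),
                      status = character(0), stringsAsFactors = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(empty)
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol < 6) stopf("%s: BED junction files need >= 6 columns, found %d",
                      path, ncol)
  extra <- if (ncol >= 7) c(status = "character") else character(0)
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED", extraCols = extra),
    error = function(e) stopf("malformed BED in %s: %s", path,
                              conditionMessage(e)))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    donor = GenomicRanges::start(gr) - 1L,
    acceptor = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    count = as.integer(gr$score),
    status = if (ncol >= 7) gr$status else NA_character_,
    stringsAsFactors = FALSE)
  if (strip_chr_prefix) df$chrom <- sub("^chr", "", df$chrom)
  if (any(is.na(df$count) | df$count < 0)) {
    bad <- which(is.na(df$count) | df$count < 0)[1]
    stopf("%s line %d: negative or missing read count", path, bad)
  }
  key <- junction_key(df$chrom, df$donor, df$acceptor, df$strand)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warnf("%s: %d duplicate junction line(s) merged by summing counts",
          path, ndup)
    agg <- tapply(df$count, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$count <- as.integer(agg[junction_key(df$chrom, df$donor, df$acceptor,
                                            df$strand)])
  }
  df <- df[order(df$chrom, df$donor, df$acceptor, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write splice junctions as BED6+1
#'
#' @param junctions Data frame as returned by [read_junction_bed()].
#' @param path Output path.
#' @export
write_junction_bed <- function(junctions, path) {
  df <- junctions[order(junctions$chrom, junctions$donor, junctions$acceptor,
                        junctions$strand), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s",
                   df$chrom, df$donor, df$acceptor,
                   ifelse(is.na(df$name), ".", df$name),
                   df$count, df$strand,
                   ifelse(is.na(df$status), "novel", df$status))
  writeLines(lines, path)
  invisible(path)
}

#' Read an exon annotation from GTF
#'
#' Exon features must carry a `gene_id` attribute; the optional attributes
#' `first_exon`, `last_exon`, `cage` (TRUE/FALSE) and `src`
#' (primary/secondary/denovo) populate the corresponding flags.
#'
#' @param path GTF file path.
#' @param strip_chr_prefix Drop a leading `"chr"` from chromosome names.
#' @return Exon data frame (`chrom`, `start`, `end`, `strand`, `gene_id`,
#'   `is_first_exon`, `is_last_exon`, `cage_supported`, `source`), 0-based
#'   half-open coordinates.
#' @export
read_exon_gtf <- function(path, strip_chr_prefix = FALSE) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  get_flag <- function(nm) {
    if (!is.null(S4Vectors::mcols(gr)[[nm]]))
      as.logical(S4Vectors::mcols(gr)[[nm]]) %in% TRUE
    else rep(FALSE, length(gr))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    is_first_exon = get_flag("first_exon"),
    is_last_exon = get_flag("last_exon"),
    cage_supported = get_flag("cage"),
    source = if (!is.null(gr$src)) gr$src else "primary",
    stringsAsFactors = FALSE)
  if (strip_chr_prefix) df$chrom <- sub("^chr", "", df$chrom)
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an exon annotation as GTF
#'
#' @param exons Exon data frame (see [read_exon_gtf()]).
#' @param path Output path.
#' @export
write_exon_gtf <- function(exons, path) {
  df <- exons[order(exons$chrom, exons$start, exons$end, exons$gene_id), ,
              drop = FALSE]
  attrs <- sprintf(
    'gene_id "%s"; first_exon "%s"; last_exon "%s"; cage "%s"; src "%s";',
    df$gene_id, df$is_first_exon, df$is_last_exon, df$cage_supported,
    df$source)
  lines <- sprintf("%s\tsplicescreen\texon\t%d\t%d\t.\t%s\t.\t%s",
                   df$chrom, df$start + 1L, df$end, df$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Shannon entropy of a read-start offset histogram
#'
#' \eqn{S = -\sum_i p_i \log_2 p_i} over offsets with positive counts, where
#' \eqn{p_i} is the fraction of reads starting at offset \eqn{i}. Junctions
#' supported by reads stacked at a single alignment position (entropy 0) are
#' characteristic of mapping artifacts, whereas genuine junctions accumulate
#' read starts across many offsets.
#'
#' @param counts Non-negative numeric vector of per-offset read counts.
#' @return Entropy in bits; 0 when the histogram is empty.
#' @export
#' @examples
#' shannon_entropy(c(100, 100, 100, 100))  # 2 bits
#' shannon_entropy(c(400))                 # 0 bits
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stopf("offset counts must be non-negative")
  total <- sum(counts)
  if (total == 0) return(0)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Filter novel junctions by offset entropy and read count
#'
#' Annotated junctions (status `reference` or `secondary`) pass
#' unconditionally. A novel junction is kept iff its read-start offset
#' entropy is at least `entropy_min` bits and its count is at least
#' `count_min`; novel junctions without an offset histogram are dropped with
#' a warning.
#'
#' @param junctions Junction data frame with a `status` column.
#' @param offsets Data frame (`junction`, `offset`, `count`) of read-start
#'   histograms for novel junctions.
#' @param entropy_min Minimum entropy in bits (default 2).
#' @param count_min Minimum read count (default 2).
#' @return The confident junction set, with a `filter_report` attribute
#'   listing kept/dropped counts.
#' @export
filter_novel_junctions <- function(junctions, offsets, entropy_min = 2.0,
                                   count_min = 2) {
  key <- junction_key(junctions$chrom, junctions$donor, junctions$acceptor,
                      junctions$strand)
  is_novel <- junctions$status == "novel"
  keep <- rep(TRUE, nrow(junctions))
  missing_hist <- 0L
  if (any(is_novel)) {
    ent <- tapply(offsets$count, offsets$junction, shannon_entropy)
    for (i in which(is_novel)) {
      if (!key[i] %in% names(ent)) {
        keep[i] <- FALSE
        missing_hist <- missing_hist + 1L
      } else {
        keep[i] <- ent[[key[i]]] >= entropy_min &&
          junctions$count[i] >= count_min
      }
    }
    if (missing_hist > 0)
      warnf("%d novel junction(s) lacked offset histograms and were dropped",
            missing_hist)
  }
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- data.frame(
    novel_total = sum(is_novel),
    novel_kept = sum(keep & is_novel),
    novel_dropped = sum(!keep),
    annotated_kept = sum(!is_novel))
  out
}

#' Assign annotation status to junctions
#'
#' A junction is `reference` if present in the primary annotation set,
#' otherwise `secondary` if present in the secondary set, otherwise `novel`.
#' Membership is keyed on (chrom, donor, acceptor, strand); names are
#' ignored.
#'
#' @param junctions Junction data frame.
#' @param primary,secondary Junction data frames holding the annotation sets
#'   (counts ignored).
#' @return `junctions` with its `status` column (re)assigned.
#' @export
annotate_status <- function(junctions, primary, secondary = NULL) {
  key <- junction_key(junctions$chrom, junctions$donor, junctions$acceptor,
                      junctions$strand)
  pkey <- junction_key(primary$chrom, primary$donor, primary$acceptor,
                       primary$strand)
  skey <- if (!is.null(secondary) && nrow(secondary))
    junction_key(secondary$chrom, secondary$donor, secondary$acceptor,
                 secondary$strand) else character(0)
  junctions$status <- ifelse(key %in% pkey, "reference",
                             ifelse(key %in% skey, "secondary", "novel"))
  junctions
}

read_tsv <- function(path, col_types = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = col_types)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
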