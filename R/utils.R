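# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical junction key
#'
#' Junctions are identified by their intron interval and strand; the BED name
#' field never enters equality comparisons.
#'
#' @param chrom Chromosome name.
#' @param donor 0-based start of the intron interval (genomic left).
#' @param acceptor Half-open end of the intron interval (genomic right).
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return Character vector of keys `"chrom:donor-acceptor:strand"`.
#' @export
junction_key <- function(chrom, donor, acceptor, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(donor), as.integer(acceptor), strand)
}

region_key <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

# round() uses banker's rounding; virtual-reference counts are rounded
# half-up so that e.g. 120.5 -> 121 deterministically.
round_half_up <- function(x) floor(x + 0.5)

# Run code under a temporary RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable small-offset seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000 + offset) %% 2147483647)
}

ss_message <- function(..., verbose = getOption("splicescreen.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Split "chrom:donor-acceptor:strand" keys back into components.
parse_junction_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+):([+*-])$", keys))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stopf("malformed junction key: %s", keys[bad][1])
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    donor = as.integer(vapply(m, `[`, "", 3L)),
    acceptor = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

split_tokens <- function(x, sep = ";") {
  out <- strsplit(x, sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_tokens <- function(x, sep = ";") paste(x, collapse = sep)
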