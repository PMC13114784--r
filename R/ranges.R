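#' Parse an ECOD-style residue-range string
#'
#' Domain boundaries are encoded as comma-separated `"start-end"` segments in
#' 1-based, both-ends-inclusive residue numbering, e.g. `"1-111,177-409"` for
#' a discontinuous domain split into two segments. Each segment may carry a
#' `"CHAIN:"` prefix (`"A:1-111"`); the chain must be consistent across
#' segments and is stripped after validation (single-polypeptide analysis).
#'
#' Segments must be sorted ascending and pairwise non-overlapping; reversed
#' segments (`start > end`), out-of-order or overlapping segments, and mixed
#' chains are rejected.
#'
#' @param s A single range string.
#' @return A tibble with integer columns `start` and `end`, one row per
#'   segment, with the chain identifier (or `NA`) in attribute `"chain"`.
#' @examples
#' parse_range_string("1-111,177-409")
#' parse_range_string("112-176")
#' @export
parse_range_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("range string must be a single non-empty string", call. = FALSE)
  }
  tokens <- strsplit(s, ",", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  m <- regmatches(tokens, regexec("^(?:([^:]+):)?(-?[0-9]+)-(-?[0-9]+)$", tokens))
  bad <- tokens[lengths(m) == 0L]
  if (length(bad) > 0L) {
    stop("malformed range token '", bad[[1]], "' in '", s, "'", call. = FALSE)
  }
  chain <- vapply(m, `[[`, character(1), 2L)
  start <- as.integer(vapply(m, `[[`, character(1), 3L))
  end <- as.integer(vapply(m, `[[`, character(1), 4L))
  chains <- unique(chain[nzchar(chain)])
  if (length(chains) > 1L) {
    stop("mixed chains in range string '", s, "'", call. = FALSE)
  }
  if (any(start < 1L)) {
    stop("residue index < 1 in range string '", s, "'", call. = FALSE)
  }
  if (any(start > end)) {
    i <- which(start > end)[[1]]
    stop("reversed range ", start[i], "-", end[i], " in '", s, "'", call. = FALSE)
  }
  if (length(start) > 1L) {
    prev_end <- end[-length(end)]
    next_start <- start[-1L]
    if (any(next_start <= prev_end)) {
      stop("out-of-order or overlapping segments in '", s, "'", call. = FALSE)
    }
  }
  out <- tibble::tibble(start = start, end = end)
  attr(out, "chain") <- if (length(chains) == 1L) chains else NA_character_
  out
}

#' Format residue segments back to the canonical range-string form
#'
#' Inverse of [parse_range_string()]: segments become comma-separated
#' `"start-end"` tokens, each prefixed with the chain identifier when one is
#' known.
#'
#' @param segments A data frame with `start` and `end` columns (as returned by
#'   [parse_range_string()]).
#' @param chain Optional chain identifier; defaults to the `"chain"` attribute
#'   of `segments`.
#' @return A single range string.
#' @export
format_range_string <- function(segments, chain = attr(segments, "chain")) {
  tok <- paste0(segments$start, "-", segments$end)
  if (!is.null(chain) && !is.na(chain) && nzchar(chain)) {
    tok <- paste0(chain, ":", tok)
  }
  paste(tok, collapse = ",")
}

# Total residue count covered by a set of segments.
segments_length <- function(start, end) sum(end - start + 1L)

#' Residue length of a domain
#'
#' The length of a domain is the number of residues it covers, summed over
#' all of its segments — for a discontinuous host this is A1 + A2 combined,
#' never counting the residues of the intervening gap.
#'
#' @param domain One row of a domain table (see [domain_table()]), or any list
#'   with `seg_starts`/`seg_ends` elements.
#' @return Integer residue count.
#' @examples
#' d <- domain_table("p1", "d1", "2004.1.1.71", "1-111,177-409")
#' domain_length(d[1, ])
#' @export
domain_length <- function(domain) {
  starts <- unlist(domain$seg_starts, use.names = FALSE)
  ends <- unlist(domain$seg_ends, use.names = FALSE)
  as.integer(segments_length(starts, ends))
}
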