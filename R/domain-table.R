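#' Construct a validated domain table
#'
#' The domain table is the package's central container: one row per classified
#' domain instance, with the residue segments held in list-columns. All
#' detection and downstream analyses operate on this shape.
#'
#' Columns of the returned tibble:
#' \describe{
#'   \item{protein_id, domain_uid}{identifiers; `domain_uid` unique within its
#'     protein}
#'   \item{f_id, x_group, h_group, t_group, t_group_only}{the ECOD family key
#'     (see [parse_family_id()])}
#'   \item{seg_starts, seg_ends}{integer list-columns of segment boundaries,
#'     1-based inclusive, sorted, non-overlapping}
#'   \item{n_segments, span_start, span_end, length}{derived geometry;
#'     `length` sums the segments (gap residues excluded)}
#'   \item{architecture_label, source}{optional annotations (may be `NA`)}
#' }
#'
#' @param protein_id,domain_uid,f_id,range_string Character vectors, recycled
#'   to a common length.
#' @param architecture_label,source Optional annotation vectors.
#' @return A tibble of class `"domain_tbl"`.
#' @examples
#' domain_table(
#'   protein_id = "3EPL",
#'   domain_uid = c("d1", "d2"),
#'   f_id = c("2004.1.1.71", "3949.1.1.1"),
#'   range_string = c("1-111,177-409", "112-176")
#' )
#' @export
domain_table <- function(protein_id, domain_uid, f_id, range_string,
                         architecture_label = NA_character_,
                         source = NA_character_) {
  rows <- tibble::tibble(
    protein_id = as.character(protein_id),
    domain_uid = as.character(domain_uid),
    f_id = as.character(f_id),
    range_string = as.character(range_string),
    architecture_label = as.character(architecture_label),
    source = as.character(source)
  )
  out <- build_domain_table(rows, strict = TRUE)
  out
}

# Shared validation path for the programmatic constructor and the TSV reader.
# `strict = TRUE` raises on the first invalid row; otherwise invalid rows (and
# whole proteins with overlapping domains) are dropped and recorded in the
# "rejects" attribute as a tibble(row, protein_id, domain_uid, reason).
build_domain_table <- function(rows, strict = FALSE) {
  n <- nrow(rows)
  reject <- character(n)

  miss <- !nzchar(rows$protein_id) | is.na(rows$protein_id) |
    !nzchar(rows$domain_uid) | is.na(rows$domain_uid) |
    !nzchar(rows$f_id) | is.na(rows$f_id) |
    !nzchar(rows$range_string) | is.na(rows$range_string)
  reject[miss] <- "missing mandatory field"

  fam <- family_key_cols(rows$f_id)
  bad_fam <- !fam$.valid & !nzchar(reject)
  reject[bad_fam] <- "malformed family ID"

  seg_starts <- vector("list", n)
  seg_ends <- vector("list", n)
  for (i in seq_len(n)) {
    if (nzchar(reject[i])) next
    segs <- tryCatch(parse_range_string(rows$range_string[i]), error = identity)
    if (inherits(segs, "error")) {
      reject[i] <- conditionMessage(segs)
    } else {
      seg_starts[[i]] <- segs$start
      seg_ends[[i]] <- segs$end
    }
  }

  # duplicate domain_uid within a protein
  key <- paste(rows$protein_id, rows$domain_uid, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  reject[dup & !nzchar(reject)] <- "duplicate domain_uid within protein"

  # overlap check across domains of one protein (on surviving rows)
  live <- which(!nzchar(reject))
  if (length(live) > 0L) {
    seg_tbl <- tibble::tibble(
      row = rep(live, lengths(seg_starts[live])),
      protein_id = rep(rows$protein_id[live], lengths(seg_starts[live])),
      start = unlist(seg_starts[live], use.names = FALSE),
      end = unlist(seg_ends[live], use.names = FALSE)
    )
    seg_tbl <- seg_tbl[order(seg_tbl$protein_id, seg_tbl$start, seg_tbl$end), ]
    same_prot <- seg_tbl$protein_id[-1L] == seg_tbl$protein_id[-nrow(seg_tbl)]
    overl <- c(FALSE, same_prot & seg_tbl$start[-1L] <= seg_tbl$end[-nrow(seg_tbl)])
    if (any(overl)) {
      bad_prot <- unique(seg_tbl$protein_id[overl])
      hit <- rows$protein_id %in% bad_prot & !nzchar(reject)
      reject[hit] <- "overlapping domains within protein"
    }
  }

  if (strict && any(nzchar(reject))) {
    i <- which(nzchar(reject))[[1]]
    stop("invalid domain row (protein '", rows$protein_id[i], "', domain '",
         rows$domain_uid[i], "'): ", reject[i], call. = FALSE)
  }

  keep <- !nzchar(reject)
  ks <- seg_starts[keep]
  ke <- seg_ends[keep]
  out <- tibble::tibble(
    protein_id = rows$protein_id[keep],
    domain_uid = rows$domain_uid[keep],
    f_id = rows$f_id[keep],
    x_group = fam$x_group[keep],
    h_group = fam$h_group[keep],
    t_group = fam$t_group[keep],
    t_group_only = fam$t_group_only[keep],
    seg_starts = ks,
    seg_ends = ke,
    n_segments = lengths(ks),
    span_start = vapply(ks, function(x) x[[1L]], integer(1)),
    span_end = vapply(ke, function(x) x[[length(x)]], integer(1)),
    length = vapply(seq_along(ks), function(i)
      as.integer(segments_length(ks[[i]], ke[[i]])), integer(1)),
    architecture_label = rows$architecture_label[keep],
    source = rows$source[keep]
  )
  class(out) <- c("domain_tbl", class(out))
  attr(out, "rejects") <- tibble::tibble(
    row = which(!keep),
    protein_id = rows$protein_id[!keep],
    domain_uid = rows$domain_uid[!keep],
    reason = reject[!keep]
  )
  out
}

#' @export
print.domain_tbl <- function(x, ...) {
  cat("# Domain table: ", nrow(x), " domains in ",
      length(unique(x$protein_id)), " proteins (",
      sum(x$n_segments >= 2L), " discontinuous)\n", sep = "")
  NextMethod()
}
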