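#' Enumerate candidate insertion gaps of a discontinuous domain
#'
#' A gap is the run of residues strictly between two consecutive segments of
#' a discontinuous domain (`end of segment i + 1` to `start of segment i+1
#' - 1`). Only gaps of at least `min_gap` residues are candidate insertion
#' sites; the default of 30 residues is the minimum size at which a gap could
#' plausibly accommodate an independently folded domain rather than a loop or
#' linker, and the threshold is inclusive (a 30-residue gap qualifies).
#'
#' @param host One row of a domain table.
#' @param min_gap Minimum gap length in residues (inclusive).
#' @return A tibble with one row per qualifying gap: `host_uid`, `gap_index`,
#'   `gap_start`, `gap_end`, `gap_length`. Continuous domains yield zero rows.
#' @examples
#' host <- domain_table("p", "d1", "2004.1.1.71", "1-111,177-409")
#' enumerate_gaps(host[1, ])
#' @export
enumerate_gaps <- function(host, min_gap = 30) {
  starts <- unlist(host$seg_starts, use.names = FALSE)
  ends <- unlist(host$seg_ends, use.names = FALSE)
  n <- length(starts)
  if (n < 2L) {
    return(tibble::tibble(host_uid = character(), gap_index = integer(),
                          gap_start = integer(), gap_end = integer(),
                          gap_length = integer()))
  }
  gap_start <- ends[-n] + 1L
  gap_end <- starts[-1L] - 1L
  out <- tibble::tibble(
    host_uid = host$domain_uid[[1L]],
    gap_index = seq_len(n - 1L),
    gap_start = gap_start,
    gap_end = gap_end,
    gap_length = gap_end - gap_start + 1L
  )
  out[out$gap_length >= min_gap, ]
}

# All qualifying gaps for every discontinuous domain in a domain table.
all_gaps <- function(domains, min_gap = 30) {
  disc <- domains[domains$n_segments >= 2L, ]
  if (nrow(disc) == 0L) {
    return(tibble::tibble(protein_id = character(), host_uid = character(),
                          gap_index = integer(), gap_start = integer(),
                          gap_end = integer(), gap_length = integer()))
  }
  n_gap <- disc$n_segments - 1L
  idx <- rep(seq_len(nrow(disc)), n_gap)
  gap_index <- unlist(lapply(n_gap, seq_len), use.names = FALSE)
  gap_start <- unlist(lapply(disc$seg_ends, function(e) e[-length(e)] + 1L),
                      use.names = FALSE)
  gap_end <- unlist(lapply(disc$seg_starts, function(s) s[-1L] - 1L),
                    use.names = FALSE)
  out <- tibble::tibble(
    protein_id = disc$protein_id[idx],
    host_uid = disc$domain_uid[idx],
    gap_index = gap_index,
    gap_start = gap_start,
    gap_end = gap_end,
    gap_length = gap_end - gap_start + 1L
  )
  out[out$gap_length >= min_gap, ]
}

#' Candidate insert-gap containments
#'
#' Lists every (domain, gap) pair in which *all* segments of a domain lie
#' entirely within a single gap of another domain of the same protein. A
#' domain may pair with several gaps at this stage; exclusive assignment is
#' performed by [assign_events()].
#'
#' @param domains A domain table (one or many proteins).
#' @param min_gap Minimum gap length in residues.
#' @return A tibble of candidate pairs with gap geometry columns.
#' @export
candidate_containments <- function(domains, min_gap = 30) {
  gaps <- all_gaps(domains, min_gap)
  spans <- tibble::tibble(
    protein_id = domains$protein_id,
    insert_uid = domains$domain_uid,
    span_start = domains$span_start,
    span_end = domains$span_end
  )
  cand <- dplyr::inner_join(gaps, spans, by = "protein_id",
                            relationship = "many-to-many")
  cand <- cand[cand$insert_uid != cand$host_uid &
                 cand$span_start >= cand$gap_start &
                 cand$span_end <= cand$gap_end, ]
  # segments are sorted and non-overlapping, so span containment in a
  # contiguous gap interval implies containment of every segment
  cand
}

#' Assign insertion events by the smallest-gap rule
#'
#' Each insertable domain is assigned exclusively to the smallest gap it
#' completely occupies, so that a domain participates in at most one
#' insertion event per protein (in a nested A1-B1-C-B2-A2 architecture, C is
#' an insertion into B, not into A). Several domains may share one gap
#' (side-by-side insertions). Ties between containing gaps of equal length
#' are broken by smaller gap start, then by host domain ID, for determinism.
#'
#' @param domains A domain table.
#' @param min_gap Minimum gap length in residues.
#' @return An event tibble, one row per insertion event, with family keys,
#'   nesting `depth`, `relative_position` of the insertion site in the host,
#'   and the `cross_h_group` flag.
#' @export
assign_events <- function(domains, min_gap = 30) {
  cand <- candidate_containments(domains, min_gap)
  if (nrow(cand) == 0L) {
    return(empty_event_table())
  }
  ord <- order(cand$protein_id, cand$insert_uid, cand$gap_length,
               cand$gap_start, cand$host_uid)
  cand <- cand[ord, ]
  keep <- !duplicated(paste(cand$protein_id, cand$insert_uid, sep = "\r"))
  ev <- cand[keep, ]

  info <- tibble::tibble(
    protein_id = domains$protein_id,
    domain_uid = domains$domain_uid,
    f_id = domains$f_id,
    h_group = domains$h_group,
    x_group = domains$x_group,
    t_group_only = domains$t_group_only,
    length = domains$length,
    architecture_label = domains$architecture_label
  )
  ev <- dplyr::left_join(
    ev,
    stats::setNames(info, c("protein_id", "host_uid", "host_f_id",
                            "host_h_group", "host_x_group",
                            "host_t_group_only", "host_length", "host_arch")),
    by = c("protein_id", "host_uid")
  )
  ev <- dplyr::left_join(
    ev,
    stats::setNames(info, c("protein_id", "insert_uid", "insert_f_id",
                            "insert_h_group", "insert_x_group",
                            "insert_t_group_only", "insert_length",
                            "insert_arch")),
    by = c("protein_id", "insert_uid")
  )

  # residues of the host strictly before the gap start, for relative position
  host_idx <- match(paste(ev$protein_id, ev$host_uid, sep = "\r"),
                    paste(domains$protein_id, domains$domain_uid, sep = "\r"))
  before <- vapply(seq_len(nrow(ev)), function(i) {
    s <- domains$seg_starts[[host_idx[i]]]
    e <- domains$seg_ends[[host_idx[i]]]
    gs <- ev$gap_start[i]
    sel <- s < gs
    if (!any(sel)) 0L else as.integer(sum(pmin(e[sel], gs - 1L) - s[sel] + 1L))
  }, integer(1))
  ev$relative_position <- before / ev$host_length
  ev$cross_h_group <- ev$host_h_group != ev$insert_h_group
  ev$depth <- compute_nesting_depths(ev)

  ev <- ev[order(ev$protein_id, ev$gap_start, ev$insert_uid), ]
  cols <- c("protein_id", "host_uid", "host_f_id", "insert_uid", "insert_f_id",
            "gap_index", "gap_start", "gap_end", "gap_length", "depth",
            "host_length", "insert_length", "relative_position",
            "cross_h_group", "host_h_group", "insert_h_group",
            "host_x_group", "insert_x_group", "host_t_group_only",
            "insert_t_group_only", "host_arch", "insert_arch")
  ev[, cols]
}

empty_event_table <- function() {
  tibble::tibble(
    protein_id = character(), host_uid = character(), host_f_id = character(),
    insert_uid = character(), insert_f_id = character(),
    gap_index = integer(), gap_start = integer(), gap_end = integer(),
    gap_length = integer(), depth = integer(),
    host_length = integer(), insert_length = integer(),
    relative_position = double(), cross_h_group = logical(),
    host_h_group = character(), insert_h_group = character(),
    host_x_group = character(), insert_x_group = character(),
    host_t_group_only = logical(), insert_t_group_only = logical(),
    host_arch = character(), insert_arch = character()
  )
}

#' Nesting depth of insertion events
#'
#' An event has depth 1 when its host is not itself an assigned insert, and
#' depth of the host's own event plus one otherwise. Because each insert has
#' exactly one host, the host relation is a forest; a cycle would indicate an
#' internal assignment inconsistency (impossible for valid interval
#' structures) and raises an error.
#'
#' @param events An event tibble (may span many proteins).
#' @return Integer vector of depths aligned with `events` rows.
#' @export
compute_nesting_depths <- function(events) {
  n <- nrow(events)
  if (n == 0L) return(integer(0))
  ins_key <- paste(events$protein_id, events$insert_uid, sep = "\r")
  host_key <- paste(events$protein_id, events$host_uid, sep = "\r")
  parent <- match(host_key, ins_key) # event index whose insert is my host
  depth <- rep(NA_integer_, n)
  depth[is.na(parent)] <- 1L
  current <- which(is.na(parent))
  level <- 1L
  while (length(current) > 0L) {
    child <- which(!is.na(parent) & parent %in% current & is.na(depth))
    level <- level + 1L
    if (level > n + 1L) {
      stop("cycle detected in insertion host relation (internal inconsistency)",
           call. = FALSE)
    }
    depth[child] <- level
    current <- child
  }
  if (anyNA(depth)) {
    stop("cycle detected in insertion host relation (internal inconsistency)",
         call. = FALSE)
  }
  depth
}

#' Relative position of an insertion site within its host
#'
#' The fraction of host residues lying strictly before the gap start, in
#' `[0, 1]`; 0.5 means the insertion splits the host into equal halves.
#' Thirds are bucketed as N-terminal `[0, 1/3)`, middle `[1/3, 2/3)`,
#' C-terminal `[2/3, 1]`.
#'
#' @param events An event tibble.
#' @return `events$relative_position` (computed during assignment).
#' @export
relative_position <- function(events) events$relative_position

#' Detect all insertion events and summarise a dataset
#'
#' Runs the gap enumeration, containment, exclusive smallest-gap assignment
#' and nesting-depth computation over every protein independently, and
#' summarises prevalence and complexity.
#'
#' @param domains A domain table covering one or many proteins.
#' @param min_gap Minimum gap length in residues (inclusive, default 30).
#' @return A list of class `"insertion_scan"` with elements `events` (event
#'   tibble) and `summary` (list: `n_proteins`, `n_multidomain`,
#'   `n_proteins_with_insertion`, `prevalence` over multidomain proteins,
#'   `n_events`, `n_unique_families` counting each family once regardless of
#'   role, `mean_domains_per_insertion_protein`, `depth_histogram` of
#'   per-protein maximum depth, and `prevalence_undefined` flag when no
#'   multidomain proteins exist).
#' @examples
#' d <- domain_table(
#'   protein_id = "3EPL",
#'   domain_uid = c("d1", "d2"),
#'   f_id = c("2004.1.1.71", "3949.1.1.1"),
#'   range_string = c("1-111,177-409", "112-176")
#' )
#' detect_insertions(d)
#' @export
detect_insertions <- function(domains, min_gap = 30) {
  events <- assign_events(domains, min_gap)
  n_dom <- table(domains$protein_id)
  n_proteins <- length(n_dom)
  multidomain <- names(n_dom)[n_dom >= 2L]
  prot_max_depth <- if (nrow(events) > 0L) {
    tapply(events$depth, events$protein_id, max)
  } else {
    integer(0)
  }
  with_insertion <- names(prot_max_depth)
  prevalence_undefined <- length(multidomain) == 0L
  if (prevalence_undefined && n_proteins > 0L) {
    warning("no multidomain proteins: prevalence reported as 0", call. = FALSE)
  }
  depth_hist <- if (length(prot_max_depth) > 0L) {
    tab <- table(factor(prot_max_depth, levels = seq_len(max(prot_max_depth))))
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  summary <- list(
    n_proteins = n_proteins,
    n_multidomain = length(multidomain),
    n_proteins_with_insertion = length(with_insertion),
    prevalence = if (prevalence_undefined) 0
                 else length(with_insertion) / length(multidomain),
    prevalence_undefined = prevalence_undefined,
    n_events = nrow(events),
    n_unique_families = length(unique(c(events$host_f_id, events$insert_f_id))),
    mean_domains_per_insertion_protein =
      if (length(with_insertion) > 0L)
        mean(n_dom[with_insertion]) else NA_real_,
    depth_histogram = depth_hist,
    min_gap = min_gap
  )
  structure(list(events = events, summary = summary), class = "insertion_scan")
}

#' @export
print.insertion_scan <- function(x, ...) {
  s <- x$summary
  cat("A1-B-A2 insertion scan\n")
  cat("  proteins:              ", s$n_proteins,
      " (", s$n_multidomain, " multidomain)\n", sep = "")
  cat("  with insertion:        ", s$n_proteins_with_insertion,
      sprintf("  (prevalence %.2f%% of multidomain)", 100 * s$prevalence),
      "\n", sep = "")
  cat("  events:                ", s$n_events,
      " across ", s$n_unique_families, " unique families\n", sep = "")
  if (length(s$depth_histogram) > 0L) {
    cat("  max nesting depth:     ",
        paste0(names(s$depth_histogram), ":", s$depth_histogram,
               collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}
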