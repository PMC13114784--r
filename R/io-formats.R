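#' Read an ECOD-style domain-assignment table
#'
#' Reads a TSV with one row per domain instance (discontinuity encoded in the
#' range string, never as duplicate rows) and builds a validated
#' [domain_table()]. Column names are mapped through `col_map`, so any TSV
#' dialect that carries a protein identifier, a per-protein domain identifier,
#' a hierarchical family ID and a residue-range string can be consumed.
#'
#' Invalid rows (malformed ranges or family IDs, duplicate domain IDs,
#' proteins with overlapping domains) are collected rather than silently
#' dropped: they are returned in the `"rejects"` attribute, and parse
#' statistics (rows read, proteins built, rows rejected) in `"parse_stats"`.
#' With `strict = TRUE` the first invalid row aborts the read.
#'
#' @param path Path to a TSV file with a header row.
#' @param col_map Named character vector mapping the canonical column names
#'   (`protein_id`, `domain_uid`, `f_id`, `range_string`, and optionally
#'   `architecture_label`, `source`) to the file's column names.
#' @param strict Abort on the first invalid row instead of collecting rejects.
#' @return A `"domain_tbl"` tibble; see [domain_table()].
#' @export
read_domain_table <- function(path,
                              col_map = c(protein_id = "protein_id",
                                          domain_uid = "domain_uid",
                                          f_id = "f_id",
                                          range_string = "range_string"),
                              strict = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("protein_id", "domain_uid", "f_id", "range_string")
  full_map <- c(col_map,
                stats::setNames(setdiff(c(mandatory, "architecture_label", "source"),
                                        names(col_map)),
                                setdiff(c(mandatory, "architecture_label", "source"),
                                        names(col_map))))
  missing_cols <- setdiff(full_map[mandatory], names(raw))
  if (length(missing_cols) > 0L) {
    stop("domain table '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get_col <- function(canon) {
    file_col <- full_map[[canon]]
    if (file_col %in% names(raw)) raw[[file_col]] else rep(NA_character_, nrow(raw))
  }
  rows <- tibble::tibble(
    protein_id = get_col("protein_id"),
    domain_uid = get_col("domain_uid"),
    f_id = get_col("f_id"),
    range_string = get_col("range_string"),
    architecture_label = get_col("architecture_label"),
    source = get_col("source")
  )
  out <- build_domain_table(rows, strict = strict)
  attr(out, "parse_stats") <- list(
    rows_read = nrow(rows),
    proteins_built = length(unique(out$protein_id)),
    rows_rejected = nrow(attr(out, "rejects"))
  )
  out
}

# Frozen event-table schema, stable column order for downstream consumers.
event_table_columns <- c(
  "protein_id", "host_uid", "host_f_id", "insert_uid", "insert_f_id",
  "gap_start", "gap_end", "depth", "host_length", "insert_length",
  "relative_position", "cross_h_group"
)

#' Write an insertion-event table
#'
#' Writes detected events as TSV with a frozen column order
#' (`protein_id, host_uid, host_f_id, insert_uid, insert_f_id, gap_start,
#' gap_end, depth, host_length, insert_length, relative_position,
#' cross_h_group`) so external analyses can rely on the schema.
#' Floating-point fields use 6 significant digits; output is bit-stable across
#' runs for identical input.
#'
#' @param events An event tibble from [detect_insertions()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_event_table()]
#' @export
write_event_table <- function(events, path) {
  out <- events[, event_table_columns]
  out$relative_position <- signif(out$relative_position, 6)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an insertion-event table written by [write_event_table()]
#'
#' @param path Path to the events TSV.
#' @return An event tibble; the reader/writer pair round-trips exactly.
#' @export
read_event_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = "c", host_uid = "c", host_f_id = "c",
      insert_uid = "c", insert_f_id = "c",
      gap_start = "i", gap_end = "i", depth = "i",
      host_length = "i", insert_length = "i",
      relative_position = "d", cross_h_group = "l"
    ),
    progress = FALSE
  )
}

#' Read a C-alpha trace from a PDB or mmCIF file
#'
#' Extracts one Cα position per residue for a single chain, for use in
#' N/C-termini distance analysis. Alternate locations are resolved to the
#' highest-occupancy conformer (first-seen on ties); residues are kept in
#' file order.
#'
#' @param path Coordinate file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param chain Chain identifier; `NULL` takes the first chain in the file.
#' @return A tibble of class `"ca_trace"` with columns `resno`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @export
read_ca_trace <- function(path, format = c("auto", "pdb", "cif"), chain = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  structure_obj <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  }
  atoms <- structure_obj$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) {
    chain <- ca$chain[[1L]]
  }
  ca <- ca[ca$chain == chain, , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop("no CA atoms for chain '", chain, "' in '", path, "'", call. = FALSE)
  }
  # altloc resolution: highest occupancy wins, ties to first occurrence
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  ord <- order(match(ca$resno, unique(ca$resno)), -occ,
               seq_len(nrow(ca)))
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out <- tibble::tibble(resno = as.integer(ca$resno),
                        x = ca$x, y = ca$y, z = ca$z)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }
  class(out) <- c("ca_trace", class(out))
  attr(out, "protein_id") <- sub("\\.(pdb|cif)$", "",
                                 basename(path), ignore.case = TRUE)
  attr(out, "chain") <- chain
  out
}

# Minimal fixed-width PDB writer for CA-only toy traces.
write_ca_pdb <- function(trace, path, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)), chain, trace$resno, trace$x, trace$y, trace$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
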