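#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than that of the observed
#' table (the standard two-sided convention, with a small relative tolerance
#' for ties). A table with an empty margin carries no information and yields
#' p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a b` / `c d`).
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH q-values with monotone enforcement; the mapping is
#' order-preserving with respect to the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values aligned with the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

# Haldane-Anscombe log2 odds ratio with 0.5 pseudocount in every cell.
log2_odds_ratio <- function(a, b, c, d, pseudocount = 0.5) {
  log2(((a + pseudocount) * (d + pseudocount)) /
         ((b + pseudocount) * (c + pseudocount)))
}

#' Architecture-level host/insert enrichment
#'
#' For each secondary-structure architecture label, builds the 2x2 table of
#' (host-role instances with the label, insert-role instances with the
#' label, host instances with other labels, insert instances with other
#' labels) over all events, and computes the pseudocounted log2 odds ratio —
#' positive for host-enriched architectures, negative for
#' insertion-enriched — plus Fisher's exact p and BH FDR across
#' architectures. Architectures are classified `host_enriched` when
#' `log2_or > 0.5`, `insertion_enriched` when `log2_or < -0.5`, and
#' `neutral` otherwise.
#'
#' @param events An event tibble whose domains carry architecture labels.
#' @param pseudocount Haldane-Anscombe pseudocount added to each cell for the
#'   odds ratio (default 0.5; the raw counts are used for the Fisher test).
#' @return A tibble with one row per architecture label; instances lacking a
#'   label are excluded and counted in attribute `"n_unlabelled"`.
#' @export
architecture_enrichment <- function(events, pseudocount = 0.5) {
  inst <- role_instances(events)
  unlabelled <- is.na(inst$arch) | !nzchar(inst$arch)
  inst <- inst[!unlabelled, ]
  n_host <- sum(inst$role == "host")
  n_insert <- sum(inst$role == "insert")
  out <- inst |>
    dplyr::group_by(architecture = .data$arch) |>
    dplyr::summarise(a = sum(.data$role == "host"),
                     b = sum(.data$role == "insert"), .groups = "drop") |>
    dplyr::mutate(
      c = n_host - .data$a,
      d = n_insert - .data$b,
      log2_or = log2_odds_ratio(.data$a, .data$b, .data$c, .data$d,
                                pseudocount),
      fisher_p = mapply(fisher_exact_two_sided, .data$a, .data$b, .data$c,
                        .data$d),
      fdr_q = bh_fdr(.data$fisher_p),
      classification = dplyr::case_when(
        .data$log2_or > 0.5 ~ "host_enriched",
        .data$log2_or < -0.5 ~ "insertion_enriched",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$log2_or))
  attr(out, "n_unlabelled") <- sum(unlabelled)
  out
}

#' X-group insert depletion/enrichment
#'
#' Compares, for every X-group with sufficient representation in the
#' background universe, the share of insert-role instances falling in that
#' X-group against its share of the background universe of classified
#' domain instances. Each X-group gets a 2x2 table (insert instances in
#' group, background instances in group, insert instances elsewhere,
#' background elsewhere), Fisher's exact p, BH FDR across X-groups, and a
#' pseudocounted log2 enrichment of the observed over the expected insert
#' share. X-groups with `fdr_q < fdr_threshold` are classified `depleted` or
#' `enriched` by the sign of the enrichment; others `neutral`.
#'
#' @param events An event tibble (insert-role instances are taken from it).
#' @param background A domain table providing the background universe of
#'   classified domain instances.
#' @param min_count Minimum background instances for an X-group to be tested
#'   (default 10).
#' @param pseudocount Added to the observed and expected share numerators
#'   (default 0.5).
#' @param fdr_threshold Significance cutoff on the BH q-value (default 0.05).
#' @return A tibble with one row per tested X-group.
#' @export
xgroup_insert_enrichment <- function(events, background, min_count = 10,
                                     pseudocount = 0.5, fdr_threshold = 0.05) {
  bg_counts <- table(background$x_group)
  ins_counts <- table(events$insert_x_group)
  n_bg <- sum(bg_counts)
  n_ins <- nrow(events)
  keep <- names(bg_counts)[bg_counts >= min_count]
  out <- tibble::tibble(
    x_group = keep,
    insert_in = as.integer(ifelse(is.na(ins_counts[keep]), 0L,
                                  ins_counts[keep])),
    background_in = as.integer(bg_counts[keep])
  )
  out$insert_out <- n_ins - out$insert_in
  out$background_out <- n_bg - out$background_in
  out$log2_enrichment <- log2(
    ((out$insert_in + pseudocount) / (n_ins + 2 * pseudocount)) /
      ((out$background_in + pseudocount) / (n_bg + 2 * pseudocount))
  )
  out$fisher_p <- mapply(fisher_exact_two_sided, out$insert_in,
                         out$background_in, out$insert_out, out$background_out)
  out$fdr_q <- bh_fdr(out$fisher_p)
  out$classification <- ifelse(
    out$fdr_q < fdr_threshold,
    ifelse(out$log2_enrichment < 0, "depleted", "enriched"),
    "neutral"
  )
  out[order(out$log2_enrichment), ]
}
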