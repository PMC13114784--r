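#' Run the full insertion-analysis pipeline
#'
#' Executes the stages in order — detection, family role classification,
#' partnership and host-diversity analysis, paired size statistics, position
#' distribution, architecture enrichment, top-family rankings — and collects
#' every headline statistic into a run report. Optionally writes the events,
#' profiles and enrichment tables plus a JSON report to `out_dir`. The run
#' is deterministic given its inputs and parameters.
#'
#' @param domains A domain table, or the path to a domain-assignment TSV
#'   (read with [read_domain_table()]).
#' @param min_gap Minimum insertion-gap length in residues (default 30).
#' @param min_events Minimum events for family role assessment (default 10).
#' @param generalist_cutoff Distinct host H-groups defining a generalist
#'   insert family (default 11).
#' @param top_n Families per role in the rankings (default 5).
#' @param out_dir Optional output directory for the tables and JSON report.
#' @param seed Recorded in the report for provenance (the pipeline itself is
#'   deterministic; the seed governs any upstream synthetic generation).
#' @return A list of class `"insertion_report"`: `events`, `profiles`,
#'   `h_group_categories`, `partnerships`, `host_diversity`, `enrichment`,
#'   and `report` (the nested summary statistics).
#' @export
run_pipeline <- function(domains, min_gap = 30, min_events = 10,
                         generalist_cutoff = 11, top_n = 5,
                         out_dir = NULL, seed = NULL) {
  if (is.character(domains)) {
    domains <- read_domain_table(domains)
  }
  scan <- detect_insertions(domains, min_gap = min_gap)
  events <- scan$events
  profiles <- aggregate_roles(events, min_events = min_events)
  h_cats <- classify_h_groups(profiles, min_events = min_events)
  partners <- partnership_counts(events)
  diversity <- host_diversity(events, min_events = min_events,
                              generalist_cutoff = generalist_cutoff)
  sizes <- paired_size_analysis(events)
  positions <- position_distribution(events)
  enrich <- architecture_enrichment(events)
  top_hosts <- rank_families(profiles, "host", top_n)
  top_inserts <- rank_families(profiles, "insert", top_n)

  role_counts <- table(factor(profiles$role,
                              levels = c("host_consistent",
                                         "insertion_consistent",
                                         "versatile", "insufficient")))
  report <- list(
    detection = scan$summary,
    role_counts = stats::setNames(as.integer(role_counts),
                                  names(role_counts)),
    cross_h_group_fraction = attr(partners, "cross_h_group_fraction"),
    paired_sizes = unclass(sizes),
    position_distribution = positions,
    top_host_consistent = top_hosts$f_id,
    top_insertion_consistent = top_inserts$f_id,
    parameters = list(min_gap = min_gap, min_events = min_events,
                      generalist_cutoff = generalist_cutoff, top_n = top_n),
    seed = seed,
    version = as.character(utils::packageVersion("insertarch"))
  )

  out <- structure(list(events = events, profiles = profiles,
                        h_group_categories = h_cats,
                        partnerships = partners,
                        host_diversity = diversity,
                        enrichment = enrich,
                        report = report),
                   class = "insertion_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_table(events, file.path(out_dir, "events.tsv"))
    readr::write_tsv(profiles, file.path(out_dir, "family_profiles.tsv"),
                     progress = FALSE)
    readr::write_tsv(enrich, file.path(out_dir, "architecture_enrichment.tsv"),
                     progress = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.insertion_report <- function(x, ...) {
  r <- x$report
  d <- r$detection
  cat("Insertion-architecture analysis report\n")
  cat(sprintf("  proteins %d (multidomain %d) | events %d | prevalence %.2f%%\n",
              d$n_proteins, d$n_multidomain, d$n_events, 100 * d$prevalence))
  cat(sprintf("  families: %d host-consistent, %d insertion-consistent, %d versatile (>=%d events)\n",
              r$role_counts[["host_consistent"]],
              r$role_counts[["insertion_consistent"]],
              r$role_counts[["versatile"]],
              r$parameters$min_events))
  if (!is.na(r$cross_h_group_fraction)) {
    cat(sprintf("  cross-H-group events: %.1f%%\n",
                100 * r$cross_h_group_fraction))
  }
  if (r$paired_sizes$n_pairs > 0) {
    cat(sprintf("  median lengths: insert %s vs host %s (insert smaller in %.1f%%)\n",
                format(r$paired_sizes$median_insert_length),
                format(r$paired_sizes$median_host_length),
                100 * r$paired_sizes$fraction_insert_smaller))
  }
  invisible(x)
}
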