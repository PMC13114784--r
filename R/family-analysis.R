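#' Aggregate insertion events into family role profiles
#'
#' Tallies, for every ECOD F-group family appearing in any event, how many
#' events it hosted and how many it was inserted in, and assigns a role:
#' \describe{
#'   \item{host_consistent}{only ever a host, with at least `min_events`
#'     total events}
#'   \item{insertion_consistent}{only ever an insert, with at least
#'     `min_events` total events}
#'   \item{versatile}{observed in both roles, total at least `min_events`}
#'   \item{insufficient}{fewer than `min_events` total events — excluded from
#'     role statistics}
#' }
#' Each event contributes one host tally and one insert tally, so summed
#' host events equal summed insert events equal the number of events.
#'
#' @param events An event tibble from [detect_insertions()].
#' @param min_events Minimum total events for reliable role assessment
#'   (default 10).
#' @param exclude_unassigned Drop T-group-only families (IDs ending `".0.0"`)
#'   from the profiles. They participate fully in detection but can be
#'   excluded from family rankings.
#' @return A tibble with one row per family: counts, role, H-group, and mean
#'   instance lengths per role.
#' @export
aggregate_roles <- function(events, min_events = 10, exclude_unassigned = FALSE) {
  inst <- role_instances(events)
  if (exclude_unassigned) inst <- inst[!inst$t_group_only, ]
  prof <- inst |>
    dplyr::group_by(.data$f_id, .data$h_group, .data$t_group_only) |>
    dplyr::summarise(
      host_events = sum(.data$role == "host"),
      insert_events = sum(.data$role == "insert"),
      mean_length_as_host = mean(.data$length[.data$role == "host"]),
      mean_length_as_insert = mean(.data$length[.data$role == "insert"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      total = .data$host_events + .data$insert_events,
      role = dplyr::case_when(
        .data$total < min_events ~ "insufficient",
        .data$insert_events == 0L ~ "host_consistent",
        .data$host_events == 0L ~ "insertion_consistent",
        TRUE ~ "versatile"
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$f_id)
  prof
}

# One row per family-role instance in the events (each event contributes a
# host instance and an insert instance).
role_instances <- function(events) {
  dplyr::bind_rows(
    tibble::tibble(f_id = events$host_f_id, h_group = events$host_h_group,
                   x_group = events$host_x_group,
                   t_group_only = events$host_t_group_only,
                   arch = events$host_arch,
                   length = events$host_length, role = "host"),
    tibble::tibble(f_id = events$insert_f_id, h_group = events$insert_h_group,
                   x_group = events$insert_x_group,
                   t_group_only = events$insert_t_group_only,
                   arch = events$insert_arch,
                   length = events$insert_length, role = "insert")
  )
}

#' Categorise H-groups by the role composition of their families
#'
#' An H-group qualifies when it contains at least `min_families` families
#' with at least `min_events` insertion events each. Qualifying H-groups are
#' labelled `exclusively_consistent` (all families host- or
#' insertion-consistent), `exclusively_versatile`, or `mixed`; all others are
#' `insufficient`.
#'
#' @param profiles Family role profiles from [aggregate_roles()].
#' @param min_families Minimum qualifying families per H-group (default 3).
#' @param min_events Minimum events per qualifying family (default 10).
#' @return A tibble with `h_group`, `n_qualifying_families`, and `category`.
#' @export
classify_h_groups <- function(profiles, min_families = 3, min_events = 10) {
  qual <- profiles[profiles$total >= min_events &
                     profiles$role != "insufficient", ]
  out <- qual |>
    dplyr::group_by(.data$h_group) |>
    dplyr::summarise(
      n_qualifying_families = dplyr::n(),
      n_consistent = sum(.data$role %in%
                           c("host_consistent", "insertion_consistent")),
      n_versatile = sum(.data$role == "versatile"),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = dplyr::case_when(
      .data$n_qualifying_families < min_families ~ "insufficient",
      .data$n_versatile == 0L ~ "exclusively_consistent",
      .data$n_consistent == 0L ~ "exclusively_versatile",
      TRUE ~ "mixed"
    ))
  out
}

#' Host-insert family partnership counts
#'
#' Groups events by the directional (host family, insert family) pair and
#' counts partnership instances; an event whose host and insert families
#' belong to different H-groups is a cross-H-group partnership. Partnerships
#' are never symmetrised: A hosting B is distinct from B hosting A.
#'
#' @param events An event tibble.
#' @return A tibble of partnership records sorted by descending count, with
#'   the overall cross-H-group event fraction in attribute
#'   `"cross_h_group_fraction"` (`NA` when there are no events).
#' @export
partnership_counts <- function(events) {
  out <- events |>
    dplyr::group_by(host_f_id = .data$host_f_id,
                    insert_f_id = .data$insert_f_id,
                    host_h_group = .data$host_h_group,
                    insert_h_group = .data$insert_h_group,
                    cross_h_group = .data$cross_h_group) |>
    dplyr::summarise(n_events = dplyr::n(),
                     n_proteins = dplyr::n_distinct(.data$protein_id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_events), .data$host_f_id,
                   .data$insert_f_id)
  attr(out, "cross_h_group_fraction") <-
    if (nrow(events) > 0L) mean(events$cross_h_group) else NA_real_
  out
}

#' Host-diversity spectrum of insertion families
#'
#' For every family with at least `min_events` insert-role events, counts the
#' distinct host H-groups it partners with. Families partnering with a single
#' host H-group are `specialist`; those appearing in `generalist_cutoff` or
#' more distinct host H-groups are `generalist`; the rest `intermediate`.
#'
#' @param events An event tibble.
#' @param min_events Minimum insert events per family (default 10).
#' @param generalist_cutoff Minimum distinct host H-groups for a generalist
#'   (default 11).
#' @return A tibble with one row per qualifying insertion family.
#' @export
host_diversity <- function(events, min_events = 10, generalist_cutoff = 11) {
  out <- events |>
    dplyr::group_by(insert_f_id = .data$insert_f_id) |>
    dplyr::summarise(n_events = dplyr::n(),
                     n_distinct_host_h_groups =
                       dplyr::n_distinct(.data$host_h_group),
                     .groups = "drop") |>
    dplyr::filter(.data$n_events >= min_events) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_distinct_host_h_groups == 1L ~ "specialist",
      .data$n_distinct_host_h_groups >= generalist_cutoff ~ "generalist",
      TRUE ~ "intermediate"
    )) |>
    dplyr::arrange(dplyr::desc(.data$n_distinct_host_h_groups),
                   .data$insert_f_id)
  out
}

#' Rank families by event count in a given role
#'
#' @param profiles Family role profiles from [aggregate_roles()].
#' @param role `"host"` or `"insert"`: which role's event count to rank by.
#'   Only families whose role category matches (`host_consistent` for
#'   `"host"`, `insertion_consistent` for `"insert"`) are ranked when
#'   `consistent_only = TRUE` (the default).
#' @param top_n Number of families to return (fewer if fewer qualify).
#' @param consistent_only Restrict to role-consistent families.
#' @return The top families, descending by the role's event count, ties
#'   broken by family ID.
#' @export
rank_families <- function(profiles, role = c("host", "insert"), top_n = 5,
                          consistent_only = TRUE) {
  role <- match.arg(role)
  count_col <- if (role == "host") "host_events" else "insert_events"
  cat_wanted <- if (role == "host") "host_consistent" else "insertion_consistent"
  pool <- if (consistent_only) profiles[profiles$role == cat_wanted, ] else
    profiles[profiles$role != "insufficient", ]
  pool <- pool[order(-pool[[count_col]], pool$f_id), ]
  utils::head(pool, top_n)
}
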