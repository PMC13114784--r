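test_that("role profiles follow the 10-event consistency rules", {
  events <- dplyr::bind_rows(
    make_events(rep("1001.1.1.1", 15), rep("2001.1.1.1", 15)), # host 15x
    make_events(rep("1002.1.1.1", 9), rep("2002.1.1.1", 9)),   # 9 events
    make_events(rep("1003.1.1.1", 7), rep("9999.1.1.1", 7)),
    make_events(rep("9999.1.1.1", 5), rep("1003.1.1.1", 5))    # both roles
  )
  prof <- aggregate_roles(events)
  role_of <- stats::setNames(prof$role, prof$f_id)
  expect_equal(role_of[["1001.1.1.1"]], "host_consistent")
  expect_equal(role_of[["1002.1.1.1"]], "insufficient") # 9 < 10
  expect_equal(role_of[["2001.1.1.1"]], "insertion_consistent")
  expect_equal(role_of[["1003.1.1.1"]], "versatile")    # 7 host + 5 insert
  expect_equal(role_of[["9999.1.1.1"]], "versatile")

  # double-entry conservation
  expect_equal(sum(prof$host_events), nrow(events))
  expect_equal(sum(prof$insert_events), nrow(events))
  # categories are exclusive and exhaustive
  expect_true(all(prof$role %in% c("host_consistent", "insertion_consistent",
                                   "versatile", "insufficient")))
})

test_that("T-group-only families can be excluded from profiles", {
  events <- make_events(rep("1001.1.0.0", 12), rep("2001.1.1.1", 12))
  prof_all <- aggregate_roles(events)
  expect_true("1001.1.0.0" %in% prof_all$f_id)
  prof_excl <- aggregate_roles(events, exclude_unassigned = TRUE)
  expect_false("1001.1.0.0" %in% prof_excl$f_id)
  expect_true("2001.1.1.1" %in% prof_excl$f_id)
})

test_that("H-groups are categorised by their qualifying families", {
  mk_prof <- function(f_id, h_group, role, total = 12L) {
    tibble::tibble(f_id = f_id, h_group = h_group, t_group_only = FALSE,
                   host_events = ifelse(role == "insertion_consistent", 0L,
                                        total),
                   insert_events = ifelse(role == "insertion_consistent",
                                          total, 0L),
                   mean_length_as_host = NA_real_,
                   mean_length_as_insert = NA_real_,
                   total = total, role = role)
  }
  prof <- dplyr::bind_rows(
    mk_prof(paste0("10.", 1:3), "10.1", "versatile"),
    mk_prof(paste0("20.", 1:2), "20.1", "host_consistent"),
    mk_prof("30.1", "30.1", "host_consistent"),
    mk_prof(paste0("30.", 2:3), "30.1", "versatile"),
    mk_prof(paste0("40.", 1:3), "40.1", "host_consistent")
  )
  cats <- classify_h_groups(prof)
  cat_of <- stats::setNames(cats$category, cats$h_group)
  expect_equal(cat_of[["10.1"]], "exclusively_versatile")
  expect_equal(cat_of[["20.1"]], "insufficient") # only 2 qualifying families
  expect_equal(cat_of[["30.1"]], "mixed")
  expect_equal(cat_of[["40.1"]], "exclusively_consistent")
})

test_that("partnership counts are directional with a cross-H-group fraction", {
  reps <- make_events(rep("2004.1.1.71", 3), rep("3949.1.1.1", 3))
  p <- partnership_counts(reps)
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_events, 3L)
  expect_true(p$cross_h_group) # 2004.1 != 3949.1
  expect_equal(attr(p, "cross_h_group_fraction"), 1)

  mixed <- make_events(c("1.1.1.1", "1.1.1.2", "5.1.1.1", "6.1.1.1"),
                       c("1.1.1.9", "1.1.1.9", "7.1.1.1", "7.1.1.1"))
  expect_equal(attr(partnership_counts(mixed), "cross_h_group_fraction"), 0.5)

  empty <- make_events(character(0), character(0))
  p0 <- partnership_counts(empty)
  expect_equal(nrow(p0), 0L)
  expect_true(is.na(attr(p0, "cross_h_group_fraction")))

  # direction matters: A hosting B is a different record from B hosting A
  ab <- dplyr::bind_rows(make_events("1.1.1.1", "2.1.1.1"),
                         make_events("2.1.1.1", "1.1.1.1"))
  expect_equal(nrow(partnership_counts(ab)), 2L)
})

test_that("host diversity separates specialists from generalists", {
  specialist <- make_events(paste0("236.1.1.", 1:12), rep("2003.1.1.5", 12))
  gen_hosts <- paste0(101:115, ".1.1.1")
  generalist <- make_events(gen_hosts, rep("277.1.1.1", 15))
  few <- make_events(paste0("300.1.1.", 1:9), rep("8888.1.1.1", 9))
  hd <- host_diversity(dplyr::bind_rows(specialist, generalist, few))
  class_of <- stats::setNames(hd$class, hd$insert_f_id)
  expect_equal(class_of[["2003.1.1.5"]], "specialist") # one host H-group
  expect_equal(class_of[["277.1.1.1"]], "generalist")  # 15 >= 11 H-groups
  expect_false("8888.1.1.1" %in% hd$insert_f_id)       # below 10 events
})

test_that("family ranking orders by role count with lexicographic ties", {
  events <- dplyr::bind_rows(
    make_events(rep("9.1.1.1", 13), rep("2003.1.1.5", 13)),
    make_events(rep("9.1.1.2", 11), rep("3949.1.1.1", 11)),
    make_events(rep("9.1.1.3", 11), rep("1.1.1.7", 11)),
    make_events(rep("9.1.1.4", 10), rep("298.1.1.9", 10))
  )
  prof <- aggregate_roles(events)
  top <- rank_families(prof, "insert", top_n = 3)
  expect_equal(top$f_id, c("2003.1.1.5", "1.1.1.7", "3949.1.1.1"))
  # fewer qualifying families than top_n: shorter list, no padding
  expect_equal(nrow(rank_families(prof, "insert", top_n = 10)), 4L)
  expect_equal(nrow(rank_families(prof, "host", top_n = 10)), 4L)
})

test_that("generated family roles are recovered without error", {
  g <- generate_architectures(synthetic_config(n_proteins = 2500), seed = 31)
  events <- assign_events(g$domains)
  prof <- aggregate_roles(events, min_events = 10)
  truth <- g$truth$family_roles
  m <- merge(prof, truth, by = "f_id")
  # host-only/insert-only families with >= 10 events: zero classification
  # errors (exact by construction)
  expect_true(all(m$role.x[m$role.y == "host_only" & m$total >= 10] ==
                    "host_consistent"))
  expect_true(all(m$role.x[m$role.y == "insert_only" & m$total >= 10] ==
                    "insertion_consistent"))
  # a generated host-only family can never look insertion-capable, and vice
  # versa; consistent profiles can only come from one-sided sampling of
  # versatile families, never from the opposite obligate role
  expect_false(any(m$role.y == "host_only" &
                     m$role.x %in% c("insertion_consistent", "versatile")))
  expect_false(any(m$role.y == "insert_only" &
                     m$role.x %in% c("host_consistent", "versatile")))
})
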