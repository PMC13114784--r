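test_that("gap enumeration respects the inclusive 30-residue threshold", {
  host <- fixture_mod5()[1, ]
  g <- enumerate_gaps(host)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$gap_start, g$gap_end, g$gap_length), c(112L, 176L, 65L))

  sub <- domain_table("p", "h", "1.1.1.1", "1-100,130-200")
  expect_equal(nrow(enumerate_gaps(sub[1, ], min_gap = 30)), 0L) # gap 29

  multi <- domain_table("p", "h", "1.1.1.1", "1-100,131-200,300-400")
  g2 <- enumerate_gaps(multi[1, ], min_gap = 30)
  expect_equal(g2$gap_start, c(101L, 201L))
  expect_equal(g2$gap_end, c(130L, 299L))
  expect_equal(g2$gap_length, c(30L, 99L)) # exactly 30 kept

  cont <- domain_table("p", "h", "1.1.1.1", "1-100")
  expect_equal(nrow(enumerate_gaps(cont[1, ])), 0L)
})

test_that("candidate containment lists every (domain, gap) pair", {
  cand <- candidate_containments(fixture_nested_abc())
  cand_key <- paste(cand$insert_uid, cand$host_uid)
  # C fits in both A's gap and B's gap; B fits in A's gap only
  expect_setequal(cand_key, c("C A", "C B", "B A"))

  side <- candidate_containments(fixture_side_by_side())
  expect_setequal(paste(side$insert_uid, side$host_uid), c("B A", "C A"))

  mod5 <- candidate_containments(fixture_mod5())
  expect_equal(nrow(mod5), 1L)
  expect_equal(c(mod5$gap_start, mod5$gap_end), c(112L, 176L))
})

test_that("smallest-gap exclusive assignment produces the nested events", {
  ev <- assign_events(fixture_nested_abc())
  expect_equal(nrow(ev), 2L)
  ev_key <- paste(ev$insert_uid, ev$host_uid)
  expect_setequal(ev_key, c("B A", "C B")) # C goes to B's smaller gap (70 < 230)
  expect_equal(sort(ev$depth), c(1L, 2L))

  side <- assign_events(fixture_side_by_side())
  expect_equal(nrow(side), 2L)
  expect_equal(unique(side$host_uid), "A")

  mod5 <- assign_events(fixture_mod5())
  expect_equal(mod5$host_f_id, "2004.1.1.71")
  expect_equal(mod5$insert_f_id, "3949.1.1.1")
  expect_true(mod5$cross_h_group)
})

test_that("nesting depth follows the host forest and reaches any k", {
  ev <- assign_events(fixture_nested_abc())
  depth_of <- stats::setNames(ev$depth, ev$insert_uid)
  expect_equal(depth_of[["B"]], 1L)
  expect_equal(depth_of[["C"]], 2L)

  for (k in c(1L, 2L, 4L, 6L, 8L)) {
    nest <- nested_architecture(k)
    scan <- detect_insertions(nest)
    expect_equal(nrow(scan$events), k)
    expect_equal(max(scan$events$depth), k)
    expect_equal(sort(unique(scan$events$depth)), seq_len(k))
  }
})

test_that("relative position measures host residues before the gap", {
  mod5 <- assign_events(fixture_mod5())
  expect_equal(mod5$relative_position, 111 / 344, tolerance = 1e-12)
  expect_lt(mod5$relative_position, 1 / 3) # N-terminal third

  sym <- assign_events(domain_table(
    "p", c("A", "B"), c("1.1.1.1", "2.1.1.1"),
    c("1-100,201-300", "111-190")))
  expect_equal(sym$relative_position, 0.5)

  tiny <- assign_events(domain_table(
    "p", c("A", "B"), c("1.1.1.1", "2.1.1.1"),
    c("1-1,102-200", "21-80")))
  expect_equal(tiny$relative_position, 1 / 100)
})

test_that("dataset-level detection summarises prevalence and families", {
  domains <- dplyr::bind_rows(fixture_mod5(), fixture_nested_abc(),
                              fixture_linear())
  scan <- detect_insertions(domains)
  s <- scan$summary
  expect_equal(s$n_events, 3L)
  expect_equal(s$n_proteins, 3L)
  expect_equal(s$n_multidomain, 3L)
  expect_equal(s$prevalence, 2 / 3)
  # families counted once regardless of role; B's family hosts and inserts
  expect_equal(s$n_unique_families,
               length(unique(c(scan$events$host_f_id, scan$events$insert_f_id))))
  expect_equal(sum(s$depth_histogram), s$n_proteins_with_insertion)

  singles <- domain_table(c("s1", "s2"), c("d", "d"),
                          c("1.1.1.1", "2.1.1.1"), c("1-100", "1-150"))
  expect_warning(scan0 <- detect_insertions(singles), "no multidomain")
  expect_equal(scan0$summary$prevalence, 0)
  expect_true(scan0$summary$prevalence_undefined)
})

test_that("adversarial boundary fixtures are assigned exactly as expected", {
  adv <- adversarial_architectures()
  ev <- assign_events(adv$domains)
  expect_setequal(event_key(ev), event_key(adv$expected_events))
  got <- ev[order(ev$protein_id, ev$insert_uid), ]
  want <- adv$expected_events[order(adv$expected_events$protein_id,
                                    adv$expected_events$insert_uid), ]
  expect_equal(got$depth, want$depth)
})

test_that("assignment equals the brute-force oracle on random architectures", {
  cfg <- synthetic_config(n_proteins = 300, p_nest = 0.4, max_depth = 6)
  g <- generate_architectures(cfg, seed = 101)
  ev <- assign_events(g$domains)
  expect_identical(event_key(ev), event_key(oracle_assign(g$domains)))
  # exclusive assignment: an insert appears in at most one event per protein
  expect_false(any(duplicated(paste(ev$protein_id, ev$insert_uid))))
  # containment: every insert span inside its assigned gap
  expect_true(all(ev$insert_length <= ev$gap_length))
})

test_that("raising min_gap never increases the event count", {
  g <- generate_architectures(synthetic_config(n_proteins = 200), seed = 5)
  domains <- dplyr::bind_rows(g$domains, adversarial_architectures()$domains)
  n_prev <- Inf
  for (mg in c(30, 40, 60, 100)) {
    n <- nrow(assign_events(domains, min_gap = mg))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("a discontinuous insert must sit entirely inside one gap", {
  adv <- adversarial_architectures()
  ev <- assign_events(adv$domains)
  # straddling discontinuous domain: no event
  expect_false("ADV_straddle" %in% ev$protein_id)
  # discontinuous insert within one gap: event present
  expect_true(any(ev$protein_id == "ADV_disc" & ev$insert_uid == "B"))
})
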