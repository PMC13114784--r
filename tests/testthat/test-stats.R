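test_that("signed-rank exact p matches full sign enumeration", {
  # canonical worked example: n = 6, all positive -> 2/64
  res <- wilcoxon_signed_rank(1:6)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 0.03125, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  set.seed(23)
  for (i in 1:20) {
    n <- sample(3:11, 1)
    d <- sample(c(-6:-1, 1:6), n, replace = TRUE) # ties in |d| likely
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank(d),
                 tolerance = 1e-10, label = paste(d, collapse = ","))
  }
})

test_that("signed-rank agrees with the reference test on tie-free data", {
  set.seed(4)
  for (i in 1:10) {
    d <- stats::rnorm(20)
    ref <- stats::wilcox.test(d, exact = TRUE)
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and approximate signed-rank p agree near the crossover", {
  set.seed(9)
  for (i in 1:10) {
    d <- stats::rnorm(25, mean = 0.3)
    p_exact <- wilcoxon_signed_rank(d, exact_limit = 25)$p_value
    p_approx <- wilcoxon_signed_rank(d, exact_limit = 0)$p_value
    expect_equal(p_approx, p_exact, tolerance = 0.10)
  }
})

test_that("degenerate signed-rank inputs are flagged undefined", {
  expect_true(wilcoxon_signed_rank(c(0, 0, 0))$undefined)
  expect_true(wilcoxon_signed_rank(numeric(0))$undefined)
})

test_that("paired size analysis summarises events", {
  ev <- make_events(rep("1.1.1.1", 3), rep("2.1.1.1", 3),
                    host_length = c(200L, 150L, 300L),
                    insert_length = c(100L, 160L, 120L))
  s <- paired_size_analysis(ev)
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$fraction_insert_smaller, 2 / 3)
  expect_equal(s$median_size_ratio, 0.5) # median of {0.5, 16/15, 0.4}

  one <- paired_size_analysis(make_events("1.1.1.1", "2.1.1.1",
                                          host_length = 199L,
                                          insert_length = 115L))
  expect_equal(one$median_host_length, 199)
  expect_equal(one$median_insert_length, 115)

  expect_equal(paired_size_analysis(make_events(character(0),
                                                character(0)))$n_pairs, 0L)
})

test_that("family size contrast computes category and within-family means", {
  ev <- dplyr::bind_rows(
    make_events(rep("7.1.1.1", 2), c("8.1.1.1", "8.1.1.2"),
                host_length = c(200L, 220L), insert_length = c(90L, 95L)),
    make_events("9.1.1.1", "7.1.1.1",
                host_length = 400L, insert_length = 120L)
  )
  prof <- aggregate_roles(ev, min_events = 1)
  fc <- family_size_contrast(prof, ev)
  # family 7.1.1.1: hosts {200, 220}, insert {120} -> difference 90
  expect_equal(fc$versatile_within_family_diff, 90)
  expect_equal(fc$n_families_in_both_roles, 1L)
  expect_true(all(c("host_consistent", "versatile") %in%
                    fc$category_means$category))
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_two_sided(0, 0, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(2, 8, 8, 2), oracle_fisher(2, 8, 8, 2),
               tolerance = 1e-12)
  set.seed(15)
  for (i in 1:60) {
    tab <- sample(0:15, 4, replace = TRUE) # margins <= 30
    expect_equal(
      fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
      oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12, label = paste(tab, collapse = ",")
    )
  }
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("BH q-values match hand computation and are permutation-stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  set.seed(8)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("architecture enrichment uses the pseudocounted log2 odds ratio", {
  balanced <- make_events(rep("1.1.1.1", 20), rep("2.1.1.1", 20),
                          host_arch = rep(c("a.12", "a.19"), 10),
                          insert_arch = rep(c("a.12", "a.19"), 10))
  enr <- architecture_enrichment(balanced)
  expect_equal(enr$log2_or, c(0, 0))
  expect_equal(unique(enr$classification), "neutral")

  skew <- make_events(rep("1.1.1.1", 9), rep("2.1.1.1", 9),
                      host_arch = c("a.19", rep("a.12", 8)),
                      insert_arch = c(rep("a.19", 8), "a.12"))
  e19 <- skew |> architecture_enrichment()
  row <- e19[e19$architecture == "a.19", ]
  expect_equal(row$log2_or, log2((1.5 * 1.5) / (8.5 * 8.5)),
               tolerance = 1e-12)
  expect_equal(row$classification, "insertion_enriched")
  # host-heavy architecture is positive
  expect_gt(e19$log2_or[e19$architecture == "a.12"], 0.5)

  # antisymmetric under swapping the host/insert columns
  swapped <- skew
  swapped$host_arch <- skew$insert_arch
  swapped$insert_arch <- skew$host_arch
  e_swap <- architecture_enrichment(swapped)
  m <- merge(as.data.frame(e19), as.data.frame(e_swap), by = "architecture")
  expect_equal(m$log2_or.x, -m$log2_or.y)
})

test_that("X-group enrichment recovers depletion and known fold-changes", {
  set.seed(77)
  bg <- domain_table(
    protein_id = sprintf("B%04d", 1:400),
    domain_uid = "d1",
    f_id = paste0(sample(c(10, 20, 30, 40), 400, replace = TRUE,
                         prob = c(0.25, 0.25, 0.25, 0.25)), ".1.1.1"),
    range_string = "1-100"
  )
  # group 10 at 8x its background propensity among inserts; group 40 absent
  ins_x <- sample(c(10, 20, 30), 200, replace = TRUE,
                  prob = c(8, 1, 1) / 10)
  ev <- make_events(rep("999.1.1.1", 200), paste0(ins_x, ".1.1.1"))
  res <- xgroup_insert_enrichment(ev, bg, min_count = 10)
  r10 <- res[res$x_group == "10", ]
  r40 <- res[res$x_group == "40", ]
  expect_equal(r10$log2_enrichment, log2(8 / (8 + 1 + 1) / 0.25),
               tolerance = 0.35)
  expect_equal(r10$classification, "enriched")
  expect_equal(r40$insert_in, 0L)
  expect_lt(r40$log2_enrichment, 0)
  expect_equal(r40$classification, "depleted")
  # group 20 is depleted to 0.1 of inserts vs 0.25 of background
  expect_lt(abs(res$log2_enrichment[res$x_group == "20"] -
                  log2(0.1 / 0.25)), 0.5)

  # a group matching its background share exactly sits at ~zero
  bg2 <- domain_table(sprintf("C%03d", 1:100), "d1",
                      paste0(rep(c(50, 60), each = 50), ".1.1.1"), "1-100")
  ev2 <- make_events(rep("999.1.1.1", 40),
                     paste0(rep(c(50, 60), each = 20), ".1.1.1"))
  res2 <- xgroup_insert_enrichment(ev2, bg2, min_count = 10)
  expect_equal(res2$log2_enrichment, c(0, 0), tolerance = 0.01)
  expect_equal(unique(res2$classification), "neutral")
})

test_that("insertion positions bucket into thirds with half-open bounds", {
  ev <- make_events(rep("1.1.1.1", 3), rep("2.1.1.1", 3),
                    relative_position = c(0.1, 0.5, 0.9))
  pd <- position_distribution(ev)
  expect_equal(unname(pd$fractions), rep(1 / 3, 3))
  expect_equal(pd$mean_position, 0.5)
  expect_equal(sum(pd$fractions), 1)

  edge <- position_distribution(
    make_events(rep("1.1.1.1", 3), rep("2.1.1.1", 3),
                relative_position = c(1 / 3, 2 / 3, 1)))
  expect_equal(unname(edge$counts),
               c(0L, 1L, 2L)) # 1/3 -> middle; 2/3 and 1 -> C-terminal
})

test_that("Spearman correlation handles monotone and tied inputs", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6, 8)
  expect_equal(spearman_rho(x, y)$rho,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(spearman_rho(rep(1, 5), 1:5)$undefined)
})
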