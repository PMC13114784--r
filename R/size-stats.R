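#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided signed-rank test on a vector of paired differences. Zero
#' differences are dropped (Wilcoxon's original treatment); absolute
#' differences are ranked with average ranks for ties. For up to
#' `exact_limit` non-zero differences the null distribution of the positive
#' rank sum is computed exactly by convolution over all sign assignments
#' (valid with tied ranks); beyond that a normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param differences Numeric vector of paired differences (e.g. host length
#'   minus insert length per event).
#' @param exact_limit Largest n for exact enumeration (default 25).
#' @return A list with `statistic` (positive rank sum V), `p_value`, `n`
#'   (non-zero pairs), `method`, and logical `undefined` (all differences
#'   zero, or no pairs).
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))  # two-sided p = 2/64
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 25) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "undefined", undefined = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact null: distribution of the positive rank sum over all 2^n sign
    # vectors, via polynomial convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L) # f[s+1] = P(2V == s) * 2^n (counts)
    f[1L] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
        f[seq_len(total + 1L - ri)]
      f <- g
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method, undefined = FALSE)
}

#' Paired host/insert size analysis
#'
#' For every insertion event the host length (A1 + A2 combined) and insert
#' length form one paired measurement. Summarises medians, the fraction of
#' events with a strictly smaller insert, the median insert/host size ratio,
#' and the paired Wilcoxon signed-rank test on host minus insert.
#'
#' @param events An event tibble.
#' @return A list of class `"paired_size_summary"`: `n_pairs`,
#'   `median_insert_length`, `median_host_length`, `fraction_insert_smaller`,
#'   `median_size_ratio`, `statistic`, `p_value`.
#' @export
paired_size_analysis <- function(events) {
  n <- nrow(events)
  if (n == 0L) {
    out <- list(n_pairs = 0L, median_insert_length = NA_real_,
                median_host_length = NA_real_,
                fraction_insert_smaller = NA_real_,
                median_size_ratio = NA_real_,
                statistic = NA_real_, p_value = NA_real_)
    class(out) <- "paired_size_summary"
    return(out)
  }
  test <- wilcoxon_signed_rank(events$host_length - events$insert_length)
  out <- list(
    n_pairs = n,
    median_insert_length = stats::median(events$insert_length),
    median_host_length = stats::median(events$host_length),
    fraction_insert_smaller = mean(events$insert_length < events$host_length),
    median_size_ratio = stats::median(events$insert_length / events$host_length),
    statistic = test$statistic,
    p_value = test$p_value
  )
  class(out) <- "paired_size_summary"
  out
}

#' @export
print.paired_size_summary <- function(x, ...) {
  cat("Paired host/insert size analysis (", x$n_pairs, " events)\n", sep = "")
  if (x$n_pairs > 0L) {
    cat(sprintf("  median length: insert %s vs host %s residues\n",
                format(x$median_insert_length), format(x$median_host_length)))
    cat(sprintf("  insert smaller in %.1f%% of events; median size ratio %.3f\n",
                100 * x$fraction_insert_smaller, x$median_size_ratio))
    cat(sprintf("  Wilcoxon signed-rank V = %g, p = %.3g\n",
                x$statistic, x$p_value))
  }
  invisible(x)
}

#' Family-category size contrasts
#'
#' Mean domain-instance length per role category (over all instances in
#' events belonging to families of that category), and — for families
#' observed in both roles — the within-family mean host-length minus
#' insert-length difference, averaged over families. The within-family
#' contrast uses every family seen in both roles, regardless of the
#' role-profile event threshold.
#'
#' @param profiles Family role profiles from [aggregate_roles()].
#' @param events An event tibble.
#' @return A list with `category_means` (tibble: role category, n_families,
#'   mean_length) and `versatile_within_family_diff` (scalar, `NA` when no
#'   family is seen in both roles).
#' @export
family_size_contrast <- function(profiles, events) {
  inst <- role_instances(events)
  inst$category <- profiles$role[match(inst$f_id, profiles$f_id)]
  cat_means <- inst |>
    dplyr::filter(.data$category %in%
                    c("host_consistent", "insertion_consistent", "versatile")) |>
    dplyr::group_by(category = .data$category) |>
    dplyr::summarise(n_families = dplyr::n_distinct(.data$f_id),
                     n_instances = dplyr::n(),
                     mean_length = mean(.data$length), .groups = "drop")
  both <- inst |>
    dplyr::group_by(.data$f_id) |>
    dplyr::summarise(
      has_both = any(.data$role == "host") && any(.data$role == "insert"),
      diff = mean(.data$length[.data$role == "host"]) -
        mean(.data$length[.data$role == "insert"]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$has_both)
  list(
    category_means = cat_means,
    versatile_within_family_diff =
      if (nrow(both) > 0L) mean(both$diff) else NA_real_,
    n_families_in_both_roles = nrow(both)
  )
}

#' Distribution of insertion positions within hosts
#'
#' Buckets the relative insertion positions into N-terminal `[0, 1/3)`,
#' middle `[1/3, 2/3)` and C-terminal `[2/3, 1]` thirds and reports the
#' fractions plus the arithmetic mean position.
#'
#' @param events An event tibble.
#' @return A list with `fractions` (named length-3 vector summing to 1 when
#'   events exist), `counts`, `mean_position`, `n`.
#' @export
position_distribution <- function(events) {
  p <- events$relative_position
  bucket <- cut(p, breaks = c(0, 1 / 3, 2 / 3, 1),
                labels = c("N-terminal", "middle", "C-terminal"),
                right = FALSE, include.lowest = FALSE)
  bucket[p >= 2 / 3] <- "C-terminal" # include position == 1 in the top bucket
  counts <- table(factor(bucket, levels = c("N-terminal", "middle", "C-terminal")))
  list(
    fractions = if (length(p) > 0L) as.numeric(counts) / length(p)
                else rep(NA_real_, 3L) |>
                  stats::setNames(c("N-terminal", "middle", "C-terminal")),
    counts = stats::setNames(as.integer(counts), names(counts)),
    mean_position = if (length(p) > 0L) mean(p) else NA_real_,
    n = length(p)
  ) -> out
  names(out$fractions) <- names(out$counts)
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value by the t
#' approximation. A constant input vector makes the correlation undefined.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return A list with `rho`, `p_value`, `n`, and logical `undefined`.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("spearman_rho requires n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       undefined = FALSE)
}
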