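# Independent brute-force oracles. These deliberately reimplement the
# contracts with plain nested loops and enumeration, sharing no code with
# the package internals they check.

# Exhaustive containment + minimal-gap assignment over one domain table.
oracle_assign <- function(domains, min_gap = 30) {
  res <- list()
  for (pid in unique(domains$protein_id)) {
    d <- domains[domains$protein_id == pid, ]
    gaps <- list()
    for (i in seq_len(nrow(d))) {
      s <- d$seg_starts[[i]]
      e <- d$seg_ends[[i]]
      if (length(s) < 2) next
      for (j in seq_len(length(s) - 1)) {
        gs <- e[j] + 1
        ge <- s[j + 1] - 1
        if (ge - gs + 1 >= min_gap) {
          gaps[[length(gaps) + 1]] <- list(host = d$domain_uid[i],
                                           gs = gs, ge = ge,
                                           len = ge - gs + 1)
        }
      }
    }
    for (i in seq_len(nrow(d))) {
      best <- NULL
      for (g in gaps) {
        if (g$host == d$domain_uid[i]) next
        s <- d$seg_starts[[i]]
        e <- d$seg_ends[[i]]
        if (all(s >= g$gs) && all(e <= g$ge)) {
          better <- is.null(best) || g$len < best$len ||
            (g$len == best$len && g$gs < best$gs) ||
            (g$len == best$len && g$gs == best$gs && g$host < best$host)
          if (better) best <- g
        }
      }
      if (!is.null(best)) {
        res[[length(res) + 1]] <- data.frame(
          protein_id = pid, host_uid = best$host,
          insert_uid = d$domain_uid[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(protein_id = character(), host_uid = character(),
                      insert_uid = character()))
  }
  do.call(rbind, res)
}

event_key <- function(e) {
  sort(paste(e$protein_id, e$host_uid, e$insert_uid, sep = "|"))
}

# Exact two-sided Fisher p by hypergeometric enumeration.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by full enumeration of sign assignments
# (feasible for n <= 14; handles tied absolute values via average ranks).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Mann-Whitney U for x vs y by direct pair counting.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}
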