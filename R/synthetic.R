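#' Configuration for the synthetic architecture generator
#'
#' The generator emulates the statistical structure the insertion analysis
#' assumes: a family universe with role propensities (host-only,
#' insert-only, versatile, never participating), log-normal domain sizes
#' with insert-role instances systematically smaller than host-role
#' instances, an insertion grammar producing linear, single-insertion,
#' side-by-side multi-insertion and recursively nested architectures with
#' every gap at least `min_gap` residues by construction, and toy Cα traces
#' whose N/C-termini distances differ by role.
#'
#' Default distribution targets follow the observed field-scale values:
#' host-role mean length about 240 residues, insert-role about 133,
#' insertion in about 20% of multidomain proteins, insert termini median
#' about 14.3 Angstrom versus about 29.8 for background domains.
#'
#' @param n_proteins Number of proteins to generate.
#' @param n_families Size of the family universe.
#' @param role_propensity Probabilities over roles
#'   `host_only`, `insert_only`, `versatile`, `never_insert`; must sum to 1.
#' @param p_multidomain Probability a protein is multidomain.
#' @param p_insertion Probability a multidomain protein carries an
#'   insertion.
#' @param p_nest Probability an insert itself hosts a further insert
#'   (geometric recursion, capped at `max_depth`).
#' @param p_multi_insert Probability the top-level gap holds two
#'   side-by-side inserts.
#' @param max_depth Maximum nesting depth.
#' @param lambda_chain Poisson rate for extra chain domains beyond two.
#' @param host_length_mean,host_length_sd Log-normal target moments for
#'   host-role instance lengths (residues).
#' @param insert_length_mean,insert_length_sd Same for insert-role lengths.
#' @param insert_length_max Hard cap on insert lengths; a configuration
#'   whose cap cannot reach `min_gap - 2 * linker` is infeasible.
#' @param linker Residues of unassigned linker flanking each insert inside
#'   its gap.
#' @param min_gap Minimum gap length the grammar guarantees (residues).
#' @param insert_termini_median,insert_termini_sdlog Log-normal parameters
#'   of insert-role termini distances (Angstrom).
#' @param background_termini_median,background_termini_sdlog Same for host
#'   and background domains.
#' @param ca_spacing Successive Cα spacing in the toy traces (Angstrom).
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_proteins = 1000,
                             n_families = 60,
                             role_propensity = c(host_only = 0.20,
                                                 insert_only = 0.20,
                                                 versatile = 0.30,
                                                 never_insert = 0.30),
                             p_multidomain = 0.48,
                             p_insertion = 0.20,
                             p_nest = 0.12,
                             p_multi_insert = 0.05,
                             max_depth = 6,
                             lambda_chain = 1.5,
                             host_length_mean = 240,
                             host_length_sd = 90,
                             insert_length_mean = 133,
                             insert_length_sd = 45,
                             insert_length_max = Inf,
                             linker = 5,
                             min_gap = 30,
                             insert_termini_median = 14.3,
                             insert_termini_sdlog = 0.25,
                             background_termini_median = 29.8,
                             background_termini_sdlog = 0.35,
                             ca_spacing = 3.8) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_multidomain, cfg$p_insertion, cfg$p_nest,
             cfg$p_multi_insert, cfg$role_propensity)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$role_propensity) - 1) > 1e-8) {
    stop("role_propensity must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$role_propensity),
                c("host_only", "insert_only", "versatile", "never_insert"))) {
    stop("role_propensity must name host_only, insert_only, versatile, ",
         "never_insert", call. = FALSE)
  }
  if (cfg$max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  pos <- c(cfg$host_length_mean, cfg$host_length_sd, cfg$insert_length_mean,
           cfg$insert_length_sd, cfg$min_gap, cfg$ca_spacing,
           cfg$insert_termini_median, cfg$background_termini_median)
  if (any(pos <= 0)) stop("distribution parameters must be positive",
                          call. = FALSE)
  if (cfg$insert_length_max + 2 * cfg$linker < cfg$min_gap) {
    stop("infeasible configuration: maximum insert length plus linkers (",
         cfg$insert_length_max + 2 * cfg$linker,
         ") cannot reach min_gap (", cfg$min_gap, ")", call. = FALSE)
  }
  cfg$insert_length_min <- max(cfg$min_gap - 2 * cfg$linker, 20)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Sample a synthetic family universe
#'
#' Draws `n_families` families with ECOD-shaped hierarchical IDs spread over
#' synthetic X-, H- and T-groups (so the hierarchy parsing is exercised),
#' each with an architectural role drawn from the configured propensities, a
#' secondary-structure architecture label (biased so that insert-capable
#' families lean toward compact architectures and host-capable families
#' toward layered ones), and roughly one in ten families carrying a
#' T-group-only ID (terminating `".0.0"`).
#'
#' @param config A [synthetic_config()].
#' @return A tibble with `f_id`, `x_group`, `h_group`, `role`, `arch_label`.
#' @export
sample_family_universe <- function(config) {
  n <- config$n_families
  n_x <- max(4L, ceiling(n / 10))
  x_ids <- 1000L + sort(sample.int(9000L, n_x))
  x_of_fam <- sample(x_ids, n, replace = TRUE)
  # up to two H-groups per X-group so some H-groups collect several families
  h_of_fam <- sample(1:2, n, replace = TRUE)
  role <- sample(names(config$role_propensity), n, replace = TRUE,
                 prob = config$role_propensity)
  arch_pool <- c("a.2", "a.6", "a.7", "a.9", "a.12", "a.17", "a.19")
  arch_w <- list(
    insert_only = c(3, 3, 1, 1, 1, 2, 4),
    host_only = c(1, 1, 3, 3, 4, 2, 1),
    versatile = c(1, 1, 1, 1, 1, 4, 1),
    never_insert = rep(1, 7)
  )
  arch_label <- vapply(role, function(r)
    sample(arch_pool, 1L, prob = arch_w[[r]]), character(1))
  t_only <- stats::runif(n) < 0.10
  key <- paste(x_of_fam, h_of_fam, sep = ".")
  f_index <- stats::ave(seq_len(n), key, FUN = seq_along)
  f_id <- ifelse(t_only,
                 paste(x_of_fam, h_of_fam, "0", "0", sep = "."),
                 paste(x_of_fam, h_of_fam, "1", f_index, sep = "."))
  # T-group-only IDs are unique per H-group; drop duplicates back to F-level
  dup <- duplicated(f_id)
  f_id[dup] <- paste(x_of_fam[dup], h_of_fam[dup], "1",
                     f_index[dup] + 100000L, sep = ".")
  tibble::tibble(
    f_id = f_id,
    x_group = as.character(x_of_fam),
    h_group = paste(x_of_fam, h_of_fam, sep = "."),
    role = role,
    arch_label = arch_label
  )
}

# Truncated log-normal draws targeting the configured mean/sd.
rlnorm_target <- function(n, mean, sd, lo = 1, hi = Inf) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Generate synthetic protein architectures with ground truth
#'
#' Builds proteins by the insertion grammar: linear multidomain chains in
#' which, with probability `p_insertion`, one host-capable domain is
#' interrupted by an insert; inserts recurse with probability `p_nest`
#' (hosts of nested inserts are drawn from versatile families, terminal
#' inserts from insert-capable families), and the top-level gap holds two
#' side-by-side inserts with probability `p_multi_insert`. Every gap is at
#' least `min_gap` residues by construction, so any disagreement between
#' the detector and the ground truth indicates a detector defect.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return A list with `domains` (a [domain_table()]) and `truth`, a list of
#'   class `"synthetic_truth"`: `events` (protein_id, host_uid, insert_uid,
#'   depth), `family_roles`, `prevalence` among multidomain proteins,
#'   `depth_histogram` of per-protein maximum depth, `n_multidomain`,
#'   `config`, `seed`.
#' @export
generate_architectures <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- sample_family_universe(config)
  host_capable <- which(fams$role %in% c("host_only", "versatile"))
  insert_capable <- which(fams$role %in% c("insert_only", "versatile"))
  versatile <- which(fams$role == "versatile")
  if (length(host_capable) == 0L || length(insert_capable) == 0L) {
    stop("family universe has no host-capable or no insert-capable families",
         call. = FALSE)
  }

  acc_protein <- list(); acc_uid <- list(); acc_fid <- list()
  acc_range <- list(); acc_arch <- list()
  ev_protein <- list(); ev_host <- list(); ev_insert <- list()
  ev_depth <- list()
  n_multidomain <- 0L
  n_with_insertion <- 0L
  max_depths <- integer(0)

  draw_len <- function(role) {
    if (role == "insert") {
      rlnorm_target(1L, config$insert_length_mean, config$insert_length_sd,
                    lo = config$insert_length_min, hi = config$insert_length_max)
    } else {
      rlnorm_target(1L, config$host_length_mean, config$host_length_sd, lo = 60)
    }
  }

  for (p in seq_len(config$n_proteins)) {
    pid <- sprintf("SYN%05d", p)
    uid_counter <- 0L
    new_uid <- function() {
      uid_counter <<- uid_counter + 1L
      sprintf("d%d", uid_counter)
    }
    rows_uid <- character(0); rows_fid <- character(0)
    rows_range <- character(0); rows_arch <- character(0)
    p_ev_host <- character(0); p_ev_insert <- character(0)
    p_ev_depth <- integer(0)

    multi <- stats::runif(1) < config$p_multidomain
    n_chain <- if (multi) 2L + stats::rpois(1L, config$lambda_chain) else 1L
    if (multi) n_multidomain <- n_multidomain + 1L

    with_insertion <- multi && stats::runif(1) < config$p_insertion
    host_slot <- if (with_insertion) sample.int(n_chain, 1L) else 0L

    chain_fams <- sample.int(nrow(fams), n_chain, replace = TRUE)
    if (with_insertion && !(chain_fams[host_slot] %in% host_capable)) {
      chain_fams[host_slot] <- host_capable[sample.int(length(host_capable), 1L)]
    }

    # recursive emitter: lays down one domain (possibly hosting children)
    # starting at `pos`; returns the next free residue position
    emit <- function(fam_idx, role, depth, pos) {
      uid <- new_uid()
      len <- draw_len(role)
      children_fams <- integer(0)
      if (depth < config$max_depth &&
          ((depth == 0L && role == "chain_host") ||
           (depth >= 1L && stats::runif(1) < config$p_nest &&
              fams$role[fam_idx] == "versatile"))) {
        # depth 0 chain_host always gets its planned insert; nested hosts
        # recurse stochastically and must be versatile
        n_children <- 1L
        if (depth == 0L && stats::runif(1) < config$p_multi_insert) {
          n_children <- 2L
        }
        children_fams <- insert_capable[sample.int(length(insert_capable),
                                                   n_children, replace = TRUE)]
      }
      if (length(children_fams) == 0L) {
        seg <- c(pos, pos + len - 1L)
        rows_uid <<- c(rows_uid, uid)
        rows_fid <<- c(rows_fid, fams$f_id[fam_idx])
        rows_range <<- c(rows_range, paste0(seg[1], "-", seg[2]))
        rows_arch <<- c(rows_arch, fams$arch_label[fam_idx])
        return(list(uid = uid, end = seg[2]))
      }
      a1 <- max(1L, min(len - 1L,
                        round(len * stats::runif(1, 0.15, 0.85))))
      seg1 <- c(pos, pos + a1 - 1L)
      cur <- seg1[2] + 1L + config$linker
      for (cf in children_fams) {
        child <- emit(cf, "insert", depth + 1L, cur)
        p_ev_host <<- c(p_ev_host, uid)
        p_ev_insert <<- c(p_ev_insert, child$uid)
        p_ev_depth <<- c(p_ev_depth, depth + 1L)
        cur <- child$end + 1L + config$linker
      }
      seg2 <- c(cur, cur + (len - a1) - 1L)
      rows_uid <<- c(rows_uid, uid)
      rows_fid <<- c(rows_fid, fams$f_id[fam_idx])
      rows_range <<- c(rows_range,
                       paste0(seg1[1], "-", seg1[2], ",", seg2[1], "-", seg2[2]))
      rows_arch <<- c(rows_arch, fams$arch_label[fam_idx])
      list(uid = uid, end = seg2[2])
    }

    pos <- 1L
    for (ci in seq_len(n_chain)) {
      role <- if (with_insertion && ci == host_slot) "chain_host" else "chain"
      res <- emit(chain_fams[ci], role, 0L, pos)
      pos <- res$end + 1L + config$linker
    }

    if (length(p_ev_host) > 0L) {
      n_with_insertion <- n_with_insertion + 1L
      max_depths <- c(max_depths, max(p_ev_depth))
    }
    acc_protein[[p]] <- rep(pid, length(rows_uid))
    acc_uid[[p]] <- rows_uid
    acc_fid[[p]] <- rows_fid
    acc_range[[p]] <- rows_range
    acc_arch[[p]] <- rows_arch
    ev_protein[[p]] <- rep(pid, length(p_ev_host))
    ev_host[[p]] <- p_ev_host
    ev_insert[[p]] <- p_ev_insert
    ev_depth[[p]] <- p_ev_depth
  }

  rows <- tibble::tibble(
    protein_id = unlist(acc_protein, use.names = FALSE),
    domain_uid = unlist(acc_uid, use.names = FALSE),
    f_id = unlist(acc_fid, use.names = FALSE),
    range_string = unlist(acc_range, use.names = FALSE),
    architecture_label = unlist(acc_arch, use.names = FALSE),
    source = "synthetic"
  )
  domains <- build_domain_table(rows, strict = TRUE)

  truth_events <- tibble::tibble(
    protein_id = unlist(ev_protein, use.names = FALSE),
    host_uid = unlist(ev_host, use.names = FALSE),
    insert_uid = unlist(ev_insert, use.names = FALSE),
    depth = unlist(ev_depth, use.names = FALSE)
  )
  depth_hist <- if (length(max_depths) > 0L) {
    tab <- table(factor(max_depths, levels = seq_len(max(max_depths))))
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  truth <- structure(list(
    events = truth_events,
    family_roles = fams,
    prevalence = if (n_multidomain > 0L) n_with_insertion / n_multidomain
                 else NA_real_,
    depth_histogram = depth_hist,
    n_multidomain = n_multidomain,
    n_proteins_with_insertion = n_with_insertion,
    config = config,
    seed = seed
  ), class = "synthetic_truth")
  list(domains = domains, truth = truth)
}

#' Generate toy C-alpha traces for synthetic domains
#'
#' Builds one Cα path per domain with successive-residue spacing
#' `ca_spacing` and a first-to-last residue distance drawn from the
#' role-appropriate log-normal distribution (insert-role domains close,
#' host and background domains wide); paths of the domains of one protein
#' are laid out at separated offsets and merged into one per-protein trace.
#' Targets exceeding the geometric maximum for a short path are clamped;
#' the realised distance is always recorded.
#'
#' @param domains A domain table from [generate_architectures()].
#' @param truth The matching `synthetic_truth` (defines which domains are
#'   insert-role).
#' @param config The [synthetic_config()] used for generation.
#' @param dir Optional directory: when given, one minimal PDB per protein is
#'   written as `<protein_id>.pdb`.
#' @param seed Optional integer seed.
#' @return A list with `traces` (named list of `"ca_trace"` tibbles keyed by
#'   protein ID) and `realized` (tibble: protein_id, domain_uid, role,
#'   target_distance, realized_distance).
#' @export
generate_toy_traces <- function(domains, truth, config, dir = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  insert_keys <- paste(truth$events$protein_id, truth$events$insert_uid,
                       sep = "\r")
  is_insert <- paste(domains$protein_id, domains$domain_uid, sep = "\r") %in%
    insert_keys
  med <- ifelse(is_insert, config$insert_termini_median,
                config$background_termini_median)
  sdl <- ifelse(is_insert, config$insert_termini_sdlog,
                config$background_termini_sdlog)
  target <- stats::rlnorm(nrow(domains), log(med), sdl)

  traces <- list()
  realized <- numeric(nrow(domains))
  split_idx <- split(seq_len(nrow(domains)), domains$protein_id)
  for (pid in names(split_idx)) {
    idx <- split_idx[[pid]]
    resno_all <- integer(0)
    xyz_all <- NULL
    for (k in seq_along(idx)) {
      i <- idx[k]
      res <- unlist(mapply(seq.int, domains$seg_starts[[i]],
                           domains$seg_ends[[i]], SIMPLIFY = FALSE),
                    use.names = FALSE)
      path <- ca_path(length(res), target[i], config$ca_spacing)
      path[, 3] <- path[, 3] + 20 * k # separate domains within the protein
      realized[i] <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
      resno_all <- c(resno_all, res)
      xyz_all <- rbind(xyz_all, path)
    }
    ord <- order(resno_all)
    tr <- tibble::tibble(resno = resno_all[ord],
                         x = xyz_all[ord, 1], y = xyz_all[ord, 2],
                         z = xyz_all[ord, 3])
    class(tr) <- c("ca_trace", class(tr))
    attr(tr, "protein_id") <- pid
    traces[[pid]] <- tr
    if (!is.null(dir)) {
      write_ca_pdb(tr, file.path(dir, paste0(pid, ".pdb")))
    }
  }
  list(
    traces = traces,
    realized = tibble::tibble(
      protein_id = domains$protein_id,
      domain_uid = domains$domain_uid,
      role = ifelse(is_insert, "insert", "other"),
      target_distance = target,
      realized_distance = realized
    )
  )
}

# A planar zig-zag of n points with unit step `spacing` whose endpoints are
# distance d apart (exact when n is odd; for even n the endpoint carries one
# transverse offset of at most `spacing`).
ca_path <- function(n, d, spacing) {
  if (n == 1L) return(matrix(0, 1L, 3L))
  dx <- min(d / (n - 1L), spacing * 0.999)
  h <- sqrt(spacing^2 - dx^2)
  x <- (seq_len(n) - 1L) * dx
  y <- h * ((seq_len(n) - 1L) %% 2L)
  cbind(x, y, 0)
}

#' Adversarial hand-constructed architectures with known events
#'
#' A fixed set of boundary-pushing proteins exercising the detector's edge
#' rules: gaps of exactly 29, 30 and 31 residues; an exact tie between two
#' containing gaps of equal length (broken by smaller gap start);
#' side-by-side inserts sharing one gap; a nested A1-B1-C-B2-A2; a
#' discontinuous insert fully inside one gap; and a discontinuous domain
#' straddling two gaps (which must yield no event).
#'
#' @param min_gap The gap threshold the expectations assume (default 30).
#' @return A list with `domains` (a [domain_table()]) and `expected_events`
#'   (tibble: protein_id, host_uid, insert_uid, depth).
#' @export
adversarial_architectures <- function(min_gap = 30) {
  rows <- list(
    # gap of 29: no event
    list("ADV_gap29", "host", "1001.1.1.1", "1-100,130-229"),
    list("ADV_gap29", "ins", "2001.1.1.1", "101-129"),
    # gap of exactly 30: event (threshold inclusive)
    list("ADV_gap30", "host", "1001.1.1.1", "1-100,131-230"),
    list("ADV_gap30", "ins", "2001.1.1.1", "101-130"),
    # gap of 31: event
    list("ADV_gap31", "host", "1001.1.1.1", "1-100,132-231"),
    list("ADV_gap31", "ins", "2001.1.1.1", "101-131"),
    # two containing gaps of equal length (120): smaller gap start wins
    list("ADV_tie", "A", "1001.1.1.1", "1-30,151-170"),
    list("ADV_tie", "B", "1002.1.1.1", "41-50,171-190"),
    list("ADV_tie", "C", "2001.1.1.1", "60-140"),
    # two inserts side by side in one gap
    list("ADV_side", "A", "1001.1.1.1", "1-100,301-400"),
    list("ADV_side", "B", "2001.1.1.1", "106-180"),
    list("ADV_side", "C", "2002.1.1.1", "191-280"),
    # nested A1-B1-C-B2-A2
    list("ADV_nest", "A", "1001.1.1.1", "1-100,331-430"),
    list("ADV_nest", "B", "1003.1.1.1", "101-180,251-330"),
    list("ADV_nest", "C", "2001.1.1.1", "181-250"),
    # discontinuous insert wholly inside one gap, plus a second occupant
    list("ADV_disc", "A", "1001.1.1.1", "1-50,361-420"),
    list("ADV_disc", "B", "2003.1.1.1", "61-120,181-240"),
    list("ADV_disc", "D", "2002.1.1.1", "251-350"),
    # discontinuous domain straddling two gaps: no event
    list("ADV_straddle", "A", "1001.1.1.1", "1-50,151-200,301-350"),
    list("ADV_straddle", "X", "2001.1.1.1", "61-100,211-260")
  )
  m <- do.call(rbind, lapply(rows, function(r) unlist(r)))
  domains <- domain_table(protein_id = m[, 1], domain_uid = m[, 2],
                          f_id = m[, 3], range_string = m[, 4])
  expected <- tibble::tibble(
    protein_id = c("ADV_gap30", "ADV_gap31", "ADV_tie", "ADV_side",
                   "ADV_side", "ADV_nest", "ADV_nest", "ADV_disc",
                   "ADV_disc"),
    host_uid = c("host", "host", "A", "A", "A", "A", "B", "A", "A"),
    insert_uid = c("ins", "ins", "C", "B", "C", "B", "C", "B", "D"),
    depth = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L)
  )
  list(domains = domains, expected_events = expected)
}

#' Construct a strictly nested k-level insertion architecture
#'
#' Builds one protein of `depth + 1` domains in which each domain is
#' inserted into the previous one (the outermost host is split into two
#' segments around the next domain, recursively), with every gap at least
#' `min_gap` residues. Running detection on the result yields exactly
#' `depth` events with maximum nesting depth `depth` — the construction
#' mimics the deeply nested insertion architectures seen in cyanobacterial
#' RNA polymerase rpoC2 subunits.
#'
#' @param depth Number of nesting levels (events), `>= 1`.
#' @param seg_len Residues per host segment (default 40).
#' @param linker Unassigned residues flanking each nested domain inside its
#'   gap (default 5).
#' @param min_gap Gap threshold the construction must respect.
#' @return A [domain_table()] for one protein with domains `D0` (outermost)
#'   through `D<depth>` (innermost).
#' @export
nested_architecture <- function(depth, seg_len = 40, linker = 5,
                                min_gap = 30) {
  stopifnot(depth >= 1)
  if (seg_len + 2 * linker < min_gap) {
    stop("innermost span plus linkers is below min_gap", call. = FALSE)
  }
  k <- depth
  span <- numeric(k + 1L)
  span[k + 1L] <- seg_len
  for (j in k:1) span[j] <- 2L * seg_len + 2L * linker + span[j + 1L]
  start <- integer(k + 1L)
  start[1L] <- 1L
  for (j in seq_len(k)) start[j + 1L] <- start[j] + seg_len + linker
  range_string <- character(k + 1L)
  for (j in seq_len(k)) {
    s1 <- c(start[j], start[j] + seg_len - 1L)
    s2_start <- start[j] + seg_len + linker + span[j + 1L] + linker
    s2 <- c(s2_start, s2_start + seg_len - 1L)
    range_string[j] <- paste0(s1[1], "-", s1[2], ",", s2[1], "-", s2[2])
  }
  range_string[k + 1L] <- paste0(start[k + 1L], "-",
                                 start[k + 1L] + seg_len - 1L)
  domain_table(
    protein_id = "NEST",
    domain_uid = paste0("D", 0:k),
    f_id = paste0(3000 + 0:k, ".1.1.1"),
    range_string = range_string
  )
}
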