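# Worked-example fixtures used across test files.

# Dimethylallyltransferase-style protein: P-loop hydrolase host split
# 1-111 / 177-409 around a tRNA-modification insert 112-176, plus one
# unrelated continuous domain downstream.
fixture_mod5 <- function() {
  domain_table(
    protein_id = "3EPL",
    domain_uid = c("d1", "d2", "d3"),
    f_id = c("2004.1.1.71", "3949.1.1.1", "5001.1.1.1"),
    range_string = c("1-111,177-409", "112-176", "420-520")
  )
}

# Nested A1-B1-C-B2-A2 architecture: two independent events B->A and C->B.
fixture_nested_abc <- function() {
  domain_table(
    protein_id = "NDHH",
    domain_uid = c("A", "B", "C"),
    f_id = c("1001.1.1.1", "1002.1.1.1", "2001.1.1.1"),
    range_string = c("1-100,331-430", "101-180,251-330", "181-250")
  )
}

# Two side-by-side inserts sharing one host gap (A1-B-C-A2).
fixture_side_by_side <- function() {
  domain_table(
    protein_id = "SIDE",
    domain_uid = c("A", "B", "C"),
    f_id = c("1001.1.1.1", "2001.1.1.1", "2002.1.1.1"),
    range_string = c("1-100,301-400", "106-180", "191-280")
  )
}

# A plain linear two-domain protein (no insertion).
fixture_linear <- function() {
  domain_table(
    protein_id = "LIN",
    domain_uid = c("A", "B"),
    f_id = c("1001.1.1.1", "1002.1.1.1"),
    range_string = c("1-150", "161-320")
  )
}

# Minimal synthetic event tibble for family/stats tests that do not need
# a full detection run.
make_events <- function(host_f_id, insert_f_id,
                        host_length = 200L, insert_length = 100L,
                        protein_id = NULL,
                        relative_position = 0.5,
                        host_arch = NA_character_,
                        insert_arch = NA_character_) {
  n <- max(length(host_f_id), length(insert_f_id))
  hk <- vapply(host_f_id, function(f) parse_family_id(f)$h_group, character(1))
  ik <- vapply(insert_f_id, function(f) parse_family_id(f)$h_group, character(1))
  hx <- vapply(host_f_id, function(f) parse_family_id(f)$x_group, character(1))
  ix <- vapply(insert_f_id, function(f) parse_family_id(f)$x_group, character(1))
  ht <- vapply(host_f_id, function(f) parse_family_id(f)$t_group_only, logical(1))
  it <- vapply(insert_f_id, function(f) parse_family_id(f)$t_group_only, logical(1))
  tibble::tibble(
    protein_id = if (is.null(protein_id)) sprintf("P%04d", seq_len(n))
                 else rep_len(protein_id, n),
    host_uid = "h1", host_f_id = rep_len(host_f_id, n),
    insert_uid = "i1", insert_f_id = rep_len(insert_f_id, n),
    gap_index = 1L, gap_start = 100L, gap_end = 220L, gap_length = 121L,
    depth = 1L,
    host_length = as.integer(rep_len(host_length, n)),
    insert_length = as.integer(rep_len(insert_length, n)),
    relative_position = rep_len(relative_position, n),
    cross_h_group = rep_len(hk, n) != rep_len(ik, n),
    host_h_group = rep_len(hk, n), insert_h_group = rep_len(ik, n),
    host_x_group = rep_len(hx, n), insert_x_group = rep_len(ix, n),
    host_t_group_only = rep_len(ht, n), insert_t_group_only = rep_len(it, n),
    host_arch = rep_len(host_arch, n), insert_arch = rep_len(insert_arch, n)
  )
}

# A simple in-memory CA trace.
make_trace <- function(resno, x, y, z) {
  tr <- tibble::tibble(resno = as.integer(resno), x = x, y = y, z = z)
  class(tr) <- c("ca_trace", class(tr))
  tr
}
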