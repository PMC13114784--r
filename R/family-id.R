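#' Parse a hierarchical ECOD family identifier
#'
#' ECOD identifies domain families with dot-separated integer identifiers
#' (F-group IDs such as `"2004.1.1.71"`). The leading fields encode the
#' hierarchy: the first field is the X-group (possible homology), the first
#' two the H-group (homology), and the first three the T-group (topology).
#' Domains that could only be placed at topology level carry family IDs
#' terminating in `".0.0"` ("T-group-only" assignments).
#'
#' Both 4-field and deeper identifiers are accepted; the X/H/T prefixes are
#' always the first 1/2/3 fields.
#'
#' @param f_id A single family identifier string, e.g. `"2004.1.1.71"`.
#' @return A list of class `"family_key"` with elements `f_id`, `x_group`,
#'   `h_group`, `t_group` and logical `t_group_only`.
#' @examples
#' parse_family_id("2004.1.1.71")
#' parse_family_id("298.1.0.0")$t_group_only
#' @export
parse_family_id <- function(f_id) {
  if (!is.character(f_id) || length(f_id) != 1L || is.na(f_id) || !nzchar(f_id)) {
    stop("`f_id` must be a single non-empty string", call. = FALSE)
  }
  fields <- strsplit(f_id, ".", fixed = TRUE)[[1]]
  if (length(fields) < 2L) {
    stop("malformed family ID '", f_id, "': fewer than 2 dot-separated fields",
         call. = FALSE)
  }
  bad <- fields[!grepl("^[0-9]+$", fields)]
  if (length(bad) > 0L) {
    stop("malformed family ID '", f_id, "': non-integer field '", bad[[1]], "'",
         call. = FALSE)
  }
  n <- length(fields)
  key <- list(
    f_id = f_id,
    x_group = fields[[1]],
    h_group = paste(fields[seq_len(min(2L, n))], collapse = "."),
    t_group = paste(fields[seq_len(min(3L, n))], collapse = "."),
    t_group_only = fields[[n]] == "0" && fields[[n - 1L]] == "0"
  )
  structure(key, class = "family_key")
}

#' @export
print.family_key <- function(x, ...) {
  cat("<family_key> ", x$f_id,
      "  [X ", x$x_group, " | H ", x$h_group, " | T ", x$t_group,
      if (x$t_group_only) " | T-group-only" else "", "]\n", sep = "")
  invisible(x)
}

# Vectorised family-key columns for a vector of f_ids. Invalid IDs yield NA
# columns and are reported via the "invalid" attribute (reader collects them).
family_key_cols <- function(f_ids) {
  parts <- strsplit(f_ids, ".", fixed = TRUE)
  n_fields <- lengths(parts)
  ok <- n_fields >= 2L &
    vapply(parts, function(p) all(grepl("^[0-9]+$", p)), logical(1))
  x_group <- h_group <- t_group <- rep(NA_character_, length(f_ids))
  t_group_only <- rep(NA, length(f_ids))
  if (any(ok)) {
    x_group[ok] <- vapply(parts[ok], `[[`, character(1), 1L)
    h_group[ok] <- vapply(parts[ok], function(p)
      paste(p[seq_len(min(2L, length(p)))], collapse = "."), character(1))
    t_group[ok] <- vapply(parts[ok], function(p)
      paste(p[seq_len(min(3L, length(p)))], collapse = "."), character(1))
    t_group_only[ok] <- vapply(parts[ok], function(p) {
      n <- length(p); p[[n]] == "0" && p[[n - 1L]] == "0"
    }, logical(1))
  }
  tibble::tibble(x_group = x_group, h_group = h_group, t_group = t_group,
                 t_group_only = t_group_only, .valid = ok)
}
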