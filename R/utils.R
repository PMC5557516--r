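#' @importFrom dplyr arrange bind_cols bind_rows desc distinct filter group_by
#'   left_join mutate n rename row_number select summarise ungroup
#' @importFrom purrr imap map map_dbl map_int map2
NULL

# One warning carrying a count instead of one warning per row; keeps logs
# readable on real tool outputs with thousands of stale ids.
warn_count <- function(n, what, where = NULL) {
  if (n > 0L) {
    warn(sprintf("%d %s%s", n, what,
                 if (is.null(where)) "" else paste0(" in ", where)))
  }
  invisible(n)
}

# Harmonised numeric formatting for emitted files: plain decimal notation,
# up to 6 places, no trailing-zero stripping so re-emission is byte-stable.
format_abundance <- function(x) {
  sprintf("%.6f", x)
}

stopifnot_scalar_path <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    abort("`path` must be a single file path")
  }
  invisible(path)
}
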