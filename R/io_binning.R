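#' Read a binning result
#'
#' Two dialects are accepted. The plain dialect is a tab-separated table of
#' sequence id, assigned length (bases) and taxid, with `#`/`@` comment
#' lines. The BioBoxes binning dialect declares its columns in a `@@` header
#' (`SEQUENCEID`, `TAXID`, optionally a `LENGTH`/`_LENGTH` column); when no
#' length column exists every assignment gets `default_length`. Assignments
#' whose taxid cannot be resolved are dropped with a counted warning.
#'
#' @param path Binning file path.
#' @param tree A `taxonomy`.
#' @param tool_id Tool identity; defaults to the file name.
#' @param default_length Assigned length used when the input carries none.
#' @param keep_first Keep the first of duplicated sequence ids instead of
#'   failing. Off by default: a binner assigns each read once, so duplicates
#'   usually indicate a malformed conversion.
#' @return A `tax_binning` tibble with columns `sequence_id`, `length`,
#'   `taxid`.
#' @export
read_binning <- function(path, tree, tool_id = NULL, default_length = 100L,
                         keep_first = FALSE) {
  stopifnot_scalar_path(path)
  stopifnot(inherits(tree, "taxonomy"))
  if (!file.exists(path)) abort(paste0("binning file not found: ", path))
  tool_id <- tool_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  hdr_at <- which(startsWith(lines, "@@"))
  is_data <- nzchar(lines) & !startsWith(lines, "@") & !startsWith(lines, "#")
  data_idx <- which(is_data)
  if (length(hdr_at) > 0L) data_idx <- data_idx[data_idx > hdr_at[1L]]
  if (length(data_idx) == 0L) {
    return(new_binning(tibble(sequence_id = character(0), length = integer(0),
                              taxid = integer(0)), tool_id))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)

  if (length(hdr_at) > 0L) {
    cols <- toupper(strsplit(sub("^@@", "", lines[hdr_at[1L]]), "\t",
                             fixed = TRUE)[[1L]])
    i_seq <- match("SEQUENCEID", cols)
    i_tax <- match("TAXID", cols)
    i_len <- which(grepl("LENGTH", cols))[1L]
    if (is.na(i_seq) || is.na(i_tax)) {
      abort(sprintf("%s: BioBoxes binning header must declare SEQUENCEID and TAXID", path))
    }
  } else {
    if (any(lengths(fields) < 3L)) {
      abort(sprintf("%s: line %d has fewer than 3 fields", path,
                    data_idx[which(lengths(fields) < 3L)[1L]]))
    }
    i_seq <- 1L; i_len <- 2L; i_tax <- 3L
  }
  get_col <- function(i) vapply(fields, `[[`, character(1), i)

  seq_id <- get_col(i_seq)
  taxid <- suppressWarnings(as.integer(get_col(i_tax)))
  if (anyNA(taxid)) {
    abort(sprintf("%s: non-integer taxid at line %d", path,
                  data_idx[which(is.na(taxid))[1L]]))
  }
  if (!is.na(i_len) && all(lengths(fields) >= i_len)) {
    len <- suppressWarnings(as.numeric(get_col(i_len)))
    if (anyNA(len)) {
      abort(sprintf("%s: non-numeric length at line %d", path,
                    data_idx[which(is.na(len))[1L]]))
    }
    len <- as.integer(len)
  } else {
    len <- rep(as.integer(default_length), length(seq_id))
  }
  if (any(len < 1L)) {
    abort(sprintf("%s: non-positive assigned length at line %d", path,
                  data_idx[which(len < 1L)[1L]]))
  }

  if (anyDuplicated(seq_id) > 0L) {
    if (!keep_first) {
      abort(sprintf("%s: duplicate sequence id '%s' (use keep_first = TRUE to tolerate)",
                    path, seq_id[duplicated(seq_id)][1L]))
    }
    keep <- !duplicated(seq_id)
    warn_count(sum(!keep), "duplicate sequence id(s) dropped (kept first)", path)
    seq_id <- seq_id[keep]; taxid <- taxid[keep]; len <- len[keep]
  }

  res <- resolve_taxid(tree, taxid)
  warn_count(sum(is.na(res)), "assignment(s) with unresolvable taxid dropped", path)
  keep <- !is.na(res)
  new_binning(tibble(sequence_id = seq_id[keep], length = len[keep],
                     taxid = res[keep]), tool_id)
}

new_binning <- function(tbl, tool_id) {
  attr(tbl, "tool_id") <- tool_id
  class(tbl) <- c("tax_binning", class(tibble()))
  tbl
}

# Fixed-rank ancestor closure of a set of (taxid, length) pairs: every fixed
# rank on each taxon's lineage becomes present, reference lengths summing
# upward (a database holding a species can identify its genus, with the
# species' sequences counting toward the genus total).
expand_db_ancestors <- function(taxids, lengths, tree) {
  if (length(taxids) == 0L) {
    return(tibble(taxid = integer(0), rank = character(0),
                  ref_length = numeric(0)))
  }
  rows <- map2(taxids, lengths, function(tx, ln) {
    lin <- lineage_at_ranks(tree, tx)
    tibble(taxid = unname(lin), rank = names(lin), ref_length = ln)
  })
  bind_rows(rows) |>
    group_by(.data$taxid, .data$rank) |>
    summarise(ref_length = if (all(is.na(.data$ref_length))) NA_real_
              else sum(.data$ref_length, na.rm = TRUE), .groups = "drop") |>
    arrange(rank_factor(.data$rank), .data$taxid)
}

new_db_profile <- function(tbl, tool_id) {
  attr(tbl, "tool_id") <- tool_id
  class(tbl) <- c("tax_db", class(tibble()))
  tbl
}

#' Read a per-tool database profile
#'
#' A database profile lists the taxa a tool's reference database covers, one
#' tab-separated row per taxon: taxid, then an optional total reference
#' length in bases. Taxids are resolved (unresolvable rows dropped with a
#' counted warning) and the set is closed upward over [fixed_ranks()], so a
#' database containing a species also counts as containing its genus, family,
#' and so on, with reference lengths summed into each ancestor.
#'
#' @param path Database-profile file path.
#' @param tree A `taxonomy`.
#' @param tool_id Tool identity; defaults to the file name.
#' @return A `tax_db` tibble with columns `taxid`, `rank`, `ref_length`.
#' @export
read_database_profile <- function(path, tree, tool_id = NULL) {
  stopifnot_scalar_path(path)
  stopifnot(inherits(tree, "taxonomy"))
  if (!file.exists(path)) abort(paste0("database profile not found: ", path))
  tool_id <- tool_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  data_idx <- which(nzchar(lines) & !startsWith(lines, "#") &
                      !startsWith(lines, "@"))
  if (length(data_idx) == 0L) {
    return(new_db_profile(expand_db_ancestors(integer(0), numeric(0), tree),
                          tool_id))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  taxid <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 1L)))
  if (anyNA(taxid)) {
    abort(sprintf("%s: non-integer taxid at line %d", path,
                  data_idx[which(is.na(taxid))[1L]]))
  }
  has_len <- lengths(fields) >= 2L
  len <- rep(NA_real_, length(taxid))
  if (any(has_len)) {
    len[has_len] <- suppressWarnings(
      as.numeric(vapply(fields[has_len], `[[`, character(1), 2L)))
    if (anyNA(len[has_len])) {
      abort(sprintf("%s: non-numeric reference length at line %d", path,
                    data_idx[has_len][which(is.na(len[has_len]))[1L]]))
    }
    if (any(len[has_len] <= 0)) {
      abort(sprintf("%s: non-positive reference length at line %d", path,
                    data_idx[has_len][which(len[has_len] <= 0)[1L]]))
    }
  }
  res <- resolve_taxid(tree, taxid)
  warn_count(sum(is.na(res)), "database entr(ies) with unresolvable taxid dropped",
             path)
  keep <- !is.na(res)
  new_db_profile(expand_db_ancestors(res[keep], len[keep], tree), tool_id)
}

#' Build a database profile from accession maps
#'
#' Given the two maps a reference set is usually distributed with — accession
#' to taxid and accession to sequence length, both plain two-column
#' tab-separated files — sums sequence lengths per taxon and closes the set
#' upward over the fixed ranks, exactly as [read_database_profile()] does.
#' Accessions present in only one of the two files are dropped with a counted
#' warning; an empty intersection is an error.
#'
#' @param accession2taxid Path to the accession-to-taxid map.
#' @param sequence_lengths Path to the accession-to-length map.
#' @param tree A `taxonomy`.
#' @param tool_id Tool identity; defaults to the accession map's file name.
#' @return A `tax_db` tibble.
#' @export
build_database_profile <- function(accession2taxid, sequence_lengths, tree,
                                   tool_id = NULL) {
  stopifnot(inherits(tree, "taxonomy"))
  tool_id <- tool_id %||% sub("\\.[^.]*$", "", basename(accession2taxid))
  a2t <- utils::read.delim(accession2taxid, header = FALSE,
                           col.names = c("accession", "taxid"),
                           colClasses = c("character", "integer"))
  a2l <- utils::read.delim(sequence_lengths, header = FALSE,
                           col.names = c("accession", "length"),
                           colClasses = c("character", "numeric"))
  joined <- dplyr::inner_join(a2t, a2l, by = "accession")
  if (nrow(joined) == 0L) {
    abort("no accession is present in both maps; cannot build a database profile")
  }
  warn_count(nrow(a2t) + nrow(a2l) - 2L * nrow(joined),
             "accession(s) present in only one map dropped")
  res <- resolve_taxid(tree, joined$taxid)
  warn_count(sum(is.na(res)), "accession(s) with unresolvable taxid dropped")
  joined <- joined[!is.na(res), , drop = FALSE]
  joined$taxid <- res[!is.na(res)]
  per_tax <- joined |>
    group_by(.data$taxid) |>
    summarise(ref_length = sum(.data$length), .groups = "drop")
  new_db_profile(expand_db_ancestors(per_tax$taxid, per_tax$ref_length, tree),
                 tool_id)
}

#' Write a database profile as a two-column table
#'
#' Only the deepest entries of the ancestor closure are written (taxa that
#' are not a strict ancestor of another entry), so that reading the file back
#' with [read_database_profile()] rebuilds the identical closure.
#'
#' @param db A `tax_db` tibble.
#' @param tree A `taxonomy`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_database_profile <- function(db, path, tree) {
  stopifnot(inherits(tree, "taxonomy"))
  anc <- unique(unlist(map(db$taxid, function(tx) {
    lin <- lineage_at_ranks(tree, tx)
    utils::head(unname(lin), -1L)  # strict ancestors only
  })))
  leaf <- db[!db$taxid %in% anc, , drop = FALSE]
  lines <- ifelse(is.na(leaf$ref_length),
                  sprintf("%d", leaf$taxid),
                  sprintf("%d\t%.0f", leaf$taxid, leaf$ref_length))
  writeLines(lines, path)
  invisible(path)
}
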