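#' Construct a ranked taxonomic profile
#'
#' A ranked profile is the unit flowing through the whole pipeline: a tibble
#' with one row per (rank, taxon) holding a relative abundance on the 0-100
#' scale, carrying the sample and tool identity as attributes. Within a rank
#' taxids are unique; after [normalize_profile()] each non-empty rank sums
#' to 100.
#'
#' @param entries Data frame with columns `rank`, `taxid`, `abundance`.
#' @param sample_id,tool_id Identity attached as attributes.
#' @return A `tax_profile` tibble ordered by rank then descending abundance.
#' @export
tax_profile <- function(entries = tibble(rank = character(0),
                                         taxid = integer(0),
                                         abundance = numeric(0)),
                        sample_id = "", tool_id = "") {
  entries <- as_tibble(entries)
  stopifnot(all(c("rank", "taxid", "abundance") %in% names(entries)))
  if (any(entries$abundance < 0)) abort("abundances must be >= 0")
  out <- entries |>
    mutate(rank = as.character(.data$rank), taxid = as.integer(.data$taxid),
           abundance = as.numeric(.data$abundance)) |>
    select("rank", "taxid", "abundance") |>
    arrange(rank_factor(.data$rank), desc(.data$abundance), .data$taxid)
  if (anyDuplicated(out[c("rank", "taxid")]) > 0L) {
    abort("duplicate taxid within a rank")
  }
  attr(out, "sample_id") <- sample_id
  attr(out, "tool_id") <- tool_id
  class(out) <- c("tax_profile", class(tibble()))
  out
}

profile_meta <- function(profile) {
  list(sample_id = attr(profile, "sample_id") %||% "",
       tool_id = attr(profile, "tool_id") %||% "")
}

#' Read a BioBoxes/CAMI profiling file
#'
#' Accepts the standard profiling format: `@` header lines (`@SampleID`,
#' `@Version`, `@Ranks`, ...), a `@@TAXID RANK TAXPATH TAXPATHSN PERCENTAGE`
#' column header, and tab-separated data rows. Rows are resolved against
#' `tree` (stale ids redirected through the merged map, unresolvable rows
#' dropped with a counted warning), ranks are re-derived from the tree with
#' the `domain` alias folded into `superkingdom`, and rows at off-ladder
#' ranks (strain, subspecies, no-rank) are projected to their deepest
#' fixed-rank ancestor — typically the species — and summed there. Abundances
#' reported on the 0-1 scale (every rank sum at most 1.5) are rescaled to
#' percentages with a warning.
#'
#' @param path Profiling file path.
#' @param tree A `taxonomy`.
#' @param tool_id Tool identity to attach; defaults to the file name.
#' @param keep_strains Keep off-ladder rows at their own rank instead of
#'   projecting them to species. Off by default; such rows are invisible to
#'   the fixed-rank merge.
#' @return A [tax_profile()].
#' @export
read_profile <- function(path, tree, tool_id = NULL, keep_strains = FALSE) {
  stopifnot_scalar_path(path)
  stopifnot(inherits(tree, "taxonomy"))
  if (!file.exists(path)) abort(paste0("profile file not found: ", path))
  tool_id <- tool_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  hdr_at <- which(startsWith(lines, "@@"))
  if (length(hdr_at) == 0L) {
    abort(sprintf("%s: missing '@@' column header; not a profiling file", path))
  }
  hdr_at <- hdr_at[1L]
  cols <- toupper(strsplit(sub("^@@", "", lines[hdr_at]), "\t", fixed = TRUE)[[1L]])
  need <- c("TAXID", "RANK", "PERCENTAGE")
  if (!all(need %in% cols)) {
    abort(sprintf("%s: column header must declare TAXID, RANK and PERCENTAGE", path))
  }
  sample_id <- ""
  meta <- grep("^@[^@]", lines[seq_len(hdr_at)], value = TRUE)
  sid <- grep("^@SampleID:", meta, ignore.case = TRUE, value = TRUE)
  if (length(sid) > 0L) sample_id <- trimws(sub("^@SampleID:", "", sid[1L], ignore.case = TRUE))

  body_idx <- setdiff(seq_along(lines), seq_len(hdr_at))
  body_idx <- body_idx[nzchar(lines[body_idx]) & !startsWith(lines[body_idx], "@")]
  if (length(body_idx) == 0L) {
    return(tax_profile(sample_id = sample_id, tool_id = tool_id))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < length(cols))
  if (length(bad) > 0L) {
    abort(sprintf("%s: line %d has fewer fields than the column header",
                  path, body_idx[bad[1L]]))
  }
  get_col <- function(nm) vapply(fields, `[[`, character(1), match(nm, cols))

  pct <- suppressWarnings(as.numeric(get_col("PERCENTAGE")))
  if (anyNA(pct)) {
    abort(sprintf("%s: non-numeric PERCENTAGE at line %d",
                  path, body_idx[which(is.na(pct))[1L]]))
  }
  if (any(pct < 0)) {
    abort(sprintf("%s: negative PERCENTAGE at line %d",
                  path, body_idx[which(pct < 0)[1L]]))
  }
  raw <- tibble(
    taxid = suppressWarnings(as.integer(get_col("TAXID"))),
    declared_rank = normalize_rank(get_col("RANK")),
    abundance = pct
  )
  if (anyNA(raw$taxid)) {
    abort(sprintf("%s: non-integer TAXID at line %d",
                  path, body_idx[which(is.na(raw$taxid))[1L]]))
  }

  raw$taxid <- resolve_taxid(tree, raw$taxid)
  warn_count(sum(is.na(raw$taxid)), "row(s) with unresolvable taxid dropped", path)
  raw <- filter(raw, !is.na(.data$taxid))

  # re-derive ranks from the tree; project off-ladder nodes to species
  tree_rank <- unname(tree$rank[as.character(raw$taxid)])
  on_ladder <- tree_rank %in% fixed_ranks()
  warn_count(sum(on_ladder & raw$declared_rank != tree_rank),
             "row(s) with declared rank differing from the taxonomy", path)
  raw$rank <- ifelse(on_ladder, tree_rank, raw$declared_rank)
  if (any(!on_ladder) && !keep_strains) {
    proj <- vapply(raw$taxid[!on_ladder], function(tx) project_to_fixed(tree, tx),
                   integer(1))
    raw$taxid[!on_ladder] <- proj
    raw$rank[!on_ladder] <- ifelse(is.na(proj), NA_character_,
                                   unname(tree$rank[as.character(proj)]))
    warn_count(sum(is.na(proj)), "row(s) at off-ladder ranks dropped", path)
    warn_count(sum(!is.na(proj)), "off-ladder row(s) projected to a fixed rank", path)
    raw <- filter(raw, !is.na(.data$taxid))
  }

  dups <- sum(duplicated(raw[c("rank", "taxid")]))
  warn_count(dups, "duplicate taxid row(s) within a rank summed", path)
  out <- raw |>
    group_by(.data$rank, .data$taxid) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop")

  rank_sums <- out |>
    group_by(.data$rank) |>
    summarise(s = sum(.data$abundance), .groups = "drop")
  if (nrow(rank_sums) > 0L && all(rank_sums$s <= 1.5)) {
    warn(sprintf("%s: abundances look 0-1 scaled (all rank sums <= 1.5); rescaling to percent", path))
    out$abundance <- out$abundance * 100
  }
  tax_profile(out, sample_id = sample_id, tool_id = tool_id)
}

#' Write a profile in BioBoxes/CAMI profiling format
#'
#' Ranks are emitted in [fixed_ranks()] order, entries within a rank by
#' descending abundance (ties by ascending taxid); TAXPATH and TAXPATHSN are
#' rebuilt from the taxonomy with pipe-joined fixed-rank lineages. Reading
#' the file back reproduces taxids exactly and abundances to six decimals,
#' and re-emitting a just-read canonical file is byte-identical.
#'
#' @param profile A [tax_profile()].
#' @param path Output path.
#' @param tree A `taxonomy` used to rebuild lineage paths.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path, tree) {
  stopifnot(inherits(tree, "taxonomy"))
  stopifnot_scalar_path(path)
  meta <- profile_meta(profile)
  hdr <- c(paste0("@SampleID:", meta$sample_id),
           "@Version:0.9.4",
           paste0("@Ranks:", paste(fixed_ranks(), collapse = "|")),
           "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE")
  body <- character(0)
  if (nrow(profile) > 0L) {
    ord <- profile |>
      filter(.data$rank %in% fixed_ranks()) |>
      arrange(rank_factor(.data$rank), desc(.data$abundance), .data$taxid)
    paths <- map(ord$taxid, function(tx) {
      if (!as.character(tx) %in% names(tree$parent)) {
        abort(sprintf("taxid %d in profile is not in the taxonomy", tx))
      }
      lineage_at_ranks(tree, tx)
    })
    body <- sprintf("%d\t%s\t%s\t%s\t%s",
                    ord$taxid, ord$rank,
                    vapply(paths, function(l) paste(l, collapse = "|"), character(1)),
                    vapply(paths, function(l)
                      paste(unname(tree$name[as.character(l)]), collapse = "|"),
                      character(1)),
                    format_abundance(ord$abundance))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a profile as Krona-compatible text
#'
#' One line per species: abundance, then the scientific-name lineage from
#' superkingdom to species, all tab-separated — the input dialect of Krona's
#' text importer.
#'
#' @inheritParams write_profile
#' @return Invisibly, `path`.
#' @export
write_krona <- function(profile, path, tree) {
  stopifnot(inherits(tree, "taxonomy"))
  sp <- filter(profile, .data$rank == "species") |>
    arrange(desc(.data$abundance), .data$taxid)
  lines <- vapply(seq_len(nrow(sp)), function(k) {
    lin <- lineage_at_ranks(tree, sp$taxid[k])
    paste(c(format_abundance(sp$abundance[k]),
            unname(tree$name[as.character(lin)])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
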