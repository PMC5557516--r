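# Hand-built taxonomy fixtures used across the suite, written as dump files
# in a tempdir at load time.
#
# mini tree:                    root(1)
#                             Bacteria(2, superkingdom)
#                           Proteobacteria(1224, phylum)
#
# deep tree: full 7-rank lineage with two species under one genus plus a
# "no rank" strain child of species 9, and a merged id 666 -> 1224.
#
#   1 root
#   └─ 2  Bacteria (superkingdom)
#      └─ 1224 Proteobacteria (phylum)
#         └─ 3 Gammaproteobacteria (class)
#            └─ 4 Enterobacterales (order)
#               └─ 5 Enterobacteriaceae (family)
#                  └─ 6 Escherichia (genus)
#                     ├─ 9 Escherichia coli (species)
#                     │   └─ 10 E. coli K-12 (no rank)
#                     └─ 11 Escherichia fergusonii (species)

write_dump_lines <- function(dir, nodes, names, merged = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(names, file.path(dir, "names.dmp"))
  writeLines(merged, file.path(dir, "merged.dmp"))
  list(nodes = file.path(dir, "nodes.dmp"),
       names = file.path(dir, "names.dmp"),
       merged = file.path(dir, "merged.dmp"))
}

mini_dump <- function(dir = tempfile("minitax")) {
  write_dump_lines(
    dir,
    nodes = c("1\t|\t1\t|\tno rank\t|",
              "2\t|\t1\t|\tsuperkingdom\t|",
              "1224\t|\t2\t|\tphylum\t|"),
    names = c("1\t|\troot\t|\t\t|\tscientific name\t|",
              "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
              "1224\t|\tProteobacteria\t|\t\t|\tscientific name\t|"),
    merged = "666\t|\t1224\t|"
  )
}

mini_tree <- function() {
  p <- mini_dump()
  load_taxonomy(p$nodes, p$names, p$merged)
}

deep_dump <- function(dir = tempfile("deeptax")) {
  ranks <- c("no rank", "superkingdom", "phylum", "class", "order", "family",
             "genus", "species", "no rank", "species")
  ids <- c(1, 2, 1224, 3, 4, 5, 6, 9, 10, 11)
  parents <- c(1, 1, 2, 1224, 3, 4, 5, 6, 9, 6)
  nms <- c("root", "Bacteria", "Proteobacteria", "Gammaproteobacteria",
           "Enterobacterales", "Enterobacteriaceae", "Escherichia",
           "Escherichia coli", "E. coli K-12", "Escherichia fergusonii")
  write_dump_lines(
    dir,
    nodes = sprintf("%d\t|\t%d\t|\t%s\t|", ids, parents, ranks),
    names = sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", ids, nms),
    merged = "666\t|\t1224\t|"
  )
}

deep_tree <- function() {
  p <- deep_dump()
  load_taxonomy(p$nodes, p$names, p$merged)
}

# write a CAMI profiling file from (taxid, rank, pct) rows
write_cami <- function(path, rows, sample_id = "S1") {
  writeLines(c(
    paste0("@SampleID:", sample_id),
    "@Version:0.9.4",
    paste0("@Ranks:", paste(fixed_ranks(), collapse = "|")),
    "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    vapply(rows, function(r) sprintf("%s\t%s\t\t\t%s", r[[1]], r[[2]], r[[3]]),
           character(1))
  ), path)
  path
}

# small in-code profile builder
prof <- function(..., tool_id = "t", sample_id = "s") {
  rows <- list(...)
  tax_profile(tibble::tibble(
    rank = vapply(rows, `[[`, character(1), 1),
    taxid = as.integer(vapply(rows, function(r) as.numeric(r[[2]]), numeric(1))),
    abundance = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
  ), sample_id = sample_id, tool_id = tool_id)
}

# cached default-spec replicates shared by the heavier ensemble tests
ensemble_replicates <- local({
  cache <- NULL
  function(n = 20L) {
    if (is.null(cache) || length(cache) < n) {
      cache <<- lapply(seq_len(n), function(s) {
        suppressWarnings(simulate_ensemble(ensemble_spec(seed = s)))
      })
    }
    cache[seq_len(n)]
  }
})
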