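#' Gene family constructor
#'
#' A gene family is the unit of reconciliation: a set of genes, each assigned
#' to a species, with optional coding sequences.
#'
#' @param family_id character id.
#' @param gene_id character vector of gene ids (unique within the family).
#' @param species_id character vector, parallel to `gene_id`.
#' @param seqs optional named character vector of coding sequences.
#' @return an object of class `gene_family`.
#' @export
gene_family <- function(family_id, gene_id, species_id, seqs = NULL) {
  assert_that(length(gene_id) == length(species_id),
              "gene_id and species_id must have equal length")
  assert_that(anyDuplicated(gene_id) == 0L,
              "duplicate gene_id within family %s", family_id)
  structure(list(family_id = as.character(family_id),
                 genes = data.frame(gene_id = as.character(gene_id),
                                    species_id = as.character(species_id),
                                    stringsAsFactors = FALSE),
                 seqs = seqs),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("gene_family %s: %d genes in %d species\n", x$family_id,
              nrow(x$genes), length(unique(x$genes$species_id))))
  invisible(x)
}

#' Read a gene-family membership table
#'
#' Expects a tab-separated file with header columns `family_id`, `gene_id`,
#' `species_id`. Lines starting with `#` are ignored. Families are returned in
#' stable order by `family_id`.
#'
#' @param path TSV file.
#' @param species optional character vector; when supplied, every `species_id`
#'   must be among it.
#' @return named list of [gene_family()] objects.
#' @export
read_family_table <- function(path, species = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("family_id", "gene_id", "species_id")
  missing_cols <- setdiff(need, names(tab))
  assert_that(length(missing_cols) == 0L, "missing column(s) in %s: %s", path,
              paste(missing_cols, collapse = ", "))
  if (!is.null(species)) {
    bad <- setdiff(unique(tab$species_id), species)
    assert_that(length(bad) == 0L, "unknown species in family table: %s",
                paste(bad, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(list())
  out <- lapply(split(tab, tab$family_id), function(d) {
    gene_family(d$family_id[1L], d$gene_id, d$species_id)
  })
  out[order(names(out))]
}

#' Write a gene-family membership table
#' @param families list of [gene_family()] objects.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(f) {
    data.frame(family_id = f$family_id, gene_id = f$genes$gene_id,
               species_id = f$genes$species_id, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(family_id = character(), gene_id = character(),
                       species_id = character())
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an anchor-pair table
#'
#' Anchor pairs are duplicate gene pairs retained in collinear regions;
#' expected columns: `gene_a`, `gene_b`, `scaffold_a`, `scaffold_b`, `ks`, and
#' optionally `family_id`.
#'
#' @param path TSV file (tab-separated, `#` comments allowed).
#' @return data.frame of anchor pairs.
#' @export
read_anchor_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "scaffold_a", "scaffold_b", "ks")
  missing_cols <- setdiff(need, names(tab))
  assert_that(length(missing_cols) == 0L, "missing column(s) in %s: %s", path,
              paste(missing_cols, collapse = ", "))
  assert_that(all(tab$ks >= 0), "negative Ks in anchor table %s", path)
  assert_that(all(tab$gene_a != tab$gene_b), "anchor pair with identical genes")
  if (!"family_id" %in% names(tab)) tab$family_id <- NA_character_
  tab
}

#' Write an anchor-pair table
#' @param anchors data.frame as returned by [read_anchor_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample of gene trees (one newick string per line)
#'
#' Used for posterior samples of gene-tree topologies. Malformed lines are
#' reported with their line numbers.
#'
#' @param path file with one newick tree per line.
#' @return list of [ape::phylo] objects.
#' @export
read_tree_sample <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  trees <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq_along(lines)) {
    tr <- tryCatch(ape::read.tree(text = lines[[i]]), error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(tr)) bad <- c(bad, i) else trees[[i]] <- tr
  }
  assert_that(length(bad) == 0L, "unparsable newick in %s at line(s): %s", path,
              paste(bad, collapse = ", "))
  trees
}

#' Write a sample of gene trees, one newick per line
#' @param trees list of [ape::phylo] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_sample <- function(trees, path) {
  writeLines(vapply(trees, function(tr) ape::write.tree(tr), character(1)), path)
  invisible(path)
}

#' Serialize a Bayes-factor result table to TSV
#'
#' Columns mirror the layout of a WGD hypothesis-test report: hypothesis id,
#' posterior mean retention rate, Bayes factor, verdict, and model kind.
#'
#' @param results data.frame with columns `wgd_id`, `q_mean`, `K`, `verdict`
#'   and optionally `model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  need <- c("wgd_id", "q_mean", "K", "verdict")
  assert_that(all(need %in% names(results)),
              "report needs columns %s", paste(need, collapse = ", "))
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
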