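#' Build a conditional clade distribution (CCD) from a gene-tree sample
#'
#' Summarizes a posterior sample of gene-tree topologies by the marginal
#' frequency of every observed clade and, for each clade, the conditional
#' frequencies of its observed child splits. The first `burn_in` trees are
#' discarded.
#'
#' @param trees list of rooted binary [ape::phylo] objects on a common leaf
#'   set (one posterior sample).
#' @param burn_in number of initial trees to discard (default 1000).
#' @param species_map optional named character vector mapping gene ids to
#'   species ids; by default species are recovered from the
#'   `"SPECIES__g<counter>"` gene-id convention.
#' @param family_id id stored with the CCD.
#' @return object of class `ccd`: list with `genes` (sorted), `species`
#'   (named by gene), `n` (post-burn-in sample size), `clades`
#'   (data.frame `key`, `size`, `count`), `splits` (data.frame `parent`,
#'   `c1`, `c2`, `count`, `p`). Clade keys are comma-joined sorted gene
#'   indices.
#' @export
build_ccd <- function(trees, burn_in = 1000, species_map = NULL,
                      family_id = NA_character_) {
  assert_that(length(trees) >= burn_in + 1,
              "tree sample (%d) not larger than burn-in (%d)", length(trees), burn_in)
  trees <- trees[(burn_in + 1):length(trees)]
  genes <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    assert_that(setequal(tr$tip.label, genes), "heterogeneous leaf sets in tree sample")
  }
  if (is.null(species_map)) {
    species_map <- stats::setNames(sub("__.*$", "", genes), genes)
  }
  clade_counts <- new.env(parent = emptyenv())
  split_counts <- new.env(parent = emptyenv())
  bump <- function(env, key) assign(key, (env[[key]] %||% 0L) + 1L, envir = env)
  for (tr in trees) {
    if (!ape::is.binary(tr)) tr <- ape::multi2di(tr)
    ntip <- ape::Ntip(tr)
    idx <- match(tr$tip.label, genes)
    sets <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) sets[[i]] <- idx[i]
    tr2 <- ape::reorder.phylo(tr, "postorder")
    kids <- vector("list", ntip + tr$Nnode)
    for (e in seq_len(nrow(tr2$edge))) {
      a <- tr2$edge[e, 1L]; b <- tr2$edge[e, 2L]
      sets[[a]] <- c(sets[[a]], sets[[b]])
      kids[[a]] <- c(kids[[a]], b)
    }
    for (v in (ntip + 1L):(ntip + tr$Nnode)) {
      key <- paste(sort(sets[[v]]), collapse = ",")
      bump(clade_counts, key)
      k1 <- paste(sort(sets[[kids[[v]][1L]]]), collapse = ",")
      k2 <- paste(sort(sets[[kids[[v]][2L]]]), collapse = ",")
      if (k2 < k1) { tmp <- k1; k1 <- k2; k2 <- tmp }
      bump(split_counts, paste(key, k1, k2, sep = "|"))
    }
  }
  # singleton clades are always present with frequency 1
  for (i in seq_along(genes)) assign(as.character(i), length(trees), envir = clade_counts)
  ckeys <- ls(clade_counts)
  clades <- data.frame(key = ckeys,
                       size = vapply(strsplit(ckeys, ","), length, integer(1)),
                       count = vapply(ckeys, function(k) clade_counts[[k]], integer(1)),
                       stringsAsFactors = FALSE)
  clades <- clades[order(clades$size, clades$key), ]
  rownames(clades) <- NULL
  skeys <- ls(split_counts)
  sparts <- strsplit(skeys, "|", fixed = TRUE)
  splits <- data.frame(parent = vapply(sparts, `[[`, character(1), 1L),
                       c1 = vapply(sparts, `[[`, character(1), 2L),
                       c2 = vapply(sparts, `[[`, character(1), 3L),
                       count = vapply(skeys, function(k) split_counts[[k]], integer(1)),
                       stringsAsFactors = FALSE)
  splits$p <- splits$count / clades$count[match(splits$parent, clades$key)]
  splits <- splits[order(splits$parent, splits$c1), ]
  rownames(splits) <- NULL
  structure(list(family_id = family_id, genes = genes,
                 species = species_map[genes], n = length(trees),
                 clades = clades, splits = splits),
            class = "ccd")
}

#' @export
print.ccd <- function(x, ...) {
  cat(sprintf("ccd %s: %d genes, %d clades, %d splits, n = %d\n",
              x$family_id, length(x$genes), nrow(x$clades), nrow(x$splits), x$n))
  invisible(x)
}

#' Marginal frequency of a clade (by gene ids)
#' @param ccd a [build_ccd()] object.
#' @param genes character vector of gene ids.
#' @return frequency in `[0,1]` (0 when unobserved).
#' @export
clade_frequency <- function(ccd, genes) {
  key <- paste(sort(match(genes, ccd$genes)), collapse = ",")
  i <- match(key, ccd$clades$key)
  if (is.na(i)) 0 else ccd$clades$count[i] / ccd$n
}

#' Serialize a CCD to JSON
#' @param ccd a `ccd` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ccd <- function(ccd, path) {
  jsonlite::write_json(list(family_id = ccd$family_id, genes = ccd$genes,
                            species = as.list(ccd$species), n = ccd$n,
                            clades = ccd$clades, splits = ccd$splits),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CCD from JSON
#' @param path file written by [write_ccd()].
#' @return a `ccd` object.
#' @export
read_ccd <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(family_id = x$family_id, genes = x$genes,
                 species = unlist(x$species)[x$genes], n = x$n,
                 clades = x$clades, splits = x$splits),
            class = "ccd")
}
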