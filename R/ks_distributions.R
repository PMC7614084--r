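#' Construct a Ks distribution object
#'
#' A weighted collection of pairwise synonymous distances. Retained pairs have
#' Ks in `(0, ceiling]`; saturated or out-of-range pairs are dropped at
#' construction.
#'
#' @param pairs data.frame with at least `gene_a`, `gene_b`, `ks`, `weight`.
#' @param kind `"paranome"`, `"anchor"` or `"ortholog"`.
#' @param species species label(s).
#' @param ceiling Ks ceiling (default 5).
#' @return data.frame of retained pairs with attributes `kind`, `species`,
#'   `ceiling`; class `ks_distribution`.
#' @export
ks_distribution <- function(pairs, kind = c("paranome", "anchor", "ortholog"),
                            species = NA_character_, ceiling = 5) {
  kind <- match.arg(kind)
  keep <- is.finite(pairs$ks) & pairs$ks > 0 & pairs$ks <= ceiling
  if (!any(keep) && nrow(pairs) > 0) {
    warn_wgdc("all %d pairs dropped (saturated, zero, or above the Ks ceiling)", nrow(pairs))
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, kind = kind, species = species, ceiling = ceiling,
            class = c("ks_distribution", "data.frame"))
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat(sprintf("ks_distribution (%s, %s): %d pairs, total weight %.2f, ceiling %g\n",
              attr(x, "kind"), paste(attr(x, "species"), collapse = "/"),
              nrow(x), sum(x$weight), attr(x, "ceiling")))
  invisible(x)
}

#' Node-based redundancy weights for the paralog pairs of one family
#'
#' Within a family, the `choose(n,2)` pairwise Ks values are redundant: one
#' duplication node generates many pairs. Pairs are clustered by
#' average-linkage on Ks and each inferred duplication node contributes total
#' weight 1, split equally among the `|left| x |right|` pairs it joins, so the
#' weights of a family sum to (number of genes - 1). Ties are broken by
#' lexicographic gene id via the initial ordering.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `ks` for a single family;
#'   non-finite Ks (saturated pairs) participate in the clustering at a large
#'   pseudo-distance and keep weight for downstream dropping.
#' @return `pairs` with a `weight` column added.
#' @export
weight_family_pairs <- function(pairs) {
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  n <- length(genes)
  if (n < 2L) { pairs$weight <- numeric(nrow(pairs)); return(pairs) }
  if (n == 2L) { pairs$weight <- 1; return(pairs) }
  big <- max(c(pairs$ks[is.finite(pairs$ks)], 1)) * 2 + 10
  d <- matrix(big, n, n, dimnames = list(genes, genes))
  ks_fill <- ifelse(is.finite(pairs$ks), pairs$ks, big)
  for (i in seq_len(nrow(pairs))) {
    d[pairs$gene_a[i], pairs$gene_b[i]] <- ks_fill[i]
    d[pairs$gene_b[i], pairs$gene_a[i]] <- ks_fill[i]
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  members <- c(as.list(seq_len(n)), vector("list", n - 1L))  # tips then merges
  w <- stats::setNames(rep(NA_real_, nrow(pairs)),
                       paste(pmin(pairs$gene_a, pairs$gene_b),
                             pmax(pairs$gene_a, pairs$gene_b)))
  for (k in seq_len(n - 1L)) {
    left <- hc$merge[k, 1L]; right <- hc$merge[k, 2L]
    L <- if (left < 0) -left else members[[n + left]]
    R <- if (right < 0) -right else members[[n + right]]
    members[[n + k]] <- c(L, R)
    wk <- 1 / (length(L) * length(R))
    for (i in L) for (j in R) {
      key <- paste(min(genes[i], genes[j]), max(genes[i], genes[j]))
      w[[key]] <- wk
    }
  }
  pairs$weight <- unname(w)
  pairs
}

#' Build a node-weighted paranome Ks distribution
#'
#' Computes all within-family pairwise NG86 distances for single-species
#' families with sequences, applies the duplication-node redundancy weighting
#' of [weight_family_pairs()], and drops saturated pairs and pairs above the
#' ceiling.
#'
#' @param families list of [gene_family()] objects, each restricted to one
#'   species and carrying `seqs`.
#' @param ceiling Ks ceiling (default 5).
#' @param species species label for the distribution.
#' @return a [ks_distribution()] of kind `"paranome"`.
#' @export
build_paranome_distribution <- function(families, ceiling = 5, species = NULL) {
  all_pairs <- list()
  for (f in families) {
    genes <- f$genes$gene_id
    sp <- unique(f$genes$species_id)
    assert_that(length(sp) == 1L, "paranome families must be single-species (family %s)", f$family_id)
    if (length(genes) < 2L) next
    assert_that(!is.null(f$seqs) && all(genes %in% names(f$seqs)),
                "family %s lacks coding sequences", f$family_id)
    rows <- list()
    for (i in seq_len(length(genes) - 1L)) {
      for (j in (i + 1L):length(genes)) {
        kp <- ng86_distance(f$seqs[[genes[i]]], f$seqs[[genes[j]]])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j], ks = kp$ks, ka = kp$ka,
          family_id = f$family_id, stringsAsFactors = FALSE)
      }
    }
    fam_pairs <- weight_family_pairs(do.call(rbind, rows))
    all_pairs[[length(all_pairs) + 1L]] <- fam_pairs
    if (is.null(species)) species <- sp
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else
    data.frame(gene_a = character(), gene_b = character(), ks = numeric(),
               ka = numeric(), family_id = character(), weight = numeric())
  ks_distribution(pairs, "paranome", species %||% NA_character_, ceiling)
}

#' Reciprocal-best-hit one-to-one ortholog Ks distribution
#'
#' Keeps only reciprocal best hits between the two species (each gene's single
#' best-scoring cross-species hit, required to be mutual) and computes their
#' NG86 Ks with weight 1 each.
#'
#' @param scores data.frame of cross-species similarity hits with columns
#'   `gene_a` (species A), `gene_b` (species B), `score`.
#' @param seqs named character vector of coding sequences covering all genes
#'   in the retained pairs.
#' @param species character vector of the two species labels.
#' @param ceiling Ks ceiling.
#' @return a [ks_distribution()] of kind `"ortholog"`.
#' @export
build_ortholog_distribution <- function(scores, seqs, species = c(NA, NA), ceiling = 5) {
  rbh <- reciprocal_best_hits(scores)
  if (nrow(rbh) == 0L) {
    warn_wgdc("no reciprocal-best-hit pairs between the two gene sets")
    return(ks_distribution(data.frame(gene_a = character(), gene_b = character(),
                                      ks = numeric(), ka = numeric(), weight = numeric()),
                           "ortholog", species, ceiling))
  }
  rows <- lapply(seq_len(nrow(rbh)), function(i) {
    kp <- ng86_distance(seqs[[rbh$gene_a[i]]], seqs[[rbh$gene_b[i]]])
    data.frame(gene_a = rbh$gene_a[i], gene_b = rbh$gene_b[i], ks = kp$ks,
               ka = kp$ka, weight = 1, stringsAsFactors = FALSE)
  })
  ks_distribution(do.call(rbind, rows), "ortholog", species, ceiling)
}

#' Reciprocal best hits from a cross-species score table
#' @param scores data.frame with `gene_a`, `gene_b`, `score`.
#' @return data.frame of mutual best-hit pairs.
#' @export
reciprocal_best_hits <- function(scores) {
  if (nrow(scores) == 0L) return(scores[0, c("gene_a", "gene_b")])
  ord <- order(-scores$score, scores$gene_a, scores$gene_b)
  s <- scores[ord, ]
  best_a <- s[!duplicated(s$gene_a), ]          # best hit of each A gene
  best_b <- s[!duplicated(s$gene_b), ]          # best hit of each B gene
  key_a <- paste(best_a$gene_a, best_a$gene_b)
  key_b <- paste(best_b$gene_a, best_b$gene_b)
  out <- best_a[key_a %in% key_b, c("gene_a", "gene_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}
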