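#' Filter homolog pairs by c-score
#'
#' The c-score of a pair is its similarity score divided by the best score
#' involving either gene; pairs below the threshold are likely spurious
#' homology. The denominator uses the stricter `max` of the two genes' best
#' scores by default (`min` is also available, as the convention varies).
#'
#' @param pairs data.frame with `gene_a`, `gene_b`, `score`.
#' @param threshold minimum c-score (default 0.5).
#' @param denominator `"max"` (default) or `"min"`.
#' @return `pairs` with a `c_score` column, filtered to `c_score >= threshold`.
#' @export
cscore_filter <- function(pairs, threshold = 0.5, denominator = c("max", "min")) {
  denominator <- match.arg(denominator)
  best <- tapply(c(pairs$score, pairs$score), c(pairs$gene_a, pairs$gene_b), max)
  ba <- best[pairs$gene_a]; bb <- best[pairs$gene_b]
  denom <- if (denominator == "max") pmax(ba, bb) else pmin(ba, bb)
  pairs$c_score <- pairs$score / denom
  out <- pairs[pairs$c_score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter anchor pairs by scaffold size and Ks
#'
#' Removes anchors on short scaffolds (assembly fragments whose small-Ks
#' anchor pairs are artefactual) and anchors with very small Ks: an anchor is
#' kept iff both scaffolds carry at least `min_scaffold_genes` genes and its
#' Ks is at least `min_ks`.
#'
#' @param anchors data.frame from [read_anchor_table()].
#' @param genes_per_scaffold named numeric vector: gene count per scaffold.
#' @param min_scaffold_genes minimum genes per scaffold (default 10).
#' @param min_ks minimum anchor Ks (default 0.1).
#' @return filtered data.frame.
#' @export
filter_anchors <- function(anchors, genes_per_scaffold, min_scaffold_genes = 10,
                           min_ks = 0.1) {
  scafs <- unique(c(anchors$scaffold_a, anchors$scaffold_b))
  unknown <- setdiff(scafs, names(genes_per_scaffold))
  assert_that(length(unknown) == 0L, "anchor references unknown scaffold(s): %s",
              paste(unknown, collapse = ", "))
  keep <- genes_per_scaffold[anchors$scaffold_a] >= min_scaffold_genes &
          genes_per_scaffold[anchors$scaffold_b] >= min_scaffold_genes &
          anchors$ks >= min_ks
  out <- anchors[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select WGD-candidate anchor families by per-species Ks windows
#'
#' Keeps anchors whose Ks falls inside their species' closed Ks window (the
#' window bracketing the species' WGD peak in its paranome distribution),
#' groups them into their gene families, and reports retained counts per
#' species. Anchors without a family assignment are excluded and logged.
#'
#' @param anchors data.frame with `gene_a`, `gene_b`, `ks`, `family_id` and a
#'   `species` column (or gene ids following the `SPECIES__g` convention).
#' @param families list of [gene_family()] objects (already filtered for
#'   reconciliation, e.g. via [filter_families()]).
#' @param ks_window_per_species named list: species -> `c(lo, hi)` closed
#'   interval.
#' @return list: `anchors` (kept rows), `families` (the gene families with at
#'   least one kept anchor), `counts` (per-species kept anchor counts),
#'   `unassigned` (number of anchors without family).
#' @export
select_wgd_anchor_families <- function(anchors, families, ks_window_per_species) {
  if (!"species" %in% names(anchors)) {
    anchors$species <- sub("__.*$", "", anchors$gene_a)
  }
  unassigned <- sum(is.na(anchors$family_id))
  a <- anchors[!is.na(anchors$family_id), , drop = FALSE]
  keep <- vapply(seq_len(nrow(a)), function(i) {
    win <- ks_window_per_species[[a$species[i]]]
    !is.null(win) && a$ks[i] >= win[1] && a$ks[i] <= win[2]
  }, logical(1))
  kept <- a[keep, , drop = FALSE]
  fam_ids <- vapply(families, function(f) f$family_id, character(1))
  fams <- families[fam_ids %in% unique(kept$family_id)]
  rownames(kept) <- NULL
  list(anchors = kept, families = fams,
       counts = table(kept$species), unassigned = unassigned)
}

#' Reconciliation configuration for anchor families
#'
#' Anchor-family reconciliations are run without WGD hypotheses and with the
#' root parameter held fixed (default `eta = 0.75`, matching an average of
#' about 1.3 observed genes per family at the root); per-branch rates keep
#' their exponential hyperprior. The returned list plugs into
#' [mcmc_dlwgd()] as `eta_fixed`.
#'
#' @param selected result of [select_wgd_anchor_families()] (or a non-empty
#'   list of families).
#' @param eta fixed root parameter (default 0.75).
#' @return list: `families`, `eta_fixed`, `wgd` (empty), `model`.
#' @export
anchor_reconciliation_config <- function(selected, eta = 0.75) {
  fams <- if (is.list(selected) && !is.null(selected$families)) selected$families else selected
  assert_that(length(fams) > 0, "no anchor families selected")
  assert_that(is_prob(eta) && eta > 0, "eta must lie in (0,1]")
  list(families = fams, eta_fixed = eta,
       wgd = data.frame(wgd_id = character(), node = integer(), pos = numeric()),
       model = "critical")
}
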