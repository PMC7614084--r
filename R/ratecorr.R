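#' Point estimate (KDE mode) and bootstrap sd of an ortholog Ks peak
#'
#' The peak of a one-to-one ortholog Ks distribution dates the divergence of
#' the two species on the Ks scale. The estimate is the mode of a
#' Gaussian-kernel density (Sheather-Jones bandwidth, falling back to
#' Silverman when SJ fails); the uncertainty is the sd of the mode over
#' bootstrap resamples.
#'
#' @param ks numeric vector of Ks values (or a [ks_distribution()]).
#' @param n_boot bootstrap resamples (default 200).
#' @param seed seed for the bootstrap.
#' @return list with `peak`, `sd`, `n`.
#' @export
ortholog_peak <- function(ks, n_boot = 200, seed = 1) {
  if (is.data.frame(ks)) ks <- ks$ks
  ks <- ks[is.finite(ks) & ks > 0]
  assert_that(length(ks) >= 10, "too few ortholog pairs for a peak estimate")
  mode_of <- function(v, sj = TRUE) {
    bw <- if (sj) tryCatch(stats::bw.SJ(v), error = function(e) stats::bw.nrd0(v))
          else stats::bw.nrd0(v)
    d <- stats::density(v, bw = bw)
    d$x[which.max(d$y)]
  }
  est <- mode_of(ks)
  set.seed(seed)
  # Silverman bandwidth for the resamples: the bootstrap only needs the
  # spread of the mode, and the plug-in bandwidth is much costlier
  boots <- replicate(n_boot, mode_of(sample(ks, replace = TRUE), sj = FALSE))
  list(peak = est, sd = stats::sd(boots), n = length(ks))
}

#' Fit branch lengths in Ks units to a fixed topology (non-negative LS)
#'
#' Given the ortholog-peak Ks distance for every leaf pair, solves the
#' tree-additivity equations `sum of branch lengths on path(i,j) = d_ij` by
#' non-negative least squares on the fixed topology, and reports the residual
#' norm. On an additive matrix the recovery is exact.
#'
#' @param topology a [species_tree()] (branch lengths ignored).
#' @param peak_matrix symmetric numeric matrix of pairwise ortholog peak Ks,
#'   with row/col names equal to the leaf labels.
#' @return a [species_tree()] with `units = "Ks"`; attributes `residual`
#'   (vector of per-pair residuals) and `residual_norm`.
#' @export
fit_ks_phylogram <- function(topology, peak_matrix) {
  phy <- topology$phy
  tips <- phy$tip.label
  assert_that(all(tips %in% rownames(peak_matrix)) && all(tips %in% colnames(peak_matrix)),
              "peak matrix does not cover the tree's leaf set")
  pm <- peak_matrix[tips, tips]
  assert_that(!any(is.na(pm[upper.tri(pm)])), "peak matrix is incomplete")
  par <- tree_parents(phy)
  root <- ape::Ntip(phy) + 1L
  path_to_root <- function(node) {
    out <- integer(0)
    while (node != root) { out <- c(out, node); node <- par[node] }
    out
  }
  branch_nodes <- phy$edge[, 2L]
  npair <- choose(length(tips), 2L)
  A <- matrix(0, npair, length(branch_nodes),
              dimnames = list(NULL, as.character(branch_nodes)))
  d <- numeric(npair)
  r <- 0L
  for (i in seq_len(length(tips) - 1L)) {
    for (j in (i + 1L):length(tips)) {
      r <- r + 1L
      pi_ <- path_to_root(i); pj <- path_to_root(j)
      path <- c(setdiff(pi_, pj), setdiff(pj, pi_))
      A[r, as.character(path)] <- 1
      d[r] <- pm[i, j]
    }
  }
  # pairwise distances identify only the SUM of the two root-child branch
  # lengths; a tiny balance row makes the NNLS solution unique by splitting
  # that sum evenly, without perturbing the fit
  root_kids <- tree_children(phy)[[root]]
  bal <- rep(0, length(branch_nodes))
  bal[match(root_kids, branch_nodes)] <- c(1e-6, -1e-6)
  A <- rbind(A, bal)
  d <- c(d, 0)
  fit <- pracma::lsqnonneg(A, d)
  lens <- fit$x
  A <- A[-nrow(A), , drop = FALSE]; d <- d[-length(d)]
  resid <- as.numeric(A %*% lens - d)
  rel <- sqrt(sum(resid^2)) / max(sqrt(sum(d^2)), 1e-12)
  if (rel > 0.1) {
    warn_wgdc("Ks phylogram fit has a large residual (relative norm %.2f): peak matrix is far from additive", rel)
  }
  phy2 <- phy
  phy2$edge.length <- as.numeric(lens[match(phy$edge[, 2L], branch_nodes)])
  out <- species_tree(phy2, units = "Ks", wgd = topology$wgd)
  attr(out, "residual") <- resid
  attr(out, "residual_norm") <- sqrt(sum(resid^2))
  out
}

#' Place a halved Ks peak on a Ks-unit phylogram
#'
#' Under the assumption that both duplicates evolved at similar rates after a
#' WGD, half the paralog peak Ks equals the Ks-distance from the tip back to
#' the event. Walking rootward from the species' tip, branch b covers the
#' cumulative interval `[c_low, c_high)`; the branch containing `peak_ks/2`
#' is assigned. A value exactly at a node boundary is assigned to the
#' rootward branch (a peak exactly at a speciation is evidence for the shared
#' branch); overflow past the root is flagged and assigned to the root stem.
#'
#' @param phylogram a [species_tree()] with `units = "Ks"`.
#' @param species a leaf label.
#' @param peak_ks paralog peak Ks (> 0).
#' @return list: `species`, `peak_ks`, `half`, `node` (tipward node id of the
#'   assigned branch; NA when overflowed), `leafset`, `bracket`, `overflow`.
#' @export
place_halved_peak <- function(phylogram, species, peak_ks) {
  assert_that(phylogram$units == "Ks", "phylogram must be in Ks units")
  phy <- phylogram$phy
  tip <- match(species, phy$tip.label)
  assert_that(!is.na(tip), "unknown species '%s'", species)
  assert_that(peak_ks > 0, "peak_ks must be positive")
  half <- peak_ks / 2
  par <- tree_parents(phy)
  len <- branch_lengths_above(phy)
  root <- ape::Ntip(phy) + 1L
  node <- tip; c_low <- 0
  while (node != root) {
    c_high <- c_low + len[node]
    # half in [c_low, c_high): this branch; exact upper boundary goes rootward
    if (half >= c_low && half < c_high) {
      return(list(species = species, peak_ks = peak_ks, half = half,
                  node = node, leafset = branch_leafset(phylogram, node),
                  bracket = c(c_low, c_high), overflow = FALSE))
    }
    c_low <- c_high
    node <- par[node]
  }
  # overflow beyond the root: report the root stem
  list(species = species, peak_ks = peak_ks, half = half, node = NA_integer_,
       leafset = phy$tip.label, bracket = c(c_low, Inf), overflow = TRUE)
}

#' Relative-rate trio correction of a divergence Ks to the focal scale
#'
#' For focal species F, comparison species S and an outgroup O to (F,S), the
#' focal branch contribution since the F-S divergence is
#' `b_F = (d_FS + d_FO - d_SO)/2`; the divergence re-expressed on the focal
#' rate scale is `2 b_F`. Under a clock the correction is the identity. A
#' negative `b_F` (strong rate contrast plus noise) is clamped to 0 with a
#' warning.
#'
#' @param d_FS,d_FO,d_SO non-negative ortholog peak Ks values.
#' @return corrected divergence Ks on the focal scale.
#' @export
trio_correct <- function(d_FS, d_FO, d_SO) {
  assert_that(all(is.finite(c(d_FS, d_FO, d_SO))), "trio distances must be finite")
  b_F <- (d_FS + d_FO - d_SO) / 2
  if (b_F < 0) {
    warn_wgdc("negative focal branch estimate (%.3f) clamped to 0", b_F)
    b_F <- 0
  }
  2 * b_F
}

# divergence nodes on the focal species' root path, tipward to rootward, each
# with its sister-clade species and the outgroup pool beyond it
focal_divergences <- function(tree, focal) {
  phy <- tree$phy
  tip <- match(focal, phy$tip.label)
  assert_that(!is.na(tip), "unknown focal species '%s'", focal)
  par <- tree_parents(phy)
  ch <- tree_children(phy)
  root <- ape::Ntip(phy) + 1L
  nodes <- list()
  node <- tip
  while (node != root) {
    p <- par[node]
    sib <- setdiff(ch[[p]], node)
    sister <- sort(unlist(lapply(sib, function(s) branch_leafset(tree, s))))
    nodes[[length(nodes) + 1L]] <- list(node = p, below = node, sister = sister)
    node <- p
  }
  # outgroups of divergence i = union of sister clades of divergences > i
  for (i in seq_along(nodes)) {
    og <- lapply(seq_along(nodes), function(j) {
      if (j > i) nodes[[j]]$sister else character(0)
    })
    nodes[[i]]$outgroups <- og[(i + 1):length(nodes)]
    if (i == length(nodes)) nodes[[i]]$outgroups <- list()
  }
  nodes
}

#' Consensus rate-corrected divergences for a focal species
#'
#' For each divergence node on the focal species' root path, enumerates
#' (comparison species S from the sister clade, outgroup O from deeper
#' divergences) trios in order of increasing outgroup depth (nearest
#' outgroups first, minimizing saturation; ties broken alphabetically),
#' truncates at `max_trios`, applies [trio_correct()] to each and averages
#' into a consensus.
#'
#' @param focal focal species label.
#' @param tree a [species_tree()] giving the topology.
#' @param peak_matrix symmetric matrix of pairwise ortholog peak Ks values.
#' @param max_trios maximum number of trios per divergence (default 14).
#' @return data.frame: `node` (species-tree node id of the divergence),
#'   `below` (tipward node of the branch above which the divergence sits on
#'   the focal path), `consensus`, `sd`, `n_trios`.
#' @export
consensus_divergences <- function(focal, tree, peak_matrix, max_trios = 14) {
  divs <- focal_divergences(tree, focal)
  out <- list()
  for (i in seq_along(divs)) {
    dv <- divs[[i]]
    trios <- list()
    for (og_depth in seq_along(dv$outgroups)) {
      for (S in sort(dv$sister)) {
        for (O in sort(dv$outgroups[[og_depth]])) {
          trios[[length(trios) + 1L]] <- c(S = S, O = O)
        }
      }
    }
    if (length(trios) == 0L) {
      warn_wgdc("no valid outgroup for the divergence at node %d: skipped", dv$node)
      next
    }
    trios <- trios[seq_len(min(length(trios), max_trios))]
    vals <- vapply(trios, function(tr) {
      suppressWarnings(trio_correct(peak_matrix[focal, tr[["S"]]],
                                    peak_matrix[focal, tr[["O"]]],
                                    peak_matrix[tr[["S"]], tr[["O"]]]))
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      node = dv$node, below = dv$below, consensus = mean(vals),
      sd = if (length(vals) > 1) stats::sd(vals) else 0, n_trios = length(vals))
  }
  assert_that(length(out) > 0, "no divergence could be corrected for focal '%s'", focal)
  do.call(rbind, out)
}

#' Uncorrected divergence values for a focal species
#'
#' The naive analogue of [consensus_divergences()]: each divergence on the
#' focal root path is dated by the raw ortholog peak Ks between the focal
#' species and its sister-clade species (mean over the sister clade), with no
#' rate correction. Used to demonstrate the placement bias that rate
#' differences cause.
#'
#' @inheritParams consensus_divergences
#' @return data.frame like [consensus_divergences()].
#' @export
raw_divergences <- function(focal, tree, peak_matrix) {
  divs <- focal_divergences(tree, focal)
  do.call(rbind, lapply(divs, function(dv) {
    vals <- peak_matrix[focal, dv$sister]
    data.frame(node = dv$node, below = dv$below, consensus = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               n_trios = length(vals))
  }))
}

#' Rank a paralog peak among (corrected) speciation divergences
#'
#' Places the peak between the two adjacent divergence values along the focal
#' root path. A peak within one consensus sd of a divergence is reported as
#' "at the speciation event"; a peak older than the oldest divergence is
#' flagged as root-stem.
#'
#' @param peak_ks paralog peak Ks on the focal scale.
#' @param divergences data.frame from [consensus_divergences()] (or
#'   [raw_divergences()]), ordered tipward to rootward.
#' @return list: `node` (tipward node id of the assigned branch), `at_speciation`
#'   (divergence node id or NA), `root_stem` flag.
#' @export
rank_peak_vs_divergences <- function(peak_ks, divergences) {
  assert_that(nrow(divergences) >= 1, "need at least one corrected divergence")
  d <- divergences
  at_spec <- NA_integer_
  hit <- which(abs(peak_ks - d$consensus) <= d$sd)
  if (length(hit) > 0) at_spec <- d$node[hit[1L]]
  older <- which(d$consensus >= peak_ks)
  if (length(older) == 0L) {
    return(list(node = NA_integer_, at_speciation = at_spec, root_stem = TRUE))
  }
  # the peak is younger than divergence `older[1]`: it sits on the branch
  # whose tipward node is the previous divergence's ancestor-side node
  i <- older[1L]
  list(node = d$below[i], at_speciation = at_spec, root_stem = FALSE)
}
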