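test_that("additive peak matrices are recovered exactly by the NNLS phylogram", {
  phy <- ape::read.tree(text = "((A:0.2,B:0.35):0.15,(C:0.4,D:0.25):0.1);")
  topo <- species_tree(phy, units = "time")
  pm <- ape::cophenetic.phylo(phy)
  fit <- fit_ks_phylogram(topo, pm)
  expect_equal(attr(fit, "residual_norm"), 0, tolerance = 1e-8)
  # all leaf-to-leaf path lengths reproduced
  expect_equal(ape::cophenetic.phylo(fit$phy)[rownames(pm), colnames(pm)], pm,
               tolerance = 1e-8)
  # non-root branches are identified exactly; the root pair only via its sum
  lens <- stats::setNames(fit$phy$edge.length, fit$phy$edge[, 2])
  true_lens <- stats::setNames(phy$edge.length, phy$edge[, 2])
  root_kids <- phy$edge[phy$edge[, 1] == 5, 2]
  for (nd in setdiff(names(true_lens), as.character(root_kids))) {
    expect_equal(lens[[nd]], true_lens[[nd]], tolerance = 1e-8)
  }
  expect_equal(sum(lens[as.character(root_kids)]),
               sum(true_lens[as.character(root_kids)]), tolerance = 1e-8)
})

test_that("noisy matrices are fitted within 10%, matching a grid-search oracle", {
  phy <- ape::read.tree(text = "((A:0.3,B:0.5):0.3,(C:0.4,D:0.6):0.2);")
  topo <- species_tree(phy, units = "time")
  pm0 <- ape::cophenetic.phylo(phy)
  set.seed(91)
  noise <- matrix(1, 4, 4)
  noise[upper.tri(noise)] <- 1 + runif(6, -0.05, 0.05)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  pm <- pm0 * noise
  fit <- fit_ks_phylogram(topo, pm)
  lens <- stats::setNames(fit$phy$edge.length, fit$phy$edge[, 2])
  true_lens <- stats::setNames(phy$edge.length, phy$edge[, 2])
  root_kids <- as.character(phy$edge[phy$edge[, 1] == 5, 2])
  for (nd in setdiff(names(true_lens), root_kids)) {
    expect_equal(lens[[nd]], true_lens[[nd]], tolerance = 0.1)
  }
  # brute-force grid oracle: no non-negative assignment on a grid around the
  # NNLS solution achieves a smaller residual
  resid_of <- function(l) {
    phy2 <- phy
    phy2$edge.length <- l[as.character(phy$edge[, 2])]
    sum((ape::cophenetic.phylo(phy2)[rownames(pm), colnames(pm)] - pm)^2)
  }
  base <- resid_of(lens)
  grid <- expand.grid(d1 = c(-0.04, 0, 0.04), d2 = c(-0.04, 0, 0.04),
                      d3 = c(-0.04, 0, 0.04))
  probe <- setdiff(names(lens), root_kids)[1:3]
  for (r in seq_len(nrow(grid))) {
    l2 <- lens
    l2[probe] <- pmax(l2[probe] + as.numeric(grid[r, ]), 0)
    expect_gte(resid_of(l2), base - 1e-10)
  }
})

test_that("grossly non-additive matrices fit with a warning and clamping", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  topo <- species_tree(phy)
  pm <- matrix(c(0, 0.1, 5, 5, 0.1, 0, 0.1, 5, 5, 0.1, 0, 0.1, 5, 5, 0.1, 0), 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  expect_warning(fit <- fit_ks_phylogram(topo, pm), "residual")
  expect_true(all(fit$phy$edge.length >= 0))
})

test_that("halved peaks walk tipward-to-rootward into the right bracket", {
  # terminal branch 0.3, then a branch spanning [0.3, 0.7)
  phy <- ape::read.tree(text = "((A:0.3,B:0.3):0.4,C:0.9);")
  ph <- species_tree(phy, units = "Ks")
  p1 <- place_halved_peak(ph, "A", 0.4)   # half 0.2 -> terminal branch
  expect_equal(p1$leafset, "A")
  expect_equal(p1$bracket, c(0, 0.3))
  expect_false(p1$overflow)

  p2 <- place_halved_peak(ph, "A", 1.0)   # half 0.5 -> second branch
  expect_setequal(p2$leafset, c("A", "B"))
  expect_equal(p2$bracket, c(0.3, 0.7))

  # an exact boundary goes to the rootward branch
  p3 <- place_halved_peak(ph, "A", 0.6)
  expect_setequal(p3$leafset, c("A", "B"))

  # overflow beyond the root
  p4 <- place_halved_peak(ph, "A", 10)
  expect_true(p4$overflow)
  expect_true(is.na(p4$node))
  expect_error(place_halved_peak(ph, "Z", 1), "unknown species")
})

test_that("trio correction is exact on additive inputs and clamps negatives", {
  # equal rates: identity
  expect_equal(trio_correct(1.0, 1.6, 1.6), 1.0)
  # direct substitution
  expect_equal(trio_correct(1.0, 1.5, 1.1), 1.4)
  # clamping
  expect_warning(v <- trio_correct(0.2, 0.5, 1.0), "clamped")
  expect_equal(v, 0)
  expect_error(trio_correct(NA, 1, 1), "finite")

  # exactness for arbitrary rate multipliers on a noise-free trio
  bF <- 0.23; bS <- 0.71; bO <- 1.38
  expect_equal(trio_correct(bF + bS, bF + bO, bS + bO), 2 * bF, tolerance = 1e-12)
})

test_that("consensus divergences enumerate nearest-first trios and truncate", {
  phy <- ape::read.tree(text = "(((F:1,S:1):1,(O1:1.5,O2:1.5):0.5):1,O3:3);")
  tree <- species_tree(phy)
  pm <- ape::cophenetic.phylo(phy)
  # the deepest divergence (with O3) has no species beyond it to serve as an
  # outgroup, so only the two inner divergences can be corrected
  expect_warning(cd <- consensus_divergences("F", tree, pm), "no valid outgroup")
  expect_equal(nrow(cd), 2)
  expect_equal(cd$consensus, c(2, 4), tolerance = 1e-9)
  expect_equal(cd$n_trios, c(3, 2))
  suppressWarnings(cd1 <- consensus_divergences("F", tree, pm, max_trios = 1))
  expect_equal(cd1$n_trios, c(1, 1))
})

test_that("consensus correction recovers focal-scale divergences for a slow clade", {
  # F's terminal branch evolves at 0.4 x the rate of every other branch:
  # rescale that edge of the time tree to get an additive Ks matrix
  phy <- ape::read.tree(text = "(((F:1,S:1):1,(O1:1.5,O2:1.5):0.5):1,O3:3);")
  tree <- species_tree(phy)
  ks_phy <- phy
  f_edge <- which(ks_phy$edge[, 2] == match("F", ks_phy$tip.label))
  ks_phy$edge.length[f_edge] <- 0.4 * ks_phy$edge.length[f_edge]
  pm <- ape::cophenetic.phylo(ks_phy)
  suppressWarnings(cd <- consensus_divergences("F", tree, pm))
  # focal-scale truth: twice F's Ks path length back to each divergence
  expect_equal(cd$consensus, 2 * c(0.4, 1.4), tolerance = 1e-9)
  # the uncorrected view underestimates the first divergence (slow focal tip)
  raw <- raw_divergences("F", tree, pm)
  expect_lt(raw$consensus[1], 2 * 1)
})

test_that("peaks rank correctly among corrected divergences", {
  div <- data.frame(node = c(9L, 8L, 7L), below = c(1L, 9L, 8L),
                    consensus = c(0.5, 1.2, 2.0), sd = c(0.05, 0.1, 0.1),
                    n_trios = 3)
  r1 <- rank_peak_vs_divergences(0.8, div)
  expect_equal(r1$node, 9L)            # between 0.5 and 1.2
  expect_false(r1$root_stem)
  expect_true(is.na(r1$at_speciation))

  r2 <- rank_peak_vs_divergences(0.52, div)
  expect_equal(r2$at_speciation, 9L)   # within one sd of 0.5

  r3 <- rank_peak_vs_divergences(5, div)
  expect_true(r3$root_stem)
  expect_error(rank_peak_vs_divergences(1, div[0, ]), "at least one")
})

test_that("KDE ortholog peak estimation locates the distribution mode", {
  set.seed(92)
  ks <- rlnorm(500, log(1.1), 0.2)
  est <- ortholog_peak(ks, n_boot = 50)
  expect_equal(est$peak, 1.1, tolerance = 0.12)
  expect_gt(est$sd, 0)
  expect_error(ortholog_peak(ks[1:5]), "too few")
})
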