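test_that("degenerate simulations reproduce the deterministic limits", {
  tr <- tree3()
  # no events possible: one gene per species, tree congruent
  m0 <- sim_model(tr, lambda = 0, mu = 0, eta = 1, p_miss = 0)
  fam <- simulate_family(m0, seed = 1)
  expect_equal(sort(fam$family$genes$species_id), c("A", "B", "C"))
  expect_equal(fam$n_root, 1L)
  expect_length(fam$deleted, 0)

  # deterministic doubling below a certain WGD
  tr2 <- add_wgd(tr, "w1", c("A", "B"), 0.5)
  m1 <- sim_model(tr2, lambda = 0, mu = 0, q = c(w1 = 1), eta = 1, p_miss = 0)
  fam <- simulate_family(m1, seed = 1)
  counts <- table(fam$family$genes$species_id)
  expect_equal(as.integer(counts[c("A", "B", "C")]), c(2L, 2L, 1L))
})

test_that("birth-death moments match the linear-BDP closed forms", {
  # single informative branch: 2-leaf tree with a zero-length sister branch
  lam <- 0.3; mu <- 0.1; t <- 1
  tr <- species_tree(ape::read.tree(text = sprintf("(A:%g,B:0):0;", t)))
  m <- sim_model(tr, lambda = c(`1` = lam, `2` = 0), mu = c(`1` = mu, `2` = 0),
                 eta = 1, p_miss = 0)
  set.seed(99)
  n_rep <- 4000
  counts <- vapply(seq_len(n_rep), function(i) {
    f <- simulate_family(m)
    sum(f$family$genes$species_id == "A") + sum(grepl("^A", f$deleted))
  }, numeric(1))
  m_theory <- exp((lam - mu) * t)
  v_theory <- (lam + mu) / (lam - mu) * (exp(2 * (lam - mu) * t) - exp((lam - mu) * t))
  expect_equal(mean(counts), m_theory, tolerance = 4 * sqrt(v_theory / n_rep) / m_theory)
  expect_equal(var(counts), v_theory, tolerance = 0.15)
})

test_that("same seed gives bit-identical families and every gene is accounted for", {
  tr <- add_wgd(tree6(), "w1", c("A", "B", "C"), 0.5)
  m <- sim_model(tr, lambda = 0.3, mu = 0.25, q = c(w1 = 0.5), eta = 0.7, p_miss = 0.2)
  f1 <- simulate_family(m, seed = 123)
  f2 <- simulate_family(m, seed = 123)
  expect_identical(f1, f2)
  # conservation: observed genes + deleted genes = leaves of the true tree
  leaves <- vapply(wgdcompass:::collect_leaves(f1$tree), `[[`, character(1), "gene_id")
  expect_setequal(leaves, c(f1$family$genes$gene_id, f1$deleted))
})

test_that("missingness acts as binomial thinning of the complete profiles", {
  tr <- tree3()
  p_miss <- 0.2
  m_full <- sim_model(tr, lambda = 0.2, mu = 0.2, eta = 0.75, p_miss = 0)
  m_thin <- sim_model(tr, lambda = 0.2, mu = 0.2, eta = 0.75, p_miss = p_miss)
  set.seed(7)
  n <- 1500
  tot_full <- sum(vapply(seq_len(n), function(i) nrow(simulate_family(m_full)$family$genes), numeric(1)))
  set.seed(7)
  tot_thin <- sum(vapply(seq_len(n), function(i) nrow(simulate_family(m_thin)$family$genes), numeric(1)))
  # same RNG stream start, but the thinning draw changes downstream draws, so
  # compare marginal means: E[thinned] = (1 - p_miss) E[full]
  expect_equal(tot_thin / tot_full, 1 - p_miss, tolerance = 0.1)
})

test_that("Ks emission follows the rate-weighted paths of the species tree", {
  tr <- tree3()
  # clock: ortholog Ks = 2 x divergence time
  m <- sim_model(tr, lambda = 0, mu = 0, eta = 1, rho = 1, ks_sigma = 0, p_miss = 0)
  fam <- simulate_family(m, seed = 5)
  ks <- emit_ks(fam, m, seed = 5)
  ab <- ks[ks$species_a %in% c("A", "B") & ks$species_b %in% c("A", "B"), ]
  expect_equal(ab$ks, 2 * 1)
  withc <- ks[ks$species_a == "C" | ks$species_b == "C", ]
  expect_equal(withc$ks, rep(2 * 2, 2))

  # one slow branch shrinks the ortholog distance to the outgroup
  rho <- stats::setNames(rep(1, 4), as.character(tr$phy$edge[, 2]))
  rho[as.character(match("A", tr$phy$tip.label))] <- 0.4
  m2 <- sim_model(tr, lambda = 0, mu = 0, eta = 1, rho = rho, ks_sigma = 0, p_miss = 0)
  fam2 <- simulate_family(m2, seed = 6)
  ks2 <- emit_ks(fam2, m2)
  d_ac <- ks2$ks[(ks2$species_a == "A" & ks2$species_b == "C") |
                 (ks2$species_a == "C" & ks2$species_b == "A")]
  d_bc <- ks2$ks[(ks2$species_a == "B" & ks2$species_b == "C") |
                 (ks2$species_a == "C" & ks2$species_b == "B")]
  expect_lt(d_ac, d_bc)

  # WGD-retained pairs in a descendant sit exactly at 2 x event age
  tr3 <- add_wgd(tree3(), "w1", c("A", "B"), 0.5)  # event 1.5 before present
  m3 <- sim_model(tr3, lambda = 0, mu = 0, q = c(w1 = 1), eta = 1,
                  ks_sigma = 0, p_miss = 0)
  fam3 <- simulate_family(m3, seed = 7)
  ks3 <- emit_ks(fam3, m3)
  wgd_pairs <- ks3[ks3$event == "wgd", ]
  expect_gt(nrow(wgd_pairs), 0)
  expect_equal(wgd_pairs$ks, rep(2 * 1.5, nrow(wgd_pairs)))
})

test_that("tree perturbation yields the requested sample structure", {
  # canonical key of a rooted topology: the sorted set of its clades
  topo_key <- function(x) {
    pp <- ape::prop.part(x)
    labs <- attr(pp, "labels")
    paste(sort(vapply(pp, function(p) paste(sort(labs[p]), collapse = "+"),
                      character(1))), collapse = "|")
  }
  tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  same <- perturb_tree_sample(tr, 100, error_rate = 0, seed = 1)
  expect_length(same, 100)
  expect_true(all(vapply(same, topo_key, character(1)) == topo_key(tr)))

  perturbed <- perturb_tree_sample(tr, 600, error_rate = 0.5, seed = 2)
  keys <- vapply(perturbed, topo_key, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  # the true topology is the modal topology of the sample
  expect_equal(names(tab)[1], topo_key(tr))
  expect_error(perturb_tree_sample(tr, 0, 0.1), "n must be")
  expect_error(perturb_tree_sample(tr, 10, 1.2), "error_rate")
})

test_that("codon-pair generator hits its target synonymous divergence", {
  p0 <- emit_codon_pair(0, 50, seed = 1)
  expect_identical(p0$cds1, p0$cds2)
  expect_false(p0$warn_saturated)
  expect_error(emit_codon_pair(0.5, 0), "at least one codon")
  expect_true(emit_codon_pair(6, 50, seed = 1)$warn_saturated)

  ks_hat <- vapply(seq_len(200), function(i) {
    p <- emit_codon_pair(0.5, 500, seed = 1000 + i)
    ng86_distance(p$cds1, p$cds2)$ks
  }, numeric(1))
  expect_equal(mean(ks_hat), 0.5, tolerance = 0.05)
})
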