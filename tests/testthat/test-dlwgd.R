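test_that("the no-event limit gives exactly the conditioned geometric mass", {
  tr <- tree3()
  ccd <- ccd_from_newick("((A__g1,B__g1),C__g1);")
  prep <- dlwgd_prepare(tr, list(ccd), p_obs = 1)
  ll <- dlwgd_loglik(prep, lambda = 1e-12, mu = 1e-12, eta = 0.6)
  expect_equal(ll, log(0.6), tolerance = 1e-9)
})

test_that("a certain WGD makes the doubled congruent family the modal profile", {
  tr <- add_wgd(tree3(), "w1", c("A", "B"), 0.5)
  profiles <- list(
    doubled = "(((A__g1,B__g1),(A__g2,B__g2)),C__g1);",
    single  = "((A__g1,B__g1),C__g1);",
    a_only  = "(((A__g1,B__g1),A__g2),C__g1);",
    b_only  = "(((A__g1,B__g1),B__g2),C__g1);")
  lls <- vapply(profiles, function(nwk) {
    prep <- dlwgd_prepare(tr, list(ccd_from_newick(nwk)), p_obs = 1)
    dlwgd_loglik(prep, lambda = 1e-12, mu = 1e-12, eta = 0.6, q = c(w1 = 1))
  }, numeric(1))
  expect_equal(unname(which.max(lls)), 1L)
  expect_equal(lls[["doubled"]], log(0.6), tolerance = 1e-9)
})

test_that("the compiled DP matches the history-integral oracle to 1e-6", {
  # a representative subset (the exhaustive sweep lives in the acceptance
  # tests): 3-taxon with asymmetric rates + missing data, and a 4-taxon
  # balanced tree with two WGDs and a mixed-topology CCD
  tr <- tree3()
  ccd <- ccd_from_newick("((A__g1,A__g2),C__g1);")
  prep <- dlwgd_prepare(tr, list(ccd), p_obs = 0.8)
  ll <- dlwgd_loglik(prep, lambda = 0.25, mu = 0.15, eta = 0.7)
  ll_o <- oracle_loglik(tr, ccd, 0.25, 0.15, 0.7, p_obs = 0.8)
  expect_equal(ll, ll_o, tolerance = 1e-6)

  tr4 <- species_tree(ape::read.tree(text = "((A:1,B:1):0.8,(C:0.9,D:0.9):0.9);"))
  tr4 <- add_wgd(tr4, "w1", c("A", "B"), 0.3)
  tr4 <- add_wgd(tr4, "w2", c("C", "D"), 0.7)
  g1 <- ape::read.tree(text = "(((A__g1,B__g1),(A__g2,B__g2)),(C__g1,D__g1));")
  g2 <- ape::read.tree(text = "(((A__g1,B__g1),A__g2),(B__g2,(C__g1,D__g1)));")
  ccd4 <- build_ccd(c(rep(list(g1), 8), rep(list(g2), 4)), burn_in = 2)
  prep4 <- dlwgd_prepare(tr4, list(ccd4), p_obs = 0.9)
  ll4 <- dlwgd_loglik(prep4, lambda = 0.3, mu = 0.2, eta = 0.8,
                      q = c(w1 = 0.5, w2 = 0.2))
  ll4_o <- oracle_loglik(tr4, ccd4, 0.3, 0.2, 0.8, q = c(w1 = 0.5, w2 = 0.2),
                         p_obs = 0.9)
  expect_equal(ll4, ll4_o, tolerance = 1e-6)
})

test_that("halving the integration step changes the loglik by less than 1e-4", {
  tr <- add_wgd(tree6(), "w1", c("A", "B", "C"), 0.5)
  ccd <- ccd_from_newick("(((A__g1,B__g1),(C__g1,C__g2)),((D__g1,E__g1),F__g1));")
  prep <- dlwgd_prepare(tr, list(ccd), p_obs = 0.9)
  ll10 <- dlwgd_loglik(prep, lambda = 0.3, mu = 0.25, eta = 0.7, q = c(w1 = 0.4),
                       steps = 10)
  ll20 <- dlwgd_loglik(prep, lambda = 0.3, mu = 0.25, eta = 0.7, q = c(w1 = 0.4),
                       steps = 20)
  expect_lt(abs(ll10 - ll20), 1e-4)
})

test_that("amalgamation over a two-topology CCD equals the frequency-weighted mixture", {
  # the CCD factorization is exact when the sample holds two topologies
  # differing in a single nested clade
  tr <- tree3()
  g1 <- "(((A__g1,A__g2),B__g1),C__g1);"
  g2 <- "(((A__g1,B__g1),A__g2),C__g1);"
  ccd_mix <- build_ccd(c(rep(list(ape::read.tree(text = g1)), 6),
                         rep(list(ape::read.tree(text = g2)), 4)), burn_in = 0)
  prep_mix <- dlwgd_prepare(tr, list(ccd_mix), p_obs = 1)
  ll_mix <- dlwgd_loglik(prep_mix, lambda = 0.2, mu = 0.2, eta = 0.7)
  ll_1 <- dlwgd_loglik(dlwgd_prepare(tr, list(ccd_from_newick(g1)), p_obs = 1),
                       lambda = 0.2, mu = 0.2, eta = 0.7)
  ll_2 <- dlwgd_loglik(dlwgd_prepare(tr, list(ccd_from_newick(g2)), p_obs = 1),
                       lambda = 0.2, mu = 0.2, eta = 0.7)
  expect_equal(ll_mix, log(0.6 * exp(ll_1) + 0.4 * exp(ll_2)), tolerance = 1e-9)
})

test_that("extinction propagation respects its probabilistic invariants", {
  G <- wgdcompass:::bd_G
  for (lam in c(0, 0.1, 0.5)) for (mu in c(0, 0.1, 0.5)) for (t in c(0.1, 1, 5)) {
    eps <- G(seq(0, 1, 0.1), lam, mu, t)
    expect_true(all(eps >= 0 & eps <= 1))
    expect_true(all(diff(eps) >= -1e-12))       # monotone in eps
  }
  # the WGD retention map keeps [0,1] -> [0,1] and is monotone
  wgd_eps <- function(e, q) (1 - q) * e + q * e^2
  e <- seq(0, 1, 0.05)
  for (q in c(0, 0.3, 1)) {
    out <- wgd_eps(e, q)
    expect_true(all(out >= 0 & out <= 1))
    expect_true(all(diff(out) >= 0))
    expect_true(all(out <= e + 1e-12))
  }
})

test_that("per-family diagnostics expose structurally impossible families", {
  tr <- tree3()
  ok <- ccd_from_newick("((A__g1,B__g1),C__g1);")
  # three observed root subtrees cannot be represented: joined artificially,
  # the root clade's nested artificial split spans both root-child clades
  bad <- ccd_from_newick("((C__g1,(A__g1,(B__g1,C__g2))),(A__g2,(B__g2,C__g3)));")
  prep <- dlwgd_prepare(tr, list(ok, bad), p_obs = 1)
  per <- wgdcompass:::dlwgd_loglik_by_family_cpp(
    prep$tree_spec, rep(0.2, 5), rep(0.2, 5), prep$p_obs_tip, 0.7, numeric(0),
    prep$wgd_node, prep$wgd_pos, prep$ccds, 10L)
  expect_true(is.finite(per[1]))
  expect_true(is.infinite(per[2]) && per[2] < 0)
})

test_that("pair divergence posteriors localize duplications correctly", {
  # a pair straddling a certain WGD under zero DL rates
  tr <- add_wgd(tree3(), "w1", c("A", "B"), 0.5)
  ccd <- ccd_from_newick("(((A__g1,B__g1),(A__g2,B__g2)),C__g1);")
  prep <- dlwgd_prepare(tr, list(ccd), p_obs = 1)
  p <- pair_duplication_posterior(prep, c("A__g1", "A__g2"), lambda = 1e-9,
                                  mu = 1e-9, eta = 0.6, q = c(w1 = 1),
                                  nsamples = 50, seed = 1)
  expect_equal(unname(p[["wgd:w1"]]), 1)

  # a species-specific tandem pair concentrates on the terminal branch
  ccd2 <- ccd_from_newick("(((A__g1,A__g2),B__g1),C__g1);")
  prep2 <- dlwgd_prepare(tree3(), list(ccd2), p_obs = 1)
  p2 <- pair_duplication_posterior(prep2, c("A__g1", "A__g2"), lambda = 0.2,
                                   mu = 0.2, eta = 0.6, nsamples = 300, seed = 2)
  expect_equal(sum(p2), 1)
  expect_gt(p2[["dup:1"]], 0.9)
})

test_that("partial re-evaluation with commit equals full recomputation exactly", {
  tree <- add_wgd(tree6(), "w1", c("A", "B", "C"), 0.5)
  m <- sim_model(tree, lambda = 0.25, mu = 0.2, q = c(w1 = 0.4), eta = 0.75,
                 p_miss = 0.2)
  sims <- simulate_kept_families(m, tree6(), 15, seed = 314)
  prep <- dlwgd_prepare(tree, ccds_from_sims(sims), p_obs = 0.8)
  ts <- prep$tree_spec
  branch_nodes <- setdiff(seq_len(ts$n), ts$root)
  mptr <- wgdcompass:::dlwgd_build_cpp(ts, prep$wgd_node, prep$wgd_pos,
                                       prep$ccds, prep$mult, prep$p_obs_tip)
  full_eval <- function(lam, mu, eta, q) {
    lv <- numeric(ts$n); lv[branch_nodes] <- lam
    mv <- numeric(ts$n); mv[branch_nodes] <- mu
    wgdcompass:::dlwgd_loglik_cpp(ts, lv, mv, prep$p_obs_tip, eta, q,
                                  prep$wgd_node, prep$wgd_pos, prep$ccds,
                                  prep$mult, 6L)
  }
  part_eval <- function(lam, mu, eta, q, changed) {
    lv <- numeric(ts$n); lv[branch_nodes] <- lam
    mv <- numeric(ts$n); mv[branch_nodes] <- mu
    wgdcompass:::dlwgd_eval_cpp(mptr, lv, mv, eta, q, 6L, as.integer(changed))
  }
  set.seed(9)
  lam <- rep(0.25, length(branch_nodes)); mu <- rep(0.2, length(branch_nodes))
  eta <- 0.75; q <- 0.4
  part_eval(lam, mu, eta, q, integer(0))
  wgdcompass:::dlwgd_commit_cpp(mptr)
  for (i in 1:60) {
    kind <- sample(c("branch", "eta", "q", "all"), 1)
    lam_p <- lam; mu_p <- mu; eta_p <- eta; q_p <- q; changed <- integer(0)
    if (kind == "branch") {
      b <- sample(length(branch_nodes), 1)
      lam_p[b] <- lam[b] * exp(rnorm(1, 0, 0.3)); mu_p[b] <- lam_p[b]
      changed <- branch_nodes[b]
    } else if (kind == "eta") { eta_p <- runif(1, 0.4, 0.95); changed <- ts$root
    } else if (kind == "q") { q_p <- runif(1); changed <- prep$wgd_node[1]
    } else { lam_p <- lam * exp(rnorm(length(lam), 0, 0.2)); mu_p <- lam_p }
    expect_identical(part_eval(lam_p, mu_p, eta_p, q_p, changed),
                     full_eval(lam_p, mu_p, eta_p, q_p))
    if (runif(1) < 0.5) {
      lam <- lam_p; mu <- mu_p; eta <- eta_p; q <- q_p
      wgdcompass:::dlwgd_commit_cpp(mptr)
    }
  }
})
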