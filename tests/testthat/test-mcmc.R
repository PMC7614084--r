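test_that("family filtering applies the size and root-ancestry rules", {
  tr <- tree3()
  fams <- list(
    gene_family("both", c("A__g1", "C__g1"), c("A", "C")),
    gene_family("one_side", c("A__g1", "B__g1", "A__g2"), c("A", "B", "A")),
    gene_family("big", paste0("A__g", 1:4), rep("A", 4)))
  out <- filter_families(fams, tr, max_size = 3)
  expect_equal(vapply(out$kept, function(f) f$family_id, character(1)), "both")
  expect_setequal(out$log$reason, c("no common ancestor at the root", "too large"))
})

test_that("ESS matches closed forms for iid and AR(1) chains", {
  set.seed(101)
  x <- rnorm(10000)
  expect_equal(ess(x), 10000, tolerance = 0.1)

  rho <- 0.5
  ar <- numeric(10000)
  for (i in 2:10000) ar[i] <- rho * ar[i - 1] + rnorm(1)
  expect_equal(ess(ar), 10000 * (1 - rho) / (1 + rho), tolerance = 0.15)

  expect_warning(e1 <- ess(rep(1, 100)), "constant chain")
  expect_equal(e1, 1)
  expect_error(ess(1:5), "at least 10")
})

test_that("Savage-Dickey density ratios and verdicts behave at the boundary", {
  # uniform draws reproduce the prior: K ~ 1
  set.seed(102)
  chain <- structure(list(draws = data.frame(q.w = runif(20000))),
                     class = "rates_chain")
  bf <- savage_dickey(chain, "w")
  expect_equal(bf$K, 1, tolerance = 0.1)
  expect_equal(bf$q_mean, 0.5, tolerance = 0.02)
  expect_equal(bf$verdict, bf_verdict(bf$K))

  # Beta(1,19) has density 19 at zero: H0 supported
  chain2 <- structure(list(draws = data.frame(q.w = rbeta(20000, 1, 19))),
                      class = "rates_chain")
  bf2 <- savage_dickey(chain2, "w")
  expect_equal(bf2$K, 19, tolerance = 0.25)
  expect_equal(bf2$verdict, "supports H0")
  expect_error(savage_dickey(chain2, "nope"), "no draws")
})

test_that("verdict categories follow the evidence thresholds exactly", {
  expect_equal(bf_verdict(c(0.047, 0.099)), rep("strong against H0", 2))
  expect_equal(bf_verdict(c(0.1, 0.197, 0.316)), rep("substantial against H0", 3))
  expect_equal(bf_verdict(c(10^(-0.5), 0.99)), rep("barely against H0", 2))
  expect_equal(bf_verdict(c(1, 1272.297)), rep("supports H0", 2))
  expect_error(bf_verdict(-1), "positive")
})

test_that("seeded chains are bit-reproducible and report acceptance", {
  tr <- tree3()
  ccds <- list(ccd_from_newick("((A__g1,B__g1),C__g1);"),
               ccd_from_newick("(((A__g1,A__g2),B__g1),C__g1);"))
  prep <- dlwgd_prepare(tr, ccds, p_obs = 1)
  c1 <- mcmc_dlwgd(prep, model = "critical", n_iter = 300, thin = 1, seed = 11,
                   steps = 6)
  c2 <- mcmc_dlwgd(prep, model = "critical", n_iter = 300, thin = 1, seed = 11,
                   steps = 6)
  expect_identical(c1$draws, c2$draws)
  expect_true(all(c1$accept >= 0 & c1$accept <= 1, na.rm = TRUE))
  # critical model: duplication and loss draws coincide
  expect_identical(c1$draws$lambda.1, c1$draws$mu.1)
})

test_that("eta can be held fixed for anchor-style reconciliations", {
  tr <- tree3()
  prep <- dlwgd_prepare(tr, list(ccd_from_newick("((A__g1,B__g1),C__g1);")),
                        p_obs = 1)
  ch <- mcmc_dlwgd(prep, model = "critical", n_iter = 200, thin = 1, seed = 3,
                   eta_fixed = 0.75, steps = 6)
  expect_true(all(ch$draws$eta == 0.75))
})

test_that("a relaxed fit attributes an engineered high-loss branch correctly", {
  # families simulated with strongly elevated loss (and no extra duplication)
  # on C's terminal branch: the relaxed model should recover mu >> lambda there
  tr <- tree3()
  lam <- stats::setNames(c(0.15, 0.15, 0.15, 0.15), c("1", "2", "3", "5"))
  mu <- stats::setNames(c(0.15, 0.15, 1.2, 0.15), c("1", "2", "3", "5"))
  m <- sim_model(tr, lambda = lam, mu = mu, eta = 0.8, p_miss = 0)
  sims <- simulate_kept_families(m, tr, 150, seed = 77)
  prep <- dlwgd_prepare(tr, ccds_from_sims(sims), p_obs = 1)
  ch <- mcmc_dlwgd(prep, model = "relaxed", n_iter = 1200, thin = 2, seed = 5,
                   steps = 6)
  ev <- expected_events(ch, prep)
  c_row <- ev[ev$node == 3, ]
  expect_gt(c_row$mu_mean, 2 * c_row$lambda_mean)
  other_mu <- ev$mu_mean[ev$node != 3]
  expect_gt(c_row$mu_mean, 2 * max(other_mu))
})

test_that("expected events summarize per-branch posteriors", {
  tr <- tree3()
  prep <- dlwgd_prepare(tr, list(ccd_from_newick("((A__g1,B__g1),C__g1);")),
                        p_obs = 1)
  ch <- mcmc_dlwgd(prep, model = "critical", n_iter = 200, thin = 1, seed = 9,
                   steps = 6)
  ev <- expected_events(ch, prep)
  expect_equal(ev$lambda_mean, ev$mu_mean)   # model constraint
  expect_equal(ev$dup_events, ev$lambda_mean * prep$tree_spec$length[ev$node])
})
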