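toy_homologs <- function() {
  data.frame(
    gene_a = c("A__g1", "A__g1", "A__g2", "A__g3"),
    gene_b = c("B__g1", "B__g2", "B__g1", "B__g3"),
    score = c(100, 60, 150, 80))
}

test_that("c-score filtering follows the best-hit normalization", {
  kept <- cscore_filter(toy_homologs(), threshold = 0.5)
  # pair (A1,B1): score 100, best(A1) = 100, best(B1) = 150 -> c = 0.667, kept
  expect_true("A__g1 B__g1" %in% paste(kept$gene_a, kept$gene_b))
  expect_equal(kept$c_score[kept$gene_a == "A__g1" & kept$gene_b == "B__g1"],
               100 / 150)
  # pair (A1,B2): score 60, best(A1) = 100 -> c = 0.6 kept under max-denominator
  # pair (A2,B1): 150/150 = 1; a gene's best pair is always kept
  expect_equal(kept$c_score[kept$gene_a == "A__g2"], 1)
  expect_equal(kept$c_score[kept$gene_a == "A__g3"], 1)

  # min-denominator is stricter here: (A1,B2): 60/min(100,60) = 1
  kept_min <- cscore_filter(toy_homologs(), denominator = "min")
  expect_equal(kept_min$c_score[kept_min$gene_a == "A__g1" & kept_min$gene_b == "B__g2"], 1)

  # dropping: make one pair fall below threshold
  h <- toy_homologs()
  h$score[2] <- 40  # c = 40/100 = 0.4 < 0.5
  kept2 <- cscore_filter(h, threshold = 0.5)
  expect_false("A__g1 B__g2" %in% paste(kept2$gene_a, kept2$gene_b))
})

toy_anchors <- function() {
  data.frame(
    gene_a = c("A__g1", "A__g2", "A__g3", "A__g4"),
    gene_b = c("A__g5", "A__g6", "A__g7", "A__g8"),
    scaffold_a = c("s_small", "s_big1", "s_big1", "s_big1"),
    scaffold_b = c("s_big2", "s_big2", "s_big2", "s_big2"),
    ks = c(0.5, 0.05, 0.5, 1.0),
    family_id = c("f1", "f2", "f3", NA))
}

toy_scaffolds <- c(s_small = 9, s_big1 = 50, s_big2 = 30)

test_that("anchor filters drop short scaffolds and tiny Ks", {
  out <- filter_anchors(toy_anchors(), toy_scaffolds)
  # s_small has 9 (< 10) genes; ks 0.05 < 0.1
  expect_setequal(out$gene_a, c("A__g3", "A__g4"))
  expect_error(filter_anchors(toy_anchors(), toy_scaffolds[-1]), "unknown scaffold")
})

test_that("Ks windows are closed and unassigned anchors are logged", {
  anchors <- data.frame(
    gene_a = c("A__g1", "A__g2", "A__g3", "B__g1"),
    gene_b = c("A__g4", "A__g5", "A__g6", "B__g2"),
    ks = c(0.6, 1.0, 0.5, 1.5),
    family_id = c("f1", "f2", "f3", NA))
  fams <- list(gene_family("f1", c("A__g1", "A__g4", "B__g9"), c("A", "A", "B")),
               gene_family("f2", c("A__g2", "A__g5", "B__g8"), c("A", "A", "B")),
               gene_family("f3", c("A__g3", "A__g6"), c("A", "A")))
  sel <- select_wgd_anchor_families(anchors, fams,
                                    list(A = c(0.6, 1.2), B = c(1.0, 1.9)))
  # boundary 0.6 kept (closed interval); 0.5 excluded; NA-family logged
  expect_setequal(sel$anchors$gene_a, c("A__g1", "A__g2"))
  expect_equal(sel$unassigned, 1)
  expect_equal(as.integer(sel$counts[["A"]]), 2L)
  expect_setequal(vapply(sel$families, function(f) f$family_id, character(1)),
                  c("f1", "f2"))
})

test_that("the three filters commute", {
  set.seed(111)
  n <- 60
  anchors <- data.frame(
    gene_a = sprintf("A__g%d", 1:n), gene_b = sprintf("A__h%d", 1:n),
    scaffold_a = sample(names(toy_scaffolds), n, replace = TRUE),
    scaffold_b = sample(names(toy_scaffolds), n, replace = TRUE),
    ks = round(runif(n, 0, 2), 2),
    family_id = sprintf("f%d", 1:n))
  fams <- lapply(seq_len(n), function(i) {
    gene_family(sprintf("f%d", i), c(anchors$gene_a[i], anchors$gene_b[i]), c("A", "A"))
  })
  win <- list(A = c(0.6, 1.2))
  f_scaffold <- function(a) filter_anchors(a, toy_scaffolds)
  f_window <- function(a) select_wgd_anchor_families(a, fams, win)$anchors
  r1 <- f_window(f_scaffold(anchors))
  r2 <- f_scaffold(f_window(anchors))
  expect_setequal(paste(r1$gene_a, r1$gene_b), paste(r2$gene_a, r2$gene_b))
})

test_that("anchor reconciliation configs fix eta and carry no WGDs", {
  fams <- list(gene_family("f1", c("A__g1", "A__g2"), c("A", "A")))
  cfg <- anchor_reconciliation_config(list(families = fams))
  expect_equal(cfg$eta_fixed, 0.75)
  expect_equal(nrow(cfg$wgd), 0)
  cfg2 <- anchor_reconciliation_config(fams, eta = 0.9)
  expect_equal(cfg2$eta_fixed, 0.9)
  expect_error(anchor_reconciliation_config(list()), "no anchor families")
})

test_that("the packaged verdict reference classifies by threshold exactly", {
  path <- system.file("extdata", "wgd_bayes_factor_reference.tsv",
                      package = "wgdcompass")
  ref <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(ref), 16)
  expect_equal(bf_verdict(ref$K), ref$verdict)
})
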