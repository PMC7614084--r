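test_that("duplication-node weighting splits weight across joined pairs", {
  # two recent duplicates and one older gene: the old node joins two pairs
  pairs <- data.frame(gene_a = c("g1", "g1", "g2"),
                      gene_b = c("g2", "g3", "g3"),
                      ks = c(0.1, 0.9, 1.0))
  w <- weight_family_pairs(pairs)
  expect_equal(w$weight[w$gene_a == "g1" & w$gene_b == "g2"], 1)
  expect_equal(w$weight[w$gene_b == "g3"], c(0.5, 0.5))
  expect_equal(sum(w$weight), 2)  # = number of duplication nodes

  # a pair family keeps weight 1
  p2 <- weight_family_pairs(data.frame(gene_a = "a", gene_b = "b", ks = 0.4))
  expect_equal(p2$weight, 1)
})

test_that("paranome weights sum to the number of duplication nodes", {
  set.seed(41)
  for (n_genes in c(4, 6, 9)) {
    genes <- paste0("g", seq_len(n_genes))
    combs <- t(combn(genes, 2))
    pairs <- data.frame(gene_a = combs[, 1], gene_b = combs[, 2],
                        ks = runif(nrow(combs), 0.05, 3))
    w <- weight_family_pairs(pairs)
    expect_equal(sum(w$weight), n_genes - 1)
    expect_true(all(w$weight > 0 & w$weight <= 1))
  }
})

test_that("paranome distributions are built from sequences with filtering", {
  # family of three: two recent duplicates, one older
  anc <- emit_codon_pair(0.15, 120, seed = 51)
  old <- emit_codon_pair(1.6, 120, seed = 52)
  fam <- gene_family("f1", c("A__g1", "A__g2", "A__g3"), rep("A", 3),
                     seqs = c(A__g1 = anc$cds1, A__g2 = anc$cds2, A__g3 = old$cds2))
  dist <- build_paranome_distribution(list(fam), ceiling = 5)
  expect_s3_class(dist, "ks_distribution")
  expect_equal(nrow(dist), 3)
  expect_equal(sum(dist$weight), 2)

  # families of one gene contribute nothing
  f1 <- gene_family("f2", "A__g9", "A", seqs = c(A__g9 = anc$cds1))
  expect_equal(nrow(build_paranome_distribution(list(f1), species = "A")), 0)

  # cross-species families are rejected
  bad <- gene_family("f3", c("A__g1", "B__g1"), c("A", "B"),
                     seqs = c(A__g1 = anc$cds1, B__g1 = anc$cds2))
  expect_error(build_paranome_distribution(list(bad)), "single-species")
})

test_that("saturated and above-ceiling pairs are dropped with a warning", {
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      ks = c(NA, 7), weight = 1)
  expect_warning(d <- ks_distribution(pairs, "paranome", "A", ceiling = 5),
                 "dropped")
  expect_equal(nrow(d), 0)
})

test_that("reciprocal-best-hit pairing excludes asymmetric best hits", {
  scores <- data.frame(
    gene_a = c("a1", "a1", "a2", "a2", "a3"),
    gene_b = c("b1", "b2", "b1", "b2", "b3"),
    score = c(90, 40, 100, 60, 80))
  # a1's best is b1, but b1's best is a2 -> a1 excluded; (a2,b1) and (a3,b3) kept
  rbh <- reciprocal_best_hits(scores)
  expect_equal(nrow(rbh), 2)
  expect_true(all(paste(rbh$gene_a, rbh$gene_b) %in% c("a2 b1", "a3 b3")))

  seqs <- c(a2 = emit_codon_pair(0.8, 100, seed = 61)$cds1,
            b1 = emit_codon_pair(0.8, 100, seed = 61)$cds2,
            a3 = emit_codon_pair(0.3, 100, seed = 62)$cds1,
            b3 = emit_codon_pair(0.3, 100, seed = 62)$cds2)
  d <- build_ortholog_distribution(scores[scores$gene_a %in% c("a2", "a3"), ],
                                   seqs, species = c("A", "B"))
  expect_equal(nrow(d), 2)
  expect_equal(d$weight, c(1, 1))
  expect_warning(build_ortholog_distribution(scores[0, ], seqs), "no reciprocal")
})
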