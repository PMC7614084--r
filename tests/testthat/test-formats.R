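test_that("species trees parse, validate, and accept WGD marks by leaf set", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tr <- read_species_tree(path, units = "time")
  expect_equal(ape::Ntip(tr$phy), 3)
  expect_equal(nrow(tr$wgd), 0)

  cfg <- list(wgd1 = list(leaves = list("A", "B"), position = 0.5))
  tr2 <- read_species_tree(path, units = "time", wgd_config = cfg)
  expect_equal(nrow(tr2$wgd), 1)
  expect_equal(tr2$wgd$node, ape::getMRCA(tr2$phy, c("A", "B")))
  expect_equal(tr2$wgd$pos, 0.5)

  # a non-clade leaf set is rejected
  expect_error(add_wgd(tr, "bad", c("A", "C")), "not a clade")
  # the root has no branch above it
  expect_error(add_wgd(tr, "bad", c("A", "B", "C")), "root")
  expect_error(read_species_tree(path, wgd_config = list(w = list(leaves = list("A", "Z")))),
               "unknown species")
})

test_that("branch identification is invariant under leaf-order permutation", {
  t1 <- species_tree(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  t2 <- species_tree(ape::read.tree(text = "((D:1,C:1):1,(B:1,A:1):1);"))
  for (set in list(c("A", "B"), c("C", "D"), "A")) {
    expect_setequal(branch_leafset(t1, branch_by_leafset(t1, set)),
                    branch_leafset(t2, branch_by_leafset(t2, set)))
  }
})

test_that("species tree round-trips through newick plus YAML sidecar", {
  tr <- add_wgd(tree3(), "wgd1", c("A", "B"), 0.25)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_species_tree(tr, nwk, wgd_config_path = yml)
  tr2 <- read_species_tree(nwk, units = "time", wgd_config = yml)
  expect_equal(sort(tr2$phy$tip.label), sort(tr$phy$tip.label))
  expect_equal(tr2$wgd$pos, 0.25)
  expect_setequal(branch_leafset(tr2, tr2$wgd$node), c("A", "B"))
})

test_that("family tables read, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tgene_id\tspecies_id",
               "f1\tA__g1\tA", "f1\tB__g1\tB", "f2\tC__g1\tC"), path)
  fams <- read_family_table(path)
  expect_length(fams, 2)
  expect_equal(fams[["f1"]]$genes$gene_id, c("A__g1", "B__g1"))

  # empty file with header
  writeLines("family_id\tgene_id\tspecies_id", path)
  expect_length(read_family_table(path), 0)

  # unknown species when a species list is supplied
  writeLines(c("family_id\tgene_id\tspecies_id", "f1\tX__g1\tX"), path)
  expect_error(read_family_table(path, species = c("A", "B")), "unknown species")
  # missing column
  writeLines(c("family_id\tgene_id", "f1\tg1"), path)
  expect_error(read_family_table(path), "missing column")

  out <- withr::local_tempfile(fileext = ".tsv")
  fams <- list(gene_family("f1", c("A__g1", "B__g1"), c("A", "B")))
  write_family_table(fams, out)
  back <- read_family_table(out)
  expect_equal(back[["f1"]]$genes, fams[[1]]$genes)
})

test_that("duplicate gene ids within a family are rejected", {
  expect_error(gene_family("f1", c("g1", "g1"), c("A", "A")), "duplicate gene_id")
})

test_that("anchor tables round-trip losslessly and validate Ks", {
  anchors <- data.frame(gene_a = paste0("A__g", 1:5), gene_b = paste0("A__h", 1:5),
                        scaffold_a = "s1", scaffold_b = "s2",
                        ks = c(0.1, 0.5, 1.2, 2.3, 0.05),
                        family_id = c("f1", "f1", "f2", NA, "f3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_anchor_table(anchors, path)
  back <- read_anchor_table(path)
  expect_equal(back$ks, anchors$ks)
  expect_equal(back$gene_a, anchors$gene_a)

  bad <- anchors; bad$ks[1] <- -0.2
  write_anchor_table(bad, path)
  expect_error(read_anchor_table(path), "negative Ks")
})

test_that("tree samples report malformed lines by number", {
  path <- withr::local_tempfile(fileext = ".nwk")
  good <- "((A__g1,B__g1),C__g1);"
  writeLines(c(good, "((A__g1,B__g1,C__g1;", good, "not a tree"), path)
  expect_error(read_tree_sample(path), "line\\(s\\): 2, 4")
  writeLines(rep(good, 5), path)
  expect_length(read_tree_sample(path), 5)
})

test_that("Bayes-factor reports serialize with the hypothesis/q/K/verdict layout", {
  res <- data.frame(wgd_id = c("wgd1", "wgd2"), q_mean = c(0.35, 0.01),
                    K = c(0.047, 12.9),
                    verdict = c("strong against H0", "supports H0"),
                    model = "relaxed")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(res, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("wgd_id", "q_mean", "K", "verdict", "model"))
  expect_equal(back$K, res$K)
  expect_error(write_report(res[, 1:2], path), "report needs columns")
})
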