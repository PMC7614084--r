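# Shared fixture builders for the test suite (all generated in code).

tree3 <- function() {
  species_tree(ape::read.tree(text = "((A:1,B:1):1,C:2);"), units = "time")
}

tree6 <- function() {
  species_tree(ape::read.tree(
    text = "((((A:0.3,B:0.3):0.3,C:0.6):0.4,(D:0.5,E:0.5):0.5):0.3,F:1.3);"),
    units = "time")
}

# point-mass CCD from one newick string
ccd_from_newick <- function(nwk, n = 11, burn_in = 1) {
  build_ccd(rep(list(ape::read.tree(text = nwk)), n), burn_in = burn_in)
}

# simulate `n` families that pass the reconciliation filters (root-clade
# content, size cap, and representable root-subtree count)
simulate_kept_families <- function(model, tree, n, seed, max_size = 50,
                                   max_attempts = 40 * n) {
  out <- list()
  i <- 0
  seeds <- (as.integer(seed) + 77777L * seq_len(max_attempts)) %% 2000000011L
  while (length(out) < n && i < max_attempts) {
    i <- i + 1
    s <- simulate_family(model, sprintf("fam%05d", i), seed = seeds[i])
    if (nrow(s$family$genes) < 2 || nrow(s$family$genes) > max_size) next
    if (n_root_subtrees(s) > 2) next
    filt <- filter_families(list(s$family), tree, max_size = max_size)
    if (length(filt$kept) == 1) out[[length(out) + 1L]] <- s
  }
  stopifnot(length(out) == n)
  out
}

# point-mass CCDs from the observed gene trees of simulated families
ccds_from_sims <- function(sims) {
  lapply(sims, function(s) {
    build_ccd(rep(list(observed_gene_tree(s)), 3), burn_in = 1,
              family_id = s$family$family_id)
  })
}
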