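#' Forward model for gene-family evolution with WGDs
#'
#' Bundles everything the simulator needs: a species tree in time units,
#' per-branch duplication/loss rates of the linear birth-death process,
#' per-WGD retention probabilities, the geometric root-size parameter, and the
#' lineage-specific substitution-rate multipliers that turn divergence times
#' into Ks values.
#'
#' @param tree a [species_tree()] in time units.
#' @param lambda per-branch duplication rate; scalar or vector named by the
#'   branch's tipward node id (events per gene per time unit).
#' @param mu per-branch loss rate (same shape as `lambda`).
#' @param q named vector of retention probabilities, one per WGD mark on
#'   `tree` (names = wgd ids).
#' @param eta parameter of the geometric prior on the number of genes at the
#'   root, support \{1, 2, ...\} (a family must have existed at the root);
#'   mean family size at the root is `1/eta`.
#' @param rho per-branch synonymous substitution-rate multiplier (Ks per time
#'   unit); scalar or vector named by tipward node id.
#' @param ks_sigma lognormal sigma of the multiplicative Ks noise
#'   (median-unbiased; default 0.1).
#' @param p_miss per-species missing-gene fraction (BUSCO-style); scalar or
#'   vector named by species.
#' @return object of class `sim_model`.
#' @export
sim_model <- function(tree, lambda = 0.2, mu = 0.2, q = NULL, eta = 0.75,
                      rho = 1, ks_sigma = 0.1, p_miss = 0) {
  assert_that(inherits(tree, "species_tree"), "tree must be a species_tree")
  assert_that(tree$units == "time", "simulation needs a species tree in time units")
  phy <- tree$phy
  branch_nodes <- phy$edge[, 2L]
  expand_branch <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(branch_nodes)), as.character(branch_nodes))
    }
    assert_that(all(as.character(branch_nodes) %in% names(x)),
                "%s must cover every branch (named by tipward node id)", what)
    x[as.character(branch_nodes)]
  }
  lambda <- expand_branch(lambda, "lambda")
  mu <- expand_branch(mu, "mu")
  rho <- expand_branch(rho, "rho")
  assert_that(all(lambda >= 0) && all(mu >= 0), "rates must be non-negative")
  assert_that(all(rho > 0), "rate multipliers must be positive")
  assert_that(is_prob(eta) && eta > 0, "eta must lie in (0,1]")
  if (is.null(q)) q <- stats::setNames(numeric(0), character(0))
  if (nrow(tree$wgd) > 0) {
    assert_that(all(tree$wgd$wgd_id %in% names(q)),
                "q must be supplied for every WGD mark")
    assert_that(is_prob(q), "q must lie in [0,1]")
  }
  if (length(p_miss) == 1L && is.null(names(p_miss))) {
    p_miss <- stats::setNames(rep(p_miss, ape::Ntip(phy)), phy$tip.label)
  }
  assert_that(all(phy$tip.label %in% names(p_miss)), "p_miss must cover every species")
  assert_that(is_prob(p_miss), "p_miss must lie in [0,1]")
  assert_that(ks_sigma >= 0, "ks_sigma must be non-negative")
  structure(list(tree = tree, lambda = lambda, mu = mu, q = q, eta = eta,
                 rho = rho, ks_sigma = ks_sigma, p_miss = p_miss[phy$tip.label]),
            class = "sim_model")
}

## internal: per-model cached geometry
sim_geometry <- function(model) {
  phy <- model$tree$phy
  depth <- node_depths(phy)
  par <- tree_parents(phy)
  len <- branch_lengths_above(phy)
  # rate-scaled depth from root (integral of rho along the root path)
  rdepth <- rep(NA_real_, length(depth))
  rdepth[ape::Ntip(phy) + 1L] <- 0
  for (nd in preorder_nodes(phy)) {
    if (!is.na(par[nd])) {
      rdepth[nd] <- rdepth[par[nd]] + model$rho[as.character(nd)] * len[nd]
    }
  }
  # WGD marks per branch, ordered rootward-first (descending absolute time gap)
  wgd <- model$tree$wgd
  marks <- vector("list", length(depth))
  if (nrow(wgd) > 0) {
    for (i in seq_len(nrow(wgd))) {
      nd <- wgd$node[i]
      t_abs <- depth[nd] - wgd$pos[i] * len[nd]   # absolute depth of the mark
      marks[[nd]] <- rbind(marks[[nd]],
                           data.frame(wgd_id = wgd$wgd_id[i], t = t_abs,
                                      stringsAsFactors = FALSE))
    }
    for (nd in seq_along(marks)) {
      if (!is.null(marks[[nd]])) marks[[nd]] <- marks[[nd]][order(marks[[nd]]$t), ]
    }
  }
  list(depth = depth, parent = par, len = len, rdepth = rdepth, marks = marks,
       children = tree_children(phy), ntip = ape::Ntip(phy), phy = phy)
}

#' Simulate one gene family under the DL+WGD model
#'
#' Runs the duplication-loss(+WGD) model forward: the root gene count is drawn
#' from a geometric(eta) prior on \{1,2,...\}; within every branch each lineage
#' independently duplicates at rate lambda_b and dies at rate mu_b (Gillespie
#' event-by-event sampling, so event times are exact and available for Ks
#' emission); at a WGD mark each surviving lineage is retained as two copies
#' with probability q; at a leaf each gene is deleted independently with
#' probability `p_miss` (the missing-gene thinning). All surviving lineages are
#' recorded in a true gene tree whose internal nodes are labelled
#' speciation / duplication / wgd and mapped to species-tree points.
#'
#' @param model a [sim_model()].
#' @param family_id id for the simulated family.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `sim_family`: list with elements `family`
#'   (a [gene_family()] of the observed genes), `deleted` (character vector of
#'   deleted gene ids), `tree` (the labelled true gene tree as a nested list),
#'   and `n_root` (simulated root count).
#' @export
simulate_family <- function(model, family_id = "fam1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- sim_geometry(model)
  counter <- new.env(parent = emptyenv())
  counter$i <- stats::setNames(rep(0L, geo$ntip), geo$phy$tip.label)
  counter$lineages <- 0L

  # simulate a single lineage entering the branch above `node` at absolute
  # time t0; returns a nested node record, or NULL if the lineage leaves no
  # surviving descendant
  sim_branch <- function(node, t0) {
    mk <- geo$marks[[node]]
    if (!is.null(mk)) mk <- mk[mk$t > t0, , drop = FALSE]
    sim_branch_from(node, t0, mk)
  }

  # lineage within the branch above `node`, from absolute time t0, with the
  # remaining WGD checkpoints in mk_left (ordered rootward-first)
  sim_branch_from <- function(node, t0, mk_left) {
    counter$lineages <- counter$lineages + 1L
    if (counter$lineages > 2e5) abort_wgdc("simulation exploded (>2e5 lineage segments); lower lambda")
    key <- as.character(node)
    lam <- model$lambda[[key]]; mu <- model$mu[[key]]
    t_end <- geo$depth[node]
    mk <- mk_left
    t <- t0
    repeat {
      t_next <- if (!is.null(mk) && nrow(mk) > 0) mk$t[1L] else t_end
      wait <- if (lam + mu > 0) stats::rexp(1L, lam + mu) else Inf
      if (t + wait < t_next) {
        t <- t + wait
        if (stats::runif(1L) < lam / (lam + mu)) {
          c1 <- sim_branch_from(node, t, mk)
          c2 <- sim_branch_from(node, t, mk)
          return(join2(c1, c2, type = "duplication", species_node = node, time = t))
        }
        return(NULL)
      }
      if (!is.null(mk) && nrow(mk) > 0) {
        id <- mk$wgd_id[1L]; tw <- mk$t[1L]
        mk <- mk[-1L, , drop = FALSE]
        t <- tw
        if (stats::runif(1L) < model$q[[id]]) {
          c1 <- sim_branch_from(node, t, mk)
          c2 <- sim_branch_from(node, t, mk)
          return(join2(c1, c2, type = "wgd", species_node = node, time = t, wgd_id = id))
        }
      } else {
        return(sim_node(node))
      }
    }
  }

  # lineage arrives at species-tree node `node` (tip or speciation)
  sim_node <- function(node) {
    if (node <= geo$ntip) {
      sp <- geo$phy$tip.label[node]
      counter$i[[sp]] <- counter$i[[sp]] + 1L
      gid <- sprintf("%s__g%d", sp, counter$i[[sp]])
      miss <- stats::runif(1L) < model$p_miss[[sp]]
      return(list(type = "leaf", gene_id = gid, species = sp, miss = miss,
                  species_node = node, time = geo$depth[node]))
    }
    ch <- geo$children[[node]]
    c1 <- sim_branch(ch[1L], geo$depth[node])
    c2 <- sim_branch(ch[2L], geo$depth[node])
    join2(c1, c2, type = "speciation", species_node = node, time = geo$depth[node])
  }

  # join two simulated subtrees, pruning extinct sides / suppressing
  # pass-through nodes so every surviving internal node is a real divergence
  join2 <- function(c1, c2, type, species_node, time, wgd_id = NA_character_) {
    if (is.null(c1) && is.null(c2)) return(NULL)
    if (is.null(c1)) return(c2)
    if (is.null(c2)) return(c1)
    list(type = type, species_node = species_node, time = time, wgd_id = wgd_id,
         children = list(c1, c2))
  }

  root <- geo$ntip + 1L
  n_root <- 1L + stats::rgeom(1L, model$eta)
  subtrees <- vector("list", n_root)
  for (i in seq_len(n_root)) subtrees[[i]] <- sim_node(root)
  subtrees <- Filter(Negate(is.null), subtrees)
  tree <- if (length(subtrees) == 0L) NULL
          else if (length(subtrees) == 1L) subtrees[[1L]]
          else list(type = "root", species_node = root, time = 0,
                    wgd_id = NA_character_, children = subtrees)

  leaves <- collect_leaves(tree)
  obs <- Filter(function(l) !l$miss, leaves)
  deleted <- vapply(Filter(function(l) l$miss, leaves), `[[`, character(1), "gene_id")
  fam <- gene_family(family_id,
                     vapply(obs, `[[`, character(1), "gene_id"),
                     vapply(obs, `[[`, character(1), "species"))
  structure(list(family = fam, deleted = deleted, tree = tree, n_root = n_root),
            class = "sim_family")
}

collect_leaves <- function(node) {
  if (is.null(node)) return(list())
  if (node$type == "leaf") return(list(node))
  do.call(c, lapply(node$children, collect_leaves))
}

#' Number of surviving root lineages with observed descendants
#'
#' Families descending from three or more distinct root lineages cannot be
#' represented by a single binary gene tree whose every clade is a valid
#' single-lineage clade; the reconciliation likelihood truncates its root
#' amalgamation at two observed root subtrees, so such families are usually
#' excluded from reconciliation studies.
#'
#' @param fam a `sim_family`.
#' @return integer count (0 for an empty family).
#' @export
n_root_subtrees <- function(fam) {
  if (is.null(fam$tree)) return(0L)
  if (fam$tree$type != "root") {
    return(if (any(!vapply(collect_leaves(fam$tree), `[[`, logical(1), "miss")) ) 1L else 0L)
  }
  sum(vapply(fam$tree$children, function(ch) {
    any(!vapply(collect_leaves(ch), `[[`, logical(1), "miss"))
  }, logical(1)))
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf("sim_family %s: %d observed genes, %d deleted, root count %d\n",
              x$family$family_id, nrow(x$family$genes), length(x$deleted), x$n_root))
  invisible(x)
}

#' Emit paralog and ortholog Ks values from a simulated family
#'
#' For every pair of observed genes the Ks value is the rate-weighted path
#' length on the species tree from the pair's divergence point to the two
#' tips (sum over branch segments of rho_b x segment duration), multiplied by
#' lognormal noise with the model's sigma. Paralog pairs (same species) are
#' tagged by the event that generated them (duplication / wgd / root);
#' cross-species pairs are tagged as speciation.
#'
#' @param fam a `sim_family`.
#' @param model the [sim_model()] used to simulate it.
#' @param seed optional seed for the noise draws.
#' @return data.frame with columns `gene_a`, `gene_b`, `species_a`,
#'   `species_b`, `ks`, `ks_true`, `event`, `wgd_id`.
#' @export
emit_ks <- function(fam, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geo <- sim_geometry(model)
  rows <- list()
  # rate-scaled depth of an event point (branch tipward-node `node`, time t)
  rdepth_at <- function(node, t) {
    if (node == geo$ntip + 1L) return(0)
    par <- geo$parent[node]
    geo$rdepth[par] + model$rho[[as.character(node)]] * (t - geo$depth[par])
  }
  walk <- function(node) {
    if (is.null(node) || node$type == "leaf") return()
    kids <- node$children
    leaf_sets <- lapply(kids, collect_leaves)
    rdiv <- if (node$type == "speciation" || node$type == "root") {
      geo$rdepth[node$species_node]
    } else {
      rdepth_at(node$species_node, node$time)
    }
    for (i in seq_len(length(kids) - 1L)) {
      for (j in (i + 1L):length(kids)) {
        for (la in leaf_sets[[i]]) for (lb in leaf_sets[[j]]) {
          if (la$miss || lb$miss) next
          ks_true <- (geo$rdepth[la$species_node] - rdiv) +
                     (geo$rdepth[lb$species_node] - rdiv)
          event <- if (node$type == "speciation") "speciation" else node$type
          rows[[length(rows) + 1L]] <<- data.frame(
            gene_a = la$gene_id, gene_b = lb$gene_id,
            species_a = la$species, species_b = lb$species,
            ks_true = ks_true, event = event,
            wgd_id = node$wgd_id %||% NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    for (k in kids) walk(k)
  }
  walk(fam$tree)
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      species_a = character(), species_b = character(),
                      ks = numeric(), ks_true = numeric(), event = character(),
                      wgd_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  noise <- if (model$ks_sigma > 0) exp(stats::rnorm(nrow(out), 0, model$ks_sigma)) else 1
  out$ks <- out$ks_true * noise
  out[c("gene_a", "gene_b", "species_a", "species_b", "ks", "ks_true",
        "event", "wgd_id")]
}

#' Extract the observed gene tree (topology over non-deleted genes)
#'
#' @param fam a `sim_family` with at least 2 observed genes.
#' @param binarize resolve the (possibly multifurcating) root join with
#'   [ape::multi2di()] so downstream consumers always see binary trees.
#' @return an [ape::phylo] with tip labels = gene ids.
#' @export
observed_gene_tree <- function(fam, binarize = TRUE) {
  assert_that(nrow(fam$family$genes) >= 2L, "need >= 2 observed genes for a tree")
  nwk <- function(node) {
    if (node$type == "leaf") return(node$gene_id)
    kids <- lapply(node$children, prune_obs)
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 1L) return(nwk(kids[[1L]]))
    paste0("(", paste(vapply(kids, nwk, character(1)), collapse = ","), ")")
  }
  # prune deleted leaves
  prune_obs <- function(node) {
    if (is.null(node)) return(NULL)
    if (node$type == "leaf") return(if (node$miss) NULL else node)
    kids <- Filter(Negate(is.null), lapply(node$children, prune_obs))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    node$children <- kids
    node
  }
  top <- prune_obs(fam$tree)
  txt <- paste0(if (top$type == "leaf") top$gene_id else nwk(top), ";")
  tr <- ape::read.tree(text = txt)
  if (binarize && !ape::is.binary(tr)) tr <- ape::multi2di(tr)
  tr
}

#' Perturb a gene tree into an emulated posterior sample
#'
#' Stands in for a Bayesian tree-sampler: each of the `n` output trees is the
#' input topology with a Poisson(error_rate x internal-edge-count) number of
#' random NNI moves applied. `error_rate = 0` yields `n` identical copies.
#'
#' @param true_tree an [ape::phylo].
#' @param n number of trees (>= 1).
#' @param error_rate expected NNI moves per internal edge, in `[0,1)`.
#' @param seed optional seed.
#' @return list of `n` [ape::phylo] objects.
#' @export
perturb_tree_sample <- function(true_tree, n, error_rate = 0, seed = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(error_rate >= 0 && error_rate < 1, "error_rate must lie in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  n_internal <- max(0L, true_tree$Nnode - 1L)
  lapply(seq_len(n), function(i) {
    moves <- if (error_rate > 0 && n_internal > 0) stats::rpois(1L, error_rate * n_internal) else 0L
    if (moves == 0L) true_tree else phangorn::rNNI(true_tree, moves = moves, n = 1L)
  })
}

## codon machinery shared with the Ks engine -----------------------------------

# prefixes whose third codon position is four-fold degenerate and whose first
# and second positions admit no synonymous single-nucleotide change within the
# universal code (and no mutation to a stop among the allowed moves)
fourfold_prefixes <- c("GC", "GG", "CC", "AC", "GT", "TC")

prefix_neighbors <- function() {
  nb <- list()
  for (p in fourfold_prefixes) {
    cand <- character(0)
    for (q in fourfold_prefixes) {
      if (p != q && sum(strsplit(p, "")[[1]] != strsplit(q, "")[[1]]) == 1L) {
        cand <- c(cand, q)
      }
    }
    nb[[p]] <- cand
  }
  nb
}

#' Generate a pair of coding sequences with known expected Ks
#'
#' Builds a random ancestor CDS from codons whose third position is four-fold
#' degenerate, then evolves the two copies independently for `t_ks/2` each:
#' third positions under Jukes-Cantor at the synonymous rate, first/second
#' positions by amino-acid-changing single-nucleotide moves at a configurable
#' nonsynonymous rate, restricted so no stop codon can arise. The expected
#' NG86 Ks of the pair is `t_ks`.
#'
#' @param t_ks target synonymous divergence (substitutions per synonymous site).
#' @param length_codons sequence length in codons (> 0).
#' @param seed optional seed.
#' @param t_ka target nonsynonymous divergence; default `t_ks/10`.
#' @return list with `cds1`, `cds2` (character strings) and `warn_saturated`
#'   (TRUE when `t_ks` is deep enough that the synonymous proportion is
#'   expected to approach the Jukes-Cantor domain boundary of 3/4).
#' @export
emit_codon_pair <- function(t_ks, length_codons, seed = NULL, t_ka = t_ks / 10) {
  assert_that(t_ks >= 0, "t_ks must be non-negative")
  assert_that(length_codons >= 1, "length must be at least one codon")
  if (!is.null(seed)) set.seed(seed)
  nb <- prefix_neighbors()
  bases <- c("A", "C", "G", "T")
  # JC transition: P(same) after divergence d
  evolve3 <- function(b, d) {
    p_same <- 0.25 + 0.75 * exp(-4 / 3 * d)
    ifelse(stats::runif(length(b)) < p_same, b,
           vapply(b, function(x) sample(setdiff(bases, x), 1L), character(1)))
  }
  evolve_prefix <- function(p, d) {
    k <- stats::rpois(1L, d)   # amino-acid changing moves on this codon
    for (i in seq_len(k)) p <- sample(nb[[p]], 1L)
    p
  }
  anc_pre <- sample(fourfold_prefixes, length_codons, replace = TRUE)
  anc_3 <- sample(bases, length_codons, replace = TRUE)
  mk <- function() {
    pre <- vapply(anc_pre, evolve_prefix, character(1), d = t_ka / 2)
    p3 <- evolve3(anc_3, t_ks / 2)
    paste0(paste0(pre, p3), collapse = "")
  }
  list(cds1 = mk(), cds2 = mk(),
       warn_saturated = 0.75 * (1 - exp(-4 / 3 * t_ks)) >= 0.70)
}
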