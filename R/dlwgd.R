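## R-side interface to the amalgamated DL+WGD likelihood.

# flatten a species_tree for the compiled likelihood core
tree_flatten <- function(tree) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  assert_that(ntip <= 30, "likelihood engine supports at most 30 species")
  par <- tree_parents(phy)
  ch <- tree_children(phy)
  children <- matrix(0L, n, 2)
  for (v in seq_len(n)) {
    if (length(ch[[v]]) == 2L) children[v, ] <- ch[[v]]
  }
  len <- branch_lengths_above(phy)
  len[is.na(len)] <- 0
  smask <- integer(n)
  post <- postorder_nodes(phy)
  for (v in post) {
    smask[v] <- if (v <= ntip) bitwShiftL(1L, v - 1L) else
      bitwOr(smask[children[v, 1L]], smask[children[v, 2L]])
  }
  par[is.na(par)] <- 0L
  list(n = n, ntip = ntip, root = ntip + 1L, parent = as.integer(par),
       children = children, length = as.numeric(len),
       postorder = as.integer(post), smask = as.integer(smask))
}

# flatten one CCD against a species tree (0-based indices for C++)
ccd_flatten <- function(ccd, tree) {
  phy <- tree$phy
  tipm <- stats::setNames(seq_len(ape::Ntip(phy)), phy$tip.label)
  sp_idx <- tipm[ccd$species]
  assert_that(!any(is.na(sp_idx)), "CCD contains species absent from the species tree")
  keys <- ccd$clades$key
  kidx <- stats::setNames(seq_along(keys), keys)
  gene_sets <- strsplit(keys, ",")
  mask <- vapply(gene_sets, function(g) {
    Reduce(bitwOr, bitwShiftL(1L, unname(sp_idx[as.integer(g)]) - 1L), 0L)
  }, integer(1))
  leaf_species <- rep(-1L, length(keys))
  singl <- ccd$clades$size == 1L
  leaf_species[singl] <- unname(sp_idx[as.integer(keys[singl])]) - 1L
  # splits ordered by parent clade, contiguous blocks
  sp_ord <- ccd$splits[order(match(ccd$splits$parent, keys)), , drop = FALSE]
  pidx <- kidx[sp_ord$parent]
  split_start <- integer(length(keys)); split_len <- integer(length(keys))
  if (nrow(sp_ord) > 0) {
    rle_p <- rle(as.integer(pidx))
    ends <- cumsum(rle_p$lengths)
    starts <- ends - rle_p$lengths + 1L
    split_start[rle_p$values] <- starts - 1L
    split_len[rle_p$values] <- rle_p$lengths
  }
  root_key <- paste(seq_along(ccd$genes), collapse = ",")
  root <- kidx[[root_key]]
  assert_that(!is.null(root), "CCD lacks the root clade")
  list(n_clades = length(keys), root = root - 1L, mask = as.integer(mask),
       leaf_species = as.integer(leaf_species),
       split_start = as.integer(split_start), split_len = as.integer(split_len),
       split_c1 = as.integer(kidx[sp_ord$c1] - 1L),
       split_c2 = as.integer(kidx[sp_ord$c2] - 1L),
       split_p = as.numeric(sp_ord$p))
}

#' Prepare species tree and CCDs for repeated likelihood evaluation
#'
#' Flattens the tree and the family CCDs once and deduplicates families with
#' identical flattened structure (identical profiles and split distributions
#' contribute identical likelihood terms, so they are weighted by
#' multiplicity instead of recomputed).
#'
#' @param tree a [species_tree()] (any WGD marks on it become the model's WGD
#'   events, in the order of `tree$wgd`).
#' @param ccds list of [build_ccd()] objects.
#' @param p_obs per-species sampling probability `1 - p_miss`; scalar or
#'   named by species.
#' @return an opaque list used by [dlwgd_loglik()] and [mcmc_dlwgd()].
#' @export
dlwgd_prepare <- function(tree, ccds, p_obs = 1) {
  if (inherits(ccds, "ccd")) ccds <- list(ccds)
  ts <- tree_flatten(tree)
  phy <- tree$phy
  if (length(p_obs) == 1L && is.null(names(p_obs))) {
    p_obs <- stats::setNames(rep(p_obs, ts$ntip), phy$tip.label)
  }
  assert_that(all(phy$tip.label %in% names(p_obs)), "p_obs must cover every species")
  p_obs_tip <- c(unname(p_obs[phy$tip.label]), rep(0, ts$n - ts$ntip))
  flats <- lapply(ccds, ccd_flatten, tree = tree)
  sig <- vapply(flats, function(f) paste(unlist(f), collapse = ";"), character(1))
  uniq <- !duplicated(sig)
  mult <- as.numeric(table(factor(sig, levels = sig[uniq])))
  list(tree = tree, tree_spec = ts, ccds = flats[uniq], mult = mult,
       all_ccds = ccds, p_obs_tip = p_obs_tip,
       wgd_ids = tree$wgd$wgd_id, wgd_node = as.integer(tree$wgd$node),
       wgd_pos = as.numeric(tree$wgd$pos), n_families = length(ccds))
}

# expand scalar/named branch parameters to the per-node vector the core wants
expand_branch_par <- function(x, ts, what) {
  if (length(x) == 1L && is.null(names(x))) return(rep(x, ts$n))
  out <- numeric(ts$n)
  branch_nodes <- setdiff(seq_len(ts$n), ts$root)
  assert_that(all(as.character(branch_nodes) %in% names(x)),
              "%s must name every non-root node", what)
  out[branch_nodes] <- x[as.character(branch_nodes)]
  out
}

#' Amalgamated log-likelihood under the DL+WGD model
#'
#' Computes the joint log-likelihood of the prepared families given
#' per-branch duplication and loss rates, WGD retention rates, and the
#' geometric root prior, conditioned on each family having at least one
#' observed gene in both root-child clades.
#'
#' @param prep result of [dlwgd_prepare()].
#' @param lambda,mu per-branch rates: scalar or vector named by the branch's
#'   tipward node id.
#' @param eta geometric root-prior parameter in (0,1].
#' @param q named vector of retention rates (one per WGD mark; may be empty).
#' @param steps RK4 steps per branch (default 10).
#' @return total log-likelihood (sum over families).
#' @export
dlwgd_loglik <- function(prep, lambda, mu, eta, q = NULL, steps = 10) {
  lam <- expand_branch_par(lambda, prep$tree_spec, "lambda")
  muv <- expand_branch_par(mu, prep$tree_spec, "mu")
  qv <- numeric(length(prep$wgd_ids))
  if (length(prep$wgd_ids) > 0) {
    assert_that(!is.null(q) && all(prep$wgd_ids %in% names(q)),
                "q must be named for every WGD mark")
    qv <- as.numeric(q[prep$wgd_ids])
  }
  dlwgd_loglik_cpp(prep$tree_spec, lam, muv, prep$p_obs_tip, eta, qv,
                   prep$wgd_node, prep$wgd_pos, prep$ccds, prep$mult,
                   as.integer(steps))
}

## ---- pure-R sliced DP (reference implementation + stochastic backtracking) --

# closed-form linear-BDP extinction propagation and single-lineage propagator
bd_ab <- function(lam, mu, t) {
  if (abs(lam - mu) < 1e-10) {
    x <- 0.5 * (lam + mu) * t
    c(alpha = x / (1 + x), beta = x / (1 + x))
  } else if (mu < 1e-14) {
    c(alpha = 0, beta = 1 - exp(-lam * t))
  } else {
    e <- exp((lam - mu) * t)
    a <- mu * (e - 1) / (lam * e - mu)
    c(alpha = a, beta = lam * a / mu)
  }
}
bd_G <- function(s, lam, mu, t) {
  ab <- bd_ab(lam, mu, t)
  ab[1] + (1 - ab[1]) * (1 - ab[2]) * s / (1 - ab[2] * s)
}
bd_Gp <- function(s, lam, mu, t) {
  ab <- bd_ab(lam, mu, t)
  (1 - ab[1]) * (1 - ab[2]) / (1 - ab[2] * s)^2
}

# first-order sliced DP over one family, storing W at every slice boundary of
# every branch; used by the history backtracker (and as a slow cross-check of
# the compiled core at fine slicing)
dlwgd_dp <- function(prep, lambda, mu, eta, q = NULL, ccd_index = 1,
                     nslices = 50) {
  ts <- prep$tree_spec
  fam <- ccd_flatten(prep$all_ccds[[ccd_index]], prep$tree)
  clade_keys <- prep$all_ccds[[ccd_index]]$clades$key
  lam <- expand_branch_par(lambda, ts, "lambda")
  muv <- expand_branch_par(mu, ts, "mu")
  qv <- stats::setNames(numeric(length(prep$wgd_ids)), prep$wgd_ids)
  if (length(qv) > 0) qv[] <- q[prep$wgd_ids]
  nc <- fam$n_clades
  sp_of <- fam$leaf_species
  # split lookup per clade
  spl <- lapply(seq_len(nc), function(c) {
    if (fam$split_len[c] == 0L) return(NULL)
    i <- fam$split_start[c] + seq_len(fam$split_len[c])
    list(c1 = fam$split_c1[i] + 1L, c2 = fam$split_c2[i] + 1L, p = fam$split_p[i])
  })
  branch <- vector("list", ts$n)   # per node: list(sgrid, W (nc x ns+1), eps, events)
  Wnode <- vector("list", ts$n)
  eps_top <- numeric(ts$n)
  eps_node <- numeric(ts$n)
  for (v in ts$postorder) {
    if (ts$children[v, 1L] == 0L) {
      W <- numeric(nc)
      W[which(sp_of == v - 1L)] <- prep$p_obs_tip[v]
      eps <- 1 - prep$p_obs_tip[v]
    } else {
      f <- ts$children[v, 1L]; g <- ts$children[v, 2L]
      Wf <- branch[[f]]$Wtop; Wg <- branch[[g]]$Wtop
      ef <- eps_top[f]; eg <- eps_top[g]
      eps <- ef * eg
      W <- numeric(nc)
      for (c in seq_len(nc)) {
        if (bitwAnd(fam$mask[c], ts$smask[v]) != fam$mask[c]) next
        acc <- Wf[c] * eg + Wg[c] * ef
        s <- spl[[c]]
        if (!is.null(s)) {
          acc <- acc + sum(s$p * (Wf[s$c1] * Wg[s$c2] + Wf[s$c2] * Wg[s$c1]))
        }
        W[c] <- acc
      }
    }
    Wnode[[v]] <- W
    eps_node[v] <- eps
    if (v == ts$root) break
    # slice grid for the branch above v, with WGD marks on boundaries
    len <- ts$length[v]
    marks <- which(prep$wgd_node == v)
    mpos <- sort(prep$wgd_pos[marks] * len)
    mid <- marks[order(prep$wgd_pos[marks] * len)]
    sgrid <- sort(unique(c(seq(0, len, length.out = nslices + 1), mpos)))
    ns <- length(sgrid) - 1L
    Wmat <- matrix(0, nc, ns + 1L)
    epsv <- numeric(ns + 1L)
    evs <- vector("list", ns + 1L)   # WGD mark at boundary i (if any)
    Wmat[, 1L] <- W; epsv[1L] <- eps
    active <- bitwAnd(fam$mask, ts$smask[v]) == fam$mask
    for (i in seq_len(ns)) {
      dt <- sgrid[i + 1L] - sgrid[i]
      gp <- bd_Gp(epsv[i], lam[v], muv[v], dt)
      Wprev <- Wmat[, i]
      Wcur <- gp * Wprev
      for (c in which(active)) {
        s <- spl[[c]]
        if (!is.null(s)) {
          Wcur[c] <- Wcur[c] + lam[v] * dt * sum(s$p * Wprev[s$c1] * Wprev[s$c2])
        }
      }
      Wcur[!active] <- 0
      ecur <- bd_G(epsv[i], lam[v], muv[v], dt)
      hit <- which(abs(mpos - sgrid[i + 1L]) < 1e-12)
      if (length(hit) == 1L) {
        wid <- prep$wgd_ids[mid[hit]]
        qw <- qv[[wid]]
        Wpre <- Wcur
        for (c in which(active)) {
          s <- spl[[c]]
          sterm <- if (is.null(s)) 0 else sum(s$p * Wpre[s$c1] * Wpre[s$c2])
          Wcur[c] <- (1 - qw) * Wpre[c] + qw * (2 * ecur * Wpre[c] + sterm)
        }
        evs[[i + 1L]] <- list(wgd_id = wid, q = qw, eps_below = ecur, Wpre = Wpre)
        ecur <- (1 - qw) * ecur + qw * ecur^2
      }
      Wmat[, i + 1L] <- Wcur
      epsv[i + 1L] <- ecur
    }
    branch[[v]] <- list(sgrid = sgrid, W = Wmat, eps = epsv, events = evs,
                        Wtop = Wmat[, ns + 1L])
    eps_top[v] <- epsv[ns + 1L]
  }
  root <- ts$root
  f <- ts$children[root, 1L]; g <- ts$children[root, 2L]
  ef <- eps_top[f]; eg <- eps_top[g]
  e0 <- ef * eg
  A <- 1 / (1 - (1 - eta) * e0)
  WR <- Wnode[[root]]
  rc <- fam$root + 1L
  s <- spl[[rc]]
  split_term <- if (is.null(s)) 0 else sum(s$p * WR[s$c1] * WR[s$c2])
  Lu <- eta * A^2 * WR[rc] + 2 * eta * (1 - eta) * A^3 * split_term
  gfun <- function(z) eta * z / (1 - (1 - eta) * z)
  Pobs <- 1 - gfun(ef) - gfun(eg) + gfun(e0)
  list(fam = fam, spl = spl, branch = branch, Wnode = Wnode, eps_top = eps_top,
       eps_node = eps_node, root_clade = rc, Lu = Lu, Pobs = Pobs,
       loglik = log(Lu) - log(Pobs), lam = lam, mu = muv, qv = qv, eta = eta,
       ts = ts, A = A, clade_keys = clade_keys)
}

# sample one reconciled history from the DP tables; returns, for every clade
# that splits in the sampled history, the event and its species-tree location
sample_history <- function(dp) {
  ts <- dp$ts; fam <- dp$fam
  events <- list()
  record <- function(clade, type, where, c1, c2) {
    events[[as.character(clade)]] <<- list(type = type, where = where, c1 = c1, c2 = c2)
  }
  trace_node <- function(clade, v) {
    if (ts$children[v, 1L] == 0L) return(invisible())
    f <- ts$children[v, 1L]; g <- ts$children[v, 2L]
    Wf <- dp$branch[[f]]$Wtop; Wg <- dp$branch[[g]]$Wtop
    ef <- dp$eps_top[f]; eg <- dp$eps_top[g]
    s <- dp$spl[[clade]]
    w <- c(Wf[clade] * eg, Wg[clade] * ef)
    lab <- list(list(kind = "left_only"), list(kind = "right_only"))
    if (!is.null(s)) {
      for (i in seq_along(s$p)) {
        w <- c(w, s$p[i] * Wf[s$c1[i]] * Wg[s$c2[i]], s$p[i] * Wf[s$c2[i]] * Wg[s$c1[i]])
        lab <- c(lab, list(list(kind = "split", a = s$c1[i], b = s$c2[i])),
                 list(list(kind = "split", a = s$c2[i], b = s$c1[i])))
      }
    }
    pick <- lab[[sample.int(length(w), 1L, prob = pmax(w, 0))]]
    if (pick$kind == "left_only") trace_branch(clade, f)
    else if (pick$kind == "right_only") trace_branch(clade, g)
    else {
      record(clade, "speciation", v, pick$a, pick$b)
      trace_branch(pick$a, f); trace_branch(pick$b, g)
    }
  }
  trace_branch <- function(clade, v, from = NULL, skip_first_event = FALSE) {
    br <- dp$branch[[v]]
    i <- from %||% (length(br$sgrid))
    first <- TRUE
    while (i > 1L) {
      ev <- br$events[[i]]
      if (first && skip_first_event) ev <- NULL
      first <- FALSE
      if (!is.null(ev)) {
        # WGD boundary: choose retention outcome using pre-WGD values
        Wpre <- ev$Wpre
        s <- dp$spl[[clade]]
        w <- c((1 - ev$q) * Wpre[clade], ev$q * 2 * ev$eps_below * Wpre[clade])
        lab <- list(list(kind = "pass"), list(kind = "one_side"))
        if (!is.null(s)) {
          for (k in seq_along(s$p)) {
            w <- c(w, ev$q * s$p[k] * Wpre[s$c1[k]] * Wpre[s$c2[k]])
            lab <- c(lab, list(list(kind = "split", a = s$c1[k], b = s$c2[k])))
          }
        }
        pick <- lab[[sample.int(length(w), 1L, prob = pmax(w, 0))]]
        if (pick$kind == "split") {
          record(clade, "wgd", ev$wgd_id, pick$a, pick$b)
          trace_branch(pick$a, v, from = i, skip_first_event = TRUE)
          trace_branch(pick$b, v, from = i, skip_first_event = TRUE)
          return(invisible())
        }
        # pass or one_side: continue as a single lineage below the mark
      }
      dt <- br$sgrid[i] - br$sgrid[i - 1L]
      gp <- bd_Gp(br$eps[i - 1L], dp$lam[v], dp$mu[v], dt)
      Wprev <- br$W[, i - 1L]
      s <- dp$spl[[clade]]
      w <- gp * Wprev[clade]
      lab <- list(list(kind = "pass"))
      if (!is.null(s)) {
        for (k in seq_along(s$p)) {
          w <- c(w, dp$lam[v] * dt * s$p[k] * Wprev[s$c1[k]] * Wprev[s$c2[k]])
          lab <- c(lab, list(list(kind = "dup", a = s$c1[k], b = s$c2[k])))
        }
      }
      pick <- lab[[sample.int(length(w), 1L, prob = pmax(w, 0))]]
      if (pick$kind == "dup") {
        record(clade, "duplication", v, pick$a, pick$b)
        trace_branch(pick$a, v, from = i - 1L); trace_branch(pick$b, v, from = i - 1L)
        return(invisible())
      }
      i <- i - 1L
    }
    trace_node(clade, v)
  }
  # root choice: single root subtree vs a two-lineage root split
  root <- ts$root
  WR <- dp$Wnode[[root]]
  rc <- dp$root_clade
  s <- dp$spl[[rc]]
  e0 <- dp$eps_top[ts$children[root, 1L]] * dp$eps_top[ts$children[root, 2L]]
  A <- 1 / (1 - (1 - dp$eta) * e0)
  w <- dp$eta * A^2 * WR[rc]
  lab <- list(list(kind = "single"))
  if (!is.null(s)) {
    for (k in seq_along(s$p)) {
      w <- c(w, 2 * dp$eta * (1 - dp$eta) * A^3 * s$p[k] * WR[s$c1[k]] * WR[s$c2[k]])
      lab <- c(lab, list(list(kind = "rootsplit", a = s$c1[k], b = s$c2[k])))
    }
  }
  pick <- lab[[sample.int(length(w), 1L, prob = pmax(w, 0))]]
  if (pick$kind == "single") {
    trace_node(rc, root)
  } else {
    record(rc, "root", root, pick$a, pick$b)
    trace_node(pick$a, root); trace_node(pick$b, root)
  }
  events
}

#' Posterior distribution over branches for a paralog pair's divergence
#'
#' By stochastic backtracking of the likelihood dynamic program, samples
#' reconciled histories and records, for the given gene pair, the event at
#' which the two genes diverge: a duplication on a species-tree branch
#' (keyed `dup:<node>`), a WGD retention (keyed `wgd:<id>`), a speciation
#' node (`spec:<node>`), or the root-lineage split (`root`). Probabilities
#' sum to 1 over the sampled histories.
#'
#' @param prep result of [dlwgd_prepare()].
#' @param gene_pair character vector of two gene ids in the family.
#' @param lambda,mu,eta,q model parameters, or draws: when `draws` (a
#'   data.frame of posterior samples from [mcmc_dlwgd()]) is given it takes
#'   precedence and parameters are resampled per history.
#' @param ccd_index which family.
#' @param nsamples number of sampled histories (default 200).
#' @param draws optional posterior draws.
#' @param nslices slice resolution of the backtracking DP.
#' @param seed optional seed.
#' @return named numeric vector of probabilities.
#' @export
pair_duplication_posterior <- function(prep, gene_pair, lambda = NULL, mu = NULL,
                                       eta = NULL, q = NULL, ccd_index = 1,
                                       nsamples = 200, draws = NULL,
                                       nslices = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ccd <- prep$all_ccds[[ccd_index]]
  gi <- match(gene_pair, ccd$genes)
  assert_that(!any(is.na(gi)), "gene pair not found in the family")
  counts <- new.env(parent = emptyenv())
  draw_idx <- if (!is.null(draws)) sample.int(nrow(draws), nsamples, replace = TRUE) else NULL
  dp <- NULL
  for (it in seq_len(nsamples)) {
    if (!is.null(draws)) {
      d <- draws[draw_idx[it], ]
      lam_i <- extract_branch_draw(d, "lambda")
      mu_i <- extract_branch_draw(d, "mu")
      qd <- extract_q_draw(d, prep$wgd_ids)
      dp <- dlwgd_dp(prep, lam_i, mu_i, d$eta %||% d[["eta"]], qd,
                     ccd_index = ccd_index, nslices = nslices)
    } else if (is.null(dp)) {
      dp <- dlwgd_dp(prep, lambda, mu, eta, q, ccd_index = ccd_index,
                     nslices = nslices)
    }
    ev <- sample_history(dp)
    key <- divergence_event_key(dp, ev, gi)
    assign(key, (counts[[key]] %||% 0L) + 1L, envir = counts)
  }
  ks <- ls(counts)
  stats::setNames(vapply(ks, function(k) counts[[k]], integer(1)) / nsamples, ks)
}

# walk the sampled history from the root clade down to the event separating
# the two genes
divergence_event_key <- function(dp, events, gi) {
  keys <- strsplit(dp$clade_keys, ",")
  clade <- dp$root_clade
  repeat {
    ev <- events[[as.character(clade)]]
    if (is.null(ev)) {
      # clade never split in this history: both genes coalesce below a
      # singleton - impossible unless the pair is not separated; the clade
      # must be the pair itself reaching a leaf, which cannot happen for two
      # distinct genes, so treat as undefined
      return("undefined")
    }
    in1 <- all(gi %in% as.integer(keys[[ev$c1]]))
    in2 <- all(gi %in% as.integer(keys[[ev$c2]]))
    if (in1) { clade <- ev$c1; next }
    if (in2) { clade <- ev$c2; next }
    return(switch(ev$type,
                  duplication = paste0("dup:", ev$where),
                  wgd = paste0("wgd:", ev$where),
                  speciation = paste0("spec:", ev$where),
                  root = "root"))
  }
}

extract_branch_draw <- function(d, prefix) {
  cols <- grep(paste0("^", prefix, "\\."), names(d), value = TRUE)
  stats::setNames(as.numeric(d[cols]), sub(paste0("^", prefix, "\\."), "", cols))
}

extract_q_draw <- function(d, wgd_ids) {
  if (length(wgd_ids) == 0) return(NULL)
  stats::setNames(as.numeric(d[paste0("q.", wgd_ids)]), wgd_ids)
}
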