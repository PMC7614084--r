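## End-to-end orchestration: simulate (or ingest) -> Ks -> peaks -> rate
## correction -> WGD hypotheses -> reconciliation -> Bayes-factor report.

#' Simulate a batch of gene families
#'
#' @param model a [sim_model()].
#' @param n number of families.
#' @param seed master seed (each family gets a derived sub-seed).
#' @param prefix family-id prefix.
#' @return list of `sim_family` objects.
#' @export
simulate_families <- function(model, n, seed = 1, prefix = "fam") {
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    simulate_family(model, family_id = sprintf("%s%04d", prefix, i), seed = seeds[i])
  })
}

#' Emit the Ks table for a batch of simulated families
#'
#' @param sims list of `sim_family` objects.
#' @param model the [sim_model()].
#' @param seed master seed for the noise draws.
#' @return combined data.frame (see [emit_ks()]) with a `family_id` column.
#' @export
sim_ks_table <- function(sims, model, seed = 1) {
  seeds <- derive_seeds(seed, length(sims))
  do.call(rbind, lapply(seq_along(sims), function(i) {
    k <- emit_ks(sims[[i]], model, seed = seeds[i])
    if (nrow(k) > 0) k$family_id <- sims[[i]]$family$family_id
    k
  }))
}

#' Paranome Ks distribution of one species from a simulated Ks table
#'
#' Within-species pairs are node-weighted per family with
#' [weight_family_pairs()], exactly as sequence-derived paranome
#' distributions are.
#'
#' @param ks_table output of [sim_ks_table()].
#' @param species species id.
#' @param ceiling Ks ceiling.
#' @return a [ks_distribution()].
#' @export
paranome_from_table <- function(ks_table, species, ceiling = 5) {
  par <- ks_table[ks_table$species_a == species & ks_table$species_b == species, ,
                  drop = FALSE]
  if (nrow(par) == 0) {
    return(ks_distribution(data.frame(gene_a = character(), gene_b = character(),
                                      ks = numeric(), weight = numeric()),
                           "paranome", species, ceiling))
  }
  out <- do.call(rbind, lapply(split(par, par$family_id), weight_family_pairs))
  ks_distribution(out, "paranome", species, ceiling)
}

#' Ortholog peak matrix from a simulated Ks table
#'
#' For every species pair, the one-to-one ortholog distribution (pairs whose
#' divergence event is a speciation) is summarized by its KDE-mode peak.
#'
#' @param ks_table output of [sim_ks_table()].
#' @param species character vector of species.
#' @param seed seed for the bootstrap peaks.
#' @param n_boot bootstrap resamples per peak (default 50).
#' @return list with `peak` and `sd` matrices.
#' @export
ortholog_peak_matrix <- function(ks_table, species, seed = 1, n_boot = 50) {
  ns <- length(species)
  pk <- matrix(NA_real_, ns, ns, dimnames = list(species, species))
  sd_ <- matrix(NA_real_, ns, ns, dimnames = list(species, species))
  orth <- ks_table[ks_table$event == "speciation", , drop = FALSE]
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      sel <- (orth$species_a == species[i] & orth$species_b == species[j]) |
             (orth$species_a == species[j] & orth$species_b == species[i])
      ks <- orth$ks[sel]
      assert_that(sum(is.finite(ks)) >= 10,
                  "too few ortholog pairs between %s and %s", species[i], species[j])
      est <- ortholog_peak(ks, n_boot = n_boot, seed = derive_seeds(seed, i * ns + j)[1])
      pk[i, j] <- pk[j, i] <- est$peak
      sd_[i, j] <- sd_[j, i] <- est$sd
    }
  }
  diag(pk) <- 0; diag(sd_) <- 0
  list(peak = pk, sd = sd_)
}

#' Select the WGD-candidate peak of a species from its peak calls
#'
#' Among SiZer-significant components, the WGD burst is the narrow one (the
#' small-scale-duplication background is broad on the log scale): candidates
#' with weight above `min_weight` are ranked by log-scale sd and the
#' narrowest is returned.
#'
#' @param calls data.frame from [call_peaks()].
#' @param min_weight minimum component weight (default 0.1).
#' @param significant_only use only GMM+SiZer-supported components.
#' @return one-row data.frame, or NULL when no candidate qualifies.
#' @export
select_wgd_peak <- function(calls, min_weight = 0.1, significant_only = TRUE) {
  cand <- calls[calls$weight >= min_weight, , drop = FALSE]
  if (significant_only) cand <- cand[cand$support == "GMM+SiZer", , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  cand[which.min(cand$sdlog), , drop = FALSE]
}

#' Derive deduplicated branch-level WGD hypotheses from peak placements
#'
#' Takes placements from any number of species and correction schemes and
#' returns the union of implicated branches. Hypotheses on adjacent branches
#' (parent/child) are kept as separate competing hypotheses and flagged, to
#' be discriminated by reconciliation. Root-stem placements cannot be tested
#' and are dropped with a warning.
#'
#' @param placements data.frame with columns `species`, `scheme`, `node`
#'   (tipward node id of the implicated branch; NA for root-stem overflow).
#' @param tree the [species_tree()] the node ids refer to.
#' @return data.frame: `wgd_id`, `node`, `leafset`, `n_support`,
#'   `supporters`, `adjacent_to`.
#' @export
derive_wgd_hypotheses <- function(placements, tree) {
  if (nrow(placements) == 0) {
    warn_wgdc("no placements: empty hypothesis list")
    return(data.frame(wgd_id = character(), node = integer(), leafset = character(),
                      n_support = integer(), supporters = character(),
                      adjacent_to = character()))
  }
  dropped <- is.na(placements$node)
  if (any(dropped)) {
    warn_wgdc("%d root-stem placement(s) dropped: the root has no testable branch above it",
              sum(dropped))
  }
  pl <- placements[!dropped, , drop = FALSE]
  nodes <- sort(unique(pl$node))
  par <- tree_parents(tree$phy)
  out <- data.frame(
    wgd_id = paste0("wgd_n", nodes), node = nodes,
    leafset = vapply(nodes, function(n) paste(branch_leafset(tree, n), collapse = ","),
                     character(1)),
    n_support = vapply(nodes, function(n) sum(pl$node == n), integer(1)),
    supporters = vapply(nodes, function(n) {
      paste(unique(paste0(pl$species[pl$node == n], "/", pl$scheme[pl$node == n])),
            collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  out$adjacent_to <- vapply(out$node, function(n) {
    adj <- out$node[out$node %in% c(par[n], which(par == n))]
    if (length(adj) == 0) "" else paste(paste0("wgd_n", adj), collapse = ";")
  }, character(1))
  out
}

#' Run the full WGD detection workflow on a synthetic scenario
#'
#' Simulates gene families under the configured DL+WGD model, builds
#' per-species paranome Ks distributions and peak calls (GMM + SiZer), dates
#' speciations with ortholog peak matrices, places each species' WGD peak
#' under both rate-correction schemes (halved peak on the NNLS Ks phylogram;
#' trio-corrected ranking), derives branch-level WGD hypotheses, and tests
#' every hypothesis by Bayesian reconciliation under the critical and relaxed
#' DL+WGD models with Savage-Dickey Bayes factors.
#'
#' @param config list with components `tree` (a [species_tree()], time
#'   units), `truth` (list: `wgd` data.frame of marks to plant, `q`, `lambda`,
#'   `mu`, `eta`, `rho`, `p_miss`, `ks_sigma`), `n_families`, `seed`, and
#'   optional `tree_sample` (`n`, `error_rate`, `burn_in`), `mcmc` (`n_iter`,
#'   `thin`, `steps`), `max_family_size`, `models`.
#' @param out optional output directory for TSV/JSON artifacts.
#' @return list: `peak_calls`, `selected_peaks`, `peak_matrix`, `phylogram`,
#'   `placements`, `hypotheses`, `bf_table`, `chains`, `rate_maps`, `log`.
#' @export
run_pipeline <- function(config, out = NULL) {
  assert_that(!is.null(config$tree), "config is missing the species tree")
  assert_that(inherits(config$tree, "species_tree"), "config$tree must be a species_tree")
  tree <- config$tree
  seed <- config$seed %||% 1
  truth <- config$truth %||% list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_wgdc("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## 1. simulate
  sims <- stage("simulate", {
    sim_tree <- tree
    if (!is.null(truth$wgd)) {
      for (i in seq_len(nrow(truth$wgd))) {
        sim_tree <- add_wgd(sim_tree, truth$wgd$wgd_id[i],
                            strsplit(truth$wgd$leaves[i], ",")[[1]],
                            truth$wgd$pos[i] %||% 0.5)
      }
    }
    model <- sim_model(sim_tree,
                       lambda = truth$lambda %||% 0.2, mu = truth$mu %||% 0.2,
                       q = truth$q, eta = truth$eta %||% 0.75,
                       rho = truth$rho %||% 1, ks_sigma = truth$ks_sigma %||% 0.1,
                       p_miss = truth$p_miss %||% 0)
    list(model = model,
         fams = simulate_families(model, config$n_families %||% 300, seed = seed))
  })

  ## 2. Ks distributions and peak calls
  ks_tab <- stage("ks", sim_ks_table(sims$fams, sims$model, seed = seed + 1))
  species <- tree$phy$tip.label
  # Ks ceiling for the paranome distributions. With every simulated family
  # conditioned to exist at the root, pairs that coalesce at the root form an
  # artificially sharp pile at twice the root depth (real data smear this
  # into the saturation tail); a ceiling below that age removes it exactly as
  # the usual saturation cutoff does for real paranomes.
  ceiling_ks <- config$ks_ceiling %||% 5
  peak_calls <- stage("peaks", {
    do.call(rbind, lapply(species, function(sp) {
      dist <- paranome_from_table(ks_tab, sp, ceiling = ceiling_ks)
      if (nrow(dist) < 50) return(NULL)
      call_peaks(dist, species = sp, seed = seed + 2)
    }))
  })
  selected <- do.call(rbind, lapply(split(peak_calls, peak_calls$species),
                                    select_wgd_peak))

  ## 3. rate correction, both schemes
  pkm <- stage("ortholog_peaks", ortholog_peak_matrix(ks_tab, species, seed = seed + 3))
  phylogram <- stage("phylogram", fit_ks_phylogram(tree, pkm$peak))
  placements <- stage("placement", {
    rows <- list()
    for (i in seq_len(nrow(selected %||% data.frame()))) {
      sp <- selected$species[i]; pk <- selected$peak_ks[i]
      ph <- place_halved_peak(phylogram, sp, pk)
      rows[[length(rows) + 1L]] <- data.frame(species = sp, scheme = "phylogram",
                                              node = ph$node %||% NA_integer_,
                                              stringsAsFactors = FALSE)
      # a pure outgroup species has no correctable divergence: phylogram-only
      cd <- tryCatch(suppressWarnings(consensus_divergences(sp, tree, pkm$peak)),
                     error = function(e) NULL)
      if (!is.null(cd)) {
        rk <- rank_peak_vs_divergences(pk, cd)
        rows[[length(rows) + 1L]] <- data.frame(species = sp, scheme = "trio",
                                                node = rk$node, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows) %||% data.frame(species = character(), scheme = character(),
                                         node = integer())
  })
  hyps <- stage("hypotheses", derive_wgd_hypotheses(placements, tree))

  ## 4. reconciliation of the hypotheses under both DL+WGD models
  recon <- stage("reconciliation", {
    if (nrow(hyps) == 0) return(NULL)
    htree <- tree
    for (i in seq_len(nrow(hyps))) {
      htree <- add_wgd(htree, hyps$wgd_id[i],
                       strsplit(hyps$leafset[i], ",")[[1]], 0.5)
    }
    filt <- filter_families(lapply(sims$fams, `[[`, "family"), tree,
                            max_size = config$max_family_size %||% 50)
    keep_ids <- vapply(filt$kept, function(f) f$family_id, character(1))
    fams_kept <- sims$fams[vapply(sims$fams, function(s) s$family$family_id %in% keep_ids,
                                  logical(1))]
    tsc <- config$tree_sample %||% list(n = 60, error_rate = 0.05, burn_in = 10)
    ccds <- lapply(seq_along(fams_kept), function(i) {
      tr <- observed_gene_tree(fams_kept[[i]])
      sample_ <- perturb_tree_sample(tr, tsc$n, tsc$error_rate,
                                     seed = derive_seeds(seed + 4, i)[1])
      build_ccd(sample_, burn_in = tsc$burn_in,
                family_id = fams_kept[[i]]$family$family_id)
    })
    p_obs <- 1 - (truth$p_miss %||% 0)
    prep <- dlwgd_prepare(htree, ccds, p_obs = p_obs)
    mc <- config$mcmc %||% list()
    chains <- list()
    bf_rows <- list()
    for (mod in (config$models %||% c("critical", "relaxed"))) {
      ch <- mcmc_dlwgd(prep, model = mod, n_iter = mc$n_iter %||% 4000,
                       thin = mc$thin %||% 2, seed = seed + 5,
                       steps = mc$steps %||% 10)
      chains[[mod]] <- ch
      for (w in hyps$wgd_id) {
        bf <- savage_dickey(ch, w)
        bf_rows[[length(bf_rows) + 1L]] <- data.frame(
          wgd_id = w, model = mod, q_mean = bf$q_mean, K = bf$K,
          verdict = bf$verdict, stringsAsFactors = FALSE)
      }
    }
    list(prep = prep, chains = chains, bf_table = do.call(rbind, bf_rows),
         n_families_used = length(ccds), filter_log = filt$log)
  })

  res <- list(peak_calls = peak_calls, selected_peaks = selected,
              peak_matrix = pkm, phylogram = phylogram, placements = placements,
              hypotheses = hyps,
              bf_table = recon$bf_table,
              chains = recon$chains,
              rate_maps = if (!is.null(recon)) {
                lapply(recon$chains, expected_events, prep = recon$prep)
              },
              log = list(seed = seed, n_families = length(sims$fams),
                         n_families_reconciled = recon$n_families_used,
                         ess = lapply(recon$chains, `[[`, "ess")))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res$peak_calls, file.path(out, "peak_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$placements, file.path(out, "placements.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$bf_table)) {
      write_report(res$bf_table, file.path(out, "bf_table.tsv"))
    }
    jsonlite::write_json(res$log, file.path(out, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
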