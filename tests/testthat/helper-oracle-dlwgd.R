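# Independent history-integral oracle for the DL+WGD amalgamated likelihood.
# Sums over duplication histories with nested adaptive quadrature; the
# single-lineage propagator and extinction probabilities come from the
# linear-BDP generating function in closed form. Exponential-cost recursion:
# intended for 3-4 taxon trees and small families only.
oracle_loglik <- function(tree, ccd, lambda, mu, eta, q = NULL, p_obs = 1) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  kid <- vector("list", nn); len <- rep(NA_real_, nn)
  for (e in seq_len(nrow(phy$edge))) {
    kid[[phy$edge[e, 1]]] <- c(kid[[phy$edge[e, 1]]], phy$edge[e, 2])
    len[phy$edge[e, 2]] <- phy$edge.length[e]
  }
  lamv <- if (length(lambda) == 1) rep(lambda, nn) else lambda
  muv <- if (length(mu) == 1) rep(mu, nn) else mu
  pobs <- if (length(p_obs) == 1) stats::setNames(rep(p_obs, ntip), phy$tip.label) else p_obs
  genes <- ccd$genes
  spp <- ccd$species
  ckeys <- ccd$clades$key
  gsets <- lapply(strsplit(ckeys, ","), as.integer)
  csp <- lapply(gsets, function(g) unique(unname(spp[genes[g]])))
  splits <- split(ccd$splits, ccd$splits$parent)
  node_sp <- lapply(seq_len(nn), function(v)
    if (v <= ntip) phy$tip.label[v]
    else sort(phy$tip.label[unlist(phangorn::Descendants(phy, v, "tips"))]))

  Gab <- function(lam, mu_, t) {
    if (abs(lam - mu_) < 1e-10) { x <- 0.5 * (lam + mu_) * t; c(x / (1 + x), x / (1 + x)) }
    else if (mu_ < 1e-14) c(0, 1 - exp(-lam * t))
    else { e <- exp((lam - mu_) * t); a <- mu_ * (e - 1) / (lam * e - mu_); c(a, lam * a / mu_) }
  }
  Gfun <- function(s, lam, mu_, t) {
    if (t <= 0) return(s)
    ab <- Gab(lam, mu_, t)
    ab[1] + (1 - ab[1]) * (1 - ab[2]) * s / (1 - ab[2] * s)
  }
  Gpfun <- function(s, lam, mu_, t) {
    if (t <= 0) return(1)
    ab <- Gab(lam, mu_, t)
    (1 - ab[1]) * (1 - ab[2]) / (1 - ab[2] * s)^2
  }

  wgd <- tree$wgd
  marks <- vector("list", nn)
  if (!is.null(wgd) && nrow(wgd) > 0) {
    for (i in seq_len(nrow(wgd))) {
      v <- wgd$node[i]
      marks[[v]] <- rbind(marks[[v]],
                          data.frame(s = wgd$pos[i] * len[v], q = q[[wgd$wgd_id[i]]]))
    }
    for (v in seq_len(nn)) if (!is.null(marks[[v]])) marks[[v]] <- marks[[v]][order(marks[[v]]$s), ]
  }
  seg_bounds <- function(v) sort(unique(c(0, marks[[v]]$s, len[v])))
  seg_q <- function(v, i) {   # q of the mark at the top boundary of segment i
    m <- marks[[v]]
    if (is.null(m)) return(NA_real_)
    segs <- seg_bounds(v)
    hit <- which(abs(m$s - segs[i + 1]) < 1e-12)
    if (length(hit)) m$q[hit[1]] else NA_real_
  }

  memo <- new.env(parent = emptyenv())
  cache <- function(key, expr) {
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- force(expr)
    memo[[key]] <- val
    val
  }

  eps_node <- function(v) {
    if (v <= ntip) 1 - pobs[[phy$tip.label[v]]]
    else prod(vapply(kid[[v]], eps_top, numeric(1)))
  }
  eps_seg_bottom <- function(v, i) {  # post-WGD eps at segment i's bottom
    segs <- seg_bounds(v)
    e <- eps_node(v)
    if (i > 1) for (j in seq_len(i - 1)) {
      e <- Gfun(e, lamv[v], muv[v], segs[j + 1] - segs[j])
      qq <- seg_q(v, j)
      if (!is.na(qq)) e <- (1 - qq) * e + qq * e^2
    }
    e
  }
  eps_top <- function(v) cache(paste0("e", v), {
    segs <- seg_bounds(v)
    i <- length(segs) - 1
    e <- Gfun(eps_seg_bottom(v, i), lamv[v], muv[v], segs[i + 1] - segs[i])
    qq <- seg_q(v, i)
    if (!is.na(qq)) e <- (1 - qq) * e + qq * e^2
    e
  })

  Wnode <- function(ci, v) cache(paste0("n", ci, "_", v), {
    if (!all(csp[[ci]] %in% node_sp[[v]])) return(0)
    if (v <= ntip) {
      if (length(gsets[[ci]]) == 1 && csp[[ci]] == phy$tip.label[v])
        return(pobs[[phy$tip.label[v]]])
      return(0)
    }
    f <- kid[[v]][1]; g <- kid[[v]][2]
    ef <- eps_top(f); eg <- eps_top(g)
    acc <- Wtop(ci, f) * eg + ef * Wtop(ci, g)
    sp <- splits[[ckeys[ci]]]
    if (!is.null(sp)) {
      for (r in seq_len(nrow(sp))) {
        c1 <- match(sp$c1[r], ckeys); c2 <- match(sp$c2[r], ckeys)
        acc <- acc + sp$p[r] * (Wtop(c1, f) * Wtop(c2, g) + Wtop(c2, f) * Wtop(c1, g))
      }
    }
    acc
  })

  wgd_transform <- function(ci, v, i, qq) {
    # apply the retention recursion at the mark atop segment i, using values
    # at the top of segment i
    segs <- seg_bounds(v)
    u_top <- segs[i + 1] - segs[i]
    w <- Wat(ci, v, i, u_top)
    ehere <- Gfun(eps_seg_bottom(v, i), lamv[v], muv[v], u_top)
    spl <- 0
    sp <- splits[[ckeys[ci]]]
    if (!is.null(sp)) {
      for (r in seq_len(nrow(sp))) {
        c1 <- match(sp$c1[r], ckeys); c2 <- match(sp$c2[r], ckeys)
        spl <- spl + sp$p[r] * Wat(c1, v, i, u_top) * Wat(c2, v, i, u_top)
      }
    }
    (1 - qq) * w + qq * (2 * ehere * w + spl)
  }

  Wseg_bottom <- function(ci, v, i) cache(paste0("b", ci, "_", v, "_", i), {
    if (i == 1) return(Wnode(ci, v))
    wgd_transform(ci, v, i - 1, seg_q(v, i - 1))
  })

  # W at height u above the bottom of segment i of the branch above v:
  # homogeneous propagation plus the integral over the topmost duplication
  Wat <- function(ci, v, i, u) {
    if (!all(csp[[ci]] %in% node_sp[[v]])) return(0)
    e0 <- eps_seg_bottom(v, i)
    val <- Gpfun(e0, lamv[v], muv[v], u) * Wseg_bottom(ci, v, i)
    sp <- splits[[ckeys[ci]]]
    if (!is.null(sp) && lamv[v] > 0 && u > 0) {
      integrand <- function(uu) {
        vapply(uu, function(x) {
          acc <- 0
          for (r in seq_len(nrow(sp))) {
            c1 <- match(sp$c1[r], ckeys); c2 <- match(sp$c2[r], ckeys)
            acc <- acc + sp$p[r] * Wat(c1, v, i, x) * Wat(c2, v, i, x)
          }
          Gpfun(Gfun(e0, lamv[v], muv[v], x), lamv[v], muv[v], u - x) * lamv[v] * acc
        }, numeric(1))
      }
      val <- val + stats::integrate(integrand, 0, u, rel.tol = 1e-9,
                                    abs.tol = 1e-13, subdivisions = 100L)$value
    }
    val
  }

  Wtop <- function(ci, v) cache(paste0("t", ci, "_", v), {
    if (!all(csp[[ci]] %in% node_sp[[v]])) return(0)
    segs <- seg_bounds(v)
    i <- length(segs) - 1
    qq <- seg_q(v, i)
    if (!is.na(qq)) wgd_transform(ci, v, i, qq)
    else Wat(ci, v, i, segs[i + 1] - segs[i])
  })

  f <- kid[[root]][1]; g <- kid[[root]][2]
  ef <- eps_top(f); eg <- eps_top(g)
  e0 <- ef * eg
  rooti <- match(paste(seq_along(genes), collapse = ","), ckeys)
  WR <- Wnode(rooti, root)
  sp <- splits[[ckeys[rooti]]]
  spl <- 0
  if (!is.null(sp)) {
    for (r in seq_len(nrow(sp))) {
      c1 <- match(sp$c1[r], ckeys); c2 <- match(sp$c2[r], ckeys)
      spl <- spl + sp$p[r] * Wnode(c1, root) * Wnode(c2, root)
    }
  }
  A <- 1 / (1 - (1 - eta) * e0)
  Lu <- eta * A^2 * WR + 2 * eta * (1 - eta) * A^3 * spl
  gg <- function(z) eta * z / (1 - (1 - eta) * z)
  Pobs <- 1 - gg(ef) - gg(eg) + gg(e0)
  log(Lu) - log(Pobs)
}
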