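## Genetic code and codon bookkeeping for the NG86 estimator.

codon_env <- new.env(parent = emptyenv())

standard_genetic_code <- function() {
  aa <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa
}

codon_tables <- function() {
  if (!is.null(codon_env$tab)) return(codon_env$tab)
  aa <- standard_genetic_code()
  codons <- names(aa)
  bases <- c("A", "C", "G", "T")
  # NG86 site fractions: per position, the fraction of the three possible
  # single-nucleotide changes that are synonymous; changes to stop codons
  # count as nonsynonymous
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (aa[[cd]] == "*") next
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        if (aa[[mut]] == aa[[cd]] && aa[[mut]] != "*") s <- s + 1 / 3
      }
    }
    syn_sites[[cd]] <- s
  }
  codon_env$tab <- list(aa = aa, syn_sites = syn_sites, codons = codons)
  codon_env$paths <- new.env(parent = emptyenv())
  codon_env$tab
}

# pathway-averaged synonymous/nonsynonymous difference counts between two
# codons (NG86): enumerate all orders of the differing positions, drop
# pathways passing through a stop codon (fall back to all pathways when every
# pathway is blocked), and average the per-step classifications
codon_pair_diffs <- function(c1, c2) {
  tab <- codon_tables()
  key <- paste0(c1, c2)
  hit <- codon_env$paths[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) {
    out <- c(sd = 0, nd = 0)
  } else {
    perms <- all_perms(pos)
    counts <- matrix(NA_real_, nrow = length(perms), ncol = 2)
    blocked <- logical(length(perms))
    for (k in seq_along(perms)) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in perms[[k]]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (tab$aa[[nxt]] == "*") blocked[k] <- TRUE
        if (tab$aa[[nxt]] == tab$aa[[cur]] && tab$aa[[nxt]] != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      counts[k, ] <- c(sd, nd)
    }
    use <- if (all(blocked)) rep(TRUE, length(perms)) else !blocked
    out <- c(sd = mean(counts[use, 1]), nd = mean(counts[use, 2]))
  }
  codon_env$paths[[key]] <- out
  out
}

all_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

validate_cds <- function(cds, label) {
  assert_that(nchar(cds) %% 3 == 0, "%s: length not divisible by three", label)
  assert_that(grepl("^[ACGT]*$", cds), "%s: unknown nucleotides", label)
  tab <- codon_tables()
  cods <- split_codons(cds)
  internal <- cods[-length(cods)]
  assert_that(!any(tab$aa[internal] == "*"), "%s: premature stop codon", label)
  cods
}

#' NG86 pairwise synonymous and nonsynonymous distance
#'
#' Counting estimator of Ks and Ka between two coding sequences: per-codon
#' synonymous/nonsynonymous site fractions averaged over the two sequences,
#' pathway-averaged difference counts for codons differing at several
#' positions, and a Jukes-Cantor multiple-hit correction
#' `d = -(3/4) ln(1 - (4/3) p)` applied separately to the synonymous and
#' nonsynonymous proportions. A proportion at or beyond 3/4 is outside the
#' correction's domain and sets the `saturated` flag.
#'
#' Sequences of unequal length are first aligned with a codon-aware
#' Needleman-Wunsch (scored on amino acids, affine gaps); gapped codons are
#' excluded from the counts.
#'
#' @param cds1,cds2 coding sequences (A/C/G/T, no internal stop codons).
#' @param align force (or forbid) alignment; default aligns only when lengths
#'   differ.
#' @return a one-row data.frame (class `ks_pair`) with columns `ks`, `ka`,
#'   `S`, `N`, `sd_count`, `nd_count`, `saturated_s`, `saturated_n`, `weight`.
#' @export
ng86_distance <- function(cds1, cds2, align = NULL) {
  tab <- codon_tables()
  if (is.null(align)) align <- nchar(cds1) != nchar(cds2)
  if (align) {
    al <- align_codons(cds1, cds2)
    cod1 <- al$cod1; cod2 <- al$cod2
  } else {
    assert_that(nchar(cds1) == nchar(cds2), "sequence length mismatch (pass align = TRUE to align)")
    cod1 <- validate_cds(cds1, "cds1")
    cod2 <- validate_cds(cds2, "cds2")
  }
  keep <- cod1 != "---" & cod2 != "---"
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  assert_that(length(cod1) > 0, "no aligned codons")
  # terminal stops, if present in both, are not informative; drop any stop codon
  stop_mask <- tab$aa[cod1] == "*" | tab$aa[cod2] == "*"
  cod1 <- cod1[!stop_mask]; cod2 <- cod2[!stop_mask]
  S <- (sum(tab$syn_sites[cod1]) + sum(tab$syn_sites[cod2])) / 2
  N <- 3 * length(cod1) - S
  sd_count <- 0; nd_count <- 0
  for (i in seq_along(cod1)) {
    d <- codon_pair_diffs(cod1[i], cod2[i])
    sd_count <- sd_count + d[["sd"]]
    nd_count <- nd_count + d[["nd"]]
  }
  ps <- if (S > 0) sd_count / S else 0
  pn <- if (N > 0) nd_count / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  out <- data.frame(ks = jc(ps), ka = jc(pn), S = S, N = N,
                    sd_count = sd_count, nd_count = nd_count,
                    saturated_s = ps >= 0.75, saturated_n = pn >= 0.75,
                    weight = 1)
  class(out) <- c("ks_pair", "data.frame")
  out
}

## codon-aware Needleman-Wunsch (Gotoh affine gaps) on amino acid sequences
align_codons <- function(cds1, cds2, match = 2, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  tab <- codon_tables()
  cod1 <- validate_cds(cds1, "cds1")
  cod2 <- validate_cds(cds2, "cds2")
  a1 <- tab$aa[cod1]; a2 <- tab$aa[cod2]
  n <- length(a1); m <- length(a2)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a1[i - 1] == a2[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend)
    }
  }
  # traceback
  out1 <- character(0); out2 <- character(0)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1L && i > 1 && j > 1) {
      out1 <- c(cod1[i - 1], out1); out2 <- c(cod2[j - 1], out2)
      s <- if (a1[i - 1] == a2[j - 1]) match else mismatch
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2L || (j == 1 && i > 1)) {
      out1 <- c(cod1[i - 1], out1); out2 <- c("---", out2)
      if (i > 2 && X[i, j] == X[i - 1, j] + gap_extend) state <- 2L else state <- 1L
      i <- i - 1
    } else {
      out1 <- c("---", out1); out2 <- c(cod2[j - 1], out2)
      if (j > 2 && Y[i, j] == Y[i, j - 1] + gap_extend) state <- 3L else state <- 1L
      j <- j - 1
    }
  }
  list(cod1 = out1, cod2 = out2)
}
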