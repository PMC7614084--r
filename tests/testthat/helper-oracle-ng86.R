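# Brute-force NG86 oracle: explicit site-counting tables and explicit
# enumeration of all mutational pathways per codon, written independently of
# the package's estimator.
ng86_oracle <- function(cds1, cds2) {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  bases <- c("A", "C", "G", "T")
  nsites <- function(codon) {
    s <- 0
    for (pos in 1:3) {
      for (b in bases) {
        if (b == substr(codon, pos, pos)) next
        m <- codon
        substr(m, pos, pos) <- b
        if (code[[m]] != "*" && code[[m]] == code[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms_of(v[-i]), function(r) c(v[i], r))
    }), recursive = FALSE)
  }
  c1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  c2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    S <- S + (nsites(c1[i]) + nsites(c2[i])) / 2
    pos <- which(strsplit(c1[i], "")[[1]] != strsplit(c2[i], "")[[1]])
    if (length(pos) == 0) next
    paths <- perms_of(pos)
    counts <- NULL
    for (p in paths) {
      cur <- c1[i]; sd <- 0; nd <- 0; blocked <- FALSE
      for (pp in p) {
        nxt <- cur
        substr(nxt, pp, pp) <- substr(c2[i], pp, pp)
        if (code[[nxt]] == "*") blocked <- TRUE
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      counts <- rbind(counts, c(sd, nd, blocked))
    }
    ok <- counts[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(counts))
    Sd <- Sd + mean(counts[ok, 1])
    Nd <- Nd + mean(counts[ok, 2])
  }
  N <- 3 * length(c1) - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd, ks = jc(ps), ka = jc(pn))
}

# random stop-free CDS of n codons
random_cds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code_stop <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  cods <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- paste0(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% code_stop) break
    }
    cods[i] <- cd
  }
  paste0(cods, collapse = "")
}

# random point-mutated copy avoiding stop codons
mutate_cds <- function(cds, n_mut, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code_stop <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  x <- strsplit(cds, "")[[1]]
  for (k in seq_len(n_mut)) {
    repeat {
      i <- sample(length(x), 1)
      old <- x[i]
      x[i] <- sample(setdiff(bases, old), 1)
      cod_i <- (i - 1) %/% 3
      cod <- paste0(x[cod_i * 3 + 1:3], collapse = "")
      if (!cod %in% code_stop) break
      x[i] <- old
    }
  }
  paste0(x, collapse = "")
}
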