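# Independent brute-force oracles, written from the definitions with plain
# loops; they share no code with the package internals they check.

.orc_code <- local({
  gc_map <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc_map))
  aa <- gc_map[codons]
  sense <- codons[aa != "*"]
  fams <- split(sense, aa[sense])
  list(codons = codons, aa = aa, sense = sense,
       informative = setdiff(sense, c("ATG", "TGG")),
       fams = fams[vapply(fams, length, 1L) >= 2L])
})

oracle_rscu <- function(counts) {
  out <- setNames(rep(NA_real_, 59), .orc_code$informative)
  for (fam in .orc_code$fams) {
    tot <- sum(counts[fam])
    if (tot > 0) {
      for (cd in fam) out[cd] <- counts[cd] / (tot / length(fam))
    }
  }
  out
}

oracle_nc <- function(counts) {
  fs <- list(); ns <- list()
  for (a in names(.orc_code$fams)) {
    fam <- .orc_code$fams[[a]]
    n <- sum(counts[fam])
    if (n >= 2) {
      p <- counts[fam] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) {
        fs[[a]] <- f
        ns[[a]] <- length(fam)
      }
    }
  }
  cls <- unlist(ns)
  fv <- unlist(fs)
  fbar <- function(k) if (any(cls == k)) mean(fv[cls == k]) else NA_real_
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f4, f6))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

oracle_nc_prime <- function(counts) {
  bases <- c("A", "C", "G", "T")
  # positional composition over sense codons
  pos <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (cd in .orc_code$sense) {
    for (i in 1:3) pos[i, substr(cd, i, i)] <- pos[i, substr(cd, i, i)] +
        counts[cd]
  }
  n_tot <- sum(counts[.orc_code$sense])
  q <- pos / n_tot
  fs <- list(); ns <- list()
  for (a in names(.orc_code$fams)) {
    fam <- .orc_code$fams[[a]]
    m <- length(fam)
    n <- sum(counts[fam])
    if (n < 2) next
    phat <- vapply(fam, function(cd) {
      prod(vapply(1:3, function(i) q[i, substr(cd, i, i)], 1.0))
    }, 1.0)
    if (sum(phat) == 0) next
    phat <- phat / sum(phat)
    chi2 <- 0
    for (j in seq_len(m)) {
      e <- n * phat[j]
      o <- counts[fam[j]]
      if (e == 0) {
        if (o > 0) chi2 <- Inf
      } else {
        chi2 <- chi2 + (o - e)^2 / e
      }
    }
    f <- min((chi2 + n - m) / (m * (n - 1)), 1)
    if (f > 0) {
      fs[[a]] <- f
      ns[[a]] <- m
    }
  }
  cls <- unlist(ns)
  fv <- unlist(fs)
  fbar <- function(k) if (any(cls == k)) mean(fv[cls == k]) else NA_real_
  f2 <- fbar(2); f3 <- fbar(3); f4 <- fbar(4); f6 <- fbar(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f4, f6))) return(NA_real_)
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

oracle_cdc <- function(counts) {
  bases <- c("A", "C", "G", "T")
  pos <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (cd in .orc_code$sense) {
    for (i in 1:3) pos[i, substr(cd, i, i)] <- pos[i, substr(cd, i, i)] +
        counts[cd]
  }
  n_tot <- sum(counts[.orc_code$sense])
  expd <- setNames(numeric(length(.orc_code$sense)), .orc_code$sense)
  for (cd in .orc_code$sense) {
    p <- 1
    for (i in 1:3) {
      gc_i <- (pos[i, "G"] + pos[i, "C"]) / n_tot
      ag_i <- (pos[i, "A"] + pos[i, "G"]) / n_tot
      b <- substr(cd, i, i)
      p <- p * switch(b,
                      G = gc_i * ag_i, C = gc_i * (1 - ag_i),
                      A = (1 - gc_i) * ag_i,
                      T = (1 - gc_i) * (1 - ag_i))
    }
    expd[cd] <- p
  }
  expd <- expd / sum(expd)
  obs <- counts[.orc_code$sense] / n_tot
  1 - sum(obs * expd) / sqrt(sum(obs^2) * sum(expd^2))
}

# classical correspondence analysis via eigen-decomposition of t(S) %*% S
oracle_ca <- function(X) {
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - r %o% cc) / sqrt(r %o% cc)
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  lambda <- ev$values[ev$values > max(ev$values) * 1e-10]
  V <- ev$vectors[, seq_along(lambda), drop = FALSE]
  # row principal coordinates: D_r^{-1/2} S V
  Fr <- unname((S %*% V) / sqrt(r))
  list(inertia = lambda / sum(lambda), row_coords = Fr)
}

# random codon-count vector shaped like a gene of n codons
random_gene_counts <- function(n = 300) {
  probs <- rexp(61)
  cods <- sample(.orc_code$sense, n, replace = TRUE, prob = probs)
  counts <- setNames(numeric(64), .orc_code$codons)
  t <- table(cods)
  counts[names(t)] <- as.numeric(t)
  counts
}

# sequence string from a codon count vector (sorted order, no stop)
seq_from_counts <- function(counts) {
  paste(rep(names(counts), counts), collapse = "")
}

# reverse-translate a protein using one fixed codon per amino acid
reverse_translate <- function(prot) {
  fams <- c(.orc_code$fams, list(M = "ATG", W = "TGG"))
  aa2codon <- vapply(fams, `[`, character(1), 1L)
  names(aa2codon) <- names(fams)
  paste(aa2codon[strsplit(prot, "")[[1]]], collapse = "")
}
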