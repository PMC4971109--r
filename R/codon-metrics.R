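## Per-gene codon usage quantities: codon counts, GC fractions, RSCU, CAI,
## Nc (Wright), Nc' (composition-corrected), CDC, the [0,1] rescaling and the
## cosine similarity used for tRNA comparison.
##
## Everything is implemented on a genes x 64 codon count matrix so that whole
## pangenomes are processed in vectorized form; the exported per-gene
## operations wrap single-row matrices.

#' Count codons of one CDS
#'
#' Non-overlapping triplets from position 1. A terminal stop codon is dropped
#' by default; codons containing N are excluded from the counts and from
#' `n_codons`. Stop codons never contribute to GC or positional composition.
#'
#' @param record a `gene_records` row, or a single nucleotide string.
#' @param drop_terminal_stop drop a trailing TAA/TAG/TGA before counting.
#' @return list of class `codon_counts`: `counts` (named integer, 64 codons),
#'   `n_codons` (total sense codons counted), `pos_counts` (3 x 4 positional
#'   nucleotide counts over counted sense codons).
#' @export
count_codons <- function(record, drop_terminal_stop = TRUE) {
  seq <- if (is.data.frame(record)) record$sequence[1] else as.character(record)
  seq <- toupper(seq)
  if (nchar(seq) == 0L || nchar(seq) %% 3L != 0L) {
    .val_err("sequence length ", nchar(seq), " is not a positive multiple of 3")
  }
  code <- genetic_code()
  cods <- .codon_split(seq)
  if (drop_terminal_stop && cods[length(cods)] %in% code$stops) {
    cods <- cods[-length(cods)]
  }
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  counts <- setNames(integer(64L), code$codons)
  tab <- table(factor(cods, levels = code$codons))
  counts[] <- as.integer(tab)
  M <- matrix(counts, nrow = 1L, dimnames = list(NULL, code$codons))
  structure(
    list(counts = counts,
         n_codons = sum(counts[code$sense]),
         pos_counts = .pos_counts_m(M)),
    class = "codon_counts"
  )
}

#' Codon count matrix for a record table
#'
#' Applies [count_codons()] to every record; rows are genes (rownames =
#' gene_id), columns the 64 codons in alphabetical order.
#'
#' @inheritParams count_codons
#' @param records `gene_records`.
#' @return integer matrix, genes x 64.
#' @export
codon_count_matrix <- function(records, drop_terminal_stop = TRUE) {
  code <- genetic_code()
  M <- matrix(0L, nrow = nrow(records), ncol = 64L,
              dimnames = list(records$gene_id, code$codons))
  for (i in seq_len(nrow(records))) {
    seq <- records$sequence[i]
    if (nchar(seq) %% 3L != 0L || nchar(seq) == 0L) {
      .val_err("gene ", records$gene_id[i], ": length not a multiple of 3")
    }
    cods <- .codon_split(seq)
    if (drop_terminal_stop && cods[length(cods)] %in% code$stops) {
      cods <- cods[-length(cods)]
    }
    cods <- cods[!grepl("N", cods, fixed = TRUE)]
    M[i, ] <- as.integer(table(factor(cods, levels = code$codons)))
  }
  M
}

# 3 x 4 (or genes x 4 per position) positional nucleotide counts over sense
# codons; returns 3x4 matrix for a single-row M, else list of 3 n x 4 matrices
.pos_counts_m <- function(M, as_list = FALSE) {
  code <- genetic_code()
  Ms <- M[, code$sense, drop = FALSE]
  out <- lapply(1:3, function(i) {
    Ms %*% code$base_at[[i]][code$sense, , drop = FALSE]
  })
  if (as_list || nrow(M) > 1L) {
    return(out)
  }
  m <- do.call(rbind, lapply(out, function(x) x[1, ]))
  rownames(m) <- c("pos1", "pos2", "pos3")
  m
}

.as_count_matrix <- function(counts) {
  if (inherits(counts, "codon_counts")) {
    matrix(counts$counts, nrow = 1L,
           dimnames = list(NULL, names(counts$counts)))
  } else if (is.matrix(counts)) {
    counts
  } else if (is.numeric(counts) && !is.null(names(counts))) {
    code <- genetic_code()
    v <- setNames(numeric(64L), code$codons)
    v[names(counts)] <- counts
    matrix(v, nrow = 1L, dimnames = list(NULL, code$codons))
  } else {
    .val_err("expected codon_counts, a named count vector, or a count matrix")
  }
}

# ---- GC fractions -----------------------------------------------------------

.gc_m <- function(M) {
  pos <- .pos_counts_m(M, as_list = TRUE)
  n <- rowSums(M[, genetic_code()$sense, drop = FALSE])
  gcs <- vapply(pos, function(p) (p[, "G"] + p[, "C"]) / n, numeric(nrow(M)))
  gcs <- matrix(gcs, nrow = nrow(M))
  data.frame(gc = rowMeans(gcs), gc1 = gcs[, 1], gc2 = gcs[, 2],
             gc3 = gcs[, 3], gc12 = (gcs[, 1] + gcs[, 2]) / 2)
}

#' Positional GC fractions of a gene
#'
#' `gc1`, `gc2`, `gc3` are the G+C fractions at the three codon positions over
#' counted sense codons; `gc` is their mean and `gc12 = (gc1 + gc2)/2` (the
#' neutrality-plot ordinate).
#'
#' @param counts `codon_counts` from [count_codons()].
#' @return named numeric: gc, gc1, gc2, gc3, gc12.
#' @export
gc_contents <- function(counts) {
  M <- .as_count_matrix(counts)
  if (sum(M[, genetic_code()$sense]) == 0) {
    .val_err("no counted sense codons: GC content undefined")
  }
  unlist(.gc_m(M)[1, ])
}

# ---- RSCU -------------------------------------------------------------------

.rscu_m <- function(M) {
  code <- genetic_code()
  out <- matrix(NA_real_, nrow = nrow(M), ncol = length(code$informative),
                dimnames = list(rownames(M), code$informative))
  for (fam in code$families) {
    tot <- rowSums(M[, fam, drop = FALSE])
    r <- M[, fam, drop = FALSE] * length(fam) / tot   # NaN/Inf when tot == 0
    r[tot == 0, ] <- NA_real_
    out[, fam] <- r
  }
  out
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F, RSCU = count_c / (mean count over F).
#' Only the 59 informative codons (61 sense minus ATG and TGG) are reported;
#' a family with zero total yields missing values, never zeros.
#'
#' @param counts `codon_counts`.
#' @return named numeric, length 59.
#' @export
rscu <- function(counts) {
  .rscu_m(.as_count_matrix(counts))[1, ]
}

# ---- CAI --------------------------------------------------------------------

#' Relative adaptiveness weights for CAI
#'
#' From aggregated reference codon counts, per synonymous family:
#' `w_c = (count_c + pseudocount) / (max family count + pseudocount)`, so the
#' most used codon of each family has weight 1.
#'
#' @param reference `codon_counts`, a named codon count vector, or a count
#'   matrix (rows are summed).
#' @param pseudocount added to every count (default 0.5) so unobserved
#'   reference codons keep a positive weight.
#' @return named numeric, weights for the 59 informative codons.
#' @export
cai_weights <- function(reference, pseudocount = 0.5) {
  M <- .as_count_matrix(reference)
  tot <- colSums(M)
  code <- genetic_code()
  if (sum(tot[code$sense]) == 0) {
    .val_err("empty CAI reference: no codon counts")
  }
  w <- setNames(numeric(length(code$informative)), code$informative)
  for (fam in code$families) {
    cnt <- tot[fam]
    w[fam] <- (cnt + pseudocount) / (max(cnt) + pseudocount)
  }
  w
}

.cai_m <- function(M, weights) {
  cods <- names(weights)
  logw <- log(weights)
  n <- rowSums(M[, cods, drop = FALSE])
  out <- exp(as.vector(M[, cods, drop = FALSE] %*% logw) / n)
  out[n == 0] <- NA_real_
  out
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights over the gene's
#' codons, excluding ATG, TGG and stops. Ranges from 0 (no adaptation) to 1
#' (only most-preferred codons).
#'
#' @param counts `codon_counts`.
#' @param weights from [cai_weights()].
#' @return numeric in \[0, 1\].
#' @export
cai <- function(counts, weights) {
  v <- .cai_m(.as_count_matrix(counts), weights)
  if (is.na(v)) .val_err("CAI undefined: no codons from degenerate families")
  v
}

# ---- Nc (Wright) and Nc' (composition-corrected) ---------------------------

# family homozygosity layout shared by nc variants: returns list of
# F matrix (genes x 18), usable matrix, family degeneracy classes
.nc_combine <- function(Fm, usable, classes) {
  n_genes <- nrow(Fm)
  fbar <- function(k) {
    sel <- classes == k
    u <- usable[, sel, drop = FALSE]
    fs <- Fm[, sel, drop = FALSE]
    fs[!u] <- 0
    cnt <- rowSums(u)
    s <- rowSums(fs)
    list(mean = ifelse(cnt > 0, s / cnt, NA_real_), count = cnt)
  }
  f2 <- fbar(2L); f3 <- fbar(3L); f4 <- fbar(4L); f6 <- fbar(6L)
  f3m <- f3$mean
  impute <- f3$count == 0 & f2$count > 0 & f4$count > 0
  f3m[impute] <- (f2$mean[impute] + f4$mean[impute]) / 2
  nc <- 2 + 9 / f2$mean + 1 / f3m + 5 / f4$mean + 3 / f6$mean
  nc[f2$count == 0 | f4$count == 0 | f6$count == 0] <- NA_real_
  pmin(nc, 61)
}

.nc_m <- function(M) {
  code <- genetic_code()
  fams <- code$families
  nf <- length(fams)
  n_genes <- nrow(M)
  Fm <- matrix(NA_real_, n_genes, nf)
  usable <- matrix(FALSE, n_genes, nf)
  for (j in seq_len(nf)) {
    sub <- M[, fams[[j]], drop = FALSE]
    n <- rowSums(sub)
    ss <- rowSums(sub^2)
    f <- (ss / n - 1) / (n - 1)
    ok <- n >= 2 & !is.na(f) & f > 0
    Fm[, j] <- f
    usable[, j] <- ok
  }
  classes <- lengths(fams)
  .nc_combine(Fm, usable, classes)
}

#' Effective number of codons (Wright's Nc)
#'
#' Per synonymous family with total count n >= 2, homozygosity
#' `F = (n * sum(p^2) - 1) / (n - 1)`; class means over usable families
#' (F > 0); `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. If the 3-fold (Ile) family
#' is unusable its F is imputed as (F2 + F4)/2; if any other degeneracy class
#' has no usable family the value is missing. Capped at 61.
#'
#' @param counts `codon_counts`.
#' @return numeric in \[20, 61\], or NA.
#' @export
nc_wright <- function(counts) {
  .nc_m(.as_count_matrix(counts))
}

.nc_prime_m <- function(M) {
  code <- genetic_code()
  pos <- .pos_counts_m(M, as_list = TRUE)
  n_cod <- rowSums(M[, code$sense, drop = FALSE])
  Q <- lapply(pos, function(p) p / n_cod)   # genes x 4 positional freqs
  bases <- c("A", "C", "G", "T")
  fams <- code$families
  nf <- length(fams)
  n_genes <- nrow(M)
  Fm <- matrix(NA_real_, n_genes, nf)
  usable <- matrix(FALSE, n_genes, nf)
  for (j in seq_len(nf)) {
    fam <- fams[[j]]
    m <- length(fam)
    sub <- M[, fam, drop = FALSE]
    n <- rowSums(sub)
    # expected within-family frequencies from positional composition
    phat <- matrix(1, n_genes, m)
    for (i in 1:3) {
      b <- match(substr(fam, i, i), bases)
      phat <- phat * Q[[i]][, b, drop = FALSE]
    }
    ps <- rowSums(phat)
    phat <- phat / ps
    exp_cnt <- phat * n
    term <- (sub - exp_cnt)^2 / exp_cnt
    term[phat == 0 & sub == 0] <- 0
    term[phat == 0 & sub > 0] <- Inf
    chi2 <- rowSums(term)
    fhat <- (chi2 + n - m) / (m * (n - 1))
    fhat <- pmin(fhat, 1)
    ok <- n >= 2 & !is.na(fhat) & fhat > 0
    ok[is.na(ps) | ps == 0] <- FALSE
    Fm[, j] <- fhat
    usable[, j] <- ok
  }
  .nc_combine(Fm, usable, lengths(fams))
}

#' Composition-corrected effective number of codons (Nc')
#'
#' As [nc_wright()] but the family homozygosity is
#' `Fhat = (chi2 + n - m) / (m * (n - 1))`, where m is the family size and
#' chi2 measures the deviation of observed counts from frequencies expected
#' under the gene's own positional nucleotide composition (product over the
#' three codon positions, renormalized within the family). Fhat is clipped
#' to (0, 1]; class combination, Ile imputation and the 61-cap follow
#' [nc_wright()].
#'
#' @param counts `codon_counts`.
#' @return numeric in \[20, 61\], or NA.
#' @export
nc_prime <- function(counts) {
  .nc_prime_m(.as_count_matrix(counts))
}

# ---- CDC --------------------------------------------------------------------

.cdc_m <- function(M) {
  code <- genetic_code()
  pos <- .pos_counts_m(M, as_list = TRUE)
  n <- rowSums(M[, code$sense, drop = FALSE])
  bases <- c("A", "C", "G", "T")
  n_genes <- nrow(M)
  expd <- matrix(1, n_genes, 64L, dimnames = list(NULL, code$codons))
  for (i in 1:3) {
    p <- pos[[i]] / n
    gc_i <- p[, "G"] + p[, "C"]
    ag_i <- p[, "A"] + p[, "G"]
    Pi <- cbind(A = (1 - gc_i) * ag_i, C = gc_i * (1 - ag_i),
                G = gc_i * ag_i, T = (1 - gc_i) * (1 - ag_i))
    b <- match(substr(code$codons, i, i), bases)
    expd <- expd * Pi[, b, drop = FALSE]
  }
  expd <- expd[, code$sense, drop = FALSE]
  tot <- rowSums(expd)
  expd <- expd / tot
  obs <- M[, code$sense, drop = FALSE] / n
  cosv <- rowSums(obs * expd) /
    sqrt(rowSums(obs^2) * rowSums(expd^2))
  out <- pmin(pmax(1 - cosv, 0), 1)
  out[tot == 0 | n == 0] <- NA_real_
  out
}

#' Codon deviation coefficient
#'
#' One minus the cosine similarity between the observed sense-codon usage and
#' the usage expected from the gene's positional GC and purine contents
#' (`P_i(G) = GC_i * AG_i`, etc.; expected codon probability is the product
#' over positions, renormalized over the 61 sense codons). 0 = no deviation,
#' 1 = maximal.
#'
#' @param counts `codon_counts`.
#' @return numeric in \[0, 1\].
#' @export
cdc <- function(counts) {
  M <- .as_count_matrix(counts)
  if (sum(M[, genetic_code()$sense]) == 0) {
    .val_err("CDC undefined: no counted sense codons")
  }
  v <- .cdc_m(M)
  if (is.na(v)) {
    .val_err("CDC undefined: expected codon mass degenerate (stops only)")
  }
  v
}

# ---- rescaling and cosine ---------------------------------------------------

#' Rescale an Nc-scale value to a 0-1 bias scale
#'
#' Maps the \[20, 61\] Nc range onto \[0, 1\] via `(61 - x) / 41`, so 0 means
#' no bias (Nc = 61) and 1 maximal bias (Nc = 20). NA passes through.
#'
#' @param x numeric in \[20, 61\] (Nc or Nc').
#' @return numeric in \[0, 1\].
#' @export
rescale_bias <- function(x) {
  bad <- !is.na(x) & (x < 20 - 1e-9 | x > 61 + 1e-9)
  if (any(bad)) {
    .val_err("Nc value outside [20, 61]: ", paste(x[bad], collapse = ", "))
  }
  (61 - x) / 41
}

#' Cosine similarity between two non-negative vectors
#'
#' `sum(x * y) / (||x|| * ||y||)`; entries missing in either vector are
#' dropped pairwise. Ranges from 0 (orthogonal usage) to 1 (proportional).
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return numeric in \[0, 1\].
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) .val_err("cosine: unequal lengths")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (any(x < 0) || any(y < 0)) .val_err("cosine: negative entries")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) .val_err("cosine undefined: zero-norm vector")
  min(sum(x * y) / (nx * ny), 1)
}

# ---- per-gene metric table --------------------------------------------------

#' Default CAI reference weights from annotated records
#'
#' Pools codon counts over genes whose product annotation matches `pattern`
#' (default: ribosomal proteins, the Sharp-Li convention for highly expressed
#' reference genes). Falls back, with a warning, to all genes when nothing
#' matches.
#'
#' @param records `gene_records`.
#' @param pattern regular expression matched case-insensitively on `product`.
#' @param pseudocount see [cai_weights()].
#' @return named weight vector.
#' @export
default_cai_weights <- function(records, pattern = "ribosomal protein",
                                pseudocount = 0.5) {
  sel <- grepl(pattern, records$product, ignore.case = TRUE)
  if (!any(sel)) {
    warning("no products match '", pattern,
            "'; CAI reference falls back to all genes", call. = FALSE)
    sel <- rep(TRUE, nrow(records))
  }
  cai_weights(codon_count_matrix(records[sel, , drop = FALSE]),
              pseudocount = pseudocount)
}

#' Compute the per-gene codon-usage metrics table
#'
#' One row per gene with at least `min_len` counted sense codons (after the
#' terminal stop is dropped): positional GC fractions, CAI, Nc, Nc', CDC and
#' the rescaled Nc values. Genes flagged `is_excluded` are dropped first.
#' The per-gene RSCU (genes x 59) and raw codon count (genes x 64) matrices
#' are attached as attributes `"rscu"` and `"counts"` for downstream
#' correspondence and tRNA analyses.
#'
#' @param records `gene_records`.
#' @param partition optional named character vector gene_id -> set label
#'   (see [gene_set_labels()]); unlisted genes get NA.
#' @param weights CAI weights; default [default_cai_weights()] on `records`.
#' @param min_len minimum gene length in codons (default 100; genes shorter
#'   than this are excluded to avoid small-sample bias in the measures).
#' @param drop_terminal_stop see [count_codons()].
#' @return data.frame of class `cub_metrics`.
#' @export
compute_metrics <- function(records, partition = NULL, weights = NULL,
                            min_len = 100L, drop_terminal_stop = TRUE) {
  records <- records[!records$is_excluded, , drop = FALSE]
  if (is.null(weights)) {
    weights <- default_cai_weights(records)
  }
  M <- codon_count_matrix(records, drop_terminal_stop = drop_terminal_stop)
  n_cod <- rowSums(M[, genetic_code()$sense, drop = FALSE])
  keep <- n_cod >= min_len
  M <- M[keep, , drop = FALSE]
  records <- records[keep, , drop = FALSE]
  n_cod <- n_cod[keep]
  gcs <- .gc_m(M)
  nc <- .nc_m(M)
  ncp <- .nc_prime_m(M)
  df <- data.frame(
    gene_id = records$gene_id,
    strain_id = records$strain_id,
    set_label = if (is.null(partition)) NA_character_
                else unname(partition[records$gene_id]),
    length_codons = as.integer(n_cod),
    gcs,
    cai = .cai_m(M, weights),
    nc = nc,
    nc_prime = ncp,
    cdc = .cdc_m(M),
    nc_rescaled = rescale_bias(nc),
    nc_prime_rescaled = rescale_bias(ncp),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  attr(df, "rscu") <- .rscu_m(M)
  attr(df, "counts") <- M
  class(df) <- c("cub_metrics", "data.frame")
  df
}
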