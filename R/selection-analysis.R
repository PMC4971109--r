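## Mutation-vs-selection diagnostics per gene set: ENC-plot deviation from
## the mutation-only expectation, neutrality-plot regression of GC12 on GC3,
## correspondence analysis of RSCU with factor correlations, CUB-expression
## correlation, tRNA-RSCU cosine similarity, and the supporting statistics.

#' Expected Nc under mutation alone
#'
#' The null ENC-plot curve: `2 + x + 29 / (x^2 + (1 - x)^2)` with x = GC3.
#' A gene shaped only by compositional (mutational) pressure falls on this
#' curve; falling well below it indicates selective codon preference.
#'
#' @param gc3 numeric in \[0, 1\].
#' @return expected Nc.
#' @export
expected_nc <- function(gc3) {
  if (any(!is.na(gc3) & (gc3 < 0 | gc3 > 1))) {
    .val_err("gc3 must lie in [0, 1]")
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' ENC-plot deviations per gene and gene set
#'
#' Per gene, `deviation = (expected - estimated) / expected` with expected Nc
#' from [expected_nc()] at the gene's GC3; a gene is flagged deviated when
#' deviation exceeds the threshold (default 0.15). Per gene set, the deviated
#' fraction is reported for every threshold in the sweep.
#'
#' @param metrics `cub_metrics` table.
#' @param thresholds sweep of thresholds (default 0.05..0.30 by 0.05).
#' @param threshold default flagging threshold (0.15).
#' @param nc_column which estimate to use: `"nc"` (Wright) or `"nc_prime"`.
#' @return list of class `enc_plot`: `genes` (gene_id, set_label, gc3,
#'   estimated_nc, expected_nc, deviation, deviated), `sweep` (set_label,
#'   threshold, fraction_deviated, n), `n_missing` (genes dropped for
#'   missing Nc), `threshold`.
#' @export
enc_plot <- function(metrics,
                     thresholds = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                     threshold = 0.15, nc_column = c("nc", "nc_prime")) {
  nc_column <- match.arg(nc_column)
  est <- metrics[[nc_column]]
  keep <- !is.na(est)
  n_missing <- sum(!keep)
  m <- metrics[keep, , drop = FALSE]
  est <- est[keep]
  expv <- expected_nc(m$gc3)
  dev <- (expv - est) / expv
  genes <- data.frame(gene_id = m$gene_id,
                      set_label = as.character(m$set_label),
                      gc3 = m$gc3, estimated_nc = est, expected_nc = expv,
                      deviation = dev, deviated = dev > threshold,
                      stringsAsFactors = FALSE)
  sets <- split(dev, genes$set_label)
  sweep <- do.call(rbind, lapply(names(sets), function(s) {
    data.frame(set_label = s, threshold = thresholds,
               fraction_deviated = vapply(thresholds,
                                          function(t) mean(sets[[s]] > t),
                                          numeric(1)),
               n = length(sets[[s]]), stringsAsFactors = FALSE)
  }))
  structure(list(genes = genes, sweep = sweep, n_missing = n_missing,
                 threshold = threshold),
            class = "enc_plot")
}

# closed-form ordinary least squares with Pearson r and two-sided t-test p
.ols_xy <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                p = NA_real_, n = n))
  }
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  p <- if (is.na(r) || n < 3) NA_real_ else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r = r, p = p, n = n)
}

#' Neutrality-plot regression per gene set
#'
#' Ordinary least squares of GC12 on GC3 within each gene set, with Pearson
#' r and a two-sided p. A slope of 1 indicates complete neutrality
#' (directional mutation pressure alone); 0 indicates no effect of mutation
#' pressure (complete selective constraint).
#'
#' @param metrics `cub_metrics` with set labels.
#' @param min_n minimum genes per set (default 3).
#' @return data.frame (set_label, slope, intercept, r, p, n) of class
#'   `neutrality_result`.
#' @export
neutrality_plot <- function(metrics, min_n = 3L) {
  sets <- split(metrics, as.character(metrics$set_label))
  out <- do.call(rbind, lapply(names(sets), function(s) {
    m <- sets[[s]]
    if (nrow(m) < min_n) {
      return(data.frame(set_label = s, slope = NA_real_,
                        intercept = NA_real_, r = NA_real_, p = NA_real_,
                        n = nrow(m), stringsAsFactors = FALSE))
    }
    f <- .ols_xy(m$gc3, m$gc12)
    data.frame(set_label = s, slope = f$slope, intercept = f$intercept,
               r = f$r, p = f$p, n = f$n, stringsAsFactors = FALSE)
  }))
  class(out) <- c("neutrality_result", "data.frame")
  out
}

#' Correspondence analysis of the gene x RSCU matrix
#'
#' Classical CA: the RSCU matrix (59 informative codons; missing family
#' entries imputed as 0) is scaled to a correspondence matrix, row and column
#' masses removed, standardized residuals decomposed by SVD, and row
#' principal coordinates returned. Axis signs are fixed so the codon loading
#' of largest magnitude on each axis is positive. Axis 1 is flagged a "major
#' trend" when its inertia fraction exceeds 0.10.
#'
#' @param metrics `cub_metrics` (needs the `"rscu"` attribute).
#' @param n_axes axes to retain (default 4).
#' @return list of class `coa_result`: `row_coords` (genes x n_axes principal
#'   coordinates), `col_coords` (codon principal coordinates), `inertia`
#'   (fraction per axis, all axes), `major_trend` (axis-1 inertia > 0.10),
#'   `dropped` (gene ids with zero RSCU rows), `n_axes`.
#' @export
coa_rscu <- function(metrics, n_axes = 4L) {
  R <- attr(metrics, "rscu")
  if (is.null(R)) .val_err("metrics lack the rscu attribute")
  rownames(R) <- metrics$gene_id
  R[is.na(R)] <- 0
  tot <- rowSums(R)
  dropped <- rownames(R)[tot == 0]
  R <- R[tot > 0, , drop = FALSE]
  if (nrow(R) < 2L) .val_err("COA needs >= 2 genes with nonzero RSCU")
  # codons unused across the whole collection carry no mass
  dropped_codons <- colnames(R)[colSums(R) == 0]
  R <- R[, colSums(R) > 0, drop = FALSE]
  P <- R / sum(R)
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- (P - outer(r, c_)) / sqrt(outer(r, c_))
  sv <- svd(S)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) .val_err("degenerate COA: all rows identical (zero inertia)")
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  k <- min(n_axes, length(d))
  row_coords <- sweep(U / sqrt(r), 2, d, `*`)[, seq_len(k), drop = FALSE]
  col_coords <- sweep(V / sqrt(c_), 2, d, `*`)[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| codon positive on each axis
  for (j in seq_len(k)) {
    i_max <- which.max(abs(col_coords[, j]))
    if (col_coords[i_max, j] < 0) {
      col_coords[, j] <- -col_coords[, j]
      row_coords[, j] <- -row_coords[, j]
    }
  }
  dimnames(row_coords) <- list(rownames(R), paste0("axis", seq_len(k)))
  dimnames(col_coords) <- list(colnames(R), paste0("axis", seq_len(k)))
  inertia <- d^2 / sum(d^2)
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = inertia, major_trend = inertia[1] > 0.10,
                 dropped = dropped, dropped_codons = dropped_codons,
                 n_axes = k),
            class = "coa_result")
}

#' Spearman correlations between COA axis 1 and gene-level factors
#'
#' For each gene set (and pooled over all genes as set `"all"`), Spearman's
#' rho between the axis-1 coordinate and each factor; signed and absolute
#' values are reported. Factors with fewer than 3 non-missing values in a
#' set are skipped with a warning.
#'
#' @param coa `coa_result`.
#' @param metrics `cub_metrics`.
#' @param factors columns of `metrics` to correlate (default gc, gc1, gc2,
#'   gc3, length_codons, cai, nc, nc_prime, cdc).
#' @param expression optional named abundance vector; adds factor
#'   `"expression"`.
#' @return data.frame (set_label, factor, rho, abs_rho, p, n).
#' @export
axis_factor_correlations <- function(coa, metrics,
                                     factors = c("gc", "gc1", "gc2", "gc3",
                                                 "length_codons", "cai",
                                                 "nc", "nc_prime", "cdc"),
                                     expression = NULL) {
  ax <- coa$row_coords[, 1]
  m <- metrics[match(names(ax), metrics$gene_id), , drop = FALSE]
  fac_values <- lapply(factors, function(f) {
    if (!f %in% names(m)) .val_err("unknown factor: ", f)
    as.numeric(m[[f]])
  })
  names(fac_values) <- factors
  if (!is.null(expression)) {
    fac_values$expression <- unname(expression[m$gene_id])
  }
  groups <- c(list(all = rep(TRUE, nrow(m))),
              lapply(split(seq_len(nrow(m)), as.character(m$set_label)),
                     function(i) seq_len(nrow(m)) %in% i))
  out <- list()
  for (s in names(groups)) {
    sel <- groups[[s]]
    for (f in names(fac_values)) {
      v <- fac_values[[f]][sel]
      a <- ax[sel]
      ok <- !is.na(v) & !is.na(a)
      if (sum(ok) < 3L) {
        warning("factor ", f, " in set ", s, ": < 3 values, skipped",
                call. = FALSE)
        next
      }
      sp <- spearman_rho(a[ok], v[ok])
      out[[length(out) + 1L]] <- data.frame(
        set_label = s, factor = f, rho = sp[["rho"]],
        abs_rho = abs(sp[["rho"]]), p = sp[["p"]], n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlation between codon usage bias and expression per gene set
#'
#' Spearman's rho between a CUB field (default CAI) and expression abundance
#' within each gene set. Sets with insufficient overlap yield NA with the
#' available count.
#'
#' @param metrics `cub_metrics`.
#' @param expr named abundance vector (gene_id -> abundance).
#' @param field CUB column to correlate (default `"cai"`).
#' @param min_n minimum genes with expression per set (default 3).
#' @return data.frame (set_label, rho, p, n).
#' @export
expression_correlation <- function(metrics, expr, field = "cai",
                                   min_n = 3L) {
  if (!field %in% names(metrics)) .val_err("unknown CUB field: ", field)
  sets <- split(metrics, as.character(metrics$set_label))
  do.call(rbind, lapply(names(sets), function(s) {
    m <- sets[[s]]
    ab <- unname(expr[m$gene_id])
    ok <- !is.na(ab) & !is.na(m[[field]])
    if (sum(ok) < min_n) {
      return(data.frame(set_label = s, rho = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    sp <- spearman_rho(m[[field]][ok], ab[ok])
    data.frame(set_label = s, rho = sp[["rho"]], p = sp[["p"]], n = sum(ok),
               stringsAsFactors = FALSE)
  }))
}

#' Map tRNA copy numbers onto the 59 informative codons
#'
#' Strict Watson-Crick: a codon receives the copy number of the tRNA whose
#' anticodon is its reverse complement (0 if absent). With `wobble = TRUE`,
#' a codon ending in T additionally receives copies of the G34 wobble
#' anticodon, and a codon ending in G those of the U34 anticodon.
#'
#' @param trna `trna_table`.
#' @param wobble enable GU wobble decoding (default FALSE).
#' @return named numeric over the 59 informative codons.
#' @export
trna_codon_vector <- function(trna, wobble = FALSE) {
  code <- genetic_code()
  ac <- revcomp(code$informative)
  get_cn <- function(a) ifelse(a %in% names(trna), trna[a], 0)
  v <- as.numeric(get_cn(ac))
  if (wobble) {
    third <- substr(code$informative, 3, 3)
    wob <- ifelse(third == "T", paste0("G", substr(ac, 2, 3)),
           ifelse(third == "G", paste0("T", substr(ac, 2, 3)), NA))
    add <- ifelse(is.na(wob), 0, as.numeric(get_cn(wob)))
    v <- v + add
  }
  setNames(v, code$informative)
}

#' Similarity between tRNA abundance and RSCU per gene set
#'
#' Per gene set, codon counts are pooled over member genes (or, with
#' `average = TRUE`, per-gene RSCU vectors are averaged), the pooled RSCU over
#' the 59 informative codons is computed, and its cosine similarity with the
#' tRNA copy-number vector (see [trna_codon_vector()]) is reported.
#'
#' @param metrics `cub_metrics` (needs the `"counts"` attribute).
#' @param trna `trna_table`.
#' @param wobble see [trna_codon_vector()].
#' @param average average per-gene RSCU instead of pooling counts.
#' @return data.frame (set_label, similarity, codon_coverage, n_genes) of
#'   class `similarity_result`.
#' @export
trna_similarity_by_set <- function(metrics, trna, wobble = FALSE,
                                   average = FALSE) {
  if (length(trna) == 0L) .val_err("empty tRNA table")
  tv <- trna_codon_vector(trna, wobble = wobble)
  if (sum(tv) == 0) {
    .val_err("tRNA vector has zero norm over informative codons")
  }
  M <- attr(metrics, "counts")
  if (is.null(M)) .val_err("metrics lack the counts attribute")
  sets <- split(seq_len(nrow(metrics)), as.character(metrics$set_label))
  out <- do.call(rbind, lapply(names(sets), function(s) {
    idx <- sets[[s]]
    if (average) {
      R <- .rscu_m(M[idx, , drop = FALSE])
      pooled <- colMeans(R, na.rm = TRUE)
      pooled[is.nan(pooled)] <- NA_real_
    } else {
      pooled <- .rscu_m(matrix(colSums(M[idx, , drop = FALSE]), nrow = 1,
                               dimnames = list(NULL, colnames(M))))[1, ]
    }
    data.frame(set_label = s,
               similarity = cosine_similarity(pooled, tv),
               codon_coverage = sum(tv[!is.na(pooled)] > 0),
               n_genes = length(idx), stringsAsFactors = FALSE)
  }))
  class(out) <- c("similarity_result", "data.frame")
  out
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with (k - 1, N - k) degrees of
#' freedom and upper-tail p. Zero variance everywhere gives F = 0.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return named numeric: F, p, df1, df2.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    .val_err("one_way_anova needs >= 2 groups with >= 2 values each")
  }
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  c(F = f, p = p, df1 = df1, df2 = df2)
}

#' Spearman's rank correlation with t-approximation p
#'
#' Pearson correlation of average ranks (ties get mean rank); two-sided p
#' from the t approximation with n - 2 degrees of freedom. Zero rank
#' variance yields NA with a warning.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return named numeric: rho, p, n.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .val_err("spearman: unequal lengths")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) .val_err("spearman needs >= 3 paired values")
  rx <- rank(x); ry <- rank(y)
  sdx <- sum((rx - mean(rx))^2)
  sdy <- sum((ry - mean(ry))^2)
  if (sdx == 0 || sdy == 0) {
    warning("spearman undefined: zero rank variance", call. = FALSE)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sdx * sdy)
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  c(rho = rho, p = p, n = n)
}
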