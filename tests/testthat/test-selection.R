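# fabricate a minimal metrics table for diagnostics that only need a few
# columns
fake_metrics <- function(n, set = "core", gc3 = runif(n), gc12 = runif(n),
                         nc = runif(n, 30, 60)) {
  df <- data.frame(gene_id = sprintf("%s:g%03d", set, seq_len(n)),
                   set_label = set, gc3 = gc3, gc12 = gc12, nc = nc,
                   stringsAsFactors = FALSE)
  class(df) <- c("cub_metrics", "data.frame")
  df
}

test_that("expected_nc evaluates the mutation-only curve", {
  expect_equal(expected_nc(0.5), 60.5)
  expect_equal(expected_nc(0), 31)
  expect_equal(expected_nc(1), 32)
  # the curve is symmetric about 0.5 up to the linear term
  x <- seq(0, 1, 0.1)
  expect_equal(expected_nc(x) - x, expected_nc(1 - x) - (1 - x))
  expect_error(expected_nc(1.2), class = "pancub_validation_error")
})

test_that("enc_plot computes deviations and a monotone sweep", {
  m <- fake_metrics(3, gc3 = c(0.5, 0.5, 0.5),
                    nc = c(60.5, 45.375, NA))
  ep <- enc_plot(m)
  expect_equal(ep$n_missing, 1L)
  expect_equal(ep$genes$deviation, c(0, 0.25))
  expect_equal(ep$genes$deviated, c(FALSE, TRUE))

  set.seed(10)
  m2 <- fake_metrics(200, nc = runif(200, 25, 61))
  sweep <- enc_plot(m2)$sweep
  expect_true(all(diff(sweep$fraction_deviated) <= 0))
})

test_that("neutrality_plot recovers exact and random regressions", {
  m <- fake_metrics(10, gc3 = seq(0.1, 0.9, length.out = 10),
                    gc12 = seq(0.1, 0.9, length.out = 10))
  nt <- neutrality_plot(m)
  expect_equal(nt$slope, 1)
  expect_equal(nt$r, 1)

  m2 <- fake_metrics(10, gc3 = runif(10), gc12 = rep(0.4, 10))
  expect_equal(neutrality_plot(m2)$slope, 0)

  set.seed(11)
  m3 <- fake_metrics(120, gc3 = runif(120),
                     gc12 = 0.3 + 0.4 * runif(120) + rnorm(120, 0, 0.02))
  nt3 <- neutrality_plot(m3)
  fit <- lm(gc12 ~ gc3, data = m3)
  ct <- cor.test(m3$gc3, m3$gc12)
  expect_equal(nt3$slope, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_equal(nt3$intercept, unname(coef(fit)[1]), tolerance = 1e-9)
  expect_equal(nt3$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(nt3$p, ct$p.value, tolerance = 1e-9)

  # degenerate x variance: slope reported missing
  m4 <- fake_metrics(5, gc3 = rep(0.5, 5), gc12 = runif(5))
  expect_true(is.na(neutrality_plot(m4)$slope))
})

test_that("coa_rscu agrees with the eigen oracle and vegan", {
  set.seed(12)
  rec <- gene_records(paste0("s1:g", 1:40), "s1",
                      vapply(1:40, function(i)
                        seq_from_counts(random_gene_counts(250)), ""))
  m <- compute_metrics(rec, weights = cai_weights(codon_count_matrix(rec)))
  co <- coa_rscu(m, n_axes = 4)
  expect_equal(sum(co$inertia), 1)

  X <- attr(m, "rscu")
  X[is.na(X)] <- 0
  X <- X[, colSums(X) > 0, drop = FALSE]
  o <- oracle_ca(X)
  k <- ncol(co$row_coords)
  expect_equal(co$inertia[1:k], o$inertia[1:k], tolerance = 1e-9)
  for (j in 1:k) {
    expect_equal(abs(unname(co$row_coords[, j])), abs(o$row_coords[, j]),
                 tolerance = 1e-9)
  }
  if (requireNamespace("vegan", quietly = TRUE)) {
    ca <- vegan::cca(X)
    expect_equal(co$inertia[1:k],
                 unname(ca$CA$eig[1:k] / sum(ca$CA$eig)), tolerance = 1e-6)
  }
})

test_that("coa_rscu axis 1 tracks a built-in GC3 contrast", {
  set.seed(13)
  seqs <- c(
    vapply(1:30, function(i) generate_gene_sequence(300, 0.15, 0), ""),
    vapply(1:30, function(i) generate_gene_sequence(300, 0.85, 0), ""))
  rec <- gene_records(paste0("s1:g", 1:60), "s1", seqs)
  m <- compute_metrics(rec, weights = cai_weights(codon_count_matrix(rec)))
  co <- coa_rscu(m)
  expect_true(co$major_trend)
  rho <- spearman_rho(co$row_coords[, 1], m$gc3)
  expect_gt(abs(rho[["rho"]]), 0.9)

  # row-permutation invariance up to the fixed sign convention
  perm <- sample(nrow(rec))
  m2 <- compute_metrics(rec[perm, ],
                        weights = cai_weights(codon_count_matrix(rec)))
  co2 <- coa_rscu(m2)
  common <- intersect(rownames(co$row_coords), rownames(co2$row_coords))
  expect_equal(co$row_coords[common, 1], co2$row_coords[common, 1],
               tolerance = 1e-8)

  # identical rows: zero inertia is an error
  recs_same <- gene_records(paste0("s1:h", 1:4), "s1",
                            rep(strrep("GCTTTTGAA", 40), 4))
  ms <- compute_metrics(recs_same,
                        weights = cai_weights(codon_count_matrix(recs_same)))
  expect_error(coa_rscu(ms), class = "pancub_validation_error")
})

test_that("axis_factor_correlations reports per-set Spearman rho", {
  set.seed(14)
  seqs <- vapply(runif(50, 0.2, 0.8), function(g)
    generate_gene_sequence(200, g, 0), "")
  rec <- gene_records(paste0("s1:g", 1:50), "s1", seqs)
  labels <- setNames(rep(c("core", "strain_specific"), 25), rec$gene_id)
  m <- compute_metrics(rec, partition = labels,
                       weights = cai_weights(codon_count_matrix(rec)))
  co <- coa_rscu(m)
  # an "expression" factor equal to the axis-1 coordinate: rho exactly 1
  fake_expr <- setNames(co$row_coords[, 1] + 2, rownames(co$row_coords))
  fc <- axis_factor_correlations(co, m, factors = "gc3",
                                 expression = fake_expr)
  expect_equal(fc$rho[fc$set_label == "all" & fc$factor == "expression"], 1)
  expect_true(all(c("rho", "abs_rho", "p") %in% names(fc)))

  # a permuted factor decorrelates on a large sample
  set.seed(15)
  seqs2 <- vapply(runif(400, 0.2, 0.8), function(g)
    generate_gene_sequence(150, g, 0), "")
  rec2 <- gene_records(paste0("s1:h", 1:400), "s1", seqs2)
  m2 <- compute_metrics(rec2, weights = cai_weights(codon_count_matrix(rec2)),
                        min_len = 100)
  co2 <- coa_rscu(m2)
  perm_expr <- setNames(sample(m2$gc3), m2$gene_id)
  fc2 <- axis_factor_correlations(co2, m2, factors = "gc3",
                                  expression = perm_expr)
  row_all <- fc2[fc2$set_label == "all", ]
  expect_gt(row_all$abs_rho[row_all$factor == "gc3"], 0.8)
  expect_lt(row_all$abs_rho[row_all$factor == "expression"], 0.15)
})

test_that("expression_correlation is monotone-faithful per set", {
  set.seed(16)
  m <- fake_metrics(30)
  m$cai <- runif(30)
  expr <- setNames(exp(3 * m$cai), m$gene_id)
  ec <- expression_correlation(m, expr)
  expect_equal(ec$rho, 1)
  expect_equal(ec$n, 30L)

  # insufficient overlap: NA with count
  ec2 <- expression_correlation(m, expr[1:2])
  expect_true(is.na(ec2$rho))
  expect_equal(ec2$n, 2L)

  # all-tied expression: undefined with a warning
  expr3 <- setNames(rep(1, 30), m$gene_id)
  expect_warning(ec3 <- expression_correlation(m, expr3), "zero rank")
  expect_true(is.na(ec3$rho))
})

test_that("trna similarity hits the proportional and disjoint extremes", {
  # uniform codon usage + flat tRNA pool: proportional vectors, similarity 1
  code <- genetic_code()
  rec <- gene_records("s1:u", "s1",
                      paste(rep(code$sense, each = 3), collapse = ""))
  m <- compute_metrics(rec, partition = c("s1:u" = "core"),
                       weights = cai_weights(codon_count_matrix(rec)))
  flat <- trna_table(revcomp(code$informative), rep(5L, 59))
  sim <- trna_similarity_by_set(m, flat)
  expect_equal(sim$similarity, 1)
  expect_equal(sim$codon_coverage, 59L)

  # tRNA copies only on codons the gene never uses: similarity 0
  rec2 <- gene_records("s1:v", "s1",
                       paste0(strrep("TTT", 60), strrep("GCT", 60)))
  m2 <- compute_metrics(rec2, partition = c("s1:v" = "core"),
                        weights = cai_weights(codon_count_matrix(rec2)))
  tt <- trna_table(revcomp(c("TTC", "GCC")), c(5L, 5L))
  sim2 <- trna_similarity_by_set(m2, tt)
  expect_equal(sim2$similarity, 0)

  # averaging mode stays in [0, 1] and runs on multi-gene sets
  set.seed(17)
  rec3 <- gene_records(paste0("s1:g", 1:6), "s1",
                       vapply(1:6, function(i)
                         seq_from_counts(random_gene_counts(200)), ""))
  m3 <- compute_metrics(rec3,
                        partition = setNames(rep("core", 6), rec3$gene_id),
                        weights = cai_weights(codon_count_matrix(rec3)))
  s3 <- trna_similarity_by_set(m3, flat, average = TRUE)
  expect_true(s3$similarity >= 0 && s3$similarity <= 1)

  expect_error(trna_similarity_by_set(m3, trna_table(character(0),
                                                     integer(0))),
               class = "pancub_validation_error")
})

test_that("wobble mapping adds G34/U34 decoding", {
  # tRNA with anticodon GAA decodes TTC (Watson-Crick) and TTT (wobble)
  tt <- trna_table("GAA", 4L)
  v_strict <- trna_codon_vector(tt, wobble = FALSE)
  v_wobble <- trna_codon_vector(tt, wobble = TRUE)
  expect_equal(unname(v_strict[c("TTC", "TTT")]), c(4, 0))
  expect_equal(unname(v_wobble[c("TTC", "TTT")]), c(4, 4))
})

test_that("one_way_anova matches hand values and the reference oracle", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))[["F"]], 0)
  a <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(a[["F"]], 13.5)

  set.seed(18)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(sample(5:20, 1), mean = j / 2))
    mine <- one_way_anova(g)
    ref <- oneway.test(y ~ grp,
                       data = data.frame(y = unlist(g),
                                         grp = factor(rep(seq_along(g),
                                                          lengths(g)))),
                       var.equal = TRUE)
    expect_equal(mine[["F"]], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine[["p"]], ref$p.value, tolerance = 1e-9)
  }
  expect_error(one_way_anova(list(1:3)), class = "pancub_validation_error")
  expect_error(one_way_anova(list(1:3, 2)), class = "pancub_validation_error")
})

test_that("spearman_rho matches the average-rank oracle, with ties", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10))[["rho"]], 1)
  expect_equal(spearman_rho(1:5, 5:1)[["rho"]], -1)

  set.seed(19)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- x + rnorm(30, 0, 2)
    mine <- spearman_rho(x, y)
    expect_equal(mine[["rho"]], unname(cor(rank(x), rank(y))),
                 tolerance = 1e-12)
    ref <- cor.test(rank(x), rank(y), method = "pearson")
    expect_equal(mine[["p"]], ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman_rho(1:2, 1:2), class = "pancub_validation_error")
})
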