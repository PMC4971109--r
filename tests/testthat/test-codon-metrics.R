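test_that("count_codons counts triplets, drops terminal stop, excludes N", {
  cc <- count_codons("ATGGCTGCTTAA")
  expect_equal(unname(cc$counts[c("ATG", "GCT", "TAA")]), c(1L, 2L, 0L))
  expect_equal(cc$n_codons, 3L)

  expect_equal(count_codons("GCTGCTGCT")$counts[["GCT"]], 3L)

  ccN <- count_codons("GCTGNTGCT")
  expect_equal(ccN$counts[["GCT"]], 2L)
  expect_equal(ccN$n_codons, 2L)

  expect_error(count_codons("GCTGC"), class = "pancub_validation_error")
  # keep the stop when asked
  cc2 <- count_codons("GCTTAA", drop_terminal_stop = FALSE)
  expect_equal(cc2$counts[["TAA"]], 1L)
  expect_equal(cc2$n_codons, 1L)   # stops are never sense codons
})

test_that("gc_contents gives positional fractions, their mean and gc12", {
  g <- gc_contents(count_codons(strrep("GCT", 30)))
  expect_equal(unname(g[c("gc1", "gc2", "gc3")]), c(1, 1, 0))
  expect_equal(g[["gc12"]], 1)
  expect_equal(g[["gc"]], 2 / 3)

  expect_equal(unname(gc_contents(count_codons(strrep("AAA", 10)))),
               rep(0, 5))

  g3 <- gc_contents(count_codons(paste0(strrep("GGG", 5), strrep("AAA", 5))))
  expect_equal(unname(g3), rep(0.5, 5))

  # gc12 identity on random genes
  set.seed(1)
  for (i in 1:5) {
    gg <- gc_contents(count_codons(seq_from_counts(random_gene_counts(200))))
    expect_equal(gg[["gc12"]], (gg[["gc1"]] + gg[["gc2"]]) / 2)
    expect_equal(gg[["gc"]], mean(gg[c("gc1", "gc2", "gc3")]))
  }
})

test_that("rscu follows the family-mean definition", {
  ala_uniform <- c(GCT = 5, GCC = 5, GCA = 5, GCG = 5)
  r <- rscu(ala_uniform)
  expect_equal(unname(r[names(ala_uniform)]), rep(1, 4))

  r2 <- rscu(c(GCT = 4))
  expect_equal(unname(r2[c("GCT", "GCC", "GCA", "GCG")]), c(4, 0, 0, 0))

  r3 <- rscu(c(TTT = 3, TTC = 1))
  expect_equal(unname(r3[c("TTT", "TTC")]), c(1.5, 0.5))
  # unused families are missing, not zero
  expect_true(is.na(r3[["GCT"]]))

  # family sums equal family sizes, and match the brute-force oracle
  set.seed(2)
  counts <- random_gene_counts(400)
  rr <- rscu(counts)
  code <- genetic_code()
  for (fam in code$families) {
    if (sum(counts[fam]) > 0) {
      expect_equal(sum(rr[fam]), length(fam))
    }
  }
  expect_equal(rr, oracle_rscu(counts), tolerance = 1e-12)
})

test_that("cai_weights normalizes within families with pseudocount", {
  w <- cai_weights(c(TTT = 10, TTC = 10))
  expect_equal(unname(w[c("TTT", "TTC")]), c(1, 1))

  w2 <- cai_weights(c(TTT = 19.5, TTC = 0), pseudocount = 0.5)
  expect_equal(unname(w2[c("TTT", "TTC")]), c(1, 0.025))

  # the most-used codon of every family gets weight 1
  set.seed(3)
  w3 <- cai_weights(random_gene_counts(1000))
  code <- genetic_code()
  for (fam in code$families) {
    expect_equal(max(w3[fam]), 1)
  }
  expect_error(cai_weights(setNames(numeric(64), code$codons)),
               class = "pancub_validation_error")
})

test_that("cai is the geometric mean of weights and order invariant", {
  code <- genetic_code()
  w <- setNames(rep(1, 59), code$informative)
  expect_equal(cai(count_codons(strrep("GCTTTT", 50)), w), 1)

  w["TTC"] <- 0.25
  expect_equal(cai(c(GCT = 1, TTC = 1), w), 0.5)

  set.seed(4)
  counts <- random_gene_counts(200)
  wts <- cai_weights(random_gene_counts(500))
  seq1 <- seq_from_counts(counts)
  shuffled <- paste(sample(rep(names(counts), counts)), collapse = "")
  expect_equal(cai(count_codons(paste0(seq1, "TAA")), wts),
               cai(count_codons(paste0(shuffled, "TAA")), wts))
  # oracle: product of weights ^ (1/n) over informative codons
  inf <- counts[code$informative]
  expect_equal(cai(counts, wts),
               prod(wts^inf)^(1 / sum(inf)), tolerance = 1e-9)
})

test_that("nc_wright hits both endpoints and matches the oracle", {
  # one codon per degenerate family, 30 repeats each: maximal bias
  one_per_fam <- vapply(genetic_code()$families, `[`, character(1), 1L)
  seq20 <- paste(rep(one_per_fam, each = 30), collapse = "")
  expect_equal(nc_wright(count_codons(paste0(seq20, "TAA"))), 20)

  # every sense codon at equal count: no bias, capped at 61
  seq61 <- paste(rep(genetic_code()$sense, each = 10), collapse = "")
  expect_equal(nc_wright(count_codons(seq61)), 61)

  set.seed(5)
  for (i in 1:20) {
    counts <- random_gene_counts(300)
    expect_equal(nc_wright(counts), oracle_nc(counts), tolerance = 1e-9)
  }

  # n-dependence of F: doubling all counts changes Nc only via n
  counts <- random_gene_counts(150)
  expect_equal(nc_wright(counts * 2), oracle_nc(counts * 2),
               tolerance = 1e-9)

  # missing-class rule and Ile imputation
  expect_true(is.na(nc_wright(c(TTT = 3, TTC = 1))))
  no_ile <- random_gene_counts(300)
  no_ile[c("ATT", "ATC", "ATA")] <- 0
  expect_false(is.na(nc_wright(no_ile)))
  expect_equal(nc_wright(no_ile), oracle_nc(no_ile), tolerance = 1e-9)
})

test_that("nc_prime corrects for composition and matches the oracle", {
  set.seed(6)
  for (i in 1:20) {
    counts <- random_gene_counts(300)
    expect_equal(nc_prime(counts), oracle_nc_prime(counts),
                 tolerance = 1e-9)
  }
  # uniform usage: Nc' from the chi-square definition, via oracle
  uni <- setNames(numeric(64), .orc_code$codons)
  uni[.orc_code$sense] <- 10
  expect_equal(nc_prime(uni), oracle_nc_prime(uni), tolerance = 1e-9)

  # a single-family gene leaves whole degeneracy classes unusable
  expect_true(is.na(nc_prime(count_codons(strrep("GCT", 150)))))

  # usage matching the composition expectation exactly (balanced two- and
  # four-fold families) goes through the chi2 = 0 closed form of the oracle
  counts <- setNames(numeric(64), .orc_code$codons)
  counts[c("TTT", "TTC", "GCT", "GCC", "GCA", "GCG")] <- 10
  expect_equal(nc_prime(counts), oracle_nc_prime(counts), tolerance = 1e-9)

  # concentrating a family's usage raises its bias signal (lowers Nc')
  base <- uni
  biased <- uni
  biased["GCT"] <- 38; biased["GCC"] <- 1; biased["GCA"] <- 1
  biased["GCG"] <- 0
  expect_lt(nc_prime(biased), nc_prime(base))
})

test_that("cdc is zero for a homopolymer and matches the oracle", {
  expect_equal(cdc(count_codons(strrep("GCT", 150))), 0, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    counts <- random_gene_counts(300)
    expect_equal(cdc(counts), oracle_cdc(counts), tolerance = 1e-12)
  }

  # observed usage far from compositional expectation: CDC well above 0
  skew <- c(GCT = 50, CGA = 50, TAC = 50, ATT = 50)
  expect_gt(cdc(skew), 0.2)
})

test_that("rescale_bias maps [20, 61] onto [1, 0] linearly", {
  expect_equal(rescale_bias(61), 0)
  expect_equal(rescale_bias(20), 1)
  expect_equal(rescale_bias(40.5), 0.5)
  expect_true(is.na(rescale_bias(NA_real_)))
  expect_error(rescale_bias(19), class = "pancub_validation_error")
  expect_error(rescale_bias(62), class = "pancub_validation_error")
})

test_that("cosine_similarity follows its definition", {
  v <- runif(59) + 0.1
  expect_equal(cosine_similarity(v, 3 * v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  # missing entries dropped pairwise
  expect_equal(cosine_similarity(c(1, NA, 1), c(1, 5, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "pancub_validation_error")
  expect_error(cosine_similarity(1:3, 1:4), class = "pancub_validation_error")
})

test_that("compute_metrics applies the 100-codon filter inclusively", {
  # build genes of exactly 99 and 100 codons (plus stop)
  unit <- c("GAA", "GCT", "TCT", "ATT", "CTG", "CGT", "AAA", "GGT")
  gene_of <- function(n) paste0(paste(rep(unit, length.out = n),
                                      collapse = ""), "TAA")
  rec <- gene_records(c("s1:a", "s1:b"), "s1",
                      c(gene_of(99), gene_of(100)))
  w <- cai_weights(codon_count_matrix(rec))
  m <- compute_metrics(rec, weights = w)
  expect_equal(m$gene_id, "s1:b")
  expect_equal(m$length_codons, 100L)

  # conservation: rows = genes - filtered (50, 99) - excluded (300)
  rec2 <- gene_records(paste0("s1:g", 1:6), "s1",
                       vapply(c(50, 99, 100, 150, 200, 300), gene_of, ""))
  rec2$is_excluded[6] <- TRUE
  m2 <- compute_metrics(rec2, weights = w)
  expect_equal(nrow(m2), 3L)
  expect_equal(dim(attr(m2, "rscu")), c(3L, 59L))
  expect_equal(dim(attr(m2, "counts")), c(3L, 64L))
  expect_equal(m2$gc12, (m2$gc1 + m2$gc2) / 2)
  expect_equal(m2$nc_rescaled, (61 - m2$nc) / 41)
})

test_that("rescaled bias endpoints hold for simulated extremes", {
  set.seed(8)
  # single-codon-per-family genes: rescaled bias exactly 1
  one_per_fam <- vapply(genetic_code()$families, `[`, character(1), 1L)
  seqs <- vapply(1:3, function(i) {
    paste0(paste(rep(sample(one_per_fam), each = 20), collapse = ""), "TAA")
  }, "")
  rec <- gene_records(paste0("s1:x", 1:3), "s1", seqs)
  m <- compute_metrics(rec, weights = cai_weights(codon_count_matrix(rec)))
  expect_equal(m$nc_rescaled, rep(1, 3))

  # uniform synonymous usage: mean rescaled bias near 0
  useqs <- vapply(1:10, function(i) {
    cods <- sample(genetic_code()$sense, 450, replace = TRUE)
    paste(cods, collapse = "")
  }, "")
  recu <- gene_records(paste0("s1:u", 1:10), "s1", useqs)
  mu <- compute_metrics(recu, weights = cai_weights(codon_count_matrix(recu)))
  expect_lt(mean(mu$nc_rescaled), 0.05)
})

test_that("metrics are invariant to codon order", {
  set.seed(9)
  counts <- random_gene_counts(250)
  seqa <- seq_from_counts(counts)
  seqb <- paste(sample(rep(names(counts), counts)), collapse = "")
  ca <- count_codons(seqa); cb <- count_codons(seqb)
  expect_equal(nc_wright(ca), nc_wright(cb))
  expect_equal(nc_prime(ca), nc_prime(cb))
  expect_equal(cdc(ca), cdc(cb))
  expect_equal(gc_contents(ca), gc_contents(cb))
})
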