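## Seeded synthetic pangenome generator with known mutation/selection
## structure: a U-shaped presence spectrum (abundant strain-specific and core
## families), per-family GC3 pressure rising with presence, selection toward
## one preferred codon per family rising with presence, expression coupled to
## selection, and a tRNA table whose high-copy anticodons decode the
## preferred codons.

#' Default preferred codon per degenerate family
#'
#' One codon per 18-family: the lexicographically smallest codon ending in C,
#' else the smallest ending in G (the NNR families). A fixed, GC-rich choice
#' mirroring typical enterobacterial preferences.
#'
#' @return named character, amino acid -> codon.
#' @export
default_preferred_codons <- function() {
  code <- genetic_code()
  vapply(code$families, function(fam) {
    third <- substr(fam, 3, 3)
    if (any(third == "C")) sort(fam[third == "C"])[1]
    else sort(fam[third == "G"])[1]
  }, character(1))
}

#' Synthetic pangenome configuration
#'
#' The defaults are the generator's stated world; they emulate the observed
#' pangenome structure (abundant strain-specific and core families, GC3 and
#' selection rising with presence, expression coupled to selection) and are
#' not tuning knobs.
#'
#' @param n_strains number of strains (default 10).
#' @param n_families number of gene families (default 500).
#' @param presence_spectrum probability vector over presence counts
#'   1..n_strains. Default is U-shaped with mass 0.25 at 1 and 0.32 at
#'   n_strains (the observed proportions of strain-specific and core
#'   clusters), the remaining 0.43 uniform in between.
#' @param length_range (min, max) gene length in codons (default 150..450).
#' @param length_offset extra codons for fully core families, scaled
#'   linearly with presence (default 60; core genes run longer).
#' @param gc3_range (low, high) third-position GC pressure; a family at
#'   presence fraction t draws its GC3 parameter uniformly from the width/2
#'   window starting at `low + t * (high - low) / 2` (strain-specific
#'   families from the lower half, core from the upper half).
#' @param selection_by_presence function(count, n_strains) -> s >= 0,
#'   monotone non-decreasing; default `3 * (count - 1) / (n_strains - 1)`
#'   (s in \[0, 3\]).
#' @param s_jitter_sdlog per-family lognormal jitter on s (default 0.25) so
#'   selection strength varies within a presence class.
#' @param expression_alpha,expression_sigma expression model
#'   `abundance = exp(alpha * s + eps)`, `eps ~ N(0, sigma^2)` per gene
#'   (defaults 1 and 0.5).
#' @param aa_gc_coupling mixture weight (default 0.35) tilting amino-acid
#'   family frequencies toward their mutational weight under the gene's GC
#'   pressure. The effective coupling is attenuated by selection,
#'   `aa_gc_coupling * exp(-s)`: selective constraint resists mutational
#'   drift in composition, so GC12 tracks mutation in selection-free genes
#'   (neutrality slope ~0.32) but not in strongly selected ones (~0.03).
#' @param met_trp_weight sampling weight of Met and Trp relative to the sum
#'   of degenerate families (default 0.01 each).
#' @param preferred_codons named codon-per-family map (default
#'   [default_preferred_codons()]).
#' @param trna_high_copy,trna_low_copy tRNA copies for anticodons decoding
#'   preferred vs other codons (defaults 10 and 1).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 10L, n_families = 500L,
                             presence_spectrum = NULL,
                             length_range = c(150L, 450L),
                             length_offset = 60L,
                             gc3_range = c(0.30, 0.70),
                             selection_by_presence = NULL,
                             s_jitter_sdlog = 0.25,
                             expression_alpha = 1,
                             expression_sigma = 0.5,
                             aa_gc_coupling = 0.35,
                             met_trp_weight = 0.01,
                             preferred_codons = default_preferred_codons(),
                             trna_high_copy = 10L, trna_low_copy = 1L,
                             seed = 1L) {
  if (n_strains < 2L) .val_err("n_strains must be >= 2")
  if (is.null(presence_spectrum)) {
    presence_spectrum <- numeric(n_strains)
    presence_spectrum[1] <- 0.25
    presence_spectrum[n_strains] <- 0.32
    if (n_strains > 2L) {
      presence_spectrum[2:(n_strains - 1L)] <- 0.43 / (n_strains - 2L)
    } else {
      presence_spectrum <- presence_spectrum / sum(presence_spectrum)
    }
  }
  if (length(presence_spectrum) != n_strains ||
      abs(sum(presence_spectrum) - 1) > 1e-8 || any(presence_spectrum < 0)) {
    .val_err("presence_spectrum must be a probability vector over 1..n_strains")
  }
  if (is.null(selection_by_presence)) {
    selection_by_presence <- function(count, n_strains) {
      3 * (count - 1) / (n_strains - 1)
    }
  }
  s_check <- vapply(seq_len(n_strains),
                    function(k) selection_by_presence(k, n_strains),
                    numeric(1))
  if (any(s_check < 0) || any(diff(s_check) < -1e-12)) {
    .val_err("selection_by_presence must be non-negative and monotone ",
             "non-decreasing in presence count")
  }
  stopifnot(length(length_range) == 2L, length_range[1] >= 1,
            length_range[2] >= length_range[1],
            length(gc3_range) == 2L, gc3_range[1] >= 0, gc3_range[2] <= 1,
            gc3_range[1] <= gc3_range[2],
            aa_gc_coupling >= 0, aa_gc_coupling <= 1,
            trna_high_copy > trna_low_copy, trna_low_copy >= 0)
  structure(
    list(n_strains = as.integer(n_strains),
         n_families = as.integer(n_families),
         presence_spectrum = presence_spectrum,
         length_range = as.integer(length_range),
         length_offset = as.integer(length_offset),
         gc3_range = gc3_range,
         selection_by_presence = selection_by_presence,
         s_jitter_sdlog = s_jitter_sdlog,
         expression_alpha = expression_alpha,
         expression_sigma = expression_sigma,
         aa_gc_coupling = aa_gc_coupling,
         met_trp_weight = met_trp_weight,
         preferred_codons = preferred_codons,
         trna_high_copy = as.integer(trna_high_copy),
         trna_low_copy = as.integer(trna_low_copy),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# mutational weight of a full codon: product over positions of
# gc/2 (G or C) vs (1-gc)/2 (A or T)
.codon_mut_weight <- function(codons, gc) {
  w <- rep(1, length(codons))
  for (i in 1:3) {
    b <- substr(codons, i, i)
    w <- w * ifelse(b %in% c("G", "C"), gc / 2, (1 - gc) / 2)
  }
  w
}

#' Generate one coding sequence under mutation-selection balance
#'
#' Amino acids are drawn (near-)uniformly over the 18 degenerate families
#' (Met/Trp occasionally, per `met_trp_weight`), with family frequencies
#' tilted toward their mutational weight under the GC pressure by an
#' effective coupling `aa_gc_coupling * exp(-s)` (selection constrains the
#' protein, damping compositional drift). Within a family, codon c is
#' sampled with probability
#' proportional to `m(c) * exp(s * [c == preferred])`, where the mutational
#' weight m(c) gives the third base gc3/2 for G/C and (1 - gc3)/2 for A/T.
#' A terminal TAA stop is appended. Uses the current RNG state; seed via
#' `set.seed()` or [generate_pangenome()].
#'
#' @param length_codons number of amino-acid codons (excluding the stop).
#' @param gc3 third-position GC pressure in \[0, 1\].
#' @param s selection strength >= 0 toward the preferred codon.
#' @param preferred named codon-per-family map.
#' @param aa_gc_coupling,met_trp_weight see [synthetic_config()].
#' @return nucleotide string of length `3 * (length_codons + 1)`.
#' @export
generate_gene_sequence <- function(length_codons, gc3, s,
                                   preferred = default_preferred_codons(),
                                   aa_gc_coupling = 0.35,
                                   met_trp_weight = 0.01) {
  stopifnot(length_codons >= 1, gc3 >= 0, gc3 <= 1, s >= 0)
  code <- genetic_code()
  fams <- code$families
  nf <- length(fams)
  mut_mass <- vapply(fams, function(f) sum(.codon_mut_weight(f, gc3)),
                     numeric(1))
  beta <- aa_gc_coupling * exp(-s)
  famw <- (1 - beta) / nf + beta * mut_mass / sum(mut_mass)
  famw <- famw / sum(famw)
  all_fams <- c(names(fams), "M", "W")
  probs <- c(famw * (1 - 2 * met_trp_weight), met_trp_weight, met_trp_weight)
  fam_draw <- sample(all_fams, length_codons, replace = TRUE, prob = probs)
  out <- character(length_codons)
  for (f in unique(fam_draw)) {
    idx <- which(fam_draw == f)
    if (f == "M") { out[idx] <- "ATG"; next }
    if (f == "W") { out[idx] <- "TGG"; next }
    cods <- fams[[f]]
    b3 <- substr(cods, 3, 3)
    w <- ifelse(b3 %in% c("G", "C"), gc3 / 2, (1 - gc3) / 2)
    w <- w * exp(s * (cods == preferred[[f]]))
    if (sum(w) == 0) w[] <- 1   # gc3 exactly 0/1 with no compatible codon
    out[idx] <- sample(cods, length(idx), replace = TRUE, prob = w)
  }
  paste0(paste(out, collapse = ""), "TAA")
}

#' Generate a synthetic tRNA copy-number table
#'
#' One tRNA per sense codon (anticodon = reverse complement); anticodons
#' decoding preferred codons get `high_copy` plus a small non-negative
#' integer jitter, all others `low_copy`.
#'
#' @param preferred named codon-per-family map.
#' @param high_copy,low_copy copy numbers (high > low >= 0).
#' @param jitter add U(0..2) integer jitter to high-copy entries.
#' @return `trna_table`.
#' @export
generate_trna_table <- function(preferred = default_preferred_codons(),
                                high_copy = 10L, low_copy = 1L,
                                jitter = TRUE) {
  stopifnot(high_copy > low_copy, low_copy >= 0)
  code <- genetic_code()
  ac <- revcomp(code$sense)
  cn <- rep(as.integer(low_copy), length(ac))
  hi <- code$sense %in% preferred
  cn[hi] <- as.integer(high_copy) +
    if (jitter) sample(0:2, sum(hi), replace = TRUE) else 0L
  trna_table(ac, cn)
}

#' Generate a complete synthetic pangenome
#'
#' Families draw a presence count from the spectrum and member strains
#' uniformly without replacement; each member strain receives one gene
#' realized by [generate_gene_sequence()] with the family's selection
#' strength (from `selection_by_presence`, jittered) and GC3 parameter
#' (window sliding from the lower to the upper half of `gc3_range` with
#' presence). Expression is `exp(alpha * s + eps)` per gene. Up to 30 core
#' families are annotated as synthetic ribosomal proteins so the default CAI
#' reference heuristic has a target. Deterministic given the seed.
#'
#' @param config `synthetic_config`.
#' @return list of class `synthetic_pangenome`: `records` (`gene_records`),
#'   `clusters` (`cluster_table`), `expression` (named vector), `trna`
#'   (`trna_table`), `truth` (data.frame gene_id, cluster_id,
#'   presence_count, s, gc3_param, expression_mean, expression), `config`.
#' @export
generate_pangenome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_strains
  strains <- sprintf("s%02d", seq_len(n))
  counts <- sample.int(n, config$n_families, replace = TRUE,
                       prob = config$presence_spectrum)
  gc_lo <- config$gc3_range[1]
  width <- (config$gc3_range[2] - gc_lo) / 2
  core_idx <- which(counts == n)
  ribo <- head(core_idx, 30L)
  recs <- vector("list", config$n_families)
  truth <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    k <- counts[f]
    t_frac <- if (n > 1) (k - 1) / (n - 1) else 1
    members <- sort(sample(strains, k))
    s_base <- config$selection_by_presence(k, n)
    s_fam <- s_base * exp(rnorm(1, 0, config$s_jitter_sdlog))
    gc3_fam <- runif(1, gc_lo + t_frac * width, gc_lo + t_frac * width + width)
    len <- sample(config$length_range[1]:config$length_range[2], k,
                  replace = TRUE) + round(t_frac * config$length_offset)
    seqs <- vapply(len, function(L) {
      generate_gene_sequence(L, gc3_fam, s_fam,
                             preferred = config$preferred_codons,
                             aa_gc_coupling = config$aa_gc_coupling,
                             met_trp_weight = config$met_trp_weight)
    }, character(1))
    ids <- sprintf("%s:f%04d", members, f)
    expr_mean <- exp(config$expression_alpha * s_fam)
    expr <- expr_mean * exp(rnorm(k, 0, config$expression_sigma))
    prod_lab <- if (f %in% ribo) {
      sprintf("50S ribosomal protein synthetic f%04d", f)
    } else {
      "hypothetical protein (synthetic)"
    }
    recs[[f]] <- data.frame(gene_id = ids, strain_id = members,
                            sequence = seqs, product = prod_lab,
                            is_excluded = FALSE, stringsAsFactors = FALSE)
    truth[[f]] <- data.frame(gene_id = ids,
                             cluster_id = sprintf("c%04d", f),
                             presence_count = k, s = s_fam,
                             gc3_param = gc3_fam,
                             expression_mean = expr_mean,
                             expression = expr, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  class(records) <- c("gene_records", "data.frame")
  truth <- do.call(rbind, truth)
  clusters <- cluster_table(split(truth$gene_id, truth$cluster_id))
  trna <- generate_trna_table(config$preferred_codons,
                              config$trna_high_copy, config$trna_low_copy)
  structure(
    list(records = records, clusters = clusters,
         expression = setNames(truth$expression, truth$gene_id),
         trna = trna, truth = truth, config = config),
    class = "synthetic_pangenome"
  )
}

#' Write a synthetic pangenome to disk
#'
#' Emits one CDS FASTA per strain, the cluster/expression/tRNA tables and
#' the truth table through the package writers, plus a JSON manifest listing
#' every path, the scalar config values and the seed.
#'
#' @param pg `synthetic_pangenome`.
#' @param dir output directory (created if needed).
#' @return (invisibly) the manifest path.
#' @export
write_pangenome <- function(pg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_dir <- file.path(dir, "fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  paths <- list()
  for (s in unique(pg$records$strain_id)) {
    rec <- pg$records[pg$records$strain_id == s, , drop = FALSE]
    ss <- Biostrings::DNAStringSet(setNames(
      rec$sequence,
      paste(sub("^[^:]*:", "", rec$gene_id), rec$product)))
    p <- file.path(fasta_dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(ss, p)
    paths[[paste0("fasta_", s)]] <- p
  }
  paths$clusters <- file.path(dir, "clusters.tsv")
  writeLines(vapply(names(pg$clusters), function(cid) {
    paste(c(cid, pg$clusters[[cid]]), collapse = "\t")
  }, character(1)), paths$clusters)
  paths$expression <- file.path(dir, "expression.tsv")
  write_table(data.frame(gene_id = names(pg$expression),
                         abundance = unname(pg$expression)),
              paths$expression)
  paths$trna <- file.path(dir, "trna.tsv")
  write_table(data.frame(anticodon = names(pg$trna),
                         copy_number = as.integer(pg$trna)),
              paths$trna)
  paths$truth <- file.path(dir, "truth.tsv")
  write_table(pg$truth, paths$truth)
  manifest <- file.path(dir, "manifest.json")
  cfg <- pg$config
  scalar_cfg <- cfg[vapply(cfg, function(x)
    is.numeric(x) || is.character(x), logical(1))]
  jsonlite::write_json(
    list(seed = cfg$seed, config = scalar_cfg, paths = paths),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
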