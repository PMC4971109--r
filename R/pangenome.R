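## Presence structure of gene clusters across strains and the five-class
## stratification (strain-specific ... core), plus a stand-in greedy
## clusterer and pan/core rarefaction curves.

GENE_SET_LEVELS <- c("strain_specific", "lowly_shared", "moderately_shared",
                     "highly_shared", "core")

#' Per-cluster presence profile
#'
#' @param clusters `cluster_table`.
#' @param strain_of named character vector gene_id -> strain_id (built
#'   automatically from a `gene_records` table if one is supplied).
#' @return list of class `presence_profile`: `profile` (data.frame
#'   cluster_id, presence_count), `strains_present` (list of strain sets),
#'   `paralogs` (data.frame cluster_id, strain_id, n_genes for multiplicity
#'   >= 1), `members` (the cluster membership), `strains` (all strains seen).
#' @export
presence_counts <- function(clusters, strain_of) {
  if (is.data.frame(strain_of)) {
    strain_of <- setNames(strain_of$strain_id, strain_of$gene_id)
  }
  ids <- unlist(clusters, use.names = FALSE)
  unknown <- setdiff(ids, names(strain_of))
  if (length(unknown)) {
    .val_err("gene(s) with unknown strain: ",
             paste(head(unknown, 5L), collapse = ", "))
  }
  strains_present <- lapply(clusters, function(g) unique(unname(strain_of[g])))
  paralogs <- do.call(rbind, lapply(names(clusters), function(cid) {
    t <- table(strain_of[clusters[[cid]]])
    data.frame(cluster_id = cid, strain_id = names(t),
               n_genes = as.integer(t), stringsAsFactors = FALSE)
  }))
  structure(
    list(
      profile = data.frame(cluster_id = names(clusters),
                           presence_count = lengths(strains_present),
                           stringsAsFactors = FALSE),
      strains_present = strains_present,
      paralogs = paralogs,
      members = clusters,
      strains = sort(unique(unname(strain_of)))
    ),
    class = "presence_profile"
  )
}

#' Default presence-class bin edges
#'
#' With N strains and bin width `w = floor((N - 2) / 3)`, the five classes
#' are counts {1}, \[2, 1+w\], \[2+w, 1+2w\], \[2+2w, N-1\] (the remainder is
#' absorbed by the highest shared bin) and {N}. For N = 26 this gives the
#' canonical 1 / 2-9 / 10-17 / 18-25 / 26 split.
#'
#' @param n_strains integer >= 5.
#' @return integer(4): upper bounds of the first four classes.
#' @export
default_bin_edges <- function(n_strains) {
  if (n_strains < 5L) {
    .val_err("default bin edges require >= 5 strains, got ", n_strains)
  }
  w <- (n_strains - 2L) %/% 3L
  c(1L, 1L + w, 1L + 2L * w, n_strains - 1L)
}

#' Stratify clusters into the five presence classes
#'
#' @param profile `presence_profile`.
#' @param n_strains total number of strains in the pangenome.
#' @param edges optional integer(4) upper bounds of the first four classes;
#'   default [default_bin_edges()].
#' @return data.frame of class `gene_set_partition` (cluster_id,
#'   presence_count, set_label as an ordered factor), with the edges in
#'   attribute `"edges"` and membership in `"members"`.
#' @export
partition_gene_sets <- function(profile, n_strains, edges = NULL) {
  if (is.null(edges)) edges <- default_bin_edges(n_strains)
  if (length(edges) != 4L || any(diff(edges) <= 0) || edges[1] != 1L ||
      edges[4] != n_strains - 1L) {
    .val_err("edges must be 4 increasing integers starting at 1 and ending ",
             "at n_strains - 1")
  }
  pc <- profile$profile$presence_count
  if (any(pc < 1L | pc > n_strains)) {
    .val_err("presence_count outside [1, n_strains]")
  }
  lab <- GENE_SET_LEVELS[findInterval(pc, c(edges, n_strains) + 0.5) + 1L]
  out <- data.frame(cluster_id = profile$profile$cluster_id,
                    presence_count = pc,
                    set_label = factor(lab, levels = GENE_SET_LEVELS,
                                       ordered = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "edges") <- edges
  attr(out, "members") <- profile$members
  class(out) <- c("gene_set_partition", "data.frame")
  out
}

#' Per-gene set labels from a cluster partition
#'
#' @param partition `gene_set_partition`.
#' @param clusters optional `cluster_table`; defaults to the membership
#'   recorded in the partition.
#' @return named character vector gene_id -> set label.
#' @export
gene_set_labels <- function(partition, clusters = attr(partition, "members")) {
  lab <- setNames(as.character(partition$set_label), partition$cluster_id)
  ids <- unlist(clusters, use.names = FALSE)
  reps <- rep(lab[names(clusters)], lengths(clusters))
  setNames(unname(reps), ids)
}

#' Remove paralogs, keeping one representative gene per strain per cluster
#'
#' Within each cluster, the longest gene of each strain is retained; ties
#' break on lexicographically smallest gene id.
#'
#' @param clusters `cluster_table`.
#' @param records `gene_records` providing strain and sequence length.
#' @return `cluster_table` of representatives (presence counts preserved).
#' @export
select_representatives <- function(clusters, records) {
  strain_of <- setNames(records$strain_id, records$gene_id)
  len_of <- setNames(nchar(records$sequence), records$gene_id)
  out <- lapply(clusters, function(g) {
    g <- g[order(strain_of[g], -len_of[g], g)]
    g[!duplicated(strain_of[g])]
  })
  cluster_table(out)
}

#' Pan- and core-genome rarefaction curves
#'
#' For each of `n_permutations` seeded shuffles of strain order, prefix-wise
#' union (pan) and intersection (core) cluster counts; medians are reported
#' per k.
#'
#' @param profile `presence_profile`.
#' @param strains ordered strain vector; default all strains in the profile.
#' @param n_permutations number of shuffles (default 100).
#' @param seed RNG seed recorded in the output.
#' @return list of class `rarefaction_curve`: `summary` (k, pan_median,
#'   core_median), `pan`/`core` (k x permutation matrices), `seed`.
#' @export
pangenome_curve <- function(profile, strains = profile$strains,
                            n_permutations = 100L, seed = 1L) {
  if (n_permutations < 1L) .val_err("n_permutations must be >= 1")
  n <- length(strains)
  inc <- vapply(profile$strains_present, function(s) strains %in% s,
                logical(n))            # strains x clusters
  inc <- matrix(inc, nrow = n)
  pan <- matrix(NA_real_, n, n_permutations)
  core <- matrix(NA_real_, n, n_permutations)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (p in seq_len(n_permutations)) {
    o <- sample.int(n)
    m <- inc[o, , drop = FALSE]
    seen <- apply(m, 2, function(col) {
      w <- which(col)
      c(first = if (length(w)) w[1] else n + 1L,
        miss = if (all(col)) n + 1L else which(!col)[1])
    })
    pan[, p] <- vapply(seq_len(n), function(k) sum(seen["first", ] <= k),
                       numeric(1))
    core[, p] <- vapply(seq_len(n), function(k) sum(seen["miss", ] > k),
                        numeric(1))
  }
  structure(
    list(summary = data.frame(
           k = seq_len(n),
           pan_median = apply(pan, 1, median),
           core_median = apply(core, 1, median)),
         pan = pan, core = core, seed = seed,
         n_permutations = n_permutations),
    class = "rarefaction_curve"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- stand-in greedy clusterer ---------------------------------------------

#' Greedy single-linkage protein-identity clustering (OrthoMCL stand-in)
#'
#' Genes are translated and processed in decreasing protein length order
#' (ties: lexicographic gene id). A gene joins the first existing cluster
#' whose founder shares at least one amino-acid 8-mer and aligns with
#' identity >= `identity_threshold` over >= `coverage_threshold` of the
#' shorter protein; otherwise it founds a new cluster. Deterministic. This
#' is an explicit lightweight stand-in for Markov clustering of all-vs-all
#' alignments; real-data users should supply a precomputed cluster table.
#'
#' @param records `gene_records` (QC-passed).
#' @param identity_threshold fraction in (0, 1], default 0.9.
#' @param coverage_threshold fraction in (0, 1], default 0.8.
#' @return `cluster_table` with ids c0001, c0002, ... in founding order.
#' @export
cluster_genes <- function(records, identity_threshold = 0.9,
                          coverage_threshold = 0.8) {
  if (nrow(records) == 0L) return(cluster_table(setNames(list(), character(0))))
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            coverage_threshold > 0, coverage_threshold <= 1)
  dna <- Biostrings::DNAStringSet(records$sequence)
  prot <- suppressWarnings(
    as.character(Biostrings::translate(dna, if.fuzzy.codon = "X")))
  prot <- sub("\\*$", "", prot)
  names(prot) <- records$gene_id
  ord <- order(-nchar(prot), records$gene_id)
  k <- 8L
  kmers <- function(p) {
    n <- nchar(p)
    if (n < k) return(p)
    unique(substring(p, 1:(n - k + 1L), k:n))
  }
  founders <- character(0)
  members <- list()
  kmer_index <- new.env(parent = emptyenv())
  for (i in ord) {
    p <- prot[i]
    km <- kmers(p)
    cand <- sort(unique(unlist(lapply(km, function(x) {
      if (!is.null(kmer_index[[x]])) kmer_index[[x]] else integer(0)
    }))))
    joined <- 0L
    for (cl in cand) {
      if (.prot_match(founders[cl], p, identity_threshold,
                      coverage_threshold)) {
        joined <- cl
        break
      }
    }
    if (joined > 0L) {
      members[[joined]] <- c(members[[joined]], names(prot)[i])
    } else {
      founders <- c(founders, unname(p))
      members[[length(founders)]] <- names(prot)[i]
      for (x in km) {
        kmer_index[[x]] <- c(kmer_index[[x]], length(founders))
      }
    }
  }
  names(members) <- sprintf("c%04d", seq_along(members))
  cluster_table(members)
}

# local alignment of two proteins; identity over aligned columns and
# coverage of the shorter sequence
.prot_match <- function(a, b, id_thr, cov_thr) {
  short <- min(nchar(a), nchar(b))
  if (short == 0L) return(FALSE)
  sm <- .prot_submat()
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = sm, gapOpening = 8, gapExtension = 2)
  ncols <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  if (ncols == 0L) return(FALSE)
  identity <- Biostrings::nmatch(al) / ncols
  coverage <- ncols / short
  identity >= id_thr && coverage >= cov_thr
}

.prot_submat <- function() {
  if (is.null(.pancub_env$submat)) {
    letters <- c(Biostrings::AA_STANDARD, "X", "*")
    m <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 2
    .pancub_env$submat <- m
  }
  .pancub_env$submat
}
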