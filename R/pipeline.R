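## Orchestration: a flat run configuration, the end-to-end pipeline
## (partition -> metrics -> ENC -> neutrality -> COA -> correlations ->
## similarity -> ANOVA), report writers and a small subcommand CLI.

#' Assemble a pipeline run configuration
#'
#' Paths may be NULL when the corresponding stage should be skipped
#' (expression, tRNA, exclusion list) or computed in-package (clusters).
#' Parameter defaults are the analysis defaults: 100-codon minimum length,
#' ENC deviation threshold 0.15, five presence classes, strict Watson-Crick
#' tRNA mapping.
#'
#' @param fasta_dir directory of per-strain CDS FASTA files (`<strain>.fasta`
#'   / `.fa` / `.fna`); strain id = file name without extension.
#' @param cluster_table,expression_table,trna_table,exclusion_list optional
#'   input table paths.
#' @param out_dir report directory.
#' @param min_len,enc_threshold,bin_edges,cai_reference,cai_ref_pattern,wobble,
#'   use_representatives,n_permutations,seed pipeline parameters; see the
#'   stage functions.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta_dir = NULL, cluster_table = NULL,
                       expression_table = NULL, trna_table = NULL,
                       exclusion_list = NULL, out_dir = "pancub_out",
                       min_len = 100L, enc_threshold = 0.15,
                       bin_edges = NULL, cai_reference = NULL,
                       cai_ref_pattern = "ribosomal protein",
                       wobble = FALSE, use_representatives = FALSE,
                       n_permutations = 100L, seed = 1L) {
  for (p in c(fasta_dir, cluster_table, expression_table, trna_table,
              exclusion_list, cai_reference)) {
    if (!is.null(p) && !file.exists(p)) .io_err("missing input path: ", p)
  }
  structure(list(fasta_dir = fasta_dir, cluster_table = cluster_table,
                 expression_table = expression_table,
                 trna_table = trna_table, exclusion_list = exclusion_list,
                 out_dir = out_dir, min_len = as.integer(min_len),
                 enc_threshold = as.numeric(enc_threshold),
                 bin_edges = bin_edges, cai_reference = cai_reference,
                 cai_ref_pattern = cai_ref_pattern,
                 wobble = isTRUE(as.logical(wobble)),
                 use_representatives = isTRUE(as.logical(use_representatives)),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored;
#' keys match [run_config()] arguments.
#'
#' @param path config file.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .io_err("missing config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) .val_err("malformed config line: ", lines[bad][1])
  args <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, character(1), 1L))
  known <- names(formals(run_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) .val_err("unknown config key(s): ",
                                paste(unknown, collapse = ", "))
  num_keys <- c("min_len", "enc_threshold", "n_permutations", "seed")
  for (k in intersect(num_keys, names(args))) {
    args[[k]] <- as.numeric(args[[k]])
  }
  for (k in intersect(c("wobble", "use_representatives"), names(args))) {
    args[[k]] <- toupper(args[[k]]) %in% c("TRUE", "1", "YES")
  }
  if ("bin_edges" %in% names(args)) {
    args$bin_edges <- as.integer(strsplit(args$bin_edges, "[,[:space:]]+")[[1]])
  }
  do.call(run_config, args)
}

.log_stage <- function(...) {
  message("[pancub] ", ...)
}

#' Run the full diagnostics pipeline
#'
#' Loads the per-strain FASTAs (applying QC and the exclusion list), builds
#' or reads the cluster table, stratifies clusters into the five presence
#' classes, computes the per-gene metric table, and runs every diagnostic
#' stage, writing one TSV per report plus a JSON manifest. Stages whose
#' inputs are absent (expression, tRNA) are skipped with a log line. A
#' second run on identical inputs is byte-identical.
#'
#' @param config `run_config`, or inputs passed directly via `pangenome` (a
#'   `synthetic_pangenome`), bypassing file loading.
#' @param pangenome optional in-memory `synthetic_pangenome`.
#' @return (invisibly) list with every stage result and `manifest` path.
#' @export
run_pipeline <- function(config, pangenome = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- NULL
  trna <- NULL
  clusters <- NULL
  if (!is.null(pangenome)) {
    records <- pangenome$records
    clusters <- pangenome$clusters
    expr <- pangenome$expression
    trna <- pangenome$trna
  } else {
    if (is.null(config$fasta_dir)) .val_err("no FASTA input configured")
    files <- list.files(config$fasta_dir, "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (length(files) == 0L) .io_err("no FASTA files in ", config$fasta_dir)
    records <- do.call(rbind, lapply(files, function(f) {
      read_cds_fasta(f, sub("\\.(fa|fasta|fna)$", "", basename(f)))
    }))
    class(records) <- c("gene_records", "data.frame")
    if (!is.null(config$cluster_table)) {
      clusters <- read_cluster_table(config$cluster_table)
    }
    if (!is.null(config$expression_table)) {
      expr <- read_expression_table(config$expression_table)
    }
    if (!is.null(config$trna_table)) {
      trna <- read_trna_table(config$trna_table)
    }
  }
  n_loaded <- nrow(records)
  if (!is.null(config$exclusion_list)) {
    records <- apply_exclusions(records, read_id_list(config$exclusion_list))
  }
  n_excluded <- sum(records$is_excluded)
  records_kept <- records[!records$is_excluded, , drop = FALSE]
  .log_stage("loaded ", n_loaded, " genes; ", n_excluded, " excluded")
  if (is.null(clusters)) {
    .log_stage("clustering genes (stand-in greedy clusterer)")
    clusters <- cluster_genes(records_kept)
  } else {
    keep_ids <- records_kept$gene_id
    clusters <- cluster_table(Filter(length, lapply(clusters, function(g) {
      intersect(g, keep_ids)
    })))
  }
  strains <- sort(unique(records_kept$strain_id))
  profile <- presence_counts(clusters, records_kept)
  partition <- partition_gene_sets(profile, length(strains),
                                   edges = config$bin_edges)
  if (config$use_representatives) {
    clusters <- select_representatives(clusters, records_kept)
    profile <- presence_counts(clusters, records_kept)
    partition <- partition_gene_sets(profile, length(strains),
                                     edges = config$bin_edges)
    keep <- records_kept$gene_id %in% unlist(clusters, use.names = FALSE)
    records_kept <- records_kept[keep, , drop = FALSE]
  }
  labels <- gene_set_labels(partition, clusters)
  curve <- pangenome_curve(profile, strains,
                           n_permutations = config$n_permutations,
                           seed = config$seed)
  weights <- if (!is.null(config$cai_reference)) {
    ref_ids <- read_id_list(config$cai_reference)
    cai_weights(codon_count_matrix(
      records_kept[records_kept$gene_id %in% ref_ids, , drop = FALSE]))
  } else {
    default_cai_weights(records_kept, pattern = config$cai_ref_pattern)
  }
  metrics <- compute_metrics(records_kept, partition = labels,
                             weights = weights, min_len = config$min_len)
  .log_stage(nrow(metrics), " genes pass the ", config$min_len,
             "-codon filter")
  enc <- enc_plot(metrics, threshold = config$enc_threshold)
  neut <- neutrality_plot(metrics)
  coa <- coa_rscu(metrics)
  faccor <- axis_factor_correlations(coa, metrics, expression = expr)
  expcor <- NULL
  if (!is.null(expr)) {
    expcor <- expression_correlation(metrics, expr)
  } else {
    .log_stage("no expression table: expression-correlation stage skipped")
  }
  sim <- NULL
  if (!is.null(trna) && length(trna)) {
    sim <- trna_similarity_by_set(metrics, trna, wobble = config$wobble)
  } else {
    .log_stage("no tRNA table: similarity stage skipped")
  }
  measures <- c("nc_rescaled", "nc_prime_rescaled", "cai", "cdc")
  anova_tab <- do.call(rbind, lapply(measures, function(mm) {
    g <- split(metrics[[mm]], as.character(metrics$set_label))
    g <- lapply(g, function(v) v[!is.na(v)])
    g <- g[lengths(g) >= 2L]
    if (length(g) < 2L) return(NULL)
    a <- one_way_anova(g)
    data.frame(measure = mm, F = a[["F"]], p = a[["p"]],
               df1 = a[["df1"]], df2 = a[["df2"]], stringsAsFactors = FALSE)
  }))

  out <- config$out_dir
  paths <- list(
    partition = file.path(out, "partition.tsv"),
    curve = file.path(out, "pangenome_curve.tsv"),
    metrics = file.path(out, "metrics.tsv"),
    enc_genes = file.path(out, "enc_plot_genes.tsv"),
    enc_sweep = file.path(out, "enc_plot_sweep.tsv"),
    neutrality = file.path(out, "neutrality.tsv"),
    coa_coords = file.path(out, "coa_coords.tsv"),
    coa_inertia = file.path(out, "coa_inertia.tsv"),
    factor_correlations = file.path(out, "coa_factor_correlations.tsv"),
    anova = file.path(out, "anova.tsv")
  )
  part_df <- as.data.frame(partition)
  part_df$members <- vapply(attr(partition, "members")[part_df$cluster_id],
                            paste, character(1), collapse = " ")
  write_table(part_df, paths$partition)
  write_table(curve$summary, paths$curve)
  write_table(as.data.frame(metrics), paths$metrics)
  write_table(enc$genes, paths$enc_genes)
  write_table(enc$sweep, paths$enc_sweep)
  write_table(as.data.frame(neut), paths$neutrality)
  write_table(data.frame(gene_id = rownames(coa$row_coords),
                         coa$row_coords), paths$coa_coords)
  write_table(data.frame(axis = seq_along(coa$inertia),
                         inertia_fraction = coa$inertia), paths$coa_inertia)
  write_table(faccor, paths$factor_correlations)
  if (!is.null(expcor)) {
    paths$expression_correlation <- file.path(out,
                                              "expression_correlation.tsv")
    write_table(expcor, paths$expression_correlation)
  }
  if (!is.null(sim)) {
    paths$trna_similarity <- file.path(out, "trna_similarity.tsv")
    write_table(as.data.frame(sim), paths$trna_similarity)
  }
  if (!is.null(anova_tab)) {
    write_table(anova_tab, paths$anova)
  }
  manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(package = "pancub",
         version = as.character(utils::packageVersion("pancub")),
         seed = config$seed,
         parameters = list(min_len = config$min_len,
                           enc_threshold = config$enc_threshold,
                           wobble = config$wobble,
                           use_representatives = config$use_representatives,
                           n_permutations = config$n_permutations),
         counts = list(loaded = n_loaded, excluded = n_excluded,
                       analyzed = nrow(metrics),
                       clusters = length(clusters)),
         reports = paths),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records_kept, clusters = clusters,
                 profile = profile, partition = partition, curve = curve,
                 metrics = metrics, enc = enc, neutrality = neut, coa = coa,
                 factor_correlations = faccor,
                 expression_correlation = expcor, similarity = sim,
                 anova = anova_tab, manifest = manifest, paths = paths))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic pangenome), `all` / `diagnose`
#' (run the pipeline), `cluster`, `partition`, `metrics` (individual
#' stages). Flags are `--key value` pairs matching [run_config()] (or
#' [synthetic_config()] for `simulate`); `--config file` loads a key=value
#' file first, with flags overriding. Returns the exit status: 0 success,
#' 2 validation error, 3 I/O error.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return integer exit status, invisibly.
#' @export
pancub_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      .val_err("usage: pancub <simulate|cluster|partition|metrics|",
               "diagnose|all> [--key value ...]")
    }
    cmd <- args[1]
    flags <- .parse_flags(args[-1])
    if (cmd == "simulate") {
      keep <- intersect(names(flags),
                        c("n_strains", "n_families", "seed",
                          "length_offset", "s_jitter_sdlog",
                          "expression_alpha", "expression_sigma",
                          "aa_gc_coupling", "trna_high_copy",
                          "trna_low_copy"))
      cfg_args <- lapply(flags[keep], as.numeric)
      pg <- generate_pangenome(do.call(synthetic_config, cfg_args))
      out <- if (!is.null(flags$out_dir)) flags$out_dir else "pancub_sim"
      write_pangenome(pg, out)
      .log_stage("synthetic pangenome written to ", out)
      return(invisible(0L))
    }
    cfg <- if (!is.null(flags$config)) read_run_config(flags$config)
           else run_config(out_dir = "pancub_out")
    over <- flags[setdiff(names(flags), "config")]
    if (length(over)) {
      base <- unclass(cfg)
      for (k in names(over)) {
        if (!k %in% names(formals(run_config))) {
          .val_err("unknown flag --", k)
        }
        base[[k]] <- over[[k]]
      }
      cfg <- do.call(run_config, base[names(formals(run_config))])
    }
    if (cmd %in% c("all", "diagnose", "cluster", "partition", "metrics")) {
      run_pipeline(cfg)
      return(invisible(0L))
    }
    .val_err("unknown subcommand: ", cmd)
  },
  pancub_validation_error = function(e) {
    message("pancub error (validation): ", conditionMessage(e)); 2L
  },
  pancub_io_error = function(e) {
    message("pancub error (I/O): ", conditionMessage(e)); 3L
  })
  if (is.numeric(status)) invisible(as.integer(status)) else invisible(0L)
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) .val_err("expected --flag, got: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}
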