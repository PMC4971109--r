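## Readers and writers for every external file the pipeline touches.
## All tables are tab-separated on write; tab or comma are sniffed on read.

.val_err <- function(...) {
  stop(errorCondition(paste0(...), class = c("pancub_validation_error", "error")))
}
.io_err <- function(...) {
  stop(errorCondition(paste0(...), class = c("pancub_io_error", "error")))
}

#' Construct a gene record table
#'
#' Genes are represented throughout the package as a plain data.frame with
#' one row per CDS. Gene ids are namespaced as `strain_id:local_id` so the
#' same locus tag may occur in multiple strains.
#'
#' @param gene_id character, unique ids.
#' @param strain_id character, strain of origin.
#' @param sequence character, in-frame nucleotide sequence over A/C/G/T/N.
#' @param product character, free-text annotation (may be empty).
#' @param is_excluded logical, HGT/QC exclusion flag.
#' @return data.frame with class `gene_records`.
#' @export
gene_records <- function(gene_id, strain_id, sequence,
                         product = "", is_excluded = FALSE) {
  if (anyDuplicated(gene_id)) {
    .val_err("duplicate gene_id: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  df <- data.frame(
    gene_id = as.character(gene_id),
    strain_id = as.character(strain_id),
    sequence = toupper(as.character(sequence)),
    product = rep_len(as.character(product), length(gene_id)),
    is_excluded = rep_len(as.logical(is_excluded), length(gene_id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_records", "data.frame")
  df
}

# QC verdict for one sequence; returns NULL if clean, else a reason string
.cds_qc_reason <- function(seq) {
  if (grepl("[^ACGTN]", seq)) {
    return("non-ACGTN characters")
  }
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    return(sprintf("length %d not a positive multiple of 3", n))
  }
  if (n > 0L) {
    n_frac <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / n
    if (n_frac > 0.05) {
      return(sprintf(">5%% ambiguous bases (%.1f%%)", 100 * n_frac))
    }
  }
  cods <- .codon_split(seq)
  internal <- cods[-length(cods)]
  if (any(internal %in% c("TAA", "TAG", "TGA"))) {
    return("internal stop codon in frame 0")
  }
  NULL
}

#' Apply CDS quality control to a gene record table
#'
#' Rules: sequence over A/C/G/T/N only, length a positive multiple of 3, no
#' internal frame-0 stop codon, at most 5% N. A terminal stop codon is
#' allowed (and later dropped by [count_codons()]). Idempotent.
#'
#' @param records `gene_records` data.frame.
#' @param qc_policy `"skip"` drops failing records with a warning; `"error"`
#'   aborts naming the first failing record.
#' @return filtered `gene_records`.
#' @export
qc_filter <- function(records, qc_policy = c("skip", "error")) {
  qc_policy <- match.arg(qc_policy)
  reasons <- vapply(records$sequence, .cds_qc_reason2, character(1),
                    USE.NAMES = FALSE)
  bad <- reasons != ""
  if (any(bad)) {
    msg <- paste0(records$gene_id[bad], " (", reasons[bad], ")")
    if (qc_policy == "error") {
      .val_err("CDS QC failure: ", msg[1])
    }
    warning(sprintf("QC skipped %d record(s): %s", sum(bad),
                    paste(head(msg, 5L), collapse = "; ")), call. = FALSE)
  }
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cds_qc_reason2 <- function(seq) {
  r <- .cds_qc_reason(seq)
  if (is.null(r)) "" else r
}

#' Read a CDS multi-FASTA for one strain
#'
#' One gene per entry; the first whitespace-delimited token of the header is
#' the local id, the remainder (if any) the product annotation. Gene ids are
#' namespaced as `strain_id:local_id`.
#'
#' @param path FASTA file.
#' @param strain_id strain identifier.
#' @param qc_policy see [qc_filter()].
#' @return `gene_records` data.frame (possibly 0 rows).
#' @export
read_cds_fasta <- function(path, strain_id, qc_policy = c("skip", "error")) {
  qc_policy <- match.arg(qc_policy)
  if (!file.exists(path)) {
    .io_err("cannot read FASTA: ", path)
  }
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) .io_err("malformed FASTA ", path, ": ",
                                             conditionMessage(e)))
  if (length(ss) == 0L) {
    return(gene_records(character(0), character(0), character(0)))
  }
  hdr <- names(ss)
  local_id <- sub("\\s.*$", "", hdr)
  product <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  rec <- gene_records(
    gene_id = paste0(strain_id, ":", local_id),
    strain_id = strain_id,
    sequence = as.character(ss),
    product = product
  )
  qc_filter(rec, qc_policy)
}

# sniff the delimiter of a delimited text file (tab preferred, else comma)
.sniff_sep <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return("\t")
  if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ","
}

.read_two_col <- function(path, what) {
  if (!file.exists(path)) .io_err("cannot read ", what, " table: ", path)
  sep <- .sniff_sep(path)
  df <- tryCatch(
    read.table(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", strip.white = TRUE, quote = "\""),
    error = function(e) {
      if (length(readLines(path, warn = FALSE)) == 0L ||
          all(!nzchar(readLines(path, warn = FALSE)))) {
        return(data.frame(V1 = character(0), V2 = character(0)))
      }
      .io_err("malformed ", what, " table ", path, ": ", conditionMessage(e))
    })
  if (nrow(df) == 0L) return(df)
  if (ncol(df) < 2L) .val_err(what, " table needs two columns: ", path)
  # tolerate a header line
  if (suppressWarnings(is.na(as.numeric(df[1, 2]))) && nrow(df) >= 1L &&
      grepl("[A-Za-z]", df[1, 2])) {
    df <- df[-1L, , drop = FALSE]
  }
  df
}

#' Read a tRNA copy-number table
#'
#' Two columns (anticodon, copy number), header optional. Anticodons may be
#' RNA or DNA; they are normalized to DNA (U -> T). Duplicate anticodons are
#' summed.
#'
#' @param path delimited file.
#' @return named integer vector, anticodon (DNA) -> copy number, with class
#'   `trna_table`.
#' @export
read_trna_table <- function(path) {
  df <- .read_two_col(path, "tRNA")
  if (nrow(df) == 0L) return(trna_table(character(0), integer(0)))
  trna_table(df[[1]], df[[2]])
}

#' Construct a tRNA table
#'
#' @param anticodon character triplets (RNA or DNA alphabet).
#' @param copy_number non-negative integers; duplicates are summed.
#' @return named integer vector with class `trna_table`.
#' @export
trna_table <- function(anticodon, copy_number) {
  ac <- chartr("Uu", "TT", toupper(as.character(anticodon)))
  if (any(nchar(ac) != 3L | grepl("[^ACGT]", ac))) {
    .val_err("invalid anticodon triplet: ",
             paste(anticodon[nchar(ac) != 3L | grepl("[^ACGT]", ac)],
                   collapse = ", "))
  }
  cn <- suppressWarnings(as.numeric(copy_number))
  if (any(is.na(cn)) || any(cn < 0) || any(cn != round(cn))) {
    .val_err("tRNA copy numbers must be non-negative integers")
  }
  out <- vapply(split(as.integer(round(cn)), ac), sum, integer(1))
  structure(out, class = "trna_table")
}

#' Read a gene expression table
#'
#' Two columns (gene_id, abundance). Abundances must be non-negative; a
#' duplicated gene id is an error. Missing genes are absent keys, never
#' implicit zeros.
#'
#' @param path delimited file.
#' @return named numeric vector gene_id -> abundance.
#' @export
read_expression_table <- function(path) {
  df <- .read_two_col(path, "expression")
  if (nrow(df) == 0L) return(setNames(numeric(0), character(0)))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    .val_err("duplicate gene_id in expression table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ab <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(ab)) || any(ab < 0)) {
    .val_err("expression abundances must be non-negative numbers")
  }
  setNames(ab, ids)
}

#' Read an ortholog cluster table
#'
#' One row per cluster: cluster id, then member gene ids (as extra delimited
#' fields or one whitespace-separated field). Every gene id may appear in at
#' most one cluster; empty clusters are invalid.
#'
#' @param path delimited file.
#' @return named list cluster_id -> character vector of gene ids, class
#'   `cluster_table`.
#' @export
read_cluster_table <- function(path) {
  if (!file.exists(path)) .io_err("cannot read cluster table: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) && grepl("^cluster_id\\b", lines[1])) lines <- lines[-1]
  sep <- if (any(grepl("\t", lines, fixed = TRUE))) "\t" else ","
  cl <- lapply(strsplit(lines, sep, fixed = TRUE), function(f) {
    f <- trimws(f)
    members <- unlist(strsplit(f[-1], "[,[:space:]]+"))
    list(id = f[1], members = members[nzchar(members)])
  })
  cluster_table(setNames(lapply(cl, `[[`, "members"),
                         vapply(cl, `[[`, character(1), "id")))
}

#' Construct a cluster table
#'
#' @param clusters named list cluster_id -> character vector of member ids.
#' @return validated `cluster_table`.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(structure(setNames(list(), character(0)), class = "cluster_table"))
  }
  if (is.null(names(clusters)) || anyDuplicated(names(clusters))) {
    .val_err("cluster ids must be unique and named")
  }
  if (any(lengths(clusters) == 0L)) {
    .val_err("empty cluster(s): ",
             paste(names(clusters)[lengths(clusters) == 0L], collapse = ", "))
  }
  all_ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    .val_err("gene_id in more than one cluster: ",
             paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  structure(clusters, class = "cluster_table")
}

#' Read a one-id-per-line list (e.g. HGT exclusion list)
#'
#' Blank lines are ignored; duplicates collapse to a set.
#'
#' @param path text file.
#' @return character vector of unique ids.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) .io_err("cannot read id list: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Flag excluded genes from an id list
#'
#' @param records `gene_records`.
#' @param ids character vector of gene ids to exclude (e.g. HGT calls).
#' @return records with `is_excluded` set for matching ids.
#' @export
apply_exclusions <- function(records, ids) {
  records$is_excluded <- records$is_excluded | records$gene_id %in% ids
  records
}

#' Write a uniform record table as TSV
#'
#' Header, one row per record, UTF-8, Unix newlines. Numeric fields keep
#' full precision (>= 6 significant digits) so every writer/reader pair
#' round-trips within 1e-6; fields containing the delimiter are quoted.
#'
#' @param rows data.frame.
#' @param path output file.
#' @export
write_table <- function(rows, path) {
  ok <- tryCatch(suppressWarnings({
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(rows, con, sep = "\t", quote = TRUE, row.names = FALSE,
                col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
    TRUE
  }), error = function(e) FALSE)
  if (!ok) .io_err("cannot write table: ", path)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) .io_err("cannot read table: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) .io_err("empty table file (no header): ", path)
  read.table(path, sep = .sniff_sep(path), header = TRUE, quote = "\"",
             stringsAsFactors = FALSE, comment.char = "")
}
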