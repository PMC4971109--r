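## Standard (bacterial) genetic code bookkeeping shared by every metric.

.pancub_env <- new.env(parent = emptyenv())

#' Genetic code tables used by all codon metrics
#'
#' Builds (once per session) the standard bacterial genetic code bound to the
#' 64 codons in fixed alphabetical order, together with the groupings every
#' codon-usage measure needs: synonymous families by amino acid, degeneracy
#' classes (nine 2-fold, one 3-fold, five 4-fold, three 6-fold, two 1-fold),
#' the three stop codons, and the 59 informative codons (61 sense codons
#' minus ATG and TGG).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{codons}{character(64), alphabetical DNA codons.}
#'     \item{aa}{named character(64), amino acid (one-letter, `*` = stop).}
#'     \item{sense}{character(61), non-stop codons.}
#'     \item{stops}{character(3): TAA, TAG, TGA.}
#'     \item{informative}{character(59), sense codons minus ATG/TGG.}
#'     \item{families}{named list of codon vectors, one per amino acid with
#'       degeneracy >= 2 (18 families).}
#'     \item{degeneracy}{named integer, family size per amino acid.}
#'     \item{base_at}{list of three 64 x 4 indicator matrices mapping codon
#'       counts to positional nucleotide counts (columns A, C, G, T).}
#'   }
#' @export
genetic_code <- function() {
  if (!is.null(.pancub_env$code)) {
    return(.pancub_env$code)
  }
  gc_map <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc_map))
  aa <- gc_map[codons]
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  informative <- setdiff(sense, c("ATG", "TGG"))
  fam_all <- split(sense, aa[sense])
  families <- fam_all[lengths(fam_all) >= 2L]
  families <- lapply(families, sort)
  degeneracy <- vapply(fam_all, length, integer(1))
  bases <- c("A", "C", "G", "T")
  base_at <- lapply(1:3, function(i) {
    m <- matrix(0L, nrow = 64L, ncol = 4L,
                dimnames = list(codons, bases))
    m[cbind(seq_len(64L), match(substr(codons, i, i), bases))] <- 1L
    m
  })
  code <- list(
    codons = codons, aa = aa, sense = sense, stops = stops,
    informative = informative, families = families,
    degeneracy = degeneracy, base_at = base_at
  )
  stopifnot(
    length(sense) == 61L, length(informative) == 59L,
    sum(degeneracy[names(families)] %in% 2L) == 9L,
    sum(degeneracy[names(families)] %in% 3L) == 1L,
    sum(degeneracy[names(families)] %in% 4L) == 5L,
    sum(degeneracy[names(families)] %in% 6L) == 3L
  )
  .pancub_env$code <- code
  code
}

#' Reverse complement of DNA triplets
#'
#' @param x character vector of triplets over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

# split a nucleotide string into codons (no validation)
.codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}
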