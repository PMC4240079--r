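## Codon bookkeeping shared across modules.

.BASES <- c("T", "C", "A", "G")

#' The 64 codons in TCAG box order
#' @keywords internal
all_codons <- function() {
  as.vector(t(outer(
    as.vector(t(outer(.BASES, .BASES, paste0))), .BASES, paste0
  )))
}

#' Stop codons of the standard genetic code
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' Codons are DNA alphabet, ordered by TCAG within four-codon boxes
#' (the conventional tRNA-table order).
#' @return character vector of length 61
#' @export
sense_codons <- function() setdiff(all_codons(), stop_codons())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Amino acid encoded by a codon
#' @param codon character vector of DNA codons
#' @return one-letter amino-acid codes ("*" for stop)
#' @export
codon_aa <- function(codon) {
  unname(.genetic_code()[toupper(codon)])
}

#' Synonymous codons of a codon
#'
#' Sense codons encoding the same amino acid, excluding the codon itself.
#' @param codon a single codon string
#' @export
synonymous_codons <- function(codon) {
  aa <- codon_aa(codon)
  sc <- sense_codons()
  setdiff(sc[codon_aa(sc) == aa], toupper(codon))
}

#' Codons with the same nucleotide composition
#'
#' Sense codons that are anagrams of the given codon's nucleotides,
#' excluding the codon itself.
#' @param codon a single codon string
#' @export
same_composition_codons <- function(codon) {
  codon <- toupper(codon)
  key <- paste(sort(strsplit(codon, "")[[1]]), collapse = "")
  sc <- sense_codons()
  keys <- vapply(strsplit(sc, ""), function(x) paste(sort(x), collapse = ""),
                 character(1))
  setdiff(sc[keys == key], codon)
}

#' Reverse complement of DNA strings
#' @keywords internal
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1))
}

## split an in-frame nucleotide string into codons
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

ribo_log <- function(...) message("[ribodist] ", ...)

## run expr under a fixed seed without disturbing the caller's RNG;
## NULL seed = use current RNG state
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## derive a reproducible sub-seed for a named stage from a master seed
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483647L
}
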