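## profile_io: ORF sequences, RC profiles, tRNA tables, result artifacts.

#' Construct a gene profile
#'
#' A gene profile holds one ORF's codon sequence and its ribosome footprint
#' read-count (RC) vector, codon-indexed 1-based from the start codon.
#'
#' @param gene_id gene identifier
#' @param codons character vector of codons over \{A,C,G,T\}
#' @param rc numeric vector of non-negative read counts, same length
#' @return an object of class `gene_profile`
#' @export
gene_profile <- function(gene_id, codons, rc) {
  codons <- toupper(codons)
  if (length(codons) != length(rc))
    stop("gene ", gene_id, ": codons and rc differ in length")
  if (length(codons) < 1L)
    stop("gene ", gene_id, ": empty profile")
  if (!all(grepl("^[ACGT]{3}$", codons)))
    stop("gene ", gene_id, ": malformed codon(s)")
  rc <- as.numeric(rc)
  if (anyNA(rc) || any(rc < 0))
    stop("gene ", gene_id, ": rc must be non-negative and non-missing")
  structure(list(gene_id = as.character(gene_id), codons = codons, rc = rc),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat("<gene_profile>", x$gene_id, "-", length(x$codons), "codons, total RC",
      format(sum(x$rc)), "\n")
  invisible(x)
}

#' Read ORF sequences from a FASTA file
#'
#' Sequences are upper-cased, U mapped to T, and split into codons in frame
#' from position 1.
#'
#' @param path FASTA file of in-frame ORF nucleotide sequences
#' @param on_error `"abort"` (default) or `"skip"`: what to do with records
#'   whose length is not a multiple of 3 or that contain non-ACGTU characters
#'   (skipped records are logged)
#' @return named list: gene id -> character vector of codons
#' @export
read_orfs <- function(path, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  out <- list()
  for (i in seq_along(seqs)) {
    bad <- NULL
    if (grepl("[^ACGT]", seqs[[i]]))
      bad <- "contains non-ACGTU characters"
    else if (nchar(seqs[[i]]) %% 3L != 0L || nchar(seqs[[i]]) == 0L)
      bad <- "length not a positive multiple of 3"
    if (!is.null(bad)) {
      msg <- paste0("record '", ids[i], "' ", bad)
      if (on_error == "abort") stop(msg)
      ribo_log("skipping ", msg)
      next
    }
    out[[ids[i]]] <- split_codons(seqs[[i]])
  }
  out
}

#' Read RC profiles and join them with ORF sequences
#'
#' The TSV must have a header with columns `gene_id`, `codon_index`, `rc`.
#' `codon_index` is 1-based; missing indices are treated as RC 0 (sparse
#' profiles). Genes present in only one of the two inputs are logged and
#' dropped.
#'
#' @param path TSV file of read counts
#' @param orfs named list of codon vectors, as from [read_orfs()]
#' @return list of [gene_profile()] objects, one per gene in both inputs
#' @export
read_rc_profiles <- function(path, orfs) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = "gene_id"))
  need <- c("gene_id", "codon_index", "rc")
  if (!all(need %in% names(dt)))
    stop("profile TSV must have columns: ", paste(need, collapse = ", "))
  if (any(dt$rc < 0)) stop("negative rc values in ", path)
  common <- intersect(names(orfs), unique(dt$gene_id))
  lost <- setdiff(union(unique(dt$gene_id), names(orfs)), common)
  if (length(lost))
    ribo_log(length(lost), " gene(s) present in only one input dropped: ",
             paste(head(lost, 5), collapse = ", "),
             if (length(lost) > 5) ", ...")
  split_rows <- split(dt[dt$gene_id %in% common, ], by = "gene_id")
  lapply(setNames(common, common), function(g) {
    codons <- orfs[[g]]
    rows <- split_rows[[g]]
    if (any(rows$codon_index < 1L) || any(rows$codon_index > length(codons)))
      stop("gene ", g, ": codon_index outside 1..", length(codons))
    if (anyDuplicated(rows$codon_index))
      stop("gene ", g, ": duplicate codon_index rows")
    rc <- numeric(length(codons))
    rc[rows$codon_index] <- rows$rc
    gene_profile(g, codons, rc)
  })
}

#' Write gene or NFC profiles to the package TSV dialect
#'
#' Gene profiles are written as `gene_id`, `codon_index`, `rc`; NFC profiles
#' additionally carry `nfc` and `included` columns.
#'
#' @param profiles list of `gene_profile` or `nfc_profile` objects
#' @param path output TSV path
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    d <- data.table::data.table(
      gene_id = p$gene_id,
      codon_index = seq_along(p$codons),
      rc = if (!is.null(p$rc)) p$rc else NA_real_)
    if (inherits(p, "nfc_profile")) {
      d$nfc <- p$nfc
      d$included <- p$included
    }
    d
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' Write ORF codon sequences as FASTA
#' @param orfs named list of codon vectors
#' @param path output FASTA path
#' @export
write_orfs <- function(orfs, path) {
  seqs <- vapply(orfs, paste, character(1), collapse = "")
  writeLines(paste0(">", names(orfs), "\n", seqs), path)
  invisible(path)
}

#' Read a tRNA gene copy-number table
#'
#' TSV with header columns `codon` and `copies`: for each sense codon, the
#' genomic copy number of the tRNA whose anticodon is the codon's
#' Watson-Crick partner. Missing sense codons are set to 0 with a warning;
#' duplicated codons abort.
#'
#' @param path TSV file
#' @param organism organism label attached to the table
#' @return a named integer vector over the 61 sense codons, class `trna_table`
#' @export
read_trna_table <- function(path, organism = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t")
  if (!all(c("codon", "copies") %in% names(dt)))
    stop("tRNA table must have columns codon, copies")
  dt$codon <- toupper(gsub("U", "T", dt$codon))
  if (anyDuplicated(dt$codon))
    stop("duplicate codon rows in tRNA table: ",
         paste(unique(dt$codon[duplicated(dt$codon)]), collapse = ", "))
  trna_table(setNames(dt$copies, dt$codon), organism = organism)
}

#' Construct a tRNA copy-number table
#' @param copies named numeric vector, codon -> copy number
#' @param organism organism label
#' @export
trna_table <- function(copies, organism = NA_character_) {
  sc <- sense_codons()
  unknown <- setdiff(names(copies), sc)
  if (length(unknown))
    stop("non-sense-codon keys in tRNA table: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(sc, names(copies))
  if (length(missing)) {
    warning(length(missing), " sense codon(s) missing from tRNA table, ",
            "set to 0: ", paste(missing, collapse = ", "))
  }
  full <- setNames(numeric(61), sc)
  full[names(copies)] <- copies
  if (any(full < 0) || anyNA(full)) stop("tRNA copy numbers must be >= 0")
  structure(full, organism = organism, class = "trna_table")
}
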