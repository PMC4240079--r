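## nfc_core: RC -> NFC normalization and per-codon pooling.

#' Normalize a gene's RC profile to NFC
#'
#' NFC_j = RC_j / mean(RC) with the mean taken over "included" codons:
#' positions outside the first/last `exclude_terminal` codons whose RC is at
#' least `min_rc`. Terminal codons are excluded because footprint density is
#' systematically inflated near ORF ends; low-count codons are excluded to
#' avoid biasing the per-gene average. Because mRNA level and initiation rate
#' scale every RC_j of a gene equally, NFC cancels both and proxies the
#' decoding time of codon j relative to the gene's other codons.
#'
#' @param profile a [gene_profile()]
#' @param exclude_terminal number of codons dropped at each ORF end
#'   (default 20)
#' @param min_rc inclusion threshold on RC (default 1)
#' @param pool_zeros if `TRUE`, positions failing `min_rc` keep NFC 0 and stay
#'   available for pooling (sensitivity analysis); default `FALSE` excludes
#'   them from both the mean and pooling
#' @return an `nfc_profile`: gene_id, codons, `nfc` (NA where excluded unless
#'   `pool_zeros`), logical `included` mask, or `NULL` (with a log entry) if
#'   no codon survives the filters
#' @export
compute_nfc <- function(profile, exclude_terminal = 20, min_rc = 1,
                        pool_zeros = FALSE) {
  stopifnot(inherits(profile, "gene_profile"))
  J <- length(profile$rc)
  if (J <= 2 * exclude_terminal) {
    ribo_log("gene ", profile$gene_id, " shorter than 2*exclude_terminal+1 (",
             J, " codons), dropped")
    return(NULL)
  }
  inner <- seq_len(J) > exclude_terminal & seq_len(J) <= J - exclude_terminal
  included <- inner & profile$rc >= min_rc
  if (!any(included)) {
    ribo_log("gene ", profile$gene_id, " has no included codon, dropped")
    return(NULL)
  }
  m <- mean(profile$rc[included])
  nfc <- rep(NA_real_, J)
  nfc[included] <- profile$rc[included] / m
  if (pool_zeros) {
    low <- inner & !included
    nfc[low] <- 0
    included <- inner
  }
  structure(list(gene_id = profile$gene_id, codons = profile$codons,
                 rc = profile$rc, nfc = nfc, included = included),
            class = "nfc_profile")
}

#' @export
print.nfc_profile <- function(x, ...) {
  cat("<nfc_profile>", x$gene_id, "-", length(x$codons), "codons,",
      sum(x$included), "included\n")
  invisible(x)
}

#' Normalize a set of gene profiles
#'
#' Applies [compute_nfc()] to every profile, dropping genes that fail the
#' filters and logging the drop count.
#'
#' @inheritParams compute_nfc
#' @param profiles list of [gene_profile()] objects
#' @return list of `nfc_profile` objects
#' @export
compute_nfc_profiles <- function(profiles, exclude_terminal = 20, min_rc = 1,
                                 pool_zeros = FALSE) {
  out <- lapply(profiles, compute_nfc, exclude_terminal = exclude_terminal,
                min_rc = min_rc, pool_zeros = pool_zeros)
  kept <- !vapply(out, is.null, logical(1))
  if (any(!kept))
    ribo_log(sum(!kept), " of ", length(out), " genes dropped by NFC filters")
  out[kept]
}

#' Describe an analysis region by offsets from both ORF ends
#' @param five codons skipped at the 5' end (region starts at `five + 1`)
#' @param three codons skipped at the 3' end
#' @export
region_offsets <- function(five = 20, three = 20) {
  structure(list(type = "offsets", five = five, three = three),
            class = "nfc_region")
}

#' Describe an analysis region as a fixed window anchored at one ORF end
#' @param start 1-based start position counted from the anchored end
#' @param length window length in codons
#' @param end `"5p"` or `"3p"`; for `"3p"`, position 1 is the last codon
#' @export
region_window <- function(start, length, end = c("5p", "3p")) {
  end <- match.arg(end)
  structure(list(type = "window", start = start, length = length, end = end),
            class = "nfc_region")
}

## absolute codon positions of a region within a gene of J codons,
## or NULL if the gene is too short
region_positions <- function(region, J) {
  if (region$type == "offsets") {
    lo <- region$five + 1L
    hi <- J - region$three
    if (lo > hi) return(NULL)
    return(lo:hi)
  }
  rel <- region$start:(region$start + region$length - 1L)
  if (max(rel) > J) return(NULL)
  if (region$end == "5p") rel else (J - rel + 1L)
}

#' Pool included NFC values per codon type over a region
#'
#' For every sense codon, concatenates the included NFC values observed at
#' positions whose codon matches, across genes, restricted to the given
#' region of each ORF. Stop codons are never pooled. The resulting object is
#' what all distribution fits and distance computations consume.
#'
#' @param nfc_profiles list of `nfc_profile` objects
#' @param region an [region_offsets()] or [region_window()]; default: the
#'   full included inner region
#' @param organism provenance label
#' @return a `codon_sample_set`: named list codon -> numeric samples, with
#'   provenance attributes (`organism`, `region`, `n_genes`)
#' @export
pool_by_codon <- function(nfc_profiles, region = region_offsets(0, 0),
                          organism = NA_character_) {
  sc <- sense_codons()
  acc_cod <- vector("list", length(nfc_profiles))
  acc_val <- vector("list", length(nfc_profiles))
  skipped <- 0L
  for (i in seq_along(nfc_profiles)) {
    p <- nfc_profiles[[i]]
    posn <- region_positions(region, length(p$codons))
    if (is.null(posn)) { skipped <- skipped + 1L; next }
    posn <- posn[p$included[posn]]
    posn <- posn[p$codons[posn] %in% sc]
    acc_cod[[i]] <- p$codons[posn]
    acc_val[[i]] <- p$nfc[posn]
  }
  if (skipped) ribo_log(skipped, " gene(s) shorter than the region, skipped")
  cod <- unlist(acc_cod, use.names = FALSE)
  val <- unlist(acc_val, use.names = FALSE)
  samples <- lapply(setNames(sc, sc), function(cc) val[cod == cc])
  codon_sample_set(samples, organism = organism, region = region,
                   n_genes = length(nfc_profiles) - skipped)
}

#' Construct a codon sample set
#' @param samples named list, codon -> numeric vector of NFC samples
#' @param organism,region,n_genes provenance
#' @export
codon_sample_set <- function(samples, organism = NA_character_,
                             region = NULL, n_genes = NA_integer_) {
  if (any(vapply(samples, function(x) any(x < 0 | !is.finite(x)), logical(1))))
    stop("NFC samples must be finite and non-negative")
  bad <- setdiff(names(samples), sense_codons())
  if (length(bad)) stop("non-sense codons in sample set: ",
                        paste(bad, collapse = ", "))
  structure(samples, organism = organism, region = region, n_genes = n_genes,
            class = "codon_sample_set")
}

#' @export
print.codon_sample_set <- function(x, ...) {
  n <- vapply(x, length, integer(1))
  cat("<codon_sample_set>", length(x), "codons,",
      sum(n), "samples (min", min(n), "/ median", median(n),
      "/ max", max(n), "per codon)\n")
  invisible(x)
}

#' Codons present (non-empty) in a sample set
#' @param samples a `codon_sample_set`
#' @export
present_codons <- function(samples) {
  names(samples)[vapply(samples, length, integer(1)) > 0L]
}

#' Subsample every codon to an equal number of NFC values
#'
#' Controls for unequal codon frequencies: each present codon is reduced to
#' exactly `n` samples drawn without replacement. If `n` exceeds the smallest
#' per-codon count, it is lowered to that minimum (logged).
#'
#' @param samples a `codon_sample_set`
#' @param n target samples per codon (default: the minimum count)
#' @param seed RNG seed for reproducible draws
#' @export
subsample_equal <- function(samples, n = NULL, seed = NULL) {
  present <- present_codons(samples)
  counts <- vapply(samples[present], length, integer(1))
  n_min <- min(counts)
  if (is.null(n)) n <- n_min
  if (n > n_min) {
    ribo_log("subsample_equal: n lowered from ", n, " to ", n_min)
    n <- n_min
  }
  if (n < 10) warning("subsample_equal: n < 10, distribution estimates ",
                      "will be unstable")
  out <- with_seed_or_current(seed, {
    lapply(samples, function(x) if (length(x) > n) sample(x, n) else x)
  })
  attributes(out) <- attributes(samples)
  out
}
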