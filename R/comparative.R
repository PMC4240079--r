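## comparative: cross-organism NFC distances, NJ clustering, domain test.

#' Bundle per-organism codon sample sets with domain labels
#'
#' @param sets named list: organism label -> `codon_sample_set`
#' @param domains named character vector, organism -> `"prokaryote"` or
#'   `"eukaryote"`
#' @return an `organism_set`
#' @export
organism_set <- function(sets, domains) {
  if (length(sets) < 2) stop("need at least 2 organisms")
  if (is.null(names(sets)) || anyNA(names(sets)))
    stop("sets must be a named list")
  if (!all(names(sets) %in% names(domains)))
    stop("every organism needs a domain label")
  domains <- domains[names(sets)]
  if (!all(domains %in% c("prokaryote", "eukaryote")))
    stop("domains must be 'prokaryote' or 'eukaryote'")
  structure(list(sets = sets, domains = domains), class = "organism_set")
}

## per-codon organism x organism distance matrices over shared codons
per_codon_org_matrices <- function(oset, metric = "hellinger",
                                   min_samples = 10, bin_width = 0.05,
                                   upper = 5.0) {
  orgs <- names(oset$sets)
  shared <- Reduce(intersect, lapply(oset$sets, function(s) {
    names(s)[vapply(s, length, integer(1)) >= min_samples]
  }))
  if (length(shared) == 0) stop("no codon shared across all organisms")
  dropped <- setdiff(sense_codons(), shared)
  if (length(dropped))
    ribo_log(length(dropped), " codon(s) missing in some organism dropped")
  lapply(setNames(shared, shared), function(cc) {
    D <- matrix(0, length(orgs), length(orgs),
                dimnames = list(orgs, orgs))
    for (a in seq_along(orgs)) for (b in seq_len(a - 1)) {
      D[a, b] <- D[b, a] <- sample_distance(
        oset$sets[[a]][[cc]], oset$sets[[b]][[cc]], metric,
        bin_width, upper)
    }
    D
  })
}

#' Averaged cross-organism NFC distance matrix
#'
#' For every codon present in all organisms, computes the organism-pair
#' distance between pooled NFC distributions, then averages the per-codon
#' matrices over codons.
#'
#' @param oset an [organism_set()]
#' @param metric `"hellinger"`, `"js"` or `"energy"`
#' @param min_samples codons with fewer samples in any organism are dropped
#' @param bin_width,upper histogram binning for histogram metrics
#' @return symmetric organism x organism matrix with attribute `metric` and
#'   attribute `per_codon` (the list of per-codon matrices)
#' @export
cross_organism_matrix <- function(oset, metric = c("hellinger", "js",
                                                   "energy"),
                                  min_samples = 10, bin_width = 0.05,
                                  upper = 5.0) {
  metric <- match.arg(metric)
  mats <- per_codon_org_matrices(oset, metric, min_samples, bin_width, upper)
  D <- Reduce(`+`, mats) / length(mats)
  attr(D, "metric") <- metric
  attr(D, "per_codon") <- mats
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the unrooted NJ tree (via the agglomerative neighbor-joining
#' algorithm) and returns it in Newick form. Negative branch lengths, which
#' NJ can produce on non-additive matrices, are clamped to zero with the
#' deficit moved to the adjacent (sister) branch, preserving path lengths
#' between the affected tips (logged).
#'
#' @param d symmetric distance matrix with row/column labels (>= 3 taxa)
#' @return Newick string (branch lengths at 6 significant digits); the
#'   `phylo` tree is attached as attribute `"tree"`
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (nrow(d) == 3) {
    # three-point closed form; nj() needs >= 4 taxa
    lab <- rownames(d)
    a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g,%s:%g);",
                                        lab[1], a, lab[2], b, lab[3], cc))
  } else {
    tr <- ape::nj(stats::as.dist(d))
  }
  neg <- which(tr$edge.length < 0)
  if (length(neg)) {
    ribo_log(length(neg), " negative NJ branch length(s) clamped to 0")
    for (e in neg) {
      parent <- tr$edge[e, 1]
      sisters <- which(tr$edge[, 1] == parent)
      sisters <- setdiff(sisters, e)
      deficit <- -tr$edge.length[e]
      tr$edge.length[e] <- 0
      if (length(sisters))
        tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
    }
  }
  tr$edge.length <- signif(tr$edge.length, 6)
  nwk <- ape::write.tree(tr)
  attr(nwk, "tree") <- tr
  nwk
}

#' Intra- vs inter-domain similarity test
#'
#' Pools, over all codons, the organism-pair distances classified as
#' intra-domain (both organisms prokaryotes or both eukaryotes) or
#' inter-domain, and tests whether intra-domain distances are smaller by a
#' one-sided Wilcoxon rank-sum test.
#'
#' @param d a matrix from [cross_organism_matrix()] (its `per_codon`
#'   attribute supplies the pooled observations), or a plain averaged matrix
#'   if `per_codon_matrices` is given explicitly
#' @param domains named vector, organism -> domain
#' @param per_codon_matrices optional list of per-codon organism matrices
#' @return list: `statistic` (rank-sum W), `p`, `n_intra`, `n_inter`
#' @export
domain_similarity_test <- function(d, domains, per_codon_matrices = NULL) {
  if (is.null(per_codon_matrices))
    per_codon_matrices <- attr(d, "per_codon")
  if (is.null(per_codon_matrices))
    per_codon_matrices <- list(as.matrix(d))
  orgs <- rownames(per_codon_matrices[[1]])
  domains <- domains[orgs]
  if (length(unique(domains)) < 2) stop("both domains must be represented")
  pairs <- which(upper.tri(per_codon_matrices[[1]]), arr.ind = TRUE)
  same <- domains[pairs[, 1]] == domains[pairs[, 2]]
  if (!any(same)) stop("no intra-domain organism pair available")
  intra <- unlist(lapply(per_codon_matrices, function(m) m[pairs[same, ,
                                                                 drop = FALSE]]))
  inter <- unlist(lapply(per_codon_matrices, function(m) m[pairs[!same, ,
                                                                 drop = FALSE]]))
  wt <- suppressWarnings(wilcox.test(intra, inter, alternative = "less",
                                     exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_intra = length(intra), n_inter = length(inter))
}
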