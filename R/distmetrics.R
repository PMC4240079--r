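## distmetrics: JS, Hellinger and energy distances; codon distinctness test.

check_shared_bins <- function(p, q) {
  stopifnot(inherits(p, "empirical_distribution"),
            inherits(q, "empirical_distribution"))
  if (length(p$edges) != length(q$edges) ||
      any(p$edges[is.finite(p$edges)] != q$edges[is.finite(q$edges)]))
    stop("histograms must share identical bin edges")
}

#' Jensen-Shannon distance between two histograms
#'
#' The square root of the Jensen-Shannon divergence with base-2 logarithms,
#' so the distance lies in `[0, 1]`, reaching 1 on disjoint supports.
#'
#' @param p,q `empirical_distribution` objects on identical bins
#' @return a scalar in `[0, 1]`
#' @export
js_distance <- function(p, q) {
  check_shared_bins(p, q)
  js_from_prob(p$prob, q$prob)
}

js_from_prob <- function(pp, qq) {
  m <- (pp + qq) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  d2 <- (kl(pp) + kl(qq)) / 2
  sqrt(max(d2, 0))
}

#' Hellinger distance between two histograms
#'
#' `sqrt(1 - sum(sqrt(p_i * q_i)))`, in `[0, 1]`.
#'
#' @inheritParams js_distance
#' @return a scalar in `[0, 1]`
#' @export
hellinger_distance <- function(p, q) {
  check_shared_bins(p, q)
  hellinger_from_prob(p$prob, q$prob)
}

hellinger_from_prob <- function(pp, qq) {
  sqrt(max(1 - sum(sqrt(pp * qq)), 0))
}

## mean absolute difference between all pairs of two sorted samples,
## O((n+m) log) via rank decomposition
mean_abs_cross <- function(x, y) {
  sx <- sort(x)
  cs <- c(0, cumsum(sx))
  n <- length(sx)
  k <- findInterval(y, sx)
  # sum_i |y_j - x_i| = y_j*k - S_k + (S_n - S_k) - y_j*(n-k)
  tot <- sum(y * k - cs[k + 1] + (cs[n + 1] - cs[k + 1]) - y * (n - k))
  tot / (n * length(y))
}

#' Energy distance between two samples
#'
#' `sqrt(2 E|X - Y| - E|X - X'| - E|Y - Y'|)` with expectations taken as
#' means over all sample pairs. Operates on raw samples, not histograms.
#' When the implied pair count exceeds `max_pairs`, each side is first
#' subsampled (seeded) to at most 20,000 values.
#'
#' @param x,y non-empty numeric samples
#' @param max_pairs pair-count threshold that triggers subsampling
#' @param seed RNG seed used only if subsampling triggers
#' @return a non-negative scalar
#' @export
energy_distance <- function(x, y, max_pairs = 4e8, seed = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (as.numeric(length(x)) * length(y) > max_pairs) {
    x <- with_seed_or_current(seed, {
      xs <- if (length(x) > 2e4) sample(x, 2e4) else x
      ys <- if (length(y) > 2e4) sample(y, 2e4) else y
      list(xs, ys)
    })
    y <- x[[2]]; x <- x[[1]]
  }
  exy <- mean_abs_cross(x, y)
  exx <- mean_abs_cross(x, x)
  eyy <- mean_abs_cross(y, y)
  sqrt(max(2 * exy - exx - eyy, 0))
}

#' Distance between two NFC sample vectors under a named metric
#'
#' JS and Hellinger are computed on shared fixed-bin histograms
#' ([nfc_histogram()]); energy on the raw samples.
#'
#' @param x,y numeric NFC samples
#' @param metric `"js"`, `"hellinger"` or `"energy"`
#' @param bin_width,upper histogram binning for the histogram metrics
#' @export
sample_distance <- function(x, y, metric = c("hellinger", "js", "energy"),
                            bin_width = 0.05, upper = 5.0) {
  metric <- match.arg(metric)
  if (metric == "energy") return(energy_distance(x, y))
  p <- nfc_histogram(x, bin_width, upper)
  q <- nfc_histogram(y, bin_width, upper)
  if (metric == "js") js_distance(p, q) else hellinger_distance(p, q)
}

## pool one codon's NFC samples over a subset of genes
pool_codon_genes <- function(per_gene, genes, codon) {
  unlist(lapply(per_gene[genes], function(g) g[[codon]]), use.names = FALSE)
}

## per-gene, per-codon sample lists from nfc profiles (inner region)
per_gene_codon_samples <- function(nfc_profiles) {
  sc <- sense_codons()
  lapply(nfc_profiles, function(p) {
    idx <- which(p$included & p$codons %in% sc)
    split(p$nfc[idx], factor(p$codons[idx], levels = sc))
  })
}

#' Codon distinctness test by repeated gene partitioning
#'
#' Tests whether codon `codon`'s NFC distribution is characteristic of the
#' codon rather than generic. Genes are randomly split into two halves
#' (`n_partitions` times). In each partition the codon's pooled distribution
#' in half 1 is compared to its own pooled distribution in half 2
#' (self-distance) and to every comparison codon's distribution in half 2
#' (cross-distances). The reported p-value is the fraction of
#' (partition, comparison codon) pairs in which the self-distance is not
#' smaller than the cross-distance; the codon is declared distinct when
#' `p < 0.01`.
#'
#' @param nfc_profiles list of `nfc_profile` objects (>= 2 genes)
#' @param codon the codon under test
#' @param metric distance metric (see [sample_distance()])
#' @param n_partitions number of random equal splits (default 100)
#' @param restrict comparison set: `"all"` other sense codons,
#'   `"synonymous"` codons of the same amino acid, or `"same_composition"`
#'   anagram codons
#' @param seed RNG seed
#' @param min_samples partitions where either half has fewer than this many
#'   samples of `codon` are redrawn (logged)
#' @param bin_width,upper histogram binning for histogram metrics
#' @return list: `p`, `distinct`, `self_distances` (per partition),
#'   `cross_distances` (partitions x comparison codons matrix), `codons`
#' @export
distinctness_test <- function(nfc_profiles, codon,
                              metric = c("hellinger", "js", "energy"),
                              n_partitions = 100,
                              restrict = c("all", "synonymous",
                                           "same_composition"),
                              seed = NULL, min_samples = 10,
                              bin_width = 0.05, upper = 5.0) {
  metric <- match.arg(metric)
  restrict <- match.arg(restrict)
  codon <- toupper(codon)
  if (length(nfc_profiles) < 2L) stop("need at least 2 genes")
  others <- switch(restrict,
                   all = setdiff(sense_codons(), codon),
                   synonymous = synonymous_codons(codon),
                   same_composition = same_composition_codons(codon))
  if (length(others) == 0L) {
    ribo_log("distinctness_test: empty comparison set for ", codon,
             " under '", restrict, "'")
    return(list(p = NA_real_, distinct = NA, self_distances = numeric(0),
                cross_distances = matrix(numeric(0), 0, 0), codons = others))
  }
  per_gene <- per_gene_codon_samples(nfc_profiles)
  ng <- length(per_gene)
  half <- floor(ng / 2)

  selfd <- numeric(n_partitions)
  crossd <- matrix(NA_real_, n_partitions, length(others),
                   dimnames = list(NULL, others))
  with_seed_or_current(seed, {
    for (b in seq_len(n_partitions)) {
      for (try in 1:50) {
        idx <- sample.int(ng)
        g1 <- idx[seq_len(half)]
        g2 <- idx[(half + 1):ng]
        s1 <- pool_codon_genes(per_gene, g1, codon)
        s2 <- pool_codon_genes(per_gene, g2, codon)
        if (length(s1) >= min_samples && length(s2) >= min_samples) break
        if (try == 50) stop("codon ", codon,
                            " too rare to populate both halves")
        ribo_log("partition redrawn: codon ", codon, " too rare in a half")
      }
      selfd[b] <- sample_distance(s1, s2, metric, bin_width, upper)
      for (cc in others) {
        sx <- pool_codon_genes(per_gene, g2, cc)
        if (length(sx) >= min_samples)
          crossd[b, cc] <- sample_distance(s1, sx, metric, bin_width, upper)
      }
    }
  })
  valid <- !is.na(crossd)
  p <- sum(selfd[row(crossd)[valid]] >= crossd[valid]) / sum(valid)
  list(p = p, distinct = p < 0.01, self_distances = selfd,
       cross_distances = crossd, codons = others)
}

#' Distinctness test over all present codons
#'
#' @inheritParams distinctness_test
#' @param codons codons to test (default: all sense codons with data)
#' @return data.frame: codon, metric, p, distinct, n_self, n_cross
#' @export
distinctness_table <- function(nfc_profiles, codons = NULL,
                               metric = "hellinger", n_partitions = 100,
                               restrict = "all", seed = NULL, ...) {
  if (is.null(codons)) {
    pooled <- pool_by_codon(nfc_profiles)
    codons <- present_codons(pooled)
  }
  rows <- lapply(seq_along(codons), function(i) {
    r <- distinctness_test(nfc_profiles, codons[i], metric = metric,
                           n_partitions = n_partitions, restrict = restrict,
                           seed = if (is.null(seed)) NULL else seed + i, ...)
    data.frame(codon = codons[i], metric = metric, p = r$p,
               distinct = r$distinct, n_self = length(r$self_distances),
               n_cross = sum(!is.na(r$cross_distances)))
  })
  do.call(rbind, rows)
}
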