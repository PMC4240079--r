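## positional: sliding-window NFC distributions along ORF ends, the mean
## distance vector, and the Wilcoxon-scan boundary estimator.

#' Per-window codon sample sets near one ORF end
#'
#' Pools included NFC values per codon type in sliding windows of
#' `window` codons (step `step`) anchored at the chosen ORF end, covering the
#' first (or last) `span` codons. Per-gene NFC normalization is taken as-is
#' from the profiles (computed once over the gene's included region); the
#' windows only restrict pooling. For the 3' end, position 1 is the last
#' codon and windows run inward (mirror order).
#'
#' @param nfc_profiles list of `nfc_profile` objects
#' @param end `"5p"` or `"3p"`
#' @param span how many codons from the end are scanned (default 200)
#' @param window window length in codons (default 50)
#' @param step window step (default 1)
#' @param equalize_rc if `TRUE`, each codon is subsampled to its minimum
#'   per-window count across windows, controlling for unequal codon coverage
#' @param seed RNG seed (used only when `equalize_rc`)
#' @return a `window_sets` object: list with `starts` (window start
#'   positions, 1-based from the anchored end) and `sets` (a
#'   `codon_sample_set` per window)
#' @export
window_sample_sets <- function(nfc_profiles, end = c("5p", "3p"), span = 200,
                               window = 50, step = 1, equalize_rc = FALSE,
                               seed = NULL) {
  end <- match.arg(end)
  starts <- seq(1L, span - window + 1L, by = step)
  sc <- sense_codons()

  ## flatten: one record per included sense-codon position within `span`
  ## of the anchored end
  rel_l <- vector("list", length(nfc_profiles))
  cod_l <- vector("list", length(nfc_profiles))
  val_l <- vector("list", length(nfc_profiles))
  for (i in seq_along(nfc_profiles)) {
    p <- nfc_profiles[[i]]
    J <- length(p$codons)
    pos <- which(p$included & p$codons %in% sc)
    rel <- if (end == "5p") pos else J - pos + 1L
    keep <- rel <= span
    rel_l[[i]] <- rel[keep]
    cod_l[[i]] <- p$codons[pos[keep]]
    val_l[[i]] <- p$nfc[pos[keep]]
  }
  rel <- unlist(rel_l, use.names = FALSE)
  cod <- unlist(cod_l, use.names = FALSE)
  val <- unlist(val_l, use.names = FALSE)
  ord <- order(rel)
  rel <- rel[ord]; cod <- cod[ord]; val <- val[ord]

  sets <- lapply(starts, function(k) {
    lo <- findInterval(k - 1L, rel) + 1L
    hi <- findInterval(k + window - 1L, rel)
    if (hi < lo) {
      s <- lapply(setNames(sc, sc), function(x) numeric(0))
    } else {
      s <- split(val[lo:hi], factor(cod[lo:hi], levels = sc))
    }
    codon_sample_set(s, region = region_window(k, window, end),
                     n_genes = length(nfc_profiles))
  })

  if (equalize_rc) {
    counts <- sapply(sets, function(s) vapply(s, length, integer(1)))
    min_per_codon <- apply(counts, 1, min)
    sets <- with_seed_or_current(seed, {
      lapply(sets, function(s) {
        out <- lapply(sc, function(cc) {
          x <- s[[cc]]
          m <- min_per_codon[[cc]]
          if (m > 0 && length(x) > m) sample(x, m) else x[seq_len(m * (m > 0))]
        })
        names(out) <- sc
        attributes(out) <- attributes(s)
        out
      })
    })
  }
  structure(list(starts = starts, sets = sets, end = end, window = window),
            class = "window_sets")
}

#' Mean distance vector over sliding windows
#'
#' For every codon, computes the all-pairs distance matrix between its NFC
#' distributions in the different windows; averages these matrices over
#' codons (entries where a codon is absent from either window are skipped);
#' then averages each column (excluding the diagonal). Each component
#' describes how different one window's NFC distributions are, on average,
#' from all other windows'.
#'
#' @param window_sets a `window_sets` object from [window_sample_sets()]
#' @param metric `"hellinger"`, `"js"` or `"energy"`
#' @param min_samples windows with fewer samples of a codon are treated as
#'   absent for that codon (default 10)
#' @param bin_width,upper histogram binning for histogram metrics
#' @return a `mean_distance_vector`: data.frame with `start`, `mean_dist`,
#'   `sd_dist`, plus attributes `metric`, `window`, `end`
#' @export
mean_distance_vector <- function(window_sets,
                                 metric = c("hellinger", "js", "energy"),
                                 min_samples = 10, bin_width = 0.05,
                                 upper = 5.0) {
  metric <- match.arg(metric)
  sets <- window_sets$sets
  nw <- length(sets)
  if (nw < 2) stop("need at least 2 windows")
  sc <- sense_codons()
  dsum <- matrix(0, nw, nw)
  dcnt <- matrix(0L, nw, nw)

  for (cc in sc) {
    xs <- lapply(sets, `[[`, cc)
    ok <- which(vapply(xs, length, integer(1)) >= min_samples)
    if (length(ok) < 2) next
    if (metric == "energy") {
      D <- matrix(0, length(ok), length(ok))
      for (a in seq_along(ok)) for (b in seq_len(a - 1L)) {
        D[a, b] <- D[b, a] <- energy_distance(xs[[ok[a]]], xs[[ok[b]]])
      }
    } else {
      P <- t(vapply(xs[ok], function(x)
        nfc_histogram(x, bin_width, upper)$prob,
        numeric(round(upper / bin_width) + 1)))
      if (metric == "hellinger") {
        S <- sqrt(P) %*% t(sqrt(P))
        D <- sqrt(pmax(1 - S, 0))
      } else {
        D <- matrix(0, length(ok), length(ok))
        for (a in seq_along(ok)) {
          M <- (P[rep(a, nrow(P)), , drop = FALSE] + P) / 2
          t1 <- P[rep(a, nrow(P)), , drop = FALSE] *
            log2(P[rep(a, nrow(P)), , drop = FALSE] / M)
          t2 <- P * log2(P / M)
          t1[!is.finite(t1)] <- 0
          t2[!is.finite(t2)] <- 0
          D[a, ] <- sqrt(pmax((rowSums(t1) + rowSums(t2)) / 2, 0))
        }
        D <- (D + t(D)) / 2
      }
      diag(D) <- 0
    }
    dsum[ok, ok] <- dsum[ok, ok] + D
    dcnt[ok, ok] <- dcnt[ok, ok] + 1L
  }

  avg <- dsum / pmax(dcnt, 1L)
  avg[dcnt == 0L] <- NA_real_
  diag(avg) <- NA_real_  # column means exclude the diagonal
  v <- colMeans(avg, na.rm = TRUE)
  s <- apply(avg, 2, sd, na.rm = TRUE)
  structure(data.frame(start = window_sets$starts, mean_dist = v,
                       sd_dist = s),
            metric = metric, window = window_sets$window,
            end = window_sets$end, class = c("mean_distance_vector",
                                             "data.frame"))
}

## Wilcoxon scan shared by detect_boundary and boundary_on_mean_rc:
## first index k whose scan window no longer differs from the rest
wilcoxon_scan <- function(v, scan = 10, alpha = 0.05) {
  n <- length(v)
  if (n <= scan + 5) stop("vector too short for the scan")
  pvals <- rep(NA_real_, n - scan + 1L)
  boundary <- NA_integer_
  for (k in seq_len(n - scan + 1L)) {
    inside <- v[k:(k + scan - 1L)]
    outside <- v[-(k:(k + scan - 1L))]
    pvals[k] <- suppressWarnings(
      wilcox.test(inside, outside, exact = FALSE)$p.value)
    if (is.na(pvals[k])) pvals[k] <- 1  # constant data: no evidence of change
    if (pvals[k] > alpha) { boundary <- k; break }
  }
  list(boundary = boundary, pvals = pvals[!is.na(pvals)])
}

#' Estimate the boundary of the end region with shifted NFC distributions
#'
#' Slides a window of `scan` consecutive components over the mean distance
#' vector and compares the values inside the window with all remaining
#' values by a two-sided Wilcoxon rank-sum test. The boundary is the start
#' position of the first window whose test exceeds `alpha` (no longer
#' significantly different); if every test is significant the estimate is
#' flagged none-found.
#'
#' @param v a `mean_distance_vector`
#' @param scan scan window length (default 10)
#' @param alpha significance level (default 0.05)
#' @return a `boundary_estimate`: `end`, `boundary` (codon position, NA if
#'   none found), `pvals` (per tested start), `alpha`
#' @export
detect_boundary <- function(v, scan = 10, alpha = 0.05) {
  res <- wilcoxon_scan(v$mean_dist, scan = scan, alpha = alpha)
  boundary <- if (is.na(res$boundary)) NA_integer_ else
    as.integer(v$start[res$boundary])
  structure(list(end = attr(v, "end"), boundary = boundary,
                 pvals = res$pvals, alpha = alpha, scan = scan,
                 source = "nfc_distributions"),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat("<boundary_estimate>", x$end, "end:",
      if (is.na(x$boundary)) "no boundary found in scanned range"
      else paste("codon", x$boundary),
      "(", x$source, ", alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Boundary scan on the positional mean RC profile
#'
#' The comparison analysis: instead of distribution distances, the raw RC
#' values are averaged position-wise across genes (positions counted from
#' the chosen end, up to `span`), and the same Wilcoxon scan is applied to
#' that positional profile. A boundary found here reflects a shift in mean
#' coverage; [detect_boundary()] can find regions whose distributions shift
#' even when mean coverage does not.
#'
#' @param profiles list of `gene_profile` (or `nfc_profile`) objects with
#'   raw `rc`
#' @param end `"5p"` or `"3p"`
#' @param span positions from the end to include (default 200)
#' @param scan,alpha as in [detect_boundary()]
#' @return a `boundary_estimate` with `source = "mean_rc"`
#' @export
boundary_on_mean_rc <- function(profiles, end = c("5p", "3p"), span = 200,
                                scan = 10, alpha = 0.05) {
  end <- match.arg(end)
  tot <- numeric(span)
  cnt <- numeric(span)
  for (p in profiles) {
    J <- length(p$rc)
    m <- min(span, J)
    idx <- if (end == "5p") seq_len(m) else J - seq_len(m) + 1L
    tot[seq_len(m)] <- tot[seq_len(m)] + p$rc[idx]
    cnt[seq_len(m)] <- cnt[seq_len(m)] + 1
  }
  v <- tot / pmax(cnt, 1)
  res <- wilcoxon_scan(v, scan = scan, alpha = alpha)
  structure(list(end = end, boundary = res$boundary, pvals = res$pvals,
                 alpha = alpha, scan = scan, source = "mean_rc"),
            class = "boundary_estimate")
}
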