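## distfit: empirical histograms, ML family fits, log-normal features.

#' Empirical NFC histogram on fixed shared bins
#'
#' Uniform bins of width `bin_width` on `[0, upper)` plus one overflow bin
#' `[upper, Inf)`. All histogram-based distances in the package require the
#' two distributions to share these edges.
#'
#' @param samples numeric vector of non-negative NFC values
#' @param bin_width bin width in NFC units (default 0.05)
#' @param upper start of the overflow bin (default 5)
#' @return an `empirical_distribution`: bin edges, per-bin probabilities
#'   summing to 1, midpoints, sample count
#' @export
nfc_histogram <- function(samples, bin_width = 0.05, upper = 5.0) {
  if (length(samples) < 1L) stop("histogram needs at least one sample")
  if (any(!is.finite(samples))) stop("non-finite sample")
  if (any(samples < 0)) stop("negative NFC sample")
  edges <- seq(0, upper, by = bin_width)
  nb <- length(edges)  # nb-1 regular bins + overflow
  idx <- findInterval(samples, edges)
  counts <- tabulate(idx, nbins = nb)
  mids <- c(edges[-length(edges)] + bin_width / 2, upper + bin_width / 2)
  structure(list(edges = c(edges, Inf), prob = counts / length(samples),
                 mids = mids, n = length(samples),
                 bin_width = bin_width, upper = upper),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat("<empirical_distribution>", length(x$prob), "bins of width",
      x$bin_width, "- n =", x$n, "\n")
  invisible(x)
}

#' Fit one distribution family by maximum likelihood
#'
#' Families with closed-form MLEs (normal, log-normal, Rayleigh, inverse
#' Gaussian) are solved directly; the rest are maximized numerically from
#' moment-based starts. For positive-support families, samples at 0 are
#' dropped (count logged). A fit that fails (non-convergence, degenerate
#' boundary, non-finite likelihood) is returned flagged `converged = FALSE`
#' and is excluded from model selection.
#'
#' @param samples numeric NFC samples
#' @param family a family name from [nfc_families()] or a family definition
#' @param min_n minimum sample size (default 30)
#' @return a `fit_result`: family name, named natural parameters,
#'   log-likelihood, n, `converged`
#' @export
fit_family <- function(samples, family, min_n = 30) {
  if (is.character(family)) {
    fam_name <- family
    family <- nfc_families()[[family]]
    if (is.null(family)) stop("unknown family: ", fam_name)
  } else fam_name <- family$label
  x <- samples[is.finite(samples)]
  if (length(x) != length(samples)) stop("non-finite samples")
  if (isTRUE(family$positive) || isTRUE(family$scaled)) {
    n0 <- sum(x <= 0)
    if (n0 > 0) {
      ribo_log(fam_name, ": dropped ", n0, " non-positive sample(s)")
      x <- x[x > 0]
    }
  }
  fail <- function(msg) structure(
    list(family = fam_name, params = NULL, loglik = -Inf, n = length(x),
         converged = FALSE, message = msg),
    class = "fit_result")
  if (length(x) < min_n) return(fail("too few samples"))

  if (!is.null(family$fit)) {          # closed form
    res <- family$fit(x)
    if (is.null(res) || !is.finite(res$loglik))
      return(fail("degenerate closed-form MLE"))
    return(structure(list(family = fam_name, params = res$params,
                          loglik = res$loglik, n = length(x),
                          converged = TRUE, message = "ok"),
                     class = "fit_result"))
  }

  jac <- 0
  if (isTRUE(family$scaled)) {         # Beta: map onto (0,1)
    M <- max(x) * (1 + 1e-6)
    jac <- -length(x) * log(M)
    x <- x / M
  }
  nll <- function(q) {
    ld <- family$logdens(x, family$untrans(q))
    v <- sum(ld)
    if (!is.finite(v)) 1e10 else -v
  }
  q0 <- family$start(x)
  opt <- tryCatch(
    optim(q0, nll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || opt$value >= 1e10)
    return(fail("optimizer did not converge"))
  structure(list(family = fam_name, params = family$untrans(opt$par),
                 loglik = -opt$value + jac, n = length(x),
                 converged = TRUE, message = "ok"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$family,
      if (x$converged) paste0("logLik = ", format(x$loglik),
                              " (", paste(names(x$params), "=",
                                          signif(unlist(x$params), 4),
                                          collapse = ", "), ")")
      else paste("FAILED:", x$message), "\n")
  invisible(x)
}

#' Select the best-fitting family by maximum likelihood
#'
#' Fits every candidate family and returns the converged fit with maximal
#' attained log-likelihood (no parameter-count penalty: selection is by the
#' raw maximum-likelihood criterion). The full ranked table is attached as
#' attribute `"table"`.
#'
#' @param samples numeric NFC samples
#' @param families candidate set, default [nfc_families()]
#' @param min_n minimum sample size per fit
#' @param label identifier used in error messages (e.g. the codon)
#' @return the winning `fit_result`
#' @export
best_fit <- function(samples, families = nfc_families(), min_n = 30,
                     label = "sample") {
  fits <- lapply(names(families), function(nm)
    fit_family(samples, families[[nm]], min_n = min_n))
  names(fits) <- names(families)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$loglik),
               logical(1))
  if (!any(ok)) stop("all family fits failed for ", label)
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  winner <- fits[[which.max(ifelse(ok, ll, -Inf))]]
  tab <- data.frame(family = names(families), loglik = ll, converged = ok,
                    selected = names(families) ==
                      names(which.max(ifelse(ok, ll, -Inf))))
  tab <- tab[order(-tab$loglik), ]
  attr(winner, "table") <- tab
  winner
}

#' Closed-form features of a log-normal distribution
#'
#' For parameters (mu, sigma): mean `exp(mu + sigma^2/2)`, median `exp(mu)`,
#' and skewness `(exp(sigma^2) + 2) * sqrt(exp(sigma^2) - 1)`.
#'
#' @param mu log-scale location
#' @param sigma log-scale standard deviation, `sigma >= 0`
#' @return named vector `ln_mean`, `ln_median`, `ln_skewness`
#' @export
lognormal_features <- function(mu, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  e <- exp(sigma^2)
  c(ln_mean = exp(mu + sigma^2 / 2),
    ln_median = exp(mu),
    ln_skewness = (e + 2) * sqrt(e - 1))
}

#' Empirical features of an NFC sample
#'
#' Mean and median of the samples, and the mode estimated as the midpoint of
#' the tallest histogram bin (fixed bins of `bin_width` on `[0, upper]`; ties
#' resolved to the lowest-value bin and logged).
#'
#' @inheritParams nfc_histogram
#' @return named vector `mean`, `median`, `mode`
#' @export
empirical_features <- function(samples, bin_width = 0.05, upper = 5.0) {
  h <- nfc_histogram(samples, bin_width = bin_width, upper = upper)
  top <- which(h$prob == max(h$prob))
  if (length(top) > 1L)
    ribo_log("mode tie between ", length(top), " bins, lowest taken")
  c(mean = mean(samples), median = median(samples), mode = h$mids[top[1]])
}

#' Full feature set of one codon's NFC sample
#'
#' Combines the empirical features (mean, median, histogram mode) with the
#' log-normal-fit features (fitted mean, median and skewness). The log-normal
#' parameters come from the closed-form MLE on the positive samples.
#'
#' @inheritParams empirical_features
#' @param min_n minimum samples for the log-normal fit
#' @return named vector: mean, median, mode, ln_mean, ln_median, ln_skewness,
#'   mu, sigma (NA for the fitted block if the fit fails)
#' @export
nfc_features <- function(samples, bin_width = 0.05, upper = 5.0, min_n = 30) {
  emp <- empirical_features(samples, bin_width, upper)
  fit <- fit_family(samples, "lognormal", min_n = min_n)
  if (fit$converged) {
    lf <- lognormal_features(fit$params[["mu"]], fit$params[["sigma"]])
    c(emp, lf, mu = fit$params[["mu"]], sigma = fit$params[["sigma"]])
  } else {
    c(emp, ln_mean = NA_real_, ln_median = NA_real_, ln_skewness = NA_real_,
      mu = NA_real_, sigma = NA_real_)
  }
}

#' Per-codon feature table of a sample set
#'
#' @param samples a `codon_sample_set`
#' @inheritParams nfc_features
#' @return data.frame with one row per present codon and the columns of
#'   [nfc_features()] plus `codon` and `n`
#' @export
feature_table <- function(samples, bin_width = 0.05, upper = 5.0, min_n = 30) {
  present <- present_codons(samples)
  rows <- lapply(present, function(cc) {
    f <- nfc_features(samples[[cc]], bin_width, upper, min_n)
    data.frame(codon = cc, n = length(samples[[cc]]), t(f))
  })
  do.call(rbind, rows)
}

#' Per-codon best-fit table of a sample set
#'
#' Runs [best_fit()] on every present codon with at least `min_n` samples.
#'
#' @param samples a `codon_sample_set`
#' @param families candidate families
#' @param min_n minimum samples per codon
#' @return data.frame: codon, n, selected family, its parameters
#'   (JSON-encoded), log-likelihood
#' @export
best_fit_table <- function(samples, families = nfc_families(), min_n = 30) {
  present <- present_codons(samples)
  present <- present[vapply(samples[present], length, integer(1)) >= min_n]
  rows <- lapply(present, function(cc) {
    bf <- best_fit(samples[[cc]], families, min_n = min_n, label = cc)
    data.frame(codon = cc, n = bf$n, family = bf$family,
               params = as.character(
                 jsonlite::toJSON(as.list(bf$params), auto_unbox = TRUE,
                                  digits = NA)),
               loglik = bf$loglik)
  })
  do.call(rbind, rows)
}
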