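## trna: tAI relative-adaptiveness weights and feature/proxy correlations.

#' Default wobble selective constraints (s-values) for tAI
#'
#' The optimized constraint set of the tRNA adaptation index method
#' (dos Reis et al. 2004): 0 for the four Watson-Crick pairings, then
#' `G:U` 0.41, `I:C` 0.28, `I:A` 0.9999 and `U:G` 0.68 for the wobble
#' pairings (codon third base : anticodon wobble base, inosine written I).
#'
#' @return named numeric vector of s-values
#' @export
tai_s_values <- function() {
  c(WC_T = 0, WC_C = 0, WC_A = 0, WC_G = 0,
    GU = 0.41, IC = 0.28, IA = 0.9999, UG = 0.68)
}

#' tAI relative adaptiveness weights from tRNA copy numbers
#'
#' For each sense codon the absolute adaptiveness is
#' `W = (1 - s_WC) * copies(cognate) + (1 - s_wobble) * copies(wobble donor)`
#' where the wobble donor is the codon read by the same anticodon through
#' the non-Watson-Crick pairing: codons ending T gain from the anticodon
#' cognate to the C-ending codon of the box (G:U), C-enders from the T-ender
#' (inosine I:C), A-enders from the T-ender (I:A), and G-enders from the
#' A-ender (U:G). Copy numbers are keyed by codon (copies of the tRNA whose
#' anticodon is the codon's Watson-Crick partner); a wobble donor that is a
#' stop codon contributes 0. Relative weights are `w = W / max(W)`, with
#' zero weights replaced by the geometric mean of the nonzero weights.
#'
#' @param trna a [trna_table()] (or named codon -> copies vector)
#' @param s_values wobble constraints, see [tai_s_values()]
#' @return named numeric vector of weights in (0, 1], class `tai_weights`,
#'   with attribute `s_values`
#' @export
compute_tai_weights <- function(trna, s_values = tai_s_values()) {
  if (!inherits(trna, "trna_table")) trna <- trna_table(trna)
  if (all(trna == 0)) stop("all-zero tRNA table")
  copies <- function(codon) {
    ifelse(codon %in% names(trna), unname(trna[codon]), 0)
  }
  sc <- sense_codons()
  third <- substr(sc, 3, 3)
  box <- substr(sc, 1, 2)
  donor_third <- c(T = "C", C = "T", A = "T", G = "A")[third]
  donor <- paste0(box, donor_third)
  s_wc <- c(T = s_values[["WC_T"]], C = s_values[["WC_C"]],
            A = s_values[["WC_A"]], G = s_values[["WC_G"]])[third]
  s_wob <- c(T = s_values[["GU"]], C = s_values[["IC"]],
             A = s_values[["IA"]], G = s_values[["UG"]])[third]
  W <- (1 - s_wc) * copies(sc) + (1 - s_wob) * copies(donor)
  names(W) <- sc
  w <- W / max(W)
  zero <- w == 0
  if (any(zero)) {
    gm <- exp(mean(log(w[!zero])))
    w[zero] <- gm
    ribo_log(sum(zero), " zero tAI weight(s) replaced by the geometric mean")
  }
  structure(w, s_values = s_values, class = "tai_weights")
}

#' Spearman correlation of per-codon NFC features with a tRNA-level proxy
#'
#' @param features named numeric vector codon -> feature value (e.g. one
#'   column of [feature_table()]), or a `feature_table` data.frame plus
#'   `feature_name`
#' @param proxy named numeric vector codon -> proxy (tRNA copies or tAI
#'   weight)
#' @param feature_name column to use when `features` is a data.frame
#' @return list: `r` (Spearman), `p` (two-sided), `n` (codons used),
#'   `feature`
#' @export
correlate_features <- function(features, proxy, feature_name = NULL) {
  if (is.data.frame(features)) {
    if (is.null(feature_name)) stop("feature_name required for a table")
    features <- setNames(features[[feature_name]], features$codon)
  }
  shared <- intersect(names(features)[!is.na(features)],
                      names(proxy)[!is.na(proxy)])
  dropped <- length(union(names(features), names(proxy))) - length(shared)
  if (dropped > 0)
    ribo_log("correlate_features: ", dropped,
             " codon(s) missing a value dropped")
  if (length(shared) < 10) stop("fewer than 10 codons with both values")
  x <- features[shared]; y <- proxy[shared]
  if (sd(y) == 0 || sd(x) == 0) {
    ribo_log("correlate_features: constant input, correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(shared),
                feature = feature_name))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
       feature = feature_name)
}

#' Correlate every NFC feature with a proxy
#'
#' @param ftab a [feature_table()] data.frame
#' @param proxy named codon -> proxy vector
#' @param features feature columns to use
#' @return data.frame: feature, spearman_r, p, n
#' @export
correlation_summary <- function(ftab, proxy,
                                features = c("mean", "median", "mode",
                                             "ln_mean", "ln_median",
                                             "ln_skewness")) {
  rows <- lapply(features, function(f) {
    r <- correlate_features(ftab, proxy, feature_name = f)
    data.frame(feature = f, spearman_r = r$r, p = r$p, n = r$n)
  })
  do.call(rbind, rows)
}
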