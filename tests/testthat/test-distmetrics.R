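test_that("hand-derived distance values are reproduced", {
  # two-bin histograms placed on the shared 0.05 grid:
  # masses at bins [0, 0.05) and [0.05, 0.10)
  h <- function(w) {
    x <- c(rep(0.02, round(w[1] * 100)), rep(0.07, round(w[2] * 100)))
    nfc_histogram(x)
  }
  # JS distance for p = (.5,.5), q = (.9,.1): sqrt(1/2 KL(p||m) + 1/2 KL(q||m))
  expect_equal(js_distance(h(c(.5, .5)), h(c(.9, .1))), 0.3831358799,
               tolerance = 1e-6)
  # Hellinger for p = (1,0), q = (.5,.5): sqrt(1 - sqrt(0.5))
  expect_equal(hellinger_distance(h(c(1, 0)), h(c(.5, .5))), 0.5411961001,
               tolerance = 1e-6)
  # Energy for x = {0}, y = {1}: sqrt(2*1 - 0 - 0)
  expect_equal(energy_distance(0, 1), sqrt(2), tolerance = 1e-12)
})

test_that("identity, symmetry and non-negativity hold for all metrics", {
  withr::with_seed(27, {
    for (i in 1:200) {
      pr <- random_hist_pair(n = 100)
      expect_equal(js_distance(pr$p, pr$p), 0)
      expect_equal(hellinger_distance(pr$p, pr$p), 0)
      expect_equal(energy_distance(pr$x, pr$x), 0, tolerance = 1e-7)
      d <- c(js_distance(pr$p, pr$q), hellinger_distance(pr$p, pr$q),
             energy_distance(pr$x, pr$y))
      dr <- c(js_distance(pr$q, pr$p), hellinger_distance(pr$q, pr$p),
              energy_distance(pr$y, pr$x))
      expect_equal(d, dr, tolerance = 1e-12)
      expect_true(all(d >= 0))
      expect_true(all(d[1:2] <= 1))
    }
  })
})

test_that("disjoint supports give distance 1 for JS and Hellinger", {
  p <- nfc_histogram(runif(100, 0, 0.5))
  q <- nfc_histogram(runif(100, 2, 2.5))
  expect_equal(js_distance(p, q), 1, tolerance = 1e-12)
  expect_equal(hellinger_distance(p, q), 1, tolerance = 1e-12)
  expect_error(js_distance(p, nfc_histogram(1, upper = 4)), "identical bin")
})

test_that("energy distance matches the brute-force pairwise oracle and
           scales as sqrt of a common rescaling", {
  brute <- function(x, y) {
    exy <- mean(abs(outer(x, y, "-")))
    exx <- mean(abs(outer(x, x, "-")))
    eyy <- mean(abs(outer(y, y, "-")))
    sqrt(max(2 * exy - exx - eyy, 0))
  }
  withr::with_seed(31, {
    for (i in 1:25) {
      x <- rlnorm(10, 0, 1); y <- rlnorm(10, 0.5, 0.7)
      expect_equal(energy_distance(x, y), brute(x, y), tolerance = 1e-10)
      a <- runif(1, 0.5, 4)
      expect_equal(energy_distance(a * x, a * y),
                   sqrt(a) * energy_distance(x, y), tolerance = 1e-10)
    }
    # identical multisets in different order
    x <- rlnorm(50); expect_equal(energy_distance(x, sample(x)), 0,
                                  tolerance = 1e-8)
  })
  expect_error(energy_distance(numeric(0), 1), "empty")
})

test_that("binned JS/Hellinger rank-agree with a dense-grid analytic
           oracle", {
  # oracle: distances between the TRUE log-normal laws discretized on a
  # 0.001 grid, written out directly from the definitions
  grid <- c(seq(0, 5, by = 0.001), Inf)
  oracle <- function(mu1, s1, mu2, s2) {
    p <- diff(plnorm(grid, mu1, s1)); p <- p / sum(p)
    q <- diff(plnorm(grid, mu2, s2)); q <- q / sum(q)
    m <- (p + q) / 2
    kl <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
    c(js = sqrt((kl(p) + kl(q)) / 2), he = sqrt(1 - sum(sqrt(p * q))))
  }
  withr::with_seed(41, {
    n <- 60
    pkg_js <- pkg_he <- ora_js <- ora_he <- numeric(n)
    for (i in 1:n) {
      mu1 <- runif(1, -0.4, 0.4); mu2 <- runif(1, -0.4, 0.4)
      s1 <- runif(1, 0.25, 0.8); s2 <- runif(1, 0.25, 0.8)
      x <- rlnorm(4000, mu1, s1); y <- rlnorm(4000, mu2, s2)
      pkg_js[i] <- sample_distance(x, y, "js")
      pkg_he[i] <- sample_distance(x, y, "hellinger")
      o <- oracle(mu1, s1, mu2, s2)
      ora_js[i] <- o[["js"]]; ora_he[i] <- o[["he"]]
    }
    expect_gt(cor(pkg_js, ora_js, method = "spearman"), 0.99)
    expect_gt(cor(pkg_he, ora_he, method = "spearman"), 0.99)
  })
})

test_that("binned-then-resampled energy converges to the sample value", {
  withr::with_seed(43, {
    x <- rlnorm(4000, 0, 0.5); y <- rlnorm(4000, 0.3, 0.5)
    truth <- energy_distance(x, y)
    err <- vapply(c(0.4, 0.1, 0.025), function(bw) {
      resample <- function(z) {
        h <- nfc_histogram(z, bin_width = bw)
        rep(h$mids, round(h$prob * length(z)))
      }
      abs(energy_distance(resample(x), resample(y)) - truth)
    }, numeric(1))
    expect_true(all(diff(err) <= 1e-3 + 0))  # error shrinks with bin width
    expect_lt(err[3], 0.02)
  })
})

test_that("a planted distinct codon is detected under all three metrics", {
  profs <- make_lognormal_profiles(
    n_genes = 40, gene_length = 150,
    params = list(GCT = c(0.45, 0.3)), default = c(0, 0.3), seed = 51)
  for (m in c("hellinger", "js", "energy")) {
    r <- distinctness_test(profs, "GCT", metric = m, n_partitions = 40,
                           seed = 52)
    expect_lt(r$p, 0.01)
    expect_true(r$distinct)
  }
})

test_that("an unremarkable codon is not declared distinct under the null", {
  profs <- make_lognormal_profiles(n_genes = 40, gene_length = 150,
                                   default = c(0, 0.3), seed = 53)
  r <- distinctness_test(profs, "GCT", metric = "hellinger",
                         n_partitions = 40, seed = 54)
  expect_gt(r$p, 0.05)
})

test_that("restriction sets follow the genetic code", {
  expect_setequal(synonymous_codons("GCT"), c("GCC", "GCA", "GCG"))
  expect_length(synonymous_codons("ATG"), 0)
  expect_setequal(same_composition_codons("GCT"),
                  setdiff(c("GTC", "CGT", "CTG", "TGC", "TCG"), NA))

  profs <- make_lognormal_profiles(n_genes = 30, gene_length = 120, seed = 55)
  r <- suppressMessages(
    distinctness_test(profs, "ATG", metric = "hellinger",
                      n_partitions = 5, restrict = "synonymous", seed = 1))
  expect_true(is.na(r$p))  # defined-empty comparison set

  r2 <- distinctness_test(profs, "GCT", metric = "hellinger",
                          n_partitions = 5, restrict = "same_composition",
                          seed = 2)
  expect_setequal(colnames(r2$cross_distances),
                  same_composition_codons("GCT"))
})
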