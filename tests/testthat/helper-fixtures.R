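# Fixtures built in code; no data files.

# gene profiles with i.i.d. log-normal NFC per codon type: params is a
# named list codon -> c(mu, sigma); codons not listed use `default`
make_lognormal_profiles <- function(n_genes = 40, gene_length = 120,
                                    params = list(),
                                    default = c(0, 0.4), seed = 1) {
  sc <- sense_codons()
  withr::with_seed(seed, {
    lapply(seq_len(n_genes), function(i) {
      codons <- sample(sc, gene_length, replace = TRUE)
      mu <- rep(default[1], gene_length)
      sg <- rep(default[2], gene_length)
      for (cc in names(params)) {
        hit <- codons == cc
        mu[hit] <- params[[cc]][1]
        sg[hit] <- params[[cc]][2]
      }
      raw <- stats::rlnorm(gene_length, mu, sg)
      structure(list(gene_id = sprintf("fix_g%03d", i), codons = codons,
                     rc = raw, nfc = raw / mean(raw),
                     included = rep(TRUE, gene_length)),
                class = "nfc_profile")
    })
  })
}

# a small deterministic gene_profile
toy_profile <- function(id = "g1",
                        codons = c("ATG", "GCT", "AAA", "GCT", "TAA"),
                        rc = c(3, 2, 4, 6, 1)) {
  gene_profile(id, codons, rc)
}

# write a FASTA string to a temp file
write_fasta_tmp <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# random histogram pair on shared bins
random_hist_pair <- function(n = 200, upper = 5, bin_width = 0.05) {
  x <- stats::rlnorm(n, stats::runif(1, -0.5, 0.5), stats::runif(1, 0.2, 0.8))
  y <- stats::rlnorm(n, stats::runif(1, -0.5, 0.5), stats::runif(1, 0.2, 0.8))
  list(p = nfc_histogram(x, bin_width, upper),
       q = nfc_histogram(y, bin_width, upper), x = x, y = y)
}

# a small TASEP dataset shared by tests in a file (cheap regime)
small_tasep <- function(seed = 11, n_genes = 20, gene_length = 80,
                        ...) {
  generate_dataset(tasep_config(n_genes = n_genes, gene_length = gene_length,
                                horizon = 12000, burn_in = 1500,
                                seed = seed, ...))
}
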