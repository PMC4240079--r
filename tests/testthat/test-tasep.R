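test_that("simulation is reproducible per seed", {
  a <- small_tasep(seed = 11)
  b <- small_tasep(seed = 11)
  expect_identical(lapply(a$profiles, `[[`, "rc"),
                   lapply(b$profiles, `[[`, "rc"))
  expect_identical(a$codon_times, b$codon_times)
  c2 <- small_tasep(seed = 12)
  expect_false(identical(lapply(a$profiles, `[[`, "rc"),
                         lapply(c2$profiles, `[[`, "rc")))
})

test_that("all decoding times equal and low initiation give a flat
           expected density", {
  tt <- setNames(rep(3, 61), sense_codons())
  cfg <- tasep_config(n_genes = 1, gene_length = 60, codon_times = tt,
                      initiation_rate = 0.003, mrna_copies = 1,
                      horizon = 150000, burn_in = 2000)
  withr::with_seed(21, {
    rc <- Reduce(`+`, lapply(1:40, function(i)
      simulate_gene(cfg, sample(sense_codons(), 60, TRUE))$rc))
  })
  # no trend along the lattice (drop edges where entry/exit effects live)
  inner <- 11:50
  fit <- lm(rc[inner] ~ inner)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(coef(fit)[2]), 3 * se + 1e-9)
})

test_that("at low initiation NFC approaches T_j / mean(T)", {
  withr::with_seed(22, tt <- setNames(10^runif(61, 0, 1), sense_codons()))
  cfg <- tasep_config(n_genes = 25, gene_length = 120, codon_times = tt,
                      initiation_rate = 0.001, mrna_copies = 1,
                      pause_prob = 0, horizon = 100000, burn_in = 2000,
                      seed = 23)
  res <- generate_dataset(cfg)
  nfc <- compute_nfc_profiles(res$profiles, exclude_terminal = 10)
  s <- pool_by_codon(nfc)
  est <- vapply(s, median, numeric(1))
  # single-ribosome oracle: expected NFC is T_j over the gene mean dwell;
  # across random genes the mean dwell concentrates at mean(T)
  expected <- tt[names(est)] / mean(tt)
  expect_gt(cor(est, expected, method = "spearman"), 0.99)
  expect_lt(median(abs(est - expected) / expected), 0.15)
})

test_that("doubling mRNA copies doubles expected RC and leaves NFC alone", {
  withr::with_seed(24, tt <- setNames(10^runif(61, 0, 1), sense_codons()))
  codons <- withr::with_seed(25, sample(sense_codons(), 100, TRUE))
  cfg1 <- tasep_config(n_genes = 1, gene_length = 100, codon_times = tt,
                       initiation_rate = 0.004, mrna_copies = 1,
                       horizon = 80000, burn_in = 2000)
  cfg2 <- cfg1; cfg2$mrna_copies <- 2
  withr::with_seed(26, r1 <- simulate_gene(cfg1, codons))
  withr::with_seed(27, r2 <- simulate_gene(cfg2, codons))
  expect_equal(sum(r2$rc) / sum(r1$rc), 2, tolerance = 0.15)
  n1 <- compute_nfc(gene_profile("a", codons, r1$rc), exclude_terminal = 10)
  n2 <- compute_nfc(gene_profile("b", codons, r2$rc), exclude_terminal = 10)
  expect_gt(cor(n1$nfc[n1$included], n2$nfc[n2$included]), 0.95)
})

test_that("snapshot mode produces count-valued RC consistent with
           occupancy", {
  withr::with_seed(28, tt <- setNames(10^runif(61, 0, 1), sense_codons()))
  codons <- withr::with_seed(29, sample(sense_codons(), 80, TRUE))
  cfg <- tasep_config(n_genes = 1, gene_length = 80, codon_times = tt,
                      initiation_rate = 0.01, mrna_copies = 1,
                      horizon = 60000, burn_in = 2000,
                      rc_mode = "snapshot", snapshots = 400)
  withr::with_seed(30, snap <- simulate_gene(cfg, codons))
  expect_true(all(snap$rc == floor(snap$rc)))
  cfg$rc_mode <- "occupancy"
  withr::with_seed(30, occ <- simulate_gene(cfg, codons))
  expect_gt(cor(snap$rc, occ$rc), 0.9)
})

test_that("degenerate configurations abort with diagnostics", {
  tt <- setNames(rep(1, 61), sense_codons())
  cfg <- tasep_config(n_genes = 1, gene_length = 50, codon_times = tt,
                      initiation_rate = 0.001, mrna_copies = 1,
                      horizon = 20, burn_in = 1)
  expect_error(withr::with_seed(1, simulate_gene(cfg, rep("GCT", 50))),
               "horizon too short")
  expect_error(simulate_gene(cfg, rep("GCT", 5)), "footprint")
  expect_error(tasep_config(horizon = 10, burn_in = 20))
  expect_error(tasep_config(pause_prob = 1.5))
  rng <- tasep_config(codon_times = setNames(rep(1, 61), sense_codons()))
  expect_error(simulate_gene(rng, rep("GCT", 50)), "scalar")
})

test_that("jammed regime degrades decoding-time rank signal of mean-based
           features relative to robust ones", {
  res <- generate_dataset(tasep_config(n_genes = 50, gene_length = 200,
                                       horizon = 20000, burn_in = 2500,
                                       seed = 31))
  nfc <- compute_nfc_profiles(res$profiles)
  s <- pool_by_codon(nfc)
  ft <- suppressMessages(feature_table(s))
  tt <- res$codon_times[ft$codon]
  r <- function(f) cor(ft[[f]], tt, method = "spearman")
  expect_gt(r("mode"), 0.9)
  expect_gt(r("ln_median"), 0.9)
  expect_lt(r("ln_skewness"), 0)  # faster codons are more jam-skewed
})

test_that("parametric generator reproduces its parameters", {
  s <- parametric_nfc_generator(list(GCT = list(mu = 0.2, sigma = 0.01)),
                                n_per_codon = 200, seed = 32)
  expect_equal(median(s$GCT), exp(0.2), tolerance = 0.01)
  s2 <- parametric_nfc_generator(list(GCT = list(mu = 0.2, sigma = 0.01)),
                                 n_per_codon = 200, seed = 32)
  expect_identical(s, s2)

  big <- parametric_nfc_generator(list(AAA = list(mu = -0.3, sigma = 0.5)),
                                  n_per_codon = 10000, seed = 33)
  fit <- fit_family(big$AAA, "lognormal")
  expect_lt(abs(fit$params[["mu"]] + 0.3), 0.03)
  expect_lt(abs(fit$params[["sigma"]] - 0.5), 0.03)

  # two codons with equal parameters are not distinct
  profs <- make_lognormal_profiles(n_genes = 30, gene_length = 120,
                                   seed = 34)
  r <- distinctness_test(profs, "AAA", metric = "js", n_partitions = 30,
                         seed = 35)
  expect_gt(r$p, 0.05)
  expect_error(parametric_nfc_generator(list(GCT = list(mu = 0, sigma = 1)),
                                        n_per_codon = 0), ">= 1")
})

test_that("positional shift generator plants recoverable boundaries", {
  null <- positional_shift_generator(delta_mu = 0, n_genes = 200,
                                     gene_length = 220, seed = 36)
  ws <- window_sample_sets(null, end = "5p", span = 120, window = 40)
  b <- detect_boundary(mean_distance_vector(ws, "hellinger"))
  expect_lte(b$boundary, 10)

  # a 76-codon block is longer than the 50-codon window, so the scan reads
  # the decay's bulk crossing and underestimates the length; the planted
  # region is still clearly separated from the null (boundary ~1)
  planted <- positional_shift_generator(shift_length = 76, delta_mu = 0.3,
                                        n_genes = 400, gene_length = 300,
                                        seed = 37)
  wsp <- window_sample_sets(planted, end = "5p", span = 180, window = 50)
  bp <- detect_boundary(mean_distance_vector(wsp, "hellinger"))
  expect_true(bp$boundary >= 25 && bp$boundary <= 86)
})

test_that("datasets round-trip through the profile TSV dialect", {
  res <- small_tasep(seed = 38, n_genes = 5, gene_length = 60)
  dir <- tempfile()
  write_tasep_dataset(res, dir)
  orfs <- read_orfs(file.path(dir, "orfs.fasta"))
  profs <- read_rc_profiles(file.path(dir, "profiles.tsv"), orfs)
  expect_length(profs, 5)
  g <- res$profiles[[1]]$gene_id
  expect_equal(profs[[g]]$rc, res$profiles[[1]]$rc, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(names(truth$codon_times)), sort(sense_codons()))
})
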