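## tasep: continuous-time TASEP translation simulator and the parametric
## synthetic-NFC generators used as unit-level fixtures.

#' TASEP simulator configuration
#'
#' Parameterizes the continuous-time (Gillespie) TASEP translation model:
#' ribosomes with a footprint of `ribosome_size` codons hop codon-by-codon
#' with exponential dwell of mean `codon_times[codon]`, blocked while the
#' next footprint position is occupied (traffic jams); initiation occurs at
#' rate `initiation_rate` per mRNA copy while the first `ribosome_size`
#' codons are free; each decoding step is independently a translational
#' pause (dwell multiplied by `pause_factor`) with probability `pause_prob`.
#' RC is the time-integrated P-site occupancy after `burn_in`, times
#' `coverage_scale` (or, in snapshot mode, ribosome counts over `snapshots`
#' evenly spaced instants, emulating the snapshot nature of a sequencing
#' experiment).
#'
#' Defaults define the package's reference simulation: 150 genes of 300
#' uniformly random sense codons, per-codon mean decoding times drawn
#' log-uniformly over one order of magnitude (1 to 10 time units), moderate
#' gene-specific initiation (log-uniform between 0.002 and 0.05 events per
#' time unit, spanning free flow up to several times the slow-codon carrying
#' capacity of about 0.006, so a fraction of genes develop traffic jams),
#' 1 to 4 mRNA copies per gene (coverage proportional to copies times
#' initiation rate, as in real libraries), and pauses at 1% with a 10x
#' dwell factor.
#'
#' @param n_genes number of genes to simulate
#' @param gene_length codons per gene
#' @param codon_times named vector codon -> mean decoding time; `NULL` draws
#'   log-uniform on `[1, 10]` for the 61 sense codons (seeded)
#' @param initiation_rate initiation events per time unit per mRNA copy: a
#'   single rate for all genes, or a length-2 range from which each gene's
#'   rate is drawn log-uniformly
#' @param mrna_copies mRNA copies per gene (independent lattices, RC
#'   summed): a single count or a length-2 integer range sampled uniformly
#'   per gene
#' @param ribosome_size footprint length in codons
#' @param pause_prob per-decoding-event pause probability
#' @param pause_factor dwell multiplier while paused
#' @param horizon simulated time per lattice
#' @param burn_in initial time discarded from RC accumulation
#' @param coverage_scale multiplier from occupancy time to RC units
#' @param rc_mode `"occupancy"` (time-integrated, default) or `"snapshot"`
#' @param snapshots number of snapshots when `rc_mode = "snapshot"`
#' @param seed RNG seed for the whole dataset
#' @return a `tasep_config` list
#' @export
tasep_config <- function(n_genes = 150, gene_length = 300, codon_times = NULL,
                         initiation_rate = c(0.002, 0.05),
                         mrna_copies = c(1, 4),
                         ribosome_size = 10, pause_prob = 0.01,
                         pause_factor = 10, horizon = 30000, burn_in = 3000,
                         coverage_scale = 1, rc_mode = c("occupancy",
                                                         "snapshot"),
                         snapshots = 200, seed = NULL) {
  rc_mode <- match.arg(rc_mode)
  stopifnot(n_genes >= 1, gene_length > ribosome_size,
            length(initiation_rate) %in% 1:2, all(initiation_rate > 0),
            length(mrna_copies) %in% 1:2, all(mrna_copies >= 1),
            ribosome_size >= 1,
            pause_prob >= 0, pause_prob <= 1, pause_factor > 0,
            horizon > burn_in, burn_in >= 0, coverage_scale > 0)
  if (!is.null(codon_times)) {
    if (is.null(names(codon_times)) ||
        !all(names(codon_times) %in% sense_codons()))
      stop("codon_times must be named by sense codons")
    if (any(codon_times <= 0)) stop("codon_times must be > 0")
  }
  structure(list(n_genes = n_genes, gene_length = gene_length,
                 codon_times = codon_times,
                 initiation_rate = initiation_rate,
                 mrna_copies = mrna_copies, ribosome_size = ribosome_size,
                 pause_prob = pause_prob, pause_factor = pause_factor,
                 horizon = horizon, burn_in = burn_in,
                 coverage_scale = coverage_scale, rc_mode = rc_mode,
                 snapshots = snapshots, seed = seed),
            class = "tasep_config")
}

## draw the default per-codon decoding times: log-uniform over [1, 10]
draw_codon_times <- function(seed = NULL) {
  sc <- sense_codons()
  with_seed_or_current(seed, setNames(10^runif(length(sc), 0, 1), sc))
}

#' Simulate one gene under the TASEP model
#'
#' @param config a [tasep_config()] (its `codon_times` must be set)
#' @param codon_sequence character vector of codons (length >
#'   `ribosome_size`)
#' @return list: `rc` (numeric, per codon), `completions` (terminated
#'   ribosomes summed over mRNA copies), `density` (mean ribosome count per
#'   codon per copy)
#' @export
simulate_gene <- function(config, codon_sequence) {
  stopifnot(inherits(config, "tasep_config"))
  if (is.null(config$codon_times))
    stop("config$codon_times must be set (see generate_dataset)")
  if (length(config$initiation_rate) != 1 || length(config$mrna_copies) != 1)
    stop("per-gene ranges are resolved by generate_dataset; ",
         "simulate_gene needs scalar initiation_rate and mrna_copies")
  codon_sequence <- toupper(codon_sequence)
  J <- length(codon_sequence)
  if (J <= config$ribosome_size)
    stop("sequence must be longer than the ribosome footprint")
  dwell <- unname(config$codon_times[codon_sequence])
  if (anyNA(dwell)) stop("sequence contains codons without a decoding time")
  occ <- numeric(J)
  snap <- numeric(J)
  completions <- 0
  for (m in seq_len(config$mrna_copies)) {
    r <- tasep_gene_cpp(dwell, config$initiation_rate, config$ribosome_size,
                        config$pause_prob, config$pause_factor,
                        config$horizon, config$burn_in,
                        if (config$rc_mode == "snapshot") config$snapshots
                        else 0L)
    occ <- occ + r$occupancy
    snap <- snap + r$snapshot
    completions <- completions + r$completions
  }
  if (completions == 0)
    stop("horizon too short: no ribosome completed elongation ",
         "(initiation_rate = ", config$initiation_rate,
         ", horizon = ", config$horizon, ")")
  rc <- if (config$rc_mode == "snapshot") as.numeric(snap)
        else occ * config$coverage_scale
  list(rc = rc, completions = completions,
       density = sum(occ) / (config$horizon - config$burn_in) /
         config$mrna_copies / J)
}

#' Generate a synthetic ribosome-profiling dataset by TASEP simulation
#'
#' Draws `n_genes` random coding sequences (uniform over the 61 sense codons
#' unless `composition` gives sampling weights), assigns per-codon mean
#' decoding times (log-uniform over one order of magnitude unless supplied),
#' and simulates each gene. The true decoding times travel with the result,
#' so feature estimates can be validated against them.
#'
#' @param config a [tasep_config()]
#' @return a `tasep_result`: `profiles` (list of [gene_profile()]),
#'   `codon_times` (the truth), `config`
#' @export
generate_dataset <- function(config = tasep_config()) {
  stopifnot(inherits(config, "tasep_config"))
  with_seed_or_current(config$seed, {
    if (is.null(config$codon_times))
      config$codon_times <- draw_codon_times(seed = NULL)
    sc <- sense_codons()
    br <- range(config$initiation_rate)
    mr <- range(config$mrna_copies)
    profiles <- lapply(seq_len(config$n_genes), function(i) {
      gcfg <- config
      gcfg$initiation_rate <- 10^runif(1, log10(br[1]), log10(br[2]))
      gcfg$mrna_copies <- sample(seq(mr[1], mr[2]), 1)
      codons <- sample(sc, config$gene_length, replace = TRUE)
      sim <- simulate_gene(gcfg, codons)
      gene_profile(sprintf("sim_g%04d", i), codons, sim$rc)
    })
    structure(list(profiles = profiles, codon_times = config$codon_times,
                   config = config),
              class = "tasep_result")
  })
}

#' @export
print.tasep_result <- function(x, ...) {
  cat("<tasep_result>", length(x$profiles), "genes x",
      x$config$gene_length, "codons, B =",
      paste(x$config$initiation_rate, collapse = ".."),
      ", pauses", x$config$pause_prob, "x", x$config$pause_factor, "\n")
  invisible(x)
}

#' Write a TASEP dataset to disk
#'
#' Emits the profile TSV dialect, a FASTA of the simulated ORFs, and a JSON
#' truth file (codon -> decoding time plus the configuration).
#'
#' @param result a `tasep_result`
#' @param dir output directory (created if needed)
#' @export
write_tasep_dataset <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(result$profiles, file.path(dir, "profiles.tsv"))
  orfs <- setNames(lapply(result$profiles, `[[`, "codons"),
                   vapply(result$profiles, `[[`, "", "gene_id"))
  write_orfs(orfs, file.path(dir, "orfs.fasta"))
  cfg <- result$config
  cfg$codon_times <- NULL
  jsonlite::write_json(list(codon_times = as.list(result$codon_times),
                            config = unclass(cfg)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Draw log-normal NFC samples per codon
#'
#' A direct parametric generator for unit-level fixtures: each codon's NFC
#' samples are i.i.d. log-normal with its own (mu, sigma).
#'
#' @param params named list or 2-column matrix (rownames = codons), giving
#'   `mu` and `sigma` per codon
#' @param n_per_codon samples per codon (>= 1)
#' @param seed RNG seed
#' @return a `codon_sample_set`
#' @export
parametric_nfc_generator <- function(params, n_per_codon, seed = NULL) {
  if (n_per_codon < 1) stop("n_per_codon must be >= 1")
  if (is.matrix(params) || is.data.frame(params)) {
    params <- setNames(
      lapply(seq_len(nrow(params)),
             function(i) list(mu = params[i, 1], sigma = params[i, 2])),
      rownames(params))
  }
  if (any(vapply(params, function(p) p$sigma <= 0, logical(1))))
    stop("sigma must be > 0")
  with_seed_or_current(seed, {
    samples <- lapply(params, function(p)
      rlnorm(n_per_codon, p$mu, p$sigma))
    codon_sample_set(samples)
  })
}

#' Synthetic profiles with a positionally shifted NFC distribution
#'
#' Generates gene profiles whose NFC values are log-normal(mu, sigma)
#' everywhere except in a region of `shift_length` codons at the chosen end,
#' where they are log-normal(mu + delta_mu, sigma). Each gene is then
#' renormalized to mean NFC 1 over its codons, emulating the positionally
#' shifted distributions near ORF ends; codon identities are uniform random
#' sense codons. All positions are marked included.
#'
#' @param mu,sigma baseline log-normal parameters
#' @param shift_length region length K at the end (< `gene_length / 2`)
#' @param delta_mu log-scale shift inside the region
#' @param n_genes,gene_length dataset shape
#' @param end `"5p"` or `"3p"`
#' @param seed RNG seed
#' @return list of `nfc_profile` objects (raw `rc` set equal to the
#'   pre-normalization values so mean-RC scans can run on them)
#' @export
positional_shift_generator <- function(mu = 0, sigma = 0.4, shift_length = 76,
                                       delta_mu = 0.3, n_genes = 100,
                                       gene_length = 300,
                                       end = c("5p", "3p"), seed = NULL) {
  end <- match.arg(end)
  if (shift_length >= gene_length / 2)
    stop("shift_length must be < gene_length / 2")
  sc <- sense_codons()
  with_seed_or_current(seed, {
    lapply(seq_len(n_genes), function(i) {
      codons <- sample(sc, gene_length, replace = TRUE)
      mus <- rep(mu, gene_length)
      idx <- seq_len(shift_length)
      if (end == "3p") idx <- gene_length - idx + 1L
      mus[idx] <- mu + delta_mu
      raw <- rlnorm(gene_length, mus, sigma)
      structure(list(gene_id = sprintf("shift_g%04d", i), codons = codons,
                     rc = raw, nfc = raw / mean(raw),
                     included = rep(TRUE, gene_length)),
                class = "nfc_profile")
    })
  })
}
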