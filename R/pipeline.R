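## pipeline: config-driven end-to-end runs with manifests.

#' Read a run configuration from YAML
#'
#' Fields (all optional unless a stage needs them): `organism`, `domain`,
#' `seed`, `paths` (`orfs`, `profiles`, `trna`, `out_dir`), `region`
#' (`exclude_terminal`, `min_rc`, `inner_five`, `inner_three`), `metric`,
#' `positional` (`span`, `window`, `step`, `scan`, `alpha`, `equalize_rc`),
#' `distinctness` (`n_partitions`, `restrict`), `simulate` (any
#' [tasep_config()] field). Referenced input paths are checked at read time.
#'
#' @param path YAML file
#' @return a validated `run_config` list
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    organism = "organism", domain = "prokaryote", seed = 1L, metric = "hellinger",
    region = list(exclude_terminal = 20, min_rc = 1,
                  inner_five = 20, inner_three = 20),
    positional = list(span = 200, window = 50, step = 1, scan = 10,
                      alpha = 0.05, equalize_rc = FALSE),
    distinctness = list(n_partitions = 100, restrict = "all"))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      cfg[[k]] <- utils::modifyList(defaults[[k]], cfg[[k]])
  }
  for (p in intersect(names(cfg$paths), c("orfs", "profiles", "trna"))) {
    if (!file.exists(cfg$paths[[p]]))
      stop("config path '", p, "' does not exist: ", cfg$paths[[p]])
  }
  class(cfg) <- "run_config"
  cfg
}

## manifest written next to every output set
write_manifest <- function(cfg, dir, stage) {
  flat <- unclass(cfg)
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("ribodist")),
         config = flat,
         config_hash = sum(utf8ToInt(paste(deparse(flat), collapse = "")))),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
}

## load profiles and normalize per the config
load_nfc <- function(cfg) {
  orfs <- read_orfs(cfg$paths$orfs)
  profiles <- read_rc_profiles(cfg$paths$profiles, orfs)
  nfc <- compute_nfc_profiles(profiles,
                              exclude_terminal = cfg$region$exclude_terminal,
                              min_rc = cfg$region$min_rc)
  list(profiles = profiles, nfc = nfc)
}

#' Characterize codon NFC distributions from a config
#'
#' Chains profile reading, NFC normalization, per-codon pooling over the
#' configured inner region, best-family fitting and feature extraction.
#' Writes `features.tsv`, `best_fits.tsv` and a manifest to
#' `paths$out_dir`.
#'
#' @param cfg a `run_config` (or YAML path)
#' @return list: `features` (data.frame), `fits` (data.frame), `samples`
#' @export
run_characterize <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dat <- load_nfc(cfg)
  region <- region_offsets(cfg$region$inner_five, cfg$region$inner_three)
  samples <- pool_by_codon(dat$nfc, region = region,
                           organism = cfg$organism)
  ftab <- feature_table(samples)
  fits <- best_fit_table(samples)
  if (!is.null(cfg$paths$out_dir)) {
    dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(ftab, file.path(cfg$paths$out_dir, "features.tsv"),
                       sep = "\t")
    data.table::fwrite(fits, file.path(cfg$paths$out_dir, "best_fits.tsv"),
                       sep = "\t")
    write_manifest(cfg, cfg$paths$out_dir, "characterize")
  }
  list(features = ftab, fits = fits, samples = samples)
}

#' Positional boundary analysis from a config
#'
#' Runs the sliding-window pipeline at both ORF ends: window sample sets,
#' mean distance vector, Wilcoxon-scan boundary — plus the comparison scan
#' on the positional mean RC profile. Writes per-end TSV/JSON outputs when
#' `paths$out_dir` is set.
#'
#' @param cfg a `run_config` (or YAML path)
#' @return named list per end: `vector` (mean distance vector), `boundary`,
#'   `rc_boundary`
#' @export
run_positional <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dat <- load_nfc(cfg)
  pp <- cfg$positional
  out <- lapply(c("5p", "3p"), function(end) {
    ws <- window_sample_sets(dat$nfc, end = end, span = pp$span,
                             window = pp$window, step = pp$step,
                             equalize_rc = isTRUE(pp$equalize_rc),
                             seed = substream_seed(cfg$seed,
                                                   paste0("pos_", end)))
    v <- mean_distance_vector(ws, metric = cfg$metric)
    list(vector = v,
         boundary = detect_boundary(v, scan = pp$scan, alpha = pp$alpha),
         rc_boundary = boundary_on_mean_rc(dat$profiles, end = end,
                                           span = pp$span, scan = pp$scan,
                                           alpha = pp$alpha))
  })
  names(out) <- c("5p", "3p")
  if (!is.null(cfg$paths$out_dir)) {
    dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (end in names(out)) {
      data.table::fwrite(out[[end]]$vector,
                         file.path(cfg$paths$out_dir,
                                   paste0("mean_distance_", end, ".tsv")),
                         sep = "\t")
      jsonlite::write_json(
        list(nfc_boundary = out[[end]]$boundary$boundary,
             rc_boundary = out[[end]]$rc_boundary$boundary,
             alpha = pp$alpha, scan = pp$scan, metric = cfg$metric),
        file.path(cfg$paths$out_dir, paste0("boundary_", end, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
    write_manifest(cfg, cfg$paths$out_dir, "positional")
  }
  out
}

#' Cross-organism comparison from multiple configs
#'
#' Pools each organism's inner-region NFC samples, computes the averaged
#' cross-organism distance matrix, the neighbor-joining tree, and the
#' intra- vs inter-domain similarity test. Writes `distance_matrix.tsv`,
#' `organisms.nwk` and `domain_test.json` to `out_dir` when given.
#'
#' @param cfgs list of `run_config`s (or YAML paths), one per organism;
#'   each needs `organism` and `domain`
#' @param metric distance metric
#' @param out_dir optional output directory
#' @return list: `matrix`, `newick`, `domain_test`
#' @export
run_compare <- function(cfgs, metric = "hellinger", out_dir = NULL) {
  cfgs <- lapply(cfgs, function(x)
    if (is.character(x)) read_run_config(x) else x)
  sets <- lapply(cfgs, function(cfg) {
    dat <- load_nfc(cfg)
    pool_by_codon(dat$nfc,
                  region = region_offsets(cfg$region$inner_five,
                                          cfg$region$inner_three),
                  organism = cfg$organism)
  })
  names(sets) <- vapply(cfgs, `[[`, "", "organism")
  domains <- setNames(vapply(cfgs, `[[`, "", "domain"), names(sets))
  oset <- organism_set(sets, domains)
  D <- cross_organism_matrix(oset, metric = metric)
  nwk <- neighbor_joining(D)
  dtest <- domain_similarity_test(D, domains)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(data.table::as.data.table(as.matrix(D),
                                                 keep.rownames = "organism"),
                       file.path(out_dir, "distance_matrix.tsv"), sep = "\t")
    writeLines(nwk, file.path(out_dir, "organisms.nwk"))
    jsonlite::write_json(dtest, file.path(out_dir, "domain_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(matrix = D, newick = nwk, domain_test = dtest)
}

#' Simulate a dataset from a config and write it to disk
#'
#' @param cfg a `run_config` with a `simulate` block (any [tasep_config()]
#'   field) and `paths$out_dir`
#' @return the `tasep_result`, invisibly
#' @export
run_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  sim_args <- cfg$simulate
  if (is.null(sim_args)) sim_args <- list()
  if (is.null(sim_args$seed))
    sim_args$seed <- substream_seed(cfg$seed, "simulate")
  res <- generate_dataset(do.call(tasep_config, sim_args))
  if (!is.null(cfg$paths$out_dir)) {
    write_tasep_dataset(res, cfg$paths$out_dir)
    write_manifest(cfg, cfg$paths$out_dir, "simulate")
  }
  invisible(res)
}
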