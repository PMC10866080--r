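# Stage orchestration: a structured config file, deterministic stage
# substreams, provenance manifests, and a one-shot end-to-end mode.
#
# Stages and their artifacts (under out_dir):
#   simulate        proteomes/*.faa, metadata.tsv, truth.tsv
#   build-profiles  alignments/*.afa, thresholds.tsv, calibration.tsv
#   search          hits.tsv
#   call            strategies.tsv, dropped.tsv
#   prevalence      prevalence.tsv
#   associate       associations.json, ordination.tsv
# Each stage writes manifest_<stage>.json recording config hash, seed,
# and md5 of every input and output artifact.

PIPELINE_STAGES <- c("simulate", "build-profiles", "search", "call",
                     "prevalence", "associate", "all")

KNOWN_CONFIG_KEYS <- c("seed", "out_dir", "simulate", "profiles", "search",
                       "call", "prevalence", "associate")

#' Load and validate a pipeline configuration
#'
#' The config is a single YAML (or JSON) document with top-level keys
#' `seed`, `out_dir`, and optional per-stage blocks `simulate`,
#' `profiles`, `search`, `call`, `prevalence`, `associate`.  Unknown
#' top-level keys are rejected.
#'
#' @param path config file path, or a named list already in memory.
#' @return validated config list of class `"pipeline_config"`.
#' @export
load_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), KNOWN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("config schema violation; unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_seed <- function(cfg, stage) substream_seed(cfg$seed, paste0("stage:", stage))

require_artifacts <- function(out_dir, files, producing_stage) {
  paths <- file.path(out_dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("missing upstream artifact(s) ", paste(missing, collapse = ", "),
         "; run stage '", producing_stage, "' first")
  }
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("nstrat")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(write_canonical_config(cfg))),
    input_hashes = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    output_hashes = as.list(tools::md5sum(outputs[file.exists(outputs)])),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  path <- file.path(cfg$out_dir, paste0("manifest_", gsub("-", "_", stage), ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

write_canonical_config <- function(cfg) {
  tmp <- file.path(tempdir(), "nstrat_config_canonical.json")
  plain <- cfg
  attributes(plain) <- list(names = names(cfg))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  tmp
}

pipeline_profiles <- function(cfg) {
  pcfg <- cfg$profiles %||% list()
  adir <- file.path(cfg$out_dir, "alignments")
  if (!is.null(pcfg$alignments_dir)) adir <- pcfg$alignments_dir
  files <- file.path(adir, paste0(MARKER_IDS, ".afa"))
  if (all(file.exists(files))) {
    msas <- lapply(files, read_alignment)
    names(msas) <- MARKER_IDS
  } else {
    msas <- synthetic_reference_alignments(
      seed = pcfg$ref_seed %||% 20260909)
  }
  profs <- lapply(MARKER_IDS, function(mid)
    build_profile(msas[[mid]],
                  occupancy_threshold = pcfg$occupancy_threshold %||% 0.5,
                  pseudocount = pcfg$pseudocount %||% 1,
                  marker_id = mid))
  names(profs) <- MARKER_IDS
  list(msas = msas, profiles = profs)
}

run_stage_simulate <- function(cfg) {
  sim_args <- cfg$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% stage_seed(cfg, "simulate")
  config <- do.call(sim_config, sim_args)
  pp <- pipeline_profiles(cfg)
  sim <- simulate_community(config, profiles = pp$profiles)
  write_community(sim, cfg$out_dir)
  outs <- c(file.path(cfg$out_dir, c("metadata.tsv", "truth.tsv")),
            list.files(file.path(cfg$out_dir, "proteomes"), full.names = TRUE))
  write_manifest(cfg, "simulate", character(0), outs)
}

run_stage_build_profiles <- function(cfg) {
  pp <- pipeline_profiles(cfg)
  adir <- file.path(cfg$out_dir, "alignments")
  dir.create(adir, recursive = TRUE, showWarnings = FALSE)
  for (mid in MARKER_IDS) {
    write_alignment(pp$msas[[mid]], file.path(adir, paste0(mid, ".afa")))
  }
  scfg <- cfg$search %||% list()
  seed <- stage_seed(cfg, "build-profiles")
  # calibrate at the longest decoy length the simulator produces (local
  # forward scores grow with query length, so the maximum is the
  # conservative calibration point)
  lr <- (cfg$simulate %||% list())$decoy_length_range %||% c(40L, 150L)
  calibs <- lapply(pp$profiles, calibrate_null,
                   n_samples = scfg$n_decoys_calibration %||% 2000,
                   lengths = lr[2],
                   seed = seed)
  thr <- if (!is.null(scfg$thresholds)) {
    unlist(scfg$thresholds)[MARKER_IDS]
  } else {
    vapply(calibs, function(cl) cl$max_score + 2, numeric(1))[MARKER_IDS]
  }
  write_tsv(data.frame(marker_id = MARKER_IDS,
                       bit_threshold = sprintf("%.6f", thr)),
            file.path(cfg$out_dir, "thresholds.tsv"))
  write_tsv(data.frame(marker_id = MARKER_IDS,
                       gumbel_mu = sprintf("%.6f",
                         vapply(calibs, `[[`, numeric(1), "gumbel_mu")[MARKER_IDS]),
                       gumbel_lambda = sprintf("%.6f",
                         vapply(calibs, `[[`, numeric(1), "gumbel_lambda")[MARKER_IDS]),
                       n_samples = scfg$n_decoys_calibration %||% 200,
                       seed = seed),
            file.path(cfg$out_dir, "calibration.tsv"))
  outs <- c(file.path(adir, paste0(MARKER_IDS, ".afa")),
            file.path(cfg$out_dir, c("thresholds.tsv", "calibration.tsv")))
  write_manifest(cfg, "build-profiles", character(0), outs)
}

run_stage_search <- function(cfg) {
  require_artifacts(cfg$out_dir, "thresholds.tsv", "build-profiles")
  require_artifacts(cfg$out_dir, "metadata.tsv", "simulate")
  pp <- pipeline_profiles(cfg)
  thr_df <- read_tsv(file.path(cfg$out_dir, "thresholds.tsv"))
  thr <- stats::setNames(as.numeric(thr_df$bit_threshold), thr_df$marker_id)
  cal_df <- read_tsv(file.path(cfg$out_dir, "calibration.tsv"))
  calibs <- lapply(seq_len(nrow(cal_df)), function(i)
    structure(list(marker_id = cal_df$marker_id[i],
                   gumbel_mu = as.numeric(cal_df$gumbel_mu[i]),
                   gumbel_lambda = as.numeric(cal_df$gumbel_lambda[i]),
                   n_samples = cal_df$n_samples[i], seed = cal_df$seed[i]),
              class = "null_calibration"))
  names(calibs) <- cal_df$marker_id
  faa <- sort(list.files(file.path(cfg$out_dir, "proteomes"),
                         pattern = "\\.faa$", full.names = TRUE))
  if (!length(faa)) stop("no proteomes found; run stage 'simulate' first")
  hit_list <- lapply(faa, function(f)
    search_proteome(pp$profiles, read_proteome(f), thr, calibs))
  hits <- do.call(rbind, hit_list)
  write_hits(hits, file.path(cfg$out_dir, "hits.tsv"))
  write_manifest(cfg, "search",
                 c(faa, file.path(cfg$out_dir, "thresholds.tsv")),
                 file.path(cfg$out_dir, "hits.tsv"))
}

run_stage_call <- function(cfg) {
  require_artifacts(cfg$out_dir, "hits.tsv", "search")
  require_artifacts(cfg$out_dir, "metadata.tsv", "simulate")
  hits <- read_hits(file.path(cfg$out_dir, "hits.tsv"))
  metadata <- read_tsv(file.path(cfg$out_dir, "metadata.tsv"))
  rules <- default_rule_set(require_nird =
    (cfg$call %||% list())$require_nird %||% TRUE)
  profiles <- lapply(metadata$genome_id, function(gid)
    call_strategies(hits[hits$genome_id == gid, , drop = FALSE],
                    rules = rules, genome_id = gid))
  qc <- qc_filter_genomes(metadata, profiles)
  for (i in seq_len(nrow(qc$dropped))) {
    message("dropping genome ", qc$dropped$genome_id[i], ": ",
            qc$dropped$reason[i])
  }
  kept_profiles <- profiles[vapply(profiles, `[[`, character(1), "genome_id")
                            %in% qc$kept]
  write_strategies(kept_profiles, file.path(cfg$out_dir, "strategies.tsv"))
  write_tsv(qc$dropped, file.path(cfg$out_dir, "dropped.tsv"))
  write_manifest(cfg, "call",
                 file.path(cfg$out_dir, c("hits.tsv", "metadata.tsv")),
                 file.path(cfg$out_dir, c("strategies.tsv", "dropped.tsv")))
}

read_strategy_matrix <- function(out_dir) {
  st <- read_tsv(file.path(out_dir, "strategies.tsv"))
  m <- as.matrix(st[, c(STRATEGIES, TRANSPORTER_FAMILIES)])
  rownames(m) <- st$genome_id
  list(table = st, matrix = m)
}

run_stage_prevalence <- function(cfg) {
  require_artifacts(cfg$out_dir, "strategies.tsv", "call")
  sm <- read_strategy_matrix(cfg$out_dir)
  pcfg <- cfg$prevalence %||% list()
  scheme <- pcfg$scheme %||% "plain"
  taxonomy <- NULL
  if (scheme == "taxon_balanced") {
    metadata <- read_tsv(file.path(cfg$out_dir, "metadata.tsv"))
    rank <- pcfg$rank %||% "phylum"
    taxonomy <- metadata[[rank]][match(rownames(sm$matrix),
                                       metadata$genome_id)]
  }
  est <- bootstrap_prevalence(sm$matrix,
                              n_boot = pcfg$n_boot %||% 1000,
                              seed = stage_seed(cfg, "prevalence"),
                              scheme = scheme, taxonomy = taxonomy)
  write_prevalence(rank_strategies(est), file.path(cfg$out_dir, "prevalence.tsv"))
  write_manifest(cfg, "prevalence",
                 file.path(cfg$out_dir, "strategies.tsv"),
                 file.path(cfg$out_dir, "prevalence.tsv"))
}

run_stage_associate <- function(cfg) {
  require_artifacts(cfg$out_dir, "strategies.tsv", "call")
  require_artifacts(cfg$out_dir, "metadata.tsv", "simulate")
  sm <- read_strategy_matrix(cfg$out_dir)
  st <- sm$table
  metadata <- read_tsv(file.path(cfg$out_dir, "metadata.tsv"))
  md <- metadata[match(st$genome_id, metadata$genome_id), ]
  acfg <- cfg$associate %||% list()
  results <- list()
  results$count_scaling <- fit_count_scaling(st$strategy_count,
                                             md$genome_length_bp)
  results$metabolism_counts <- group_compare(st$strategy_count,
                                             md$respiration_mode)
  use_random <- identical(acfg$family_effects, "random")
  for (s in c("chitin_depoly", "bnf")) {
    if (length(unique(st[[s]])) == 2) {
      results[[paste0("presence_", s)]] <- fit_presence_model(
        st[[s]], md$respiration_mode, family_ids = md$family,
        model = "logistic_with_family", family_random = use_random)
    }
  }
  organic <- rowSums(st[, setdiff(STRATEGIES, INORGANIC_STRATEGIES)])
  results$habitat_counts <- fit_habitat_counts(organic,
                                               md$ecosystem_category,
                                               family_ids = md$family)
  results$host_contrast <- host_contrast(st$inorganic_fraction,
                                         md$host_associated == 1)
  write_associations(results, file.path(cfg$out_dir, "associations.json"))
  ord <- ordinate(sm$matrix[, STRATEGIES],
                  method = acfg$ordination_method %||% "pca",
                  k = acfg$ordination_k %||% 2)
  write_ordination(ord, md, file.path(cfg$out_dir, "ordination.tsv"))
  write_manifest(cfg, "associate",
                 file.path(cfg$out_dir, c("strategies.tsv", "metadata.tsv")),
                 file.path(cfg$out_dir, c("associations.json", "ordination.tsv")))
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' @param stage one of `"simulate"`, `"build-profiles"`, `"search"`,
#'   `"call"`, `"prevalence"`, `"associate"`, `"all"`.
#' @param config a config path or list accepted by
#'   [load_pipeline_config()].
#' @param out_dir optional override for the config's `out_dir`.
#' @param seed optional override for the config's root seed.
#' @return the output directory, invisibly.
#' @export
run_stage <- function(stage, config, out_dir = NULL, seed = NULL) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- load_pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") {
    c("simulate", "build-profiles", "search", "call", "prevalence",
      "associate")
  } else stage
  for (s in stages) {
    switch(s,
      "simulate" = run_stage_simulate(cfg),
      "build-profiles" = run_stage_build_profiles(cfg),
      "search" = run_stage_search(cfg),
      "call" = run_stage_call(cfg),
      "prevalence" = run_stage_prevalence(cfg),
      "associate" = run_stage_associate(cfg))
  }
  invisible(cfg$out_dir)
}

#' Command-line entry point
#'
#' Usage: `Rscript -e 'nstrat::nstrat_main()' <stage> --config config.yaml
#' [--out DIR] [--seed N] [--log-level L]` (a ready-made wrapper script is
#' installed at `system.file("cli", "nstrat.R", package = "nstrat")`).
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
nstrat_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "nstrat <stage> --config config.yaml [--out DIR] [--seed N]",
    option_list = list(
      optparse::make_option("--config", type = "character"),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--log-level", type = "character",
                            default = "info", dest = "log_level")))
  parsed <- optparse::parse_args(parser, args = args, positional_arguments = 1)
  stage <- parsed$args[1]
  if (is.null(parsed$options$config)) stop("--config is required")
  if (identical(parsed$options$log_level, "quiet")) {
    suppressMessages(run_stage(stage, parsed$options$config,
                               out_dir = parsed$options$out,
                               seed = parsed$options$seed))
  } else {
    run_stage(stage, parsed$options$config, out_dir = parsed$options$out,
              seed = parsed$options$seed)
  }
  invisible(0L)
}
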