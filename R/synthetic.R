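# Seeded synthetic communities: reference marker alignments, genome
# covariates with planted effect structure, planted marker homologs, and
# background decoy proteins.  Every pipeline stage downstream of genome
# compilation can be exercised on this generator without any download.
#
# The stated world: ten strategies with baseline prevalences ordered as
# in genome-catalogue surveys (amino-acid and ammonium uptake most
# common, BNF rarest); strategy propensity increasing with log10 genome
# length; aerobes richer in strategies than anaerobes except for BNF
# (enriched in anaerobes) and chitinase (enriched in aerobes);
# host-associated genomes depleted of inorganic strategies; a shared
# per-family log-odds perturbation for taxonomic structure.

RESPIRATION_MODES <- c("aerobic", "facultatively_anaerobic", "anaerobic",
                       "phototrophic")
TROPHIC_MODES <- c("photoautotrophic", "photoheterotrophic",
                   "chemoautotrophic", "chemoorganotrophic", "mixotrophic")
ECOSYSTEMS <- c("soil", "marine", "freshwater", "host_associated",
                "engineered")

# Baseline log-odds at the reference covariates, ordered as in
# genome-catalogue surveys: amino-acid and ammonium uptake most common,
# then the chitin pair, ferredoxin-dependent nitrite reduction leading
# the remaining inorganic routes, BNF rarest.  Gaps are wide enough that
# the implied marginal ordering is recoverable at community sizes of a
# few hundred genomes.
default_baseline_logit <- function() {
  c(ammonium_uptake = 1.4, bnf = -3.0, fd_nitrite = -0.4,
    nadh_nitrite = -1.4, nitrate_assim = -1.8, urea = -0.9,
    cyanate = -2.3, chitin_depoly = 0.5, hexnac_assim = 0.1,
    amino_acid_uptake = 2.0)
}

default_beta_respiration <- function() {
  zero <- stats::setNames(rep(0, 10), STRATEGIES)
  aerobic <- zero + 0.4; aerobic["bnf"] <- -1.5; aerobic["chitin_depoly"] <- 1.0
  fac <- zero + 0.3; fac["bnf"] <- -0.5
  photo <- zero + 0.2
  list(aerobic = aerobic, facultatively_anaerobic = fac,
       anaerobic = zero, phototrophic = photo)
}

default_beta_host <- function() {
  b <- stats::setNames(rep(0, 10), STRATEGIES)
  b[INORGANIC_STRATEGIES] <- -1.5
  b
}

#' Configuration for the synthetic community generator
#'
#' Defaults encode the generator's stated world (see the methods
#' vignette); effect sizes are chosen for estimator testability, not to
#' mimic any real catalogue.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param seed root seed; all stage substreams derive from it.
#' @param baseline_logit named per-strategy log-odds at the reference
#'   covariates (anaerobic, free-living, log10 length 6.5).
#' @param beta_size effect of log10 genome length (centred at
#'   `ref_log10_length`) on each strategy's log-odds.
#' @param beta_respiration named list (per respiration mode) of named
#'   per-strategy log-odds offsets; anaerobic is the zero reference.
#' @param beta_host named per-strategy log-odds offset applied to
#'   host-associated genomes.
#' @param n_families taxonomic grouping factor size (round-robin).
#' @param family_sd between-family log-odds SD (shared across strategies).
#' @param decoys_per_genome background decoy proteins appended per genome.
#' @param planted_copies copies planted per present marker (>= 1).
#' @param mutation_rate per-residue substitution probability in [0, 1]
#'   applied to planted homologs.
#' @param prob_clamp optional named per-strategy probabilities that
#'   override the logistic model (degenerate worlds for testing).
#' @param log10_length_range genome length sampling range (log10 bp).
#' @param ref_log10_length centring constant for the size effect.
#' @param respiration_probs,trophic_probs,ecosystem_probs categorical
#'   sampling distributions.
#' @param host_prob probability a genome is host-associated.
#' @param family_probs conditional transporter-family probabilities given
#'   amino-acid uptake is present.
#' @param decoy_length_range decoy protein length range.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_genomes = 100, seed = 1,
                       baseline_logit = default_baseline_logit(),
                       beta_size = 1.5,
                       beta_respiration = default_beta_respiration(),
                       beta_host = default_beta_host(),
                       n_families = 20, family_sd = 0.5,
                       decoys_per_genome = 20, planted_copies = 1,
                       mutation_rate = 0.02, prob_clamp = NULL,
                       log10_length_range = c(6.0, 7.0),
                       ref_log10_length = 6.5,
                       respiration_probs = c(aerobic = 0.35,
                                             facultatively_anaerobic = 0.2,
                                             anaerobic = 0.35,
                                             phototrophic = 0.1),
                       trophic_probs = c(photoautotrophic = 0.08,
                                         photoheterotrophic = 0.07,
                                         chemoautotrophic = 0.15,
                                         chemoorganotrophic = 0.6,
                                         mixotrophic = 0.1),
                       ecosystem_probs = c(soil = 0.25, marine = 0.2,
                                           freshwater = 0.15,
                                           host_associated = 0.25,
                                           engineered = 0.15),
                       host_prob = 0.3,
                       family_probs = c(APC = 0.6, AGCS = 0.5, BCCT = 0.3,
                                        LIVCS = 0.25, HAAAP = 0.2),
                       decoy_length_range = c(40L, 150L)) {
  if (n_genomes < 2) stop("n_genomes must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (family_sd < 0) stop("family_sd must be >= 0")
  if (planted_copies < 1) stop("planted_copies must be >= 1")
  if (decoys_per_genome < 0) stop("decoys_per_genome must be >= 0")
  bad_resp <- setdiff(names(respiration_probs), RESPIRATION_MODES)
  if (length(bad_resp)) stop("unknown respiration mode(s): ",
                             paste(bad_resp, collapse = ", "))
  bad_troph <- setdiff(names(trophic_probs), TROPHIC_MODES)
  if (length(bad_troph)) stop("unknown trophic mode(s): ",
                              paste(bad_troph, collapse = ", "))
  bad_beta <- setdiff(names(beta_respiration), RESPIRATION_MODES)
  if (length(bad_beta)) stop("unknown respiration mode(s) in beta_respiration: ",
                             paste(bad_beta, collapse = ", "))
  if (!is.null(prob_clamp)) {
    if (any(prob_clamp < 0 | prob_clamp > 1)) stop("prob_clamp outside [0, 1]")
    bad <- setdiff(names(prob_clamp), STRATEGIES)
    if (length(bad)) stop("unknown strategy in prob_clamp: ",
                          paste(bad, collapse = ", "))
  }
  cfg <- list(n_genomes = as.integer(n_genomes), seed = as.integer(seed),
              baseline_logit = baseline_logit, beta_size = beta_size,
              beta_respiration = beta_respiration, beta_host = beta_host,
              n_families = as.integer(n_families), family_sd = family_sd,
              decoys_per_genome = as.integer(decoys_per_genome),
              planted_copies = as.integer(planted_copies),
              mutation_rate = mutation_rate, prob_clamp = prob_clamp,
              log10_length_range = log10_length_range,
              ref_log10_length = ref_log10_length,
              respiration_probs = respiration_probs,
              trophic_probs = trophic_probs,
              ecosystem_probs = ecosystem_probs, host_prob = host_prob,
              family_probs = family_probs,
              decoy_length_range = as.integer(decoy_length_range))
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic reference alignments for all registry markers
#'
#' Each marker gets a deterministic random ancestral sequence; rows are
#' divergent copies with per-residue substitutions and sparse gaps.
#' Random profiles over the 20-letter alphabet are effectively
#' orthogonal, so markers are well separated by construction.
#'
#' @param seed integer seed (fixed default so all callers share one
#'   reference world).
#' @param n_rows rows per alignment.
#' @param n_columns alignment length (= match states when gaps are rare).
#' @param divergence per-residue substitution probability between rows.
#' @param gap_prob per-cell gap probability (kept below the occupancy
#'   threshold so columns stay match states).
#' @return named list of `"msa"` objects, one per marker.
#' @export
synthetic_reference_alignments <- function(seed = 20260909, n_rows = 8,
                                           n_columns = 50,
                                           divergence = 0.05,
                                           gap_prob = 0.03) {
  out <- list()
  for (mid in MARKER_IDS) {
    out[[mid]] <- with_seed(substream_seed(seed, paste0("refmsa:", mid)), {
      anc <- sample(AA_ALPHABET, n_columns, replace = TRUE)
      rows <- vapply(seq_len(n_rows), function(r) {
        row <- anc
        mut <- stats::runif(n_columns) < divergence
        if (any(mut)) row[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE)
        gap <- stats::runif(n_columns) < gap_prob
        row[gap] <- "-"
        paste(row, collapse = "")
      }, character(1))
      new_msa(sprintf("%s_ref%02d", mid, seq_len(n_rows)), rows)
    })
  }
  out
}

.profile_cache <- new.env(parent = emptyenv())

#' Profile models for the synthetic reference alignments
#'
#' Builds (and caches per seed) one `"profile_model"` per registry
#' marker from [synthetic_reference_alignments()].
#'
#' @inheritParams synthetic_reference_alignments
#' @return named list of `"profile_model"`s.
#' @export
default_marker_profiles <- function(seed = 20260909) {
  key <- as.character(seed)
  if (!is.null(.profile_cache[[key]])) return(.profile_cache[[key]])
  msas <- synthetic_reference_alignments(seed = seed)
  profs <- lapply(names(msas), function(mid)
    build_profile(msas[[mid]], marker_id = mid))
  names(profs) <- names(msas)
  .profile_cache[[key]] <- profs
  profs
}

# Per-strategy linear predictor (log-odds) for one genome, excluding the
# family effect and the probability clamp.
strategy_eta <- function(config, log10len, respiration, host) {
  eta <- config$baseline_logit[STRATEGIES] +
    config$beta_size * (log10len - config$ref_log10_length)
  off <- config$beta_respiration[[respiration]]
  if (!is.null(off)) eta <- eta + off[STRATEGIES]
  if (host) eta <- eta + config$beta_host[STRATEGIES]
  stats::setNames(as.numeric(eta), STRATEGIES)
}

# Presence probability including family effect and clamp.
strategy_probs <- function(config, log10len, respiration, host,
                           family_effect = 0) {
  p <- stats::plogis(strategy_eta(config, log10len, respiration, host) +
                     family_effect)
  if (!is.null(config$prob_clamp)) {
    p[names(config$prob_clamp)] <- config$prob_clamp
  }
  p
}

#' Simulate a synthetic community
#'
#' Samples genome covariates, realizes per-strategy presence from the
#' logistic model, makes the truth rule-consistent (nitrate assimilation
#' without a nitrite route forces the ferredoxin route; amino-acid
#' uptake forces at least one transporter family), plants the marker
#' genes each present strategy requires as sequences emitted from the
#' marker profiles, and appends background decoys.
#'
#' @param config a `"sim_config"`.
#' @param profiles named list of `"profile_model"`s used for planting;
#'   defaults to [default_marker_profiles()].
#' @param emit_proteins generate protein sequences (set `FALSE` for
#'   covariate/truth-only simulations used by estimator tests; the
#'   covariate and truth draws are identical either way).
#' @param rules rule set used to determine required marker complements.
#' @return list with `genomes` (list of `"genome_record"`; empty when
#'   `emit_proteins = FALSE`), `metadata` (data.frame), `truth`
#'   (data.frame: genome_id + 15 binary columns), `planted` (data.frame
#'   genome_id, protein_id, marker_id), `family_effects`, `config`.
#' @export
simulate_community <- function(config, profiles = NULL,
                               emit_proteins = TRUE,
                               rules = default_rule_set()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genomes
  gids <- sprintf("G%05d", seq_len(n))

  cov <- with_seed(substream_seed(config$seed, "covariates"), {
    fam_effect <- stats::rnorm(config$n_families, 0, config$family_sd)
    fam <- ((seq_len(n) - 1) %% config$n_families) + 1
    log10len <- stats::runif(n, config$log10_length_range[1],
                             config$log10_length_range[2])
    respiration <- sample(names(config$respiration_probs), n, replace = TRUE,
                          prob = config$respiration_probs)
    trophic <- sample(names(config$trophic_probs), n, replace = TRUE,
                      prob = config$trophic_probs)
    host <- stats::runif(n) < config$host_prob
    ecosystem <- sample(names(config$ecosystem_probs), n, replace = TRUE,
                        prob = config$ecosystem_probs)
    completeness <- stats::runif(n, 92, 100)
    contamination <- stats::runif(n, 0, 4)
    n_trna <- sample(18:21, n, replace = TRUE)
    pres <- matrix(FALSE, n, 10, dimnames = list(gids, STRATEGIES))
    fams <- matrix(FALSE, n, 5, dimnames = list(gids, TRANSPORTER_FAMILIES))
    for (i in seq_len(n)) {
      p <- strategy_probs(config, log10len[i], respiration[i], host[i],
                          family_effect = fam_effect[fam[i]])
      pres[i, ] <- stats::runif(10) < p
      if (pres[i, "amino_acid_uptake"]) {
        f <- stats::runif(5) < config$family_probs[TRANSPORTER_FAMILIES]
        if (!any(f)) f[which.max(config$family_probs[TRANSPORTER_FAMILIES])] <- TRUE
        fams[i, ] <- f
      }
      if (pres[i, "nitrate_assim"] && !pres[i, "fd_nitrite"] &&
          !pres[i, "nadh_nitrite"]) {
        pres[i, "fd_nitrite"] <- TRUE
      }
    }
    list(fam = fam, fam_effect = fam_effect, log10len = log10len,
         respiration = respiration, trophic = trophic, host = host,
         ecosystem = ecosystem, completeness = completeness,
         contamination = contamination, n_trna = n_trna,
         presence = pres, families = fams)
  })

  genome_length <- round(10 ^ cov$log10len)
  metadata <- data.frame(
    genome_id = gids,
    domain = "Bacteria",
    phylum = sprintf("p%02d", ((cov$fam - 1) %% 6) + 1),
    family = sprintf("f%02d", cov$fam),
    genome_length_bp = genome_length,
    n_cds = round(genome_length / 1000),
    ecosystem_category = cov$ecosystem,
    host_associated = as.integer(cov$host),
    respiration_mode = cov$respiration,
    trophic_mode = cov$trophic,
    completeness = cov$completeness,
    contamination = cov$contamination,
    has_rrna = 1L,
    n_trna = cov$n_trna,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(genome_id = gids, cov$presence + 0L, cov$families + 0L,
                      check.names = FALSE, stringsAsFactors = FALSE)

  genomes <- list()
  planted <- data.frame(genome_id = character(0), protein_id = character(0),
                        marker_id = character(0), stringsAsFactors = FALSE)
  if (emit_proteins) {
    if (is.null(profiles)) profiles <- default_marker_profiles()
    plant_rows <- list()
    proteins_by_genome <- with_seed(substream_seed(config$seed, "planting"), {
      lapply(seq_len(n), function(i) {
        markers <- character(0)
        for (s in STRATEGIES) {
          if (!cov$presence[i, s]) next
          if (s == "amino_acid_uptake") {
            markers <- c(markers, TRANSPORTER_FAMILIES[cov$families[i, ]])
          } else {
            markers <- c(markers, strategy_required_markers(s, rules))
          }
        }
        markers <- unique(markers)
        seqs <- character(0)
        for (m in markers) {
          for (k in seq_len(config$planted_copies)) {
            pid <- sprintf("%s_%d", m, k)
            seqs[pid] <- emit_from_profile(profiles[[m]],
                                           n_inserts = stats::rpois(1, 2),
                                           mutation_rate = config$mutation_rate)
          }
        }
        seqs
      })
    })
    decoys_by_genome <- with_seed(substream_seed(config$seed, "decoys"), {
      lapply(seq_len(n), function(i) {
        if (config$decoys_per_genome == 0) return(character(0))
        lens <- sample(seq(config$decoy_length_range[1],
                           config$decoy_length_range[2]),
                       config$decoys_per_genome, replace = TRUE)
        seqs <- vapply(lens, emit_background, character(1))
        names(seqs) <- sprintf("decoy_%03d", seq_along(seqs))
        seqs
      })
    })
    for (i in seq_len(n)) {
      prot <- c(proteins_by_genome[[i]], decoys_by_genome[[i]])
      genomes[[i]] <- genome_record(gids[i], prot,
                                    metadata = as.list(metadata[i, ]))
      if (length(proteins_by_genome[[i]])) {
        pid <- names(proteins_by_genome[[i]])
        plant_rows[[i]] <- data.frame(
          genome_id = gids[i], protein_id = pid,
          marker_id = sub("_\\d+$", "", pid), stringsAsFactors = FALSE)
      }
    }
    if (length(plant_rows)) planted <- do.call(rbind, plant_rows)
    rownames(planted) <- NULL
  }

  list(genomes = genomes, metadata = metadata, truth = truth,
       planted = planted,
       family_effects = cov$fam_effect, config = config)
}

#' Write a simulated community to disk
#'
#' One protein FASTA per genome (headers `genome_id|protein_id`) under
#' `dir/proteomes/`, plus `metadata.tsv` and `truth.tsv`.
#'
#' @param sim result of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in sim$genomes) {
    seqs <- g$proteins
    names(seqs) <- paste0(g$genome_id, "|", names(seqs))
    write_fasta(seqs, file.path(dir, "proteomes", paste0(g$genome_id, ".faa")))
  }
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read a proteome FASTA written by [write_community()]
#'
#' @param path FASTA path; headers `genome_id|protein_id`.
#' @return a `"genome_record"`.
#' @export
read_proteome <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  gid <- unique(sub("\\|.*$", "", ids))
  if (length(gid) != 1) stop("proteome mixes genome ids: ", path)
  names(seqs) <- sub("^[^|]*\\|", "", ids)
  genome_record(gid, seqs)
}
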