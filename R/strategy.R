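# Strategy calling from marker hits, genome QC filtering, and the
# per-genome summary statistics (strategy count, inorganic fraction).

#' Call N acquisition strategies from one genome's marker hits
#'
#' Default rules: ammonium uptake from AmtB; BNF requires the complete
#' NifH + NifD + NifK nitrogenase complement; ferredoxin-dependent
#' nitrite reduction from NirA; NADH-dependent nitrite reduction from
#' NirB plus NirD (NirD relaxable via the rule set flag); nitrate
#' assimilation requires NasA co-occurring with an assimilatory nitrite
#' reductase; urea from UreC; cyanate from CynS; chitin depolymerization
#' from chitinase; HexNAc assimilation from hexosaminidase; amino-acid
#' uptake from any of the APC, AGCS, BCCT, LIVCS, HAAAP transporter
#' families.
#'
#' @param hits hits data.frame for a single genome (may have zero rows,
#'   in which case `genome_id` must be supplied).
#' @param rules a `"rule_set"` from [default_rule_set()].
#' @param genome_id required when `hits` is empty.
#' @return object of class `"strategy_profile"`: list with `genome_id`,
#'   `presence` (named logical over the 10 strategies),
#'   `transporter_families` (named logical over the 5 families).
#' @export
call_strategies <- function(hits, rules = default_rule_set(),
                            genome_id = NULL) {
  if (nrow(hits) == 0) {
    if (is.null(genome_id)) stop("empty hits need an explicit genome_id")
    gid <- genome_id
    markers <- character(0)
  } else {
    gid <- unique(hits$genome_id)
    if (length(gid) != 1) {
      stop("hits span multiple genomes: ", paste(gid, collapse = ", "))
    }
    markers <- unique(hits$marker_id)
    unknown <- setdiff(markers, MARKER_IDS)
    if (length(unknown)) {
      stop("unknown marker id(s): ", paste(unknown, collapse = ", "))
    }
  }
  present <- stats::setNames(MARKER_IDS %in% markers, MARKER_IDS)
  ev <- evaluate_rules(present, rules)
  structure(list(genome_id = gid, presence = ev$strategies,
                 transporter_families = ev$transporter_families),
            class = "strategy_profile")
}

#' @export
print.strategy_profile <- function(x, ...) {
  cat("strategy_profile ", x$genome_id, ": ",
      paste(names(x$presence)[x$presence], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of N acquisition strategies in a profile
#'
#' Counts the 10 strategy flags; the transporter family sub-flags are a
#' decomposition of amino-acid uptake and are excluded.
#'
#' @param profile a `"strategy_profile"`.
#' @return integer in 0..10.
#' @export
strategy_count <- function(profile) {
  stopifnot(inherits(profile, "strategy_profile"))
  sum(profile$presence)
}

#' Fraction of present strategies targeting inorganic N
#'
#' Inorganic strategies are ammonium uptake, BNF, both nitrite reduction
#' routes, and nitrate assimilation (substrates N2, ammonium, nitrite,
#' nitrate).  Urea, cyanate, chitin, HexNAc and amino-acid uptake are
#' organic.  Undefined for a zero-strategy profile (such genomes are
#' QC-dropped upstream).
#'
#' @param profile a `"strategy_profile"`.
#' @return real in [0, 1].
#' @export
inorganic_fraction <- function(profile) {
  n <- strategy_count(profile)
  if (n == 0) stop("inorganic_fraction undefined for a zero-strategy profile")
  sum(profile$presence[INORGANIC_STRATEGIES]) / n
}

#' Default genome quality criteria (MIMAG high quality)
#'
#' Completeness strictly greater than 90%, contamination strictly below
#' 5%, rRNA present, and at least 18 tRNAs.
#'
#' @return named list of thresholds.
#' @export
default_qc_criteria <- function() {
  list(min_completeness = 90, max_contamination = 5,
       require_rrna = TRUE, min_trna = 18)
}

#' Filter genomes on assembly quality and strategy content
#'
#' Drops genomes failing the MIMAG-style quality thresholds, genomes
#' lacking domain-level taxonomy, and genomes whose 10-strategy vector is
#' all false (indistinguishable from incomplete assemblies).  Boundary
#' conventions are strict: completeness exactly 90 or contamination
#' exactly 5 fail.
#'
#' @param metadata data.frame with columns genome_id, domain,
#'   completeness, contamination, has_rrna, n_trna.
#' @param profiles list of `"strategy_profile"`s.
#' @param criteria list from [default_qc_criteria()].
#' @return list with `kept` (character genome ids) and `dropped`
#'   (data.frame genome_id, reason).
#' @export
qc_filter_genomes <- function(metadata, profiles,
                              criteria = default_qc_criteria()) {
  ids <- vapply(profiles, `[[`, character(1), "genome_id")
  miss <- setdiff(ids, metadata$genome_id)
  if (length(miss)) {
    stop("missing metadata row for genome(s): ", paste(miss, collapse = ", "))
  }
  md <- metadata[match(ids, metadata$genome_id), ]
  counts <- vapply(profiles, strategy_count, numeric(1))
  reason <- rep(NA_character_, length(ids))
  flag <- function(cond, code) {
    reason <<- ifelse(is.na(reason) & cond, code, reason)
  }
  flag(!(md$completeness > criteria$min_completeness), "low_completeness")
  flag(!(md$contamination < criteria$max_contamination), "high_contamination")
  if (isTRUE(criteria$require_rrna)) flag(!(md$has_rrna %in% c(1, TRUE)), "no_rrna")
  flag(!(md$n_trna >= criteria$min_trna), "few_trna")
  flag(is.na(md$domain) | !nzchar(as.character(md$domain)), "no_domain_taxonomy")
  flag(counts == 0, "zero_pathways")
  dropped <- data.frame(genome_id = ids[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  list(kept = ids[is.na(reason)], dropped = dropped)
}

#' Strategy profiles as a binary matrix
#'
#' @param profiles list of `"strategy_profile"`s.
#' @param include_families include the 5 transporter family columns.
#' @return integer 0/1 matrix, rownames = genome ids.
#' @export
profiles_to_matrix <- function(profiles, include_families = TRUE) {
  rows <- lapply(profiles, function(p) {
    v <- as.integer(p$presence)
    if (include_families) v <- c(v, as.integer(p$transporter_families))
    v
  })
  m <- do.call(rbind, rows)
  colnames(m) <- if (include_families) c(STRATEGIES, TRANSPORTER_FAMILIES)
    else STRATEGIES
  rownames(m) <- vapply(profiles, `[[`, character(1), "genome_id")
  m
}

#' Write per-genome strategy calls as TSV
#'
#' One row per genome: the 10 strategy flags, the 5 transporter family
#' flags, strategy_count, and inorganic_fraction (NA when count is 0).
#'
#' @param profiles list of `"strategy_profile"`s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_strategies <- function(profiles, path) {
  m <- profiles_to_matrix(profiles)
  counts <- vapply(profiles, strategy_count, numeric(1))
  frac <- ifelse(counts > 0,
                 vapply(profiles, function(p)
                   if (strategy_count(p) > 0) inorganic_fraction(p) else NA_real_,
                   numeric(1)),
                 NA_real_)
  df <- data.frame(genome_id = rownames(m), m, strategy_count = counts,
                   inorganic_fraction = frac, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
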