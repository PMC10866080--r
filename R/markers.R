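# Marker registry, strategy rule set, and the energetic cost model.
#
# Ten N acquisition strategies are called from seventeen marker proteins:
# single-marker strategies (AmtB, NirA, UreC, CynS, chitinase,
# hexosaminidase), multi-subunit complexes (NifHDK nitrogenase, NirBD
# NADH-nitrite reductase), a co-occurrence rule (NasA with an assimilatory
# nitrite reductase), and amino-acid uptake as the union of five
# transporter families from the APC superfamily.

STRATEGIES <- c("ammonium_uptake", "bnf", "fd_nitrite", "nadh_nitrite",
                "nitrate_assim", "urea", "cyanate", "chitin_depoly",
                "hexnac_assim", "amino_acid_uptake")

INORGANIC_STRATEGIES <- c("ammonium_uptake", "bnf", "fd_nitrite",
                          "nadh_nitrite", "nitrate_assim")

TRANSPORTER_FAMILIES <- c("APC", "AGCS", "BCCT", "LIVCS", "HAAAP")

MARKER_IDS <- c("AmtB", "NifH", "NifD", "NifK", "NirA", "NirB", "NirD",
                "NasA", "CynS", "UreC", "Chitinase", "HexNAcase",
                TRANSPORTER_FAMILIES)

MARKER_DESCRIPTIONS <- c(
  AmtB = "ammonium permease",
  NifH = "nitrogenase iron protein",
  NifD = "nitrogenase molybdenum-iron protein alpha subunit",
  NifK = "nitrogenase molybdenum-iron protein beta subunit",
  NirA = "ferredoxin-dependent assimilatory nitrite reductase",
  NirB = "NADH-dependent nitrite reductase large subunit",
  NirD = "NADH-dependent nitrite reductase small subunit",
  NasA = "assimilatory nitrate reductase",
  CynS = "cyanase",
  UreC = "urease alpha subunit",
  Chitinase = "chitinase",
  HexNAcase = "beta-N-acetyl hexosaminidase",
  APC = "amino acid-polyamine-organocation family transporter",
  AGCS = "alanine/glycine:cation symporter",
  BCCT = "betaine/carnitine/choline transporter",
  LIVCS = "branched-chain amino acid:cation symporter",
  HAAAP = "hydroxy/aromatic amino acid permease"
)

#' Marker registry
#'
#' The seventeen marker proteins used to call the ten N acquisition
#' strategies, with optional per-marker alignment paths and bit-score
#' thresholds.  Thresholds default to `NA` and are normally filled in by
#' [default_bit_thresholds()] (decoy-calibrated) or supplied by the user
#' to mirror an externally curated cutoff set.
#'
#' @param alignment_paths optional named character vector of aligned-FASTA
#'   paths, names in `marker_ids`.
#' @param bit_thresholds optional named numeric vector of bit-score cutoffs.
#' @return a data.frame with class `"marker_registry"`: columns
#'   `marker_id`, `description`, `alignment_path`, `bit_threshold`.
#' @export
marker_registry <- function(alignment_paths = NULL, bit_thresholds = NULL) {
  reg <- data.frame(
    marker_id = MARKER_IDS,
    description = unname(MARKER_DESCRIPTIONS[MARKER_IDS]),
    alignment_path = NA_character_,
    bit_threshold = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(alignment_paths)) {
    bad <- setdiff(names(alignment_paths), MARKER_IDS)
    if (length(bad)) stop("unknown marker ids in alignment_paths: ",
                          paste(bad, collapse = ", "))
    reg$alignment_path[match(names(alignment_paths), reg$marker_id)] <-
      unname(alignment_paths)
  }
  if (!is.null(bit_thresholds)) {
    bad <- setdiff(names(bit_thresholds), MARKER_IDS)
    if (length(bad)) stop("unknown marker ids in bit_thresholds: ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(bit_thresholds))) stop("bit thresholds must be finite")
    reg$bit_threshold[match(names(bit_thresholds), reg$marker_id)] <-
      unname(bit_thresholds)
  }
  class(reg) <- c("marker_registry", "data.frame")
  reg
}

#' Strategy rule set
#'
#' Boolean rules mapping marker presence to strategy calls.  All rules are
#' positive monotone: adding a marker hit can never switch a strategy off.
#'
#' @param require_nird require the NirD small subunit alongside NirB for
#'   the NADH-dependent nitrite reduction call (default `TRUE`, the
#'   stricter reading of the NirBD two-subunit marker).
#' @return an object of class `"rule_set"`.
#' @export
default_rule_set <- function(require_nird = TRUE) {
  structure(list(require_nird = isTRUE(require_nird)), class = "rule_set")
}

# Evaluate the rule set on a logical marker-presence vector (named by
# MARKER_IDS).  Returns list(strategies = named logical(10),
# transporter_families = named logical(5)).
evaluate_rules <- function(present, rules = default_rule_set()) {
  stopifnot(inherits(rules, "rule_set"))
  p <- stats::setNames(rep(FALSE, length(MARKER_IDS)), MARKER_IDS)
  p[names(present)] <- as.logical(present)
  fam <- p[TRANSPORTER_FAMILIES]
  fd <- unname(p["NirA"])
  nadh <- unname(if (rules$require_nird) p["NirB"] && p["NirD"] else p["NirB"])
  strat <- c(
    ammonium_uptake = unname(p["AmtB"]),
    bnf = unname(p["NifH"] && p["NifD"] && p["NifK"]),
    fd_nitrite = fd,
    nadh_nitrite = nadh,
    nitrate_assim = unname(p["NasA"]) && (fd || nadh),
    urea = unname(p["UreC"]),
    cyanate = unname(p["CynS"]),
    chitin_depoly = unname(p["Chitinase"]),
    hexnac_assim = unname(p["HexNAcase"]),
    amino_acid_uptake = any(fam)
  )
  list(strategies = strat, transporter_families = fam)
}

# Markers that must be planted for a strategy to evaluate true.
strategy_required_markers <- function(strategy, rules = default_rule_set()) {
  switch(strategy,
    ammonium_uptake = "AmtB",
    bnf = c("NifH", "NifD", "NifK"),
    fd_nitrite = "NirA",
    nadh_nitrite = if (rules$require_nird) c("NirB", "NirD") else "NirB",
    nitrate_assim = "NasA",  # plus a nitrite reductase, enforced upstream
    urea = "UreC",
    cyanate = "CynS",
    chitin_depoly = "Chitinase",
    hexnac_assim = "HexNAcase",
    amino_acid_uptake = character(0),  # family flags drive planting
    stop("unknown strategy: ", strategy)
  )
}

#' Energetic cost model for N acquisition strategies
#'
#' Fixed assimilation-cost stoichiometries per N atom-equivalent event:
#' ammonium assimilation through GS-GOGAT consumes 1 ATP and no reducing
#' equivalents; assimilatory nitrite and nitrate reduction consume 6 and 8
#' reducing equivalents; biological nitrogen fixation consumes 16 ATP and
#' 8 reducing equivalents per mole of N2 fixed.  Amino-acid uptake is
#' transport-coupled (PMF/SMF) with no assimilation electron cost.  Urea,
#' cyanate, chitin depolymerization and HexNAc assimilation carry high
#' indirect machinery costs without a headline ATP stoichiometry; they are
#' flagged `high` with `NA` ATP.
#'
#' @return a data.frame of class `"cost_model"` with columns `strategy`,
#'   `atp_cost`, `electron_cost`, `cost_class`.
#' @export
#' @examples
#' cost_table()[cost_table()$strategy == "bnf", "atp_cost"]  # 16
cost_table <- function() {
  tab <- data.frame(
    strategy = STRATEGIES,
    atp_cost = c(1, 16, NA, NA, NA, NA, NA, NA, NA, 0),
    electron_cost = c(0, 8, 6, 6, 8, NA, NA, NA, NA, 0),
    cost_class = c("low", "high", "medium", "medium", "medium",
                   "high", "high", "high", "high", "low"),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("cost_model", "data.frame")
  tab
}

cost_of <- function(strategy, field) {
  tab <- cost_table()
  tab[[field]][match(strategy, tab$strategy)]
}
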