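# Homology search: native forward scoring of proteins against profile
# models, Gumbel null calibration for E-values, decoy-calibrated bit
# thresholds, and interop with HMMER3 per-target tabular output.

encode_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("sequence must be a non-empty character scalar")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  wild <- chars %in% AA_WILDCARDS
  if (any(is.na(idx) & !wild)) {
    stop("illegal residue(s): ",
         paste(unique(chars[is.na(idx) & !wild]), collapse = ""))
  }
  idx[wild] <- 0L  # placeholder, flagged below
  out <- idx - 1L
  out[wild] <- -1L
  out
}

#' Score a protein sequence against a profile model
#'
#' Computes `log2` of the ratio between the forward-summed probability of
#' the sequence under a local alignment to the profile (free entry at any
#' match state with uniform mass 1/M, free exit from any match state) and
#' its probability under the background model.  Flanking residues outside
#' the aligned region are background-emitted and cancel from the ratio.
#'
#' @param profile a `"profile_model"`.
#' @param sequence amino-acid string; wildcards (B, Z, X, U, O, J) emit
#'   with background probability.
#' @return bit score (numeric scalar, log2 odds).
#' @export
score_sequence <- function(profile, sequence) {
  stopifnot(inherits(profile, "profile_model"))
  seq_i <- encode_sequence(sequence)
  tr <- profile$trans
  .forward_bits(seq_i, profile$match_emis, profile$insert_emis,
                profile$background, tr$tMM, tr$tMI, tr$tMD,
                tr$tII, tr$tIM, tr$tDD, tr$tDM)
}

#' Calibrate the null score distribution of a profile
#'
#' Scores background-sampled decoy sequences and fits a Gumbel by the
#' method of moments: `lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - 0.5772157 / lambda`.  E-values are then
#' `N_targets * exp(-lambda * (score - mu))`.
#'
#' @param profile a `"profile_model"`.
#' @param n_samples number of decoys, at least 100.
#' @param lengths either a single integer (constant decoy length), an
#'   integer vector to resample, or a `function(n)` returning lengths;
#'   default is the profile's match-state count.
#' @param seed integer seed.
#' @return object of class `"null_calibration"` with fields `marker_id`,
#'   `gumbel_mu`, `gumbel_lambda`, `n_samples`, `length_distribution`,
#'   `seed`, and `max_score` (largest decoy score observed).
#' @export
calibrate_null <- function(profile, n_samples = 200, lengths = NULL,
                           seed = 1) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_samples < 100) stop("n_samples must be >= 100")
  sampler <- length_sampler(lengths, profile$M)
  scores <- with_seed(substream_seed(seed, paste0("null:", profile$marker_id)), {
    lens <- sampler(n_samples)
    vapply(lens, function(L)
      score_sequence(profile, emit_background(L, profile$background)),
      numeric(1))
  })
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("calibration error: zero score variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  structure(list(marker_id = profile$marker_id, gumbel_mu = mu,
                 gumbel_lambda = lambda, n_samples = n_samples,
                 length_distribution = attr(sampler, "descriptor"),
                 seed = seed, max_score = max(scores)),
            class = "null_calibration")
}

length_sampler <- function(lengths, default_len) {
  if (is.null(lengths)) lengths <- default_len
  if (is.function(lengths)) {
    f <- lengths
    attr(f, "descriptor") <- "user function"
    return(f)
  }
  stopifnot(is.numeric(lengths), all(lengths >= 1))
  lengths <- as.integer(lengths)
  f <- if (length(lengths) == 1) {
    function(n) rep(lengths, n)
  } else {
    function(n) sample(lengths, n, replace = TRUE)
  }
  attr(f, "descriptor") <- paste0("empirical(", length(lengths), " lengths)")
  f
}

#' E-value for a bit score under a Gumbel null calibration
#'
#' @param calibration a `"null_calibration"`.
#' @param score bit score(s).
#' @param n_targets number of sequences searched.
#' @return expected number of false positives at or above `score`.
#' @export
evalue <- function(calibration, score, n_targets = 1) {
  stopifnot(inherits(calibration, "null_calibration"))
  n_targets * exp(-calibration$gumbel_lambda * (score - calibration$gumbel_mu))
}

#' Decoy-calibrated default bit thresholds
#'
#' Per-marker acceptance threshold = max decoy bit score + 2 bits, the
#' package's stand-in for externally curated E-value cutoffs.
#'
#' @param profiles named list of `"profile_model"`s.
#' @param n_decoys decoys per marker (>= 100); the default is large
#'   because the threshold is an empirical maximum and its tail position
#'   stabilizes only slowly with sample size.
#' @param lengths decoy length specifier, see [calibrate_null()]; the default
#'   calibrates at the longest query length the synthetic communities
#'   produce (150 aa), the conservative choice since local forward
#'   scores grow with the number of alignment entry points and hence
#'   with query length.
#' @param seed integer seed.
#' @return named numeric vector of thresholds (bits).
#' @export
default_bit_thresholds <- function(profiles, n_decoys = 2000,
                                   lengths = 150, seed = 1) {
  vapply(profiles, function(p)
    calibrate_null(p, n_samples = n_decoys, lengths = lengths,
                   seed = seed)$max_score + 2, numeric(1))
}

#' Construct a genome record
#'
#' @param genome_id identifier.
#' @param proteins named character vector of protein sequences.
#' @param metadata named list or one-row data.frame of genome metadata.
#' @return object of class `"genome_record"`.
#' @export
genome_record <- function(genome_id, proteins, metadata = list()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1)
  if (length(proteins) && is.null(names(proteins))) {
    names(proteins) <- sprintf("p%04d", seq_along(proteins))
  }
  structure(list(genome_id = genome_id, proteins = proteins,
                 metadata = metadata), class = "genome_record")
}

empty_hits <- function() {
  data.frame(genome_id = character(0), protein_id = character(0),
             marker_id = character(0), bit_score = numeric(0),
             e_value = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Search one proteome against a profile registry
#'
#' Every (protein, marker) pair scoring at or above the marker's bit
#' threshold is emitted as a hit; one protein may hit several markers.
#' Hits are sorted by (marker_id, descending bit_score, protein_id).
#'
#' @param profiles named list of `"profile_model"`s (names = marker ids).
#' @param genome a `"genome_record"`.
#' @param thresholds named numeric vector of per-marker bit thresholds.
#' @param calibrations optional named list of `"null_calibration"`s used
#'   to attach E-values.
#' @return a hits data.frame with columns genome_id, protein_id,
#'   marker_id, bit_score, e_value, source.
#' @export
search_proteome <- function(profiles, genome, thresholds,
                            calibrations = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  missing_thr <- setdiff(names(profiles), names(thresholds))
  if (length(missing_thr)) {
    stop("no bit threshold for marker(s): ", paste(missing_thr, collapse = ", "))
  }
  if (length(genome$proteins) == 0) return(empty_hits())
  n_prot <- length(genome$proteins)
  rows <- list()
  for (mid in names(profiles)) {
    scores <- vapply(genome$proteins, function(s)
      score_sequence(profiles[[mid]], s), numeric(1))
    keep <- which(scores >= thresholds[[mid]])
    if (!length(keep)) next
    ev <- if (!is.null(calibrations) && !is.null(calibrations[[mid]])) {
      evalue(calibrations[[mid]], scores[keep], n_targets = n_prot)
    } else rep(NA_real_, length(keep))
    rows[[mid]] <- data.frame(
      genome_id = genome$genome_id,
      protein_id = names(genome$proteins)[keep],
      marker_id = mid, bit_score = unname(scores[keep]),
      e_value = unname(ev), source = "native", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$marker_id, -hits$bit_score, hits$protein_id), ]
  rownames(hits) <- NULL
  hits
}

#' Read HMMER3 per-target tabular output (tblout)
#'
#' Parses the whitespace-separated tblout dialect: '#' comment lines;
#' target name in column 1, query (marker) name in column 3,
#' full-sequence E-value in column 5, full-sequence bit score in column
#' 6.  Target names of the form `genome|protein` are split into the two
#' ids.  Query names absent from the marker registry are flagged in the
#' `known_marker` column.
#'
#' @param path tblout file path.
#' @return hits data.frame (source = "hmmer_tblout") with an extra
#'   logical column `known_marker`.
#' @export
read_hmmer_tblout <- function(path) {
  if (!file.exists(path)) stop("tblout file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    out <- empty_hits()
    out$known_marker <- logical(0)
    return(out)
  }
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 18) {
      stop("malformed tblout row at line ", i, ": ", length(f),
           " fields (need >= 18)")
    }
    f
  })
  target <- vapply(rows, `[`, character(1), 1)
  query <- vapply(rows, `[`, character(1), 3)
  ev <- as.numeric(vapply(rows, `[`, character(1), 5))
  score <- as.numeric(vapply(rows, `[`, character(1), 6))
  has_gid <- grepl("|", target, fixed = TRUE)
  gid <- ifelse(has_gid, sub("\\|.*$", "", target), NA_character_)
  pid <- ifelse(has_gid, sub("^[^|]*\\|", "", target), target)
  out <- data.frame(genome_id = gid, protein_id = pid, marker_id = query,
                    bit_score = score, e_value = ev,
                    source = "hmmer_tblout",
                    known_marker = query %in% MARKER_IDS,
                    stringsAsFactors = FALSE)
  out
}

#' Write hits in the HMMER3 tblout dialect
#'
#' Emits the 18 mandatory columns (unused ones as '-'), so files
#' round-trip through [read_hmmer_tblout()].
#'
#' @param hits a hits data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hmmer_tblout <- function(hits, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target", con)
  for (i in seq_len(nrow(hits))) {
    target <- if (is.na(hits$genome_id[i])) hits$protein_id[i] else
      paste0(hits$genome_id[i], "|", hits$protein_id[i])
    writeLines(paste(target, "-", hits$marker_id[i], "-",
                     format(hits$e_value[i], scientific = TRUE, digits = 7),
                     format(hits$bit_score[i], digits = 7),
                     "0.0", "-", "-", "-", "-", "-", "-", "-", "-", "-", "-",
                     "-", "-", sep = " "), con)
  }
  invisible(path)
}

#' Write a hits table as TSV
#'
#' Pinned dialect: bit_score with six decimal places, e_value in
#' scientific notation.
#'
#' @param hits hits data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- hits[, c("genome_id", "protein_id", "marker_id", "bit_score",
                  "e_value", "source")]
  out$bit_score <- sprintf("%.6f", out$bit_score)
  out$e_value <- ifelse(is.na(out$e_value), "NA",
                        sprintf("%.6e", out$e_value))
  write_tsv(out, path)
}

#' Read a hits TSV written by [write_hits()]
#'
#' @param path file path.
#' @return hits data.frame.
#' @export
read_hits <- function(path) {
  h <- read_tsv(path)
  h$bit_score <- as.numeric(h$bit_score)
  h$e_value <- suppressWarnings(as.numeric(h$e_value))
  h
}
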