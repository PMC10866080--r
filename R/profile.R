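# Position-specific profile models built from marker reference alignments.
#
# The model is a lightweight profile HMM: M match states with
# position-specific emissions, one shared insert emission distribution
# (the background, by default), and per-position Match/Insert/Delete
# transitions estimated from alignment gap patterns.  Scoring is a local
# forward algorithm: free entry at any match state with uniform entry
# mass 1/M, free exit from any match state, flanking residues emitted by
# the background model so they cancel from the log-odds.

#' Uniform amino-acid background distribution
#'
#' @return named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
}

#' Build a profile model from a multiple sequence alignment
#'
#' Columns whose gap fraction is strictly below `occupancy_threshold`
#' become match states; the rest are insert columns.  Match emissions are
#' pseudocount-smoothed column frequencies,
#' `(count + pseudocount * background) / (n_contributing + pseudocount)`;
#' wildcard residues do not contribute counts.  Transitions are estimated
#' from observed gap patterns with Laplace (+1) smoothing.  Insert states
#' emit the background.
#'
#' @param msa an `"msa"` object from [read_alignment()].
#' @param occupancy_threshold real in (0, 1]; default 0.5.
#' @param pseudocount positive smoothing weight; default 1.
#' @param background length-20 emission distribution; default uniform.
#' @param marker_id label stored on the model.
#' @return an object of class `"profile_model"`.
#' @export
build_profile <- function(msa, occupancy_threshold = 0.5, pseudocount = 1,
                          background = uniform_background(),
                          marker_id = "unknown") {
  stopifnot(inherits(msa, "msa"),
            occupancy_threshold > 0, occupancy_threshold <= 1,
            pseudocount > 0, length(background) == 20)
  background <- background / sum(background)
  mat <- msa_matrix(msa)
  n_rows <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  is_match <- gap_frac < occupancy_threshold
  M <- sum(is_match)
  if (M == 0) {
    stop("degenerate profile: no column has gap fraction < ",
         occupancy_threshold)
  }

  match_cols <- which(is_match)
  match_emis <- matrix(0, nrow = M, ncol = 20,
                       dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(M)) {
    col <- mat[, match_cols[j]]
    col <- col[col %in% AA_ALPHABET]
    counts <- table(factor(col, levels = AA_ALPHABET))
    match_emis[j, ] <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
  }

  trans <- estimate_transitions(mat, is_match, M)

  structure(list(
    marker_id = marker_id,
    M = M,
    match_emis = match_emis,
    insert_emis = background,
    trans = trans,
    background = background,
    occupancy_threshold = occupancy_threshold,
    pseudocount = pseudocount
  ), class = "profile_model")
}

# Transition counting: each alignment row is converted to a state path
# (match column + residue -> M_j; match column + gap -> D_j; insert
# column + residue -> I_j with j = preceding match index).  Events before
# the first match state and transition types absent from the state graph
# (I->D, D->I) are ignored.  Laplace +1 smoothing over each source
# state's outgoing options: M_j -> {M,I,D}, I_j -> {I,M}, D_j -> {D,M}.
estimate_transitions <- function(mat, is_match, M) {
  K <- max(M - 1, 0)
  cMM <- cMI <- cMD <- cII <- cIM <- cDD <- cDM <- rep(0, K)
  match_index <- cumsum(is_match)
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    types <- character(0); pos <- integer(0)
    for (cc in seq_along(row)) {
      j <- match_index[cc]
      if (is_match[cc]) {
        types <- c(types, if (row[cc] == "-") "D" else "M"); pos <- c(pos, j)
      } else if (row[cc] != "-") {
        if (j >= 1) { types <- c(types, "I"); pos <- c(pos, j) }
      }
    }
    if (length(types) < 2) next
    for (k in seq_len(length(types) - 1)) {
      a <- types[k]; b <- types[k + 1]; j <- pos[k]
      if (j < 1 || j > K) next
      key <- paste0(a, b)
      ok_step <- switch(key,
        MM = , MD = , IM = , DD = , DM = pos[k + 1] == j + 1,
        MI = , II = pos[k + 1] == j,
        FALSE)
      if (!ok_step) next
      switch(key,
        MM = cMM[j] <- cMM[j] + 1, MI = cMI[j] <- cMI[j] + 1,
        MD = cMD[j] <- cMD[j] + 1, II = cII[j] <- cII[j] + 1,
        IM = cIM[j] <- cIM[j] + 1, DD = cDD[j] <- cDD[j] + 1,
        DM = cDM[j] <- cDM[j] + 1)
    }
  }
  mtot <- cMM + cMI + cMD + 3
  itot <- cII + cIM + 2
  dtot <- cDD + cDM + 2
  list(tMM = (cMM + 1) / mtot, tMI = (cMI + 1) / mtot, tMD = (cMD + 1) / mtot,
       tII = (cII + 1) / itot, tIM = (cIM + 1) / itot,
       tDD = (cDD + 1) / dtot, tDM = (cDM + 1) / dtot)
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model '", x$marker_id, "': ", x$M, " match states\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a profile model
#'
#' Per-position argmax of the match emissions; ties resolved towards the
#' alphabetically first residue for determinism.
#'
#' @param profile a `"profile_model"`.
#' @return a character scalar of length `M`.
#' @export
consensus_sequence <- function(profile) {
  stopifnot(inherits(profile, "profile_model"))
  paste(AA_ALPHABET[apply(profile$match_emis, 1, which.max)], collapse = "")
}

# Sample a sequence from the profile's match emissions, with `n_inserts`
# background-emitted insertions at uniform internal positions and
# per-residue substitution noise at `mutation_rate`.  Uses the current
# RNG stream (caller seeds).
emit_from_profile <- function(profile, n_inserts = 0, mutation_rate = 0) {
  M <- profile$M
  res <- vapply(seq_len(M), function(j)
    sample(AA_ALPHABET, 1, prob = profile$match_emis[j, ]), character(1))
  if (n_inserts > 0) {
    ins_res <- sample(AA_ALPHABET, n_inserts, replace = TRUE,
                      prob = profile$insert_emis)
    at <- sample(seq_len(M), n_inserts, replace = TRUE)
    parts <- split(ins_res, at)
    out <- character(0)
    for (j in seq_len(M)) {
      out <- c(out, res[j], parts[[as.character(j)]])
    }
    res <- out
  }
  if (mutation_rate > 0) {
    hit <- stats::runif(length(res)) < mutation_rate
    if (any(hit)) res[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  }
  paste(res, collapse = "")
}

# background-sampled decoy protein
emit_background <- function(length, background = uniform_background()) {
  paste(sample(AA_ALPHABET, length, replace = TRUE, prob = background),
        collapse = "")
}
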