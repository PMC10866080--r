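# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written against the model definitions, not against the
# package's implementation paths.

# Exhaustive path-enumeration forward score (linear-space sum over every
# local alignment path; entry at any match state with mass 1/M, exit
# from any match state with weight 1).  Practical for M <= 3, len <= 4.
enum_forward_bits <- function(profile, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx <- match(chars, aa)
  L <- length(idx)
  M <- profile$M
  tr <- profile$trans
  bg <- profile$background
  er <- function(j, i) {
    if (is.na(idx[i])) return(1)  # wildcard: background emission
    unname(profile$match_emis[j, idx[i]] / bg[idx[i]])
  }
  ir <- function(i) {
    if (is.na(idx[i])) return(1)
    unname(profile$insert_emis[idx[i]] / bg[idx[i]])
  }
  total <- 0
  at_match <- function(j, i, w) {
    total <<- total + w  # exit from this match state, weight 1
    if (j < M) {
      if (i < L) at_match(j + 1, i + 1, w * tr$tMM[j] * er(j + 1, i + 1))
      if (i < L) at_insert(j, i + 1, w * tr$tMI[j] * ir(i + 1))
      at_delete(j + 1, i, w * tr$tMD[j])
    }
  }
  at_insert <- function(j, i, w) {
    if (i < L) at_insert(j, i + 1, w * tr$tII[j] * ir(i + 1))
    if (i < L) at_match(j + 1, i + 1, w * tr$tIM[j] * er(j + 1, i + 1))
  }
  at_delete <- function(j, i, w) {
    if (j < M) {
      at_delete(j + 1, i, w * tr$tDD[j])
      if (i < L) at_match(j + 1, i + 1, w * tr$tDM[j] * er(j + 1, i + 1))
    }
  }
  for (j0 in seq_len(M)) {
    for (s in seq_len(L)) at_match(j0, s, (1 / M) * er(j0, s))
  }
  log2(total)
}

# A random valid profile model constructed directly (not via an MSA), to
# exercise the scorer over arbitrary parameter values.
random_profile <- function(M, seed) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rdirich <- function(k) { x <- rgamma(k, 1); x / sum(x) }
  match_emis <- t(vapply(seq_len(M), function(j) rdirich(20), numeric(20)))
  colnames(match_emis) <- aa
  K <- max(M - 1, 0)
  r3 <- t(vapply(seq_len(max(K, 1)), function(j) rdirich(3), numeric(3)))
  r2a <- t(vapply(seq_len(max(K, 1)), function(j) rdirich(2), numeric(2)))
  r2b <- t(vapply(seq_len(max(K, 1)), function(j) rdirich(2), numeric(2)))
  trans <- if (K == 0) {
    list(tMM = numeric(0), tMI = numeric(0), tMD = numeric(0),
         tII = numeric(0), tIM = numeric(0), tDD = numeric(0),
         tDM = numeric(0))
  } else {
    list(tMM = r3[seq_len(K), 1], tMI = r3[seq_len(K), 2],
         tMD = r3[seq_len(K), 3],
         tII = r2a[seq_len(K), 1], tIM = r2a[seq_len(K), 2],
         tDD = r2b[seq_len(K), 1], tDM = r2b[seq_len(K), 2])
  }
  structure(list(marker_id = "rand", M = M, match_emis = match_emis,
                 insert_emis = stats::setNames(rdirich(20), aa),
                 trans = trans,
                 background = stats::setNames(rep(1 / 20, 20), aa),
                 occupancy_threshold = 0.5, pseudocount = 1),
            class = "profile_model")
}

# Independent brute-force evaluation of the strategy rule definitions on
# a named logical vector of marker presence.
brute_force_strategies <- function(p, require_nird = TRUE) {
  fd <- p[["NirA"]]
  nadh <- if (require_nird) p[["NirB"]] & p[["NirD"]] else p[["NirB"]]
  c(ammonium_uptake = p[["AmtB"]],
    bnf = p[["NifH"]] & p[["NifD"]] & p[["NifK"]],
    fd_nitrite = fd,
    nadh_nitrite = nadh,
    nitrate_assim = p[["NasA"]] & (fd | nadh),
    urea = p[["UreC"]],
    cyanate = p[["CynS"]],
    chitin_depoly = p[["Chitinase"]],
    hexnac_assim = p[["HexNAcase"]],
    amino_acid_uptake = p[["APC"]] | p[["AGCS"]] | p[["BCCT"]] |
      p[["LIVCS"]] | p[["HAAAP"]])
}
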