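#' @useDynLib nstrat, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_WILDCARDS <- c("B", "Z", "X", "U", "O", "J")

# Deterministic 31-bit hash of a character label; arithmetic stays below
# 2^53 so it is exact in doubles on every platform.
hash_label <- function(name) {
  h <- 0
  for (x in utf8ToInt(name)) h <- (h * 31 + x) %% 2147483647
  h
}

#' Derive a named RNG substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; independent
#' stages (covariate sampling, homolog planting, decoys, bootstrap
#' replicates) draw from substreams derived by stable hashing of the
#' stream name, so re-running one stage never perturbs another.
#'
#' @param seed integer root seed.
#' @param name character stream label.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  s <- abs(as.numeric(seed)) %% 2147483647
  as.integer((s * 48271 + hash_label(name)) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Pinned TSV dialect: header row, tab delimiter, UTF-8, '.' decimal,
# no quoting.  Used by every stage writer so outputs diff byte-for-byte.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# Minimal FASTA io.  Sequences here are short synthetic proteins; a
# dependency-free reader keeps byte-identity trivial to reason about.
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path)
  idx <- cumsum(hdr)
  ids <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- unname(seqs)
  out
}

write_fasta <- function(seqs, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
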