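# Aligned-FASTA io and validation for marker reference alignments.

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' Rows must be equal length over the 20-letter amino-acid alphabet plus
#' gap (`-` or `.`).  Non-standard residues (B, Z, X, U, O, J) are kept
#' and later scored as background-frequency emissions.
#'
#' @param path path to an aligned FASTA file.
#' @return an object of class `"msa"`: list with `ids`, `rows` (character
#'   vector of aligned rows, upper case, gaps as `-`), `n_columns`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- tryCatch(read_fasta(path), error = function(e)
    stop("alignment format error in ", path, ": ", conditionMessage(e)))
  new_msa(names(seqs), unname(seqs), path = path)
}

new_msa <- function(ids, rows, path = "<in-memory>") {
  rows <- toupper(rows)
  rows <- gsub("\\.", "-", rows)
  if (length(rows) < 2) stop("alignment needs >= 2 rows: ", path)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment (row lengths ", paste(unique(widths), collapse = "/"),
         "): ", path)
  }
  legal <- c(AA_ALPHABET, AA_WILDCARDS, "-")
  chars <- unique(strsplit(paste(rows, collapse = ""), "")[[1]])
  bad <- setdiff(chars, legal)
  if (length(bad)) stop("illegal alignment characters: ", paste(bad, collapse = ""))
  structure(list(ids = ids, rows = rows, n_columns = widths[1]),
            class = "msa")
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param msa an `"msa"` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  write_fasta(stats::setNames(msa$rows, msa$ids), path)
}

# character matrix view (rows x columns) of an msa
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$rows), " rows x ", x$n_columns, " columns\n", sep = "")
  invisible(x)
}
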