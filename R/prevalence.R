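# Bootstrapped prevalence estimation over the genome x strategy matrix.
#
# A non-parametric bootstrap over genomes counters uneven sampling
# depth: each replicate resamples genomes with replacement (or draws a
# capped number per taxon under the taxon-balanced scheme) and records
# the per-strategy count of genomes carrying it.  Summaries are the
# replicate median and the 2.5/97.5 percentiles with linear
# interpolation between order statistics.

#' Bootstrap per-strategy prevalence
#'
#' @param matrix logical/0-1 matrix, genomes x strategies (rownames =
#'   genome ids, colnames = strategies).
#' @param n_boot number of bootstrap replicates (>= 1); surveys of this
#'   kind conventionally use 1000.
#' @param seed integer seed.
#' @param scheme `"plain"` (resample n genomes with replacement) or
#'   `"taxon_balanced"` (per replicate draw `min(k, available)` genomes
#'   per taxon without replacement, k defaulting to the median per-taxon
#'   size).
#' @param taxonomy character vector of taxon labels per genome, required
#'   for the balanced scheme (default rank: phylum labels).
#' @param k per-taxon draw cap for the balanced scheme.
#' @return data.frame of class `"prevalence_estimates"`: strategy,
#'   point_count, point_proportion, boot_median, ci_low, ci_high,
#'   n_boot, scheme, seed.
#' @export
bootstrap_prevalence <- function(matrix, n_boot = 1000, seed = 1,
                                 scheme = c("plain", "taxon_balanced"),
                                 taxonomy = NULL, k = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(dim(matrix)) || nrow(matrix) == 0) stop("empty matrix")
  if (n_boot < 1) stop("n_boot must be >= 1")
  mode(matrix) <- "integer"
  n <- nrow(matrix)
  if (scheme == "taxon_balanced") {
    if (is.null(taxonomy)) stop("taxon_balanced scheme requires taxonomy")
    if (length(taxonomy) != n) stop("taxonomy length must match matrix rows")
    groups <- split(seq_len(n), taxonomy)
    sizes <- lengths(groups)
    empty <- sizes == 0
    if (any(empty)) {
      warning("skipping empty taxon/taxa: ",
              paste(names(groups)[empty], collapse = ", "))
      groups <- groups[!empty]
    }
    if (is.null(k)) k <- stats::median(lengths(groups))
  }
  counts <- with_seed(substream_seed(seed, "bootstrap"), {
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- if (scheme == "plain") {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(groups, function(g)
          if (length(g) <= k) g else sample(g, k)), use.names = FALSE)
      }
      colSums(matrix[idx, , drop = FALSE])
    }, numeric(ncol(matrix)))
    # vapply drops to a vector when the matrix has one column
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
    t(reps)
  })
  qs <- apply(counts, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              type = 7, names = FALSE)
  out <- data.frame(
    strategy = colnames(matrix),
    point_count = colSums(matrix),
    point_proportion = colMeans(matrix),
    boot_median = qs[1, ],
    ci_low = qs[2, ],
    ci_high = qs[3, ],
    n_boot = n_boot, scheme = scheme, seed = seed,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("prevalence_estimates", "data.frame")
  out
}

#' Rank strategies by bootstrapped prevalence
#'
#' Sorts by boot_median descending, breaking ties by point_count then
#' strategy name, and annotates whether each strategy's CI overlaps the
#' next-ranked one's.
#'
#' @param estimates a `"prevalence_estimates"` data.frame.
#' @return the estimates, sorted, with columns `rank` and
#'   `ci_overlaps_next`.
#' @export
rank_strategies <- function(estimates) {
  if (anyDuplicated(estimates$strategy)) {
    stop("duplicate strategies in estimates")
  }
  ord <- order(-estimates$boot_median, -estimates$point_count,
               estimates$strategy)
  out <- estimates[ord, ]
  out$rank <- seq_len(nrow(out))
  nxt <- c(seq_len(nrow(out))[-1], NA)
  out$ci_overlaps_next <- c(
    out$ci_low[-nrow(out)] <= out$ci_high[-1], NA)
  rownames(out) <- NULL
  out
}

#' Write prevalence estimates as TSV
#'
#' @param estimates a `"prevalence_estimates"` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_prevalence <- function(estimates, path) {
  write_tsv(as.data.frame(estimates), path)
}
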