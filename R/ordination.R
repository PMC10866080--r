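# Ordination of the binary genome x strategy matrix: column-centred PCA
# and projection-form logistic PCA fit by majorization-minimization on
# the Bernoulli deviance (Landgraf-Lee formulation with the natural
# parameters of the saturated model scaled by a constant m).

#' Ordinate the binary strategy matrix
#'
#' `method = "pca"`: column-centred singular value decomposition;
#' constant columns are retained (they contribute zero variance).
#' `method = "logistic_pca"`: the binary matrix is mapped to saturated
#' natural parameters `m * (2X - 1)` (m = 4 by default), the column-mean
#' offset is fixed, and an orthonormal loading matrix U is updated by a
#' majorization-minimization step whose quadratic surrogate is solved by
#' an eigendecomposition; the Bernoulli deviance is non-increasing
#' across iterations.  Constant columns are dropped with a warning for
#' logistic PCA.
#'
#' @param matrix logical/0-1 matrix, genomes x strategies.
#' @param method `"pca"` or `"logistic_pca"`.
#' @param k number of components (>= 1).
#' @param m natural-parameter scale constant for logistic PCA.
#' @param max_iter,tol iteration cap and relative deviance tolerance.
#' @return object of class `"ordination_result"`: `method`, `scores`
#'   (n x k), `loadings` (d x k), `explained` (variance fractions for
#'   PCA; deviance trace for logistic PCA), `k`, `converged`,
#'   `iterations`.
#' @export
ordinate <- function(matrix, method = c("pca", "logistic_pca"), k = 2,
                     m = 4, max_iter = 200, tol = 1e-6) {
  method <- match.arg(method)
  X <- as.matrix(matrix)
  mode(X) <- "numeric"
  if (k < 1) stop("k must be >= 1")
  if (nrow(unique(X)) < k + 1) {
    stop("matrix needs >= k + 1 distinct rows")
  }
  if (method == "pca") {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    ev <- pc$sdev^2
    res <- list(method = "pca",
                scores = pc$x[, seq_len(kk), drop = FALSE],
                loadings = pc$rotation[, seq_len(kk), drop = FALSE],
                explained = if (sum(ev) > 0) ev / sum(ev) else ev,
                k = kk, converged = TRUE, iterations = 0L,
                deviance_trace = NULL)
    class(res) <- "ordination_result"
    return(res)
  }
  const <- apply(X, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    warning("dropping constant column(s) for logistic PCA: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  d <- ncol(X)
  if (k > d) stop("k exceeds number of usable strategies")
  theta_sat <- m * (2 * X - 1)
  mu <- colMeans(theta_sat)
  Tc <- sweep(theta_sat, 2, mu)  # centred saturated natural parameters

  deviance_of <- function(U) {
    Theta <- sweep(Tc %*% U %*% t(U), 2, mu, "+")
    P <- stats::plogis(Theta)
    eps <- 1e-12
    -2 * sum(X * log(pmax(P, eps)) + (1 - X) * log(pmax(1 - P, eps)))
  }

  # init from linear PCA of the saturated natural parameters, so the
  # starting deviance equals the k-truncated linear-PCA baseline
  sv <- svd(Tc, nu = 0, nv = k)
  U <- sv$v
  dev <- deviance_of(U)
  trace <- dev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Theta <- sweep(Tc %*% U %*% t(U), 2, mu, "+")
    Z <- Theta + 4 * (X - stats::plogis(Theta))   # majorizer working response
    Zc <- sweep(Z, 2, mu)
    S <- crossprod(Zc, Tc) + crossprod(Tc, Zc) - crossprod(Tc)
    S <- (S + t(S)) / 2
    U <- eigen(S, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
    dev_new <- deviance_of(U)
    trace <- c(trace, dev_new)
    if (abs(dev - dev_new) <= tol * (abs(dev) + 1)) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  res <- list(method = "logistic_pca",
              scores = Tc %*% U,
              loadings = U,
              explained = trace,
              k = k, converged = converged, iterations = it,
              deviance_trace = trace)
  class(res) <- "ordination_result"
  res
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("ordination_result: ", x$method, ", k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Write ordination scores with ecosystem labels as TSV
#'
#' @param ord an `"ordination_result"`.
#' @param metadata data.frame with genome_id and ecosystem_category.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ordination <- function(ord, metadata, path) {
  sc <- as.data.frame(ord$scores)
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  gid <- rownames(ord$scores) %||% metadata$genome_id
  df <- data.frame(genome_id = gid, sc,
                   ecosystem_category = metadata$ecosystem_category[
                     match(gid, metadata$genome_id)],
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
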