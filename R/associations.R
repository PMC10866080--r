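# Association analyses over the strategy matrix and genome metadata:
# strategy-count scaling with genome size, nonparametric group
# comparisons, presence/absence models for costly strategies with
# family-level taxonomic adjustment, Poisson habitat models, and the
# host-associated vs free-living Welch contrast.

new_association_result <- function(model_id, formula, coefficients,
                                   statistics = list(), n_observations = NA,
                                   grouping = NULL) {
  structure(list(model_id = model_id, formula = formula,
                 coefficients = coefficients, statistics = statistics,
                 n_observations = n_observations, grouping = grouping),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result [", x$model_id, "] ", x$formula,
      "  (n = ", x$n_observations, ")\n", sep = "")
  if (is.data.frame(x$coefficients)) print(x$coefficients)
  invisible(x)
}

#' Strategy-count scaling with genome size
#'
#' Ordinary least squares of the per-genome strategy count on log10
#' genome length.
#'
#' @param counts integer vector of strategy counts.
#' @param genome_lengths genome lengths in bp (> 0).
#' @return `"association_result"` with slope/intercept estimates, SEs,
#'   t statistics, p-values, and R^2 in `statistics`.
#' @export
fit_count_scaling <- function(counts, genome_lengths) {
  if (length(counts) < 3) stop("need >= 3 genomes")
  if (any(genome_lengths <= 0)) stop("genome lengths must be > 0")
  x <- log10(genome_lengths)
  if (stats::sd(x) == 0) stop("zero variance in log genome length")
  fit <- stats::lm(counts ~ x)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "statistic", "p_value")
  co$term <- c("intercept", "log10_length")
  rownames(co) <- NULL
  new_association_result(
    "count_scaling", "strategy_count ~ log10(genome_length)",
    co[, c("term", "estimate", "se", "statistic", "p_value")],
    statistics = list(r_squared = sm$r.squared,
                      slope = co$estimate[2],
                      slope_p = co$p_value[2]),
    n_observations = length(counts))
}

#' Compare a statistic across groups (Kruskal-Wallis + pairwise Wilcoxon)
#'
#' Tie-corrected Kruskal-Wallis test followed by all pairwise two-sided
#' Wilcoxon rank-sum tests with Holm adjustment; each pair is annotated
#' with the direction of the median difference.  Groups with fewer than
#' two members are excluded with a warning.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @return `"association_result"`; `statistics` holds `kw_statistic`,
#'   `kw_df`, `kw_p`; `coefficients` is the pairwise table.
#' @export
group_compare <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  if (length(tab) < 2) stop("need >= 2 groups with >= 2 members each")
  kw <- stats::kruskal.test(values, factor(groups))
  gs <- sort(names(tab))
  pairs <- utils::combn(gs, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- values[groups == a]; vb <- values[groups == b]
    wt <- suppressWarnings(stats::wilcox.test(va, vb))
    data.frame(group_a = a, group_b = b, w_statistic = unname(wt$statistic),
               p_value = wt$p.value,
               direction = sign(stats::median(va) - stats::median(vb)),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, res)
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = "holm")
  new_association_result(
    "group_compare", "values ~ group (Kruskal-Wallis + pairwise Wilcoxon/Holm)",
    pw,
    statistics = list(kw_statistic = unname(kw$statistic),
                      kw_df = unname(kw$parameter),
                      kw_p = kw$p.value),
    n_observations = length(values),
    grouping = as.list(tab))
}

#' Logistic presence/absence model with respiration mode
#'
#' Logistic regression of a strategy's presence on respiration-mode
#' indicators (reference category: anaerobic), optionally adjusted for
#' taxonomic relatedness at the family level, either as family indicator
#' fixed effects (`"logistic_with_family"`, the default reading of
#' family-level adjustment) or as a random intercept
#' (`family_random = TRUE`, via lme4).
#'
#' Complete separation / degenerate outcomes are reported through the
#' `converged` flag and a diagnostic message rather than silently.
#'
#' @param presence logical/0-1 vector.
#' @param respiration_mode character vector of modes.
#' @param family_ids optional character vector of family labels.
#' @param model `"logistic"` or `"logistic_with_family"`.
#' @param family_random use a random intercept for family instead of
#'   fixed effects.
#' @return `"association_result"` with per-mode log-odds coefficients,
#'   Wald z and p; `statistics$converged`, `statistics$diagnostic`.
#' @export
fit_presence_model <- function(presence, respiration_mode, family_ids = NULL,
                               model = c("logistic", "logistic_with_family"),
                               family_random = FALSE) {
  model <- match.arg(model)
  y <- as.integer(presence)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: presence is constant (all ",
         unique(y), ")")
  }
  mode <- factor(respiration_mode)
  if ("anaerobic" %in% levels(mode)) {
    mode <- stats::relevel(mode, ref = "anaerobic")
  }
  df <- data.frame(y = y, mode = mode)
  use_family <- model == "logistic_with_family"
  if (use_family) {
    if (is.null(family_ids)) stop("family adjustment requires family_ids")
    df$fam <- factor(family_ids)
  }
  if (use_family && family_random) {
    fit <- lme4::glmer(y ~ mode + (1 | fam), data = df, family = stats::binomial())
    co <- as.data.frame(summary(fit)$coefficients)
    converged <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
    diagnostic <- paste(fit@optinfo$conv$lme4$messages %||% "", collapse = "; ")
  } else {
    form <- if (use_family) y ~ mode + fam else y ~ mode
    fit <- suppressWarnings(stats::glm(form, data = df,
                                       family = stats::binomial()))
    co <- as.data.frame(summary(fit)$coefficients)
    # separation shows up as huge coefficients with huge SEs
    sep <- any(abs(co[, 1]) > 15) || any(co[, 2] > 100)
    converged <- fit$converged && !sep
    diagnostic <- if (sep) "possible complete separation" else ""
  }
  names(co) <- c("estimate", "se", "statistic", "p_value")
  co$term <- rownames(co)
  rownames(co) <- NULL
  co <- co[, c("term", "estimate", "se", "statistic", "p_value")]
  new_association_result(
    "presence_model",
    paste0("presence ~ respiration_mode",
           if (use_family) if (family_random) " + (1|family)" else " + family"),
    co,
    statistics = list(converged = converged, diagnostic = diagnostic),
    n_observations = length(y))
}

#' Poisson habitat model for organic-strategy counts
#'
#' Log-linear Poisson model of the per-genome organic N strategy count
#' (0-5) on ecosystem indicators with family-level fixed-effect
#' adjustment; the reference ecosystem is the largest category.
#' Ecosystems whose genomes have all-zero counts are flagged unstable.
#'
#' @param organic_counts integer vector in 0..5.
#' @param ecosystem character vector of ecosystem categories.
#' @param family_ids optional character vector of family labels (fixed
#'   effects when supplied).
#' @return `"association_result"`; ecosystem coefficients carry an
#'   `unstable` flag.
#' @export
fit_habitat_counts <- function(organic_counts, ecosystem, family_ids = NULL) {
  if (any(organic_counts < 0)) stop("counts must be >= 0")
  eco <- as.character(ecosystem)
  if (length(unique(eco)) < 2) stop("need >= 2 ecosystems")
  ref <- names(sort(table(eco), decreasing = TRUE))[1]
  eco <- stats::relevel(factor(eco), ref = ref)
  df <- data.frame(y = organic_counts, eco = eco)
  form <- y ~ eco
  if (!is.null(family_ids)) {
    df$fam <- factor(family_ids)
    form <- y ~ eco + fam
  }
  fit <- stats::glm(form, data = df, family = stats::poisson())
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "statistic", "p_value")
  co$term <- rownames(co)
  rownames(co) <- NULL
  zero_eco <- names(which(tapply(organic_counts, eco, sum) == 0))
  co$unstable <- co$term %in% paste0("eco", zero_eco)
  co <- co[, c("term", "estimate", "se", "statistic", "p_value", "unstable")]
  new_association_result(
    "habitat_counts",
    paste0("organic_count ~ ecosystem",
           if (!is.null(family_ids)) " + family", " (Poisson)"),
    co,
    statistics = list(reference = ref,
                      unstable_ecosystems = zero_eco),
    n_observations = length(organic_counts))
}

#' Host-associated vs free-living contrast of inorganic fractions
#'
#' Welch two-sample t-test (unequal variances, Welch-Satterthwaite
#' degrees of freedom) of the per-genome inorganic strategy fraction
#' between free-living and host-associated genomes.
#'
#' @param inorganic_fractions numeric vector in [0, 1].
#' @param host_flag logical vector (TRUE = host-associated).
#' @return `"association_result"`; `statistics` holds `t`, `df`, `p`,
#'   `mean_free_living`, `mean_host_associated`.
#' @export
host_contrast <- function(inorganic_fractions, host_flag) {
  host_flag <- as.logical(host_flag)
  a <- inorganic_fractions[!host_flag]  # free-living
  b <- inorganic_fractions[host_flag]
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need >= 2 members")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    stop("t statistic undefined: zero variance in both groups with equal means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  co <- data.frame(term = c("mean_free_living", "mean_host_associated"),
                   estimate = c(mean(a), mean(b)),
                   se = c(stats::sd(a) / sqrt(length(a)),
                          stats::sd(b) / sqrt(length(b))),
                   statistic = NA_real_, p_value = NA_real_,
                   stringsAsFactors = FALSE)
  new_association_result(
    "host_contrast",
    "inorganic_fraction ~ host_associated (Welch t)",
    co,
    statistics = list(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value,
                      mean_free_living = mean(a),
                      mean_host_associated = mean(b)),
    n_observations = length(inorganic_fractions))
}

#' Serialize association results to JSON
#'
#' @param results list of `"association_result"`s.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_associations <- function(results, path) {
  payload <- lapply(results, function(r) {
    list(model_id = r$model_id, formula = r$formula,
         coefficients = r$coefficients, statistics = r$statistics,
         n_observations = r$n_observations, grouping = r$grouping)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
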