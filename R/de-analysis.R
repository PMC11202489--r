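# Differential expression between eggshell-colour groups: median-of-ratios
# library normalisation, method-of-moments NB dispersion with shrinkage,
# an exact conditional NB test, BH adjustment and threshold classification.

# Median-of-ratios size factors (geometric-mean reference over features
# expressed everywhere).
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  sf <- apply(counts, 2L, function(col)
    exp(median((log(col) - log_geo)[use & col > 0])))
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

#' Estimate per-feature negative-binomial dispersion
#'
#' Method-of-moments estimate on library-size-normalised counts,
#' `phi = max(0, (s^2 - mu) / mu^2)`, computed within each group (so
#' group mean differences do not inflate the estimate) and pooled across
#' groups weighted by degrees of freedom, then shrunk towards the trimmed
#' mean dispersion across features with weight 0.3.
#'
#' @param counts Integer count matrix (features x samples).
#' @param design A `study_design` covering the count columns.
#' @param groups Group labels to use (default: all groups in the design).
#' @param shrink Weight of the trimmed-mean target in (0, 1) (default 0.3).
#' @return Named numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(counts, design, groups = NULL, shrink = 0.3) {
  if (is.null(groups)) groups <- levels(design$group)
  norm <- normalize_counts(counts, design)
  per_group <- lapply(groups, function(g) {
    cols <- design_samples(design, g)
    if (length(cols) < 2L)
      stop("each group needs at least 2 replicates for dispersion estimation")
    x <- norm[, cols, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- apply(x, 1L, var)
    list(phi = (s2 - mu) / pmax(mu, 1e-8)^2, w = length(cols) - 1L)
  })
  w <- vapply(per_group, `[[`, numeric(1), "w")
  phi <- Reduce(`+`, Map(function(pg) pg$phi * pg$w, per_group)) / sum(w)
  phi <- pmax(phi, 0)
  target <- mean(phi, trim = 0.1)
  (1 - shrink) * phi + shrink * target
}

# Library-size-normalised pseudo-counts (median-of-ratios).
normalize_counts <- function(counts, design = NULL) {
  sf <- size_factors(counts)
  sweep(counts, 2L, sf, "/")
}

#' Exact conditional negative-binomial test for one feature
#'
#' Tests equality of group means for a single feature given
#' library-size-normalised pseudo-counts from two groups. Conditional on
#' the rounded combined total, the group-B total follows a beta-binomial
#' (negative-hypergeometric) law under the null of equal per-sample NB
#' means with common dispersion; the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param counts_a,counts_b Normalised pseudo-count vectors for the two
#'   groups (each length >= 1).
#' @param dispersion NB dispersion (>= 0; 0 gives the Poisson/binomial
#'   limit).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_test <- function(counts_a, counts_b, dispersion) {
  .assert_scalar_number(dispersion, "dispersion", lower = 0)
  a <- round(sum(counts_a)); b <- round(sum(counts_b))
  total <- a + b
  if (total == 0) return(1)
  n_a <- length(counts_a); n_b <- length(counts_b)
  phi <- max(dispersion, 1e-8)
  r_a <- n_a / phi; r_b <- n_b / phi
  mu_per <- total / (n_a + n_b)
  k <- 0:total
  logp <- dnbinom(k, size = r_b, mu = n_b * mu_per, log = TRUE) +
    dnbinom(total - k, size = r_a, mu = n_a * mu_per, log = TRUE)
  logp <- logp - max(logp)
  p_all <- exp(logp) / sum(exp(logp))
  # The relative tolerance guards against ties lost to rounding; clamp so
  # the summed tail never exceeds 1 by floating-point residue.
  min(1, sum(p_all[p_all <= p_all[b + 1L] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; a validated
#' interface to the standard BH procedure.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of FDR-adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify differential expression status
#'
#' A feature is `up` when its log2 fold change exceeds `lfc_cutoff` and the
#' selected significance test passes, `down` when the fold change is below
#' `-lfc_cutoff` with significance, otherwise `ns`. In `"fdr"` mode
#' significance means `FDR < alpha` (strict); in `"pvalue"` mode it means
#' `p <= alpha` (non-strict), the convention used when adjusted values
#' leave too few calls.
#'
#' @param log2fc,p,fdr Numeric vectors of equal length.
#' @param mode `"fdr"` or `"pvalue"`.
#' @param lfc_cutoff Absolute log2 fold-change threshold (default 1).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
classify_de <- function(log2fc, p, fdr, mode = c("fdr", "pvalue"),
                        lfc_cutoff = 1, alpha = 0.05) {
  mode <- match.arg(mode)
  sig <- if (mode == "fdr") fdr < alpha else p <= alpha
  ifelse(sig & log2fc > lfc_cutoff, "up",
         ifelse(sig & log2fc < -lfc_cutoff, "down", "ns"))
}

#' Differential expression between two groups
#'
#' Runs the package's exact NB test for every feature of a count matrix
#' between the two groups of a comparison: counts are normalised by
#' median-of-ratios size factors, per-feature dispersions estimated with
#' [estimate_dispersion()] (over all design groups), p-values computed
#' with [nb_test()], adjusted with [bh_adjust()], and classified with
#' [classify_de()]. The log2 fold change uses a pseudo-count so all-zero
#' groups stay finite: `log2((mean_A + pseudo) / (mean_B + pseudo))` for
#' comparison `A_vs_B` (positive = up in A).
#'
#' @param counts Integer count matrix (features x samples).
#' @param design A `study_design` covering the count columns.
#' @param comparison Character of length 2, `c("A", "B")`, or a string
#'   `"A_vs_B"`.
#' @param mode Significance mode, `"fdr"` (default) or `"pvalue"`.
#' @param lfc_cutoff,alpha Classification thresholds (defaults 1, 0.05).
#' @param pseudo_count Added to normalised group means for the fold change
#'   (default 1).
#' @param dispersion Optional fixed dispersion (scalar or per-feature);
#'   estimated when `NULL`.
#' @return Data.frame of class `"de_result"`: `feature`, `comparison`,
#'   `base_mean`, `log2fc`, `p`, `fdr`, `status`.
#' @examples
#' d <- make_design()
#' tr <- data.frame(feature = "feat_0001", comparison = "DB_vs_PK",
#'                  log2fc = 3)
#' m <- simulate_counts(d, 50, truth = tr, seed = 1)
#' res <- de_test(m, d, c("DB", "PK"))
#' res[res$feature == "feat_0001", ]
#' @export
de_test <- function(counts, design, comparison = c("DB", "PK"),
                    mode = c("fdr", "pvalue"), lfc_cutoff = 1, alpha = 0.05,
                    pseudo_count = 1, dispersion = NULL) {
  mode <- match.arg(mode)
  if (length(comparison) == 1L) comparison <- parse_comparison(comparison)
  stopifnot(length(comparison) == 2L,
            all(comparison %in% levels(design$group)))
  norm <- normalize_counts(counts, design)
  cols_a <- design_samples(design, comparison[1L])
  cols_b <- design_samples(design, comparison[2L])
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, design)
  dispersion <- rep_len(dispersion, nrow(counts))

  mean_a <- rowMeans(norm[, cols_a, drop = FALSE])
  mean_b <- rowMeans(norm[, cols_b, drop = FALSE])
  log2fc <- log2((mean_a + pseudo_count) / (mean_b + pseudo_count))
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_test(norm[i, cols_a], norm[i, cols_b], dispersion[i]), numeric(1))
  fdr <- bh_adjust(p)
  out <- data.frame(
    feature = rownames(counts),
    comparison = paste(comparison, collapse = "_vs_"),
    base_mean = (mean_a + mean_b) / 2,
    log2fc = log2fc, p = p, fdr = fdr,
    status = classify_de(log2fc, p, fdr, mode = mode,
                         lfc_cutoff = lfc_cutoff, alpha = alpha),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("DE result %s: %d features (%d up, %d down)\n",
              x$comparison[1L], nrow(x), sum(x$status == "up"),
              sum(x$status == "down")))
  NextMethod()
}
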