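#' Simulate negative-binomial count matrices with planted fold changes
#'
#' Draws a features-by-samples matrix of read counts from a negative-binomial
#' model (variance = mu + dispersion * mu^2) under a [make_design()] layout,
#' optionally planting differential expression. A planted row of `truth` with
#' comparison `"A_vs_B"` and effect `log2fc` sets the group-A mean to the
#' group-B mean times `2^log2fc`, matching the convention that a positive
#' log2 fold change in "A vs. B" means up-regulation in A. Rows of `truth`
#' are applied in order, so chained comparisons (e.g. `DB_vs_PK` followed by
#' `DB_vs_DP`) propagate consistently.
#'
#' @param design A `study_design` from [make_design()].
#' @param features Character vector of feature identifiers, or a single
#'   integer (features are then named `feat_0001`, ...).
#' @param truth Optional data.frame with columns `feature`, `comparison`
#'   (`"A_vs_B"`) and `log2fc` describing planted differential expression.
#'   `NULL` plants nothing (all-null matrix).
#' @param baseline_mean Mean count of an unperturbed feature (default 100).
#' @param dispersion NB dispersion phi (> 0); values below 1e-12 fall back to
#'   Poisson sampling.
#' @param seed Optional integer seed; identical seeds give identical
#'   matrices.
#' @return Integer matrix (features x samples) with dimnames.
#' @examples
#' d <- make_design()
#' tr <- data.frame(feature = "feat_0001", comparison = "DB_vs_PK", log2fc = 3)
#' m <- simulate_counts(d, 5, truth = tr, seed = 1)
#' @export
simulate_counts <- function(design, features, truth = NULL,
                            baseline_mean = 100, dispersion = 0.1,
                            seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  .assert_scalar_number(baseline_mean, "baseline_mean", lower = 0,
                        strict_lower = TRUE)
  .assert_scalar_number(dispersion, "dispersion", lower = 0,
                        strict_lower = TRUE)
  if (is.numeric(features) && length(features) == 1L)
    features <- sprintf("feat_%04d", seq_len(features))
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicate feature identifiers")

  group_means <- group_mean_matrix(features, design, truth, baseline_mean)
  .set_seed(seed)
  sample_counts_from_means(group_means, design, dispersion)
}

# Per-feature per-group mean matrix implied by a planted-truth table.
group_mean_matrix <- function(features, design, truth, baseline_mean) {
  groups <- levels(design$group)
  mu <- matrix(baseline_mean, nrow = length(features), ncol = length(groups),
               dimnames = list(features, groups))
  if (is.null(truth) || nrow(truth) == 0L) return(mu)
  stopifnot(all(c("feature", "comparison", "log2fc") %in% names(truth)))
  unknown <- setdiff(truth$feature, features)
  if (length(unknown))
    stop(sprintf("truth refers to unknown features: %s",
                 paste(head(unknown, 3), collapse = ", ")))
  for (i in seq_len(nrow(truth))) {
    cmp <- parse_comparison(truth$comparison[i], design)
    mu[truth$feature[i], cmp[1L]] <-
      mu[truth$feature[i], cmp[2L]] * 2^truth$log2fc[i]
  }
  mu
}

# NB (or Poisson-limit) sampling given a feature x group mean matrix.
sample_counts_from_means <- function(group_means, design, dispersion) {
  n_feat <- nrow(group_means)
  counts <- matrix(0L, nrow = n_feat, ncol = nrow(design),
                   dimnames = list(rownames(group_means), design$sample))
  for (j in seq_len(nrow(design))) {
    mu_j <- group_means[, as.character(design$group[j])]
    counts[, j] <- if (dispersion < 1e-12) {
      rpois(n_feat, lambda = mu_j)
    } else {
      rnbinom(n_feat, mu = mu_j, size = 1 / dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

# The published top-3 up/down-regulated miRNAs per comparison: the 24
# signed log2 fold changes planted by table2_fixture().
table2_mirnas <- function() {
  data.frame(
    comparison = rep(c("DB_vs_PK", "LB_vs_PK", "DP_vs_PK", "DB_vs_DP"),
                     each = 6L),
    feature = c("miR-2995-x", "novel-m0026-5p", "gga-miR-3528",
                "miR-423-y", "novel-m0066-5p", "novel-m0067-5p",
                "miR-224-x", "miR-2995-x", "novel-m0026-5p",
                "gga-miR-2984-3p", "gga-miR-6552-3p", "gga-miR-6552-5p",
                "novel-m0093-3p", "novel-m0142-3p", "miR-2995-x",
                "miR-484-x", "gga-miR-6544-5p", "novel-m0096-3p",
                "novel-m0066-5p", "novel-m0067-5p", "gga-miR-6516-3p",
                "gga-miR-217-5p", "novel-m0136-5p", "gga-miR-6544-5p"),
    log2fc = c(5.91, 5.87, 4.21, -6.51, -6.65, -6.65,
               8.72, 7.37, 7.37, -5.07, -7.4, -8.49,
               5.32, 4.43, 3.84, -3.28, -4.51, -5.14,
               5.88, 5.88, 5.17, -3.69, -4.4, -5.09),
    direction = rep(rep(c("up", "down"), each = 3L), 4L),
    stringsAsFactors = FALSE
  )
}

#' Count fixture planting the published miRNA fold-change table
#'
#' Generates a seeded miRNA count matrix over the default 13-sample design in
#' which the 24 reported top up/down-regulated miRNAs are planted at exactly
#' their published signed log2 fold changes (per comparison), embedded among
#' null features. Because several miRNAs appear in more than one comparison
#' (e.g. `miR-2995-x` in three of them), group means are solved jointly: the
#' pink control group anchors the `*_vs_PK` comparisons and `DB_vs_DP` rows
#' chain off whichever of the two groups is already constrained. Each
#' feature's largest group mean is scaled to `baseline_mean` so that even
#' features spanning a 2^12 dynamic range keep their weakly expressed groups
#' measurable.
#'
#' @param seed Optional integer seed.
#' @param n_null Number of additional unperturbed features (default 200).
#' @param baseline_mean Largest group mean per planted feature (default
#'   2000).
#' @param dispersion NB dispersion (default 0.05).
#' @return A list with `counts` (integer matrix), `design`, `expected`
#'   (data.frame: `feature`, `comparison`, `log2fc`, `direction` -- the
#'   planted classifications), `null_features` (ids expected `ns`), and
#'   `group_means` (the feature-by-group mean matrix the counts were drawn
#'   from, whose ratios encode the planted fold changes exactly).
#' @export
table2_fixture <- function(seed = NULL, n_null = 200, baseline_mean = 2000,
                           dispersion = 0.05) {
  design <- make_design()
  tab <- table2_mirnas()
  planted <- unique(tab$feature)
  nulls <- sprintf("null_%03d", seq_len(n_null))
  groups <- levels(design$group)

  # Relative group means per planted feature: PK = 1 anchors the
  # *_vs_PK rows; DB_vs_DP rows chain off the constrained side.
  rel <- matrix(NA_real_, nrow = length(planted), ncol = length(groups),
                dimnames = list(planted, groups))
  rel[, "PK"] <- 1
  for (i in order(tab$comparison != "DB_vs_PK")) {  # PK-anchored rows first
    cmp <- parse_comparison(tab$comparison[i])
    f <- tab$feature[i]
    a <- cmp[1L]; b <- cmp[2L]
    if (is.na(rel[f, b]) && !is.na(rel[f, a])) {
      rel[f, b] <- rel[f, a] * 2^(-tab$log2fc[i])
    } else {
      if (is.na(rel[f, b])) rel[f, b] <- 1
      rel[f, a] <- rel[f, b] * 2^tab$log2fc[i]
    }
  }
  rel[is.na(rel)] <- 1
  mu_planted <- rel / apply(rel, 1L, max) * baseline_mean

  mu <- rbind(mu_planted,
              matrix(100, nrow = n_null, ncol = length(groups),
                     dimnames = list(nulls, groups)))
  .set_seed(seed)
  counts <- sample_counts_from_means(mu, design, dispersion)
  list(counts = counts, design = design, expected = tab,
       null_features = nulls, group_means = mu)
}
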