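#' Construct the four-group eggshell-colour study design
#'
#' Builds the sample layout used throughout the package: four groups of hens
#' classified by the colour of the eggs they lay -- dark blue (`DB`), light
#' blue (`LB`), dark brown/greenish (`DP`) and pink (`PK`, the control) --
#' with a configurable number of replicate birds per group. Samples are named
#' deterministically as group label plus replicate index (`DB1`, `DB2`, ...).
#'
#' The default layout has 13 samples (3, 3, 4, 3), the replicate structure of
#' the uterine shell-gland study this package emulates.
#'
#' @param replicates Integer vector of length 4: number of replicates for
#'   `DB`, `LB`, `DP` and `PK`, in that order. Every entry must be at least 2
#'   (a single replicate supports neither dispersion estimation nor rank
#'   correlation).
#' @return A data.frame of class `"study_design"` with columns `sample`
#'   (character) and `group` (factor with levels `DB`, `LB`, `DP`, `PK`).
#' @examples
#' d <- make_design()
#' table(d$group)
#' @export
make_design <- function(replicates = c(3L, 3L, 4L, 3L)) {
  groups <- c("DB", "LB", "DP", "PK")
  if (length(replicates) != 4L || anyNA(replicates) || !is.numeric(replicates))
    stop("'replicates' must be four non-missing integers (DB, LB, DP, PK)")
  replicates <- as.integer(replicates)
  if (any(replicates < 2L))
    stop("each group needs at least 2 replicates")
  design <- data.frame(
    sample = unlist(mapply(function(g, n) paste0(g, seq_len(n)),
                           groups, replicates, SIMPLIFY = FALSE)),
    group = factor(rep(groups, replicates), levels = groups),
    stringsAsFactors = FALSE
  )
  rownames(design) <- NULL
  class(design) <- c("study_design", "data.frame")
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d samples in %d groups (%s)\n",
              nrow(x), nlevels(x$group),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

# Samples belonging to one group, in design order.
design_samples <- function(design, group) {
  design$sample[design$group == group]
}

# Parse "A_vs_B" into c(A, B), validating against the design's group levels.
parse_comparison <- function(comparison, design = NULL) {
  parts <- strsplit(comparison, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(sprintf("malformed comparison '%s' (expected 'A_vs_B')", comparison))
  if (!is.null(design) && !all(parts %in% levels(design$group)))
    stop(sprintf("comparison '%s' names groups absent from the design",
                 comparison))
  parts
}
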