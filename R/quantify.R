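# Expression metrics: TPM (tag counts per million), FPKM, and the
# 2^-ddCt relative-expression statistic for RT-qPCR.

#' Transcripts per million for small-RNA tag counts
#'
#' Per-sample scaling of counts to a library size of one million:
#' `count * 1e6 / column total`. No transcript-length term is applied --
#' small-RNA tags are length-homogeneous, so this is the counts-per-million
#' reading of TPM used for miRNA quantification. Columns of the result sum
#' to exactly 1e6.
#'
#' @param counts Non-negative count matrix (features x samples) with
#'   positive column sums.
#' @return Numeric matrix of TPM values.
#' @examples
#' tpm(matrix(c(50, 50), 2, 1, dimnames = list(c("a", "b"), "S1")))
#' @export
tpm <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample needs a positive count total")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `count * 1e9 / (length * column total)`. The library size is the column
#' total of the analysed matrix.
#'
#' @param counts Non-negative count matrix (features x samples).
#' @param lengths Positive feature lengths in nucleotides, one per row
#'   (recycled by name when named).
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths))
    stop("feature lengths missing for some rows")
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample needs a positive count total")
  sweep(counts / lengths, 2L, totals, "/") * 1e9
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `ddCt = (Ct_target,exp - Ct_ref,exp) - (Ct_target,ctl -
#' Ct_ref,ctl)` and returns `2^-ddCt`, the fold change of the target gene
#' in the experimental condition relative to the control, normalised to a
#' reference gene. Replicate Ct values within a (gene, condition) cell are
#' averaged.
#'
#' @param ct Long-format data.frame with columns `gene`, `role` (`target`
#'   or `reference`), `condition` (`experimental` or `control`) and `ct`
#'   (cycles); a `sample` column is allowed and ignored.
#' @param target Target gene identifier.
#' @param reference Reference gene identifier; defaults to the single gene
#'   with role `"reference"`.
#' @return Relative expression (fold change) as a single number.
#' @examples
#' ct <- data.frame(gene = rep(c("g", "u6"), 2),
#'                  role = rep(c("target", "reference"), 2),
#'                  condition = rep(c("experimental", "control"), each = 2),
#'                  ct = c(20, 15, 22, 15))
#' delta_delta_ct(ct, "g")  # ddCt = -2 -> 4
#' @export
delta_delta_ct <- function(ct, target, reference = NULL) {
  stopifnot(all(c("gene", "role", "condition", "ct") %in% names(ct)))
  if (is.null(reference)) {
    reference <- unique(ct$gene[ct$role == "reference"])
    if (length(reference) != 1L)
      stop("reference gene ambiguous; pass 'reference' explicitly")
  }
  cell <- function(gene, condition) {
    v <- ct$ct[ct$gene == gene & ct$condition == condition]
    if (!length(v) || anyNA(v))
      stop(sprintf("missing Ct for gene '%s' in condition '%s'",
                   gene, condition))
    mean(v)
  }
  ddct <- (cell(target, "experimental") - cell(reference, "experimental")) -
          (cell(target, "control") - cell(reference, "control"))
  2^(-ddct)
}
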