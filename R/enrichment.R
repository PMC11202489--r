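# Hypergeometric over-representation analysis against user-supplied
# term -> gene maps, with the rich factor as effect size.

#' Over-representation analysis of a gene set
#'
#' For every term of a term->gene map, computes the upper-tail
#' hypergeometric probability of observing at least the seen number of
#' gene-set members (`P(X >= k)`, `X ~ Hypergeometric(N, K, n)` with term
#' size `K`, gene-set size `n` and universe size `N`), alongside the BH
#' false-discovery rate and the rich factor `k / K`. The raw p-value is the
#' default significance column, with the FDR reported beside it. Genes
#' outside the universe are dropped with a warning.
#'
#' @param genes Character vector: the gene set (e.g. predicted targets of
#'   the differential miRNAs).
#' @param term2gene Data.frame with columns `term` and `gene`; an optional
#'   `name` column (term description) is carried through.
#' @param universe Background gene ids; defaults to all genes in
#'   `term2gene`.
#' @return Data.frame of class `"enrich_result"`: `term`, `k`, `n`, `K`,
#'   `N`, `rich_factor`, `p`, `fdr` (plus `name` when supplied).
#' @export
enrich <- function(genes, term2gene, universe = NULL) {
  stopifnot(all(c("term", "gene") %in% names(term2gene)))
  if (is.null(universe)) universe <- unique(term2gene$gene)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(sprintf("%d gene(s) outside the universe dropped",
                    length(outside)))
    genes <- intersect(genes, universe)
  }
  genes <- unique(genes)
  term2gene <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  n <- length(genes); N <- length(universe)
  terms <- unique(term2gene$term)
  members <- split(term2gene$gene, term2gene$term)
  K <- vapply(members, function(g) length(unique(g)), integer(1))[terms]
  k <- vapply(terms, function(t)
    length(intersect(genes, members[[t]])), integer(1))
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N,
                    rich_factor = k / K,
                    p = hypergeom_shared_test(k, n, K, N),
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p)
  if ("name" %in% names(term2gene))
    out$name <- term2gene$name[match(out$term, term2gene$term)]
  rownames(out) <- NULL
  class(out) <- c("enrich_result", "data.frame")
  out
}

#' Top enriched terms for a bubble chart
#'
#' Ranks enrichment results by ascending p-value, breaking ties by
#' descending rich factor and then term id, and returns the top `k` rows
#' in bubble-chart form (term, rich factor, p, gene count).
#'
#' @param results An `enrich_result` data.frame.
#' @param k Number of terms (default 20).
#' @return Data.frame with `term`, `rich_factor`, `p`, `fdr`, `k` (hit
#'   count), ordered by the ranking.
#' @export
top_terms <- function(results, k = 20) {
  ord <- order(results$p, -results$rich_factor, results$term)
  out <- results[head(ord, k), c("term", "rich_factor", "p", "fdr", "k"),
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a term->gene annotation map
#'
#' Random term memberships over a gene universe, for demonstration runs and
#' tests of the enrichment module.
#'
#' @param genes Gene universe (character vector).
#' @param n_terms Number of terms (default 30).
#' @param min_size,max_size Term size range (defaults 5 and 40).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `term` and `gene`.
#' @export
simulate_term_map <- function(genes, n_terms = 30, min_size = 5,
                              max_size = 40, seed = NULL) {
  .set_seed(seed)
  max_size <- min(max_size, length(genes))
  do.call(rbind, lapply(seq_len(n_terms), function(i) {
    size <- sample(min_size:max_size, 1L)
    data.frame(term = sprintf("TERM:%04d", i),
               gene = sample(genes, size), stringsAsFactors = FALSE)
  }))
}
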