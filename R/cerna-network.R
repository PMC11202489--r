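# ceRNA network inference: Spearman screening of miRNA-target pairs,
# positive circRNA-mRNA pairing with a shared-miRNA hypergeometric test,
# network assembly and connectivity ranking.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks under ties). Defined as 0
#' (with a message) when either vector is constant, so the screen never
#' propagates NaN.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    message("constant vector in Spearman correlation; returning 0")
    return(0)
  }
  cor(rx, ry)
}

#' Screen miRNA-target pairs by negative Spearman correlation
#'
#' Computes the Spearman correlation across shared samples for every
#' predicted miRNA-target edge and keeps pairs with `rho <= cutoff`
#' (non-strict at the boundary). Only predicted pairs are tested.
#'
#' @param expr_mirna,expr_rna Expression matrices (features x samples) with
#'   shared sample columns.
#' @param edges Data.frame of predicted edges (`mirna`, `target`).
#' @param cutoff Retention threshold (default -0.5).
#' @return Data.frame of class `"correlation_pairs"`: `mirna`, `target`,
#'   `rho`, `n`.
#' @export
screen_negative_pairs <- function(expr_mirna, expr_rna, edges,
                                  cutoff = -0.5) {
  shared <- intersect(colnames(expr_mirna), colnames(expr_rna))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  edges <- edges[edges$mirna %in% rownames(expr_mirna) &
                 edges$target %in% rownames(expr_rna), , drop = FALSE]
  rho <- vapply(seq_len(nrow(edges)), function(i)
    spearman_rho(expr_mirna[edges$mirna[i], shared],
                 expr_rna[edges$target[i], shared]), numeric(1))
  out <- data.frame(mirna = edges$mirna, target = edges$target, rho = rho,
                    n = length(shared), stringsAsFactors = FALSE)
  # Tiny tolerance so pairs sitting exactly on the boundary are retained
  # regardless of floating-point rounding in the rank correlation.
  out <- out[out$rho <= cutoff + 1e-12, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_pairs", "data.frame")
  out
}

#' Hypergeometric test for shared miRNAs
#'
#' Probability of observing at least `m` shared miRNAs between a circRNA
#' targeted by `n` miRNAs and an mRNA targeted by `K` miRNAs out of a
#' universe of `N`, i.e. `P(X >= m)` for `X ~ Hypergeometric(N, K, n)`.
#' The same kernel drives the enrichment module.
#'
#' @param m Shared miRNA count (vectorised).
#' @param n miRNA count of the first partner.
#' @param K miRNA count of the second partner.
#' @param N Universe size.
#' @return Upper-tail p-value(s) in (0, 1].
#' @export
hypergeom_shared_test <- function(m, n, K, N) {
  bad <- m > pmin(n, K) | n > N | K > N | m < 0
  if (any(bad)) stop("inconsistent hypergeometric counts")
  phyper(m - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assemble candidate ceRNA triples
#'
#' From the negatively screened miRNA-circRNA and miRNA-mRNA pairs, forms
#' every circRNA-mRNA pair sharing at least one screened miRNA, computes
#' their Spearman correlation and the shared-miRNA hypergeometric test,
#' and emits one triple per (circRNA, miRNA, mRNA) for pairs passing both
#' screens: `rho(circ, mRNA) > pos_cutoff` (strict) and `p < alpha`
#' (strict, unadjusted by default as in the original screen; set
#' `adjust = TRUE` for BH).
#'
#' @param neg_pairs Output of [screen_negative_pairs()] (may combine
#'   circRNA and mRNA targets; rows are split by membership in the two
#'   expression matrices).
#' @param expr_circ,expr_mrna Expression matrices for circRNAs and mRNAs.
#' @param pos_cutoff Positive-correlation threshold (default 0.5).
#' @param alpha Hypergeometric significance threshold (default 0.05).
#' @param universe Universe size for the test: `"screened"` (default, the
#'   distinct miRNAs in `neg_pairs`), `"expressed"` (all rows of a
#'   supplied miRNA matrix via `expr_mirna`), or an integer.
#' @param expr_mirna miRNA matrix, only needed for
#'   `universe = "expressed"`.
#' @param adjust Apply BH adjustment to the hypergeometric p before the
#'   alpha screen (default FALSE).
#' @return Data.frame of class `"cerna_triples"`: `circ`, `mirna`, `mrna`,
#'   `rho_mirna_circ`, `rho_mirna_mrna`, `rho_circ_mrna`, `shared`,
#'   `n_circ_mirnas`, `n_mrna_mirnas`, `universe`, `p`.
#' @export
build_cerna_triples <- function(neg_pairs, expr_circ, expr_mrna,
                                pos_cutoff = 0.5, alpha = 0.05,
                                universe = c("screened", "expressed"),
                                expr_mirna = NULL, adjust = FALSE) {
  circ_pairs <- neg_pairs[neg_pairs$target %in% rownames(expr_circ), ,
                          drop = FALSE]
  mrna_pairs <- neg_pairs[neg_pairs$target %in% rownames(expr_mrna), ,
                          drop = FALSE]
  empty <- data.frame(circ = character(), mirna = character(),
                      mrna = character(), rho_mirna_circ = numeric(),
                      rho_mirna_mrna = numeric(), rho_circ_mrna = numeric(),
                      shared = integer(), n_circ_mirnas = integer(),
                      n_mrna_mirnas = integer(), universe = integer(),
                      p = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("cerna_triples", "data.frame")
  if (!nrow(circ_pairs) || !nrow(mrna_pairs)) return(empty)

  if (is.numeric(universe)) {
    N <- as.integer(universe)
  } else {
    universe <- match.arg(universe)
    N <- if (universe == "screened") {
      length(unique(neg_pairs$mirna))
    } else {
      if (is.null(expr_mirna))
        stop("universe = 'expressed' needs 'expr_mirna'")
      nrow(expr_mirna)
    }
  }
  mir_by_circ <- split(circ_pairs$mirna, circ_pairs$target)
  mir_by_mrna <- split(mrna_pairs$mirna, mrna_pairs$target)
  shared_samples <- intersect(colnames(expr_circ), colnames(expr_mrna))

  combos <- expand.grid(circ = names(mir_by_circ),
                        mrna = names(mir_by_mrna),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  pair_p <- numeric(nrow(combos))
  pair_rho <- numeric(nrow(combos))
  pair_shared <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    mc <- mir_by_circ[[combos$circ[i]]]
    mm <- mir_by_mrna[[combos$mrna[i]]]
    shared <- intersect(mc, mm)
    pair_shared[[i]] <- shared
    if (!length(shared)) { pair_p[i] <- 1; next }
    pair_p[i] <- hypergeom_shared_test(length(shared), length(mc),
                                       length(mm), N)
    pair_rho[i] <- spearman_rho(expr_circ[combos$circ[i], shared_samples],
                                expr_mrna[combos$mrna[i], shared_samples])
  }
  has_shared <- lengths(pair_shared) > 0L
  p_screen <- pair_p
  if (adjust) p_screen[has_shared] <- bh_adjust(pair_p[has_shared])
  keep <- which(has_shared & pair_rho > pos_cutoff & p_screen < alpha)
  if (!length(keep)) return(empty)

  rho_lookup <- function(pairs) {
    setNames(pairs$rho, paste(pairs$mirna, pairs$target, sep = "\r"))
  }
  rho_mc <- rho_lookup(circ_pairs); rho_mm <- rho_lookup(mrna_pairs)
  out <- do.call(rbind, lapply(keep, function(i) {
    shared <- pair_shared[[i]]
    data.frame(
      circ = combos$circ[i], mirna = shared, mrna = combos$mrna[i],
      rho_mirna_circ = unname(rho_mc[paste(shared, combos$circ[i],
                                           sep = "\r")]),
      rho_mirna_mrna = unname(rho_mm[paste(shared, combos$mrna[i],
                                           sep = "\r")]),
      rho_circ_mrna = pair_rho[i], shared = length(shared),
      n_circ_mirnas = length(mir_by_circ[[combos$circ[i]]]),
      n_mrna_mirnas = length(mir_by_mrna[[combos$mrna[i]]]),
      universe = N, p = pair_p[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cerna_triples", "data.frame")
  out
}

#' Assemble a ceRNA network from emitted triples
#'
#' Builds the bipartite-typed network: circRNA-miRNA and miRNA-mRNA edges
#' from the triple list, with per-node connectivity (number of distinct
#' miRNA-mediated regulatory partners).
#'
#' @param triples A `cerna_triples` data.frame.
#' @return Object of class `"cerna_network"`: `triples`, `edges`
#'   (`source`, `interaction`, `target`), `nodes` (`id`, `type`,
#'   `degree`).
#' @export
cerna_network <- function(triples) {
  if (nrow(triples) == 0L) {
    edges <- data.frame(source = character(), interaction = character(),
                        target = character(), stringsAsFactors = FALSE)
    nodes <- data.frame(id = character(), type = character(),
                        degree = integer(), stringsAsFactors = FALSE)
    return(structure(list(triples = triples, edges = edges, nodes = nodes),
                     class = "cerna_network"))
  }
  edges <- unique(rbind(
    data.frame(source = triples$circ, interaction = "circ-miRNA",
               target = triples$mirna, stringsAsFactors = FALSE),
    data.frame(source = triples$mirna, interaction = "miRNA-mRNA",
               target = triples$mrna, stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  node_partner <- rbind(
    data.frame(id = edges$source, partner = edges$target,
               type = ifelse(edges$interaction == "circ-miRNA",
                             "circRNA", "miRNA")),
    data.frame(id = edges$target, partner = edges$source,
               type = ifelse(edges$interaction == "circ-miRNA",
                             "miRNA", "mRNA")))
  node_partner <- unique(node_partner)
  deg <- stats::aggregate(partner ~ id + type, node_partner, length)
  nodes <- data.frame(id = deg$id, type = deg$type, degree = deg$partner,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$type, -nodes$degree, nodes$id), ]
  rownames(nodes) <- NULL
  structure(list(triples = triples, edges = edges, nodes = nodes),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, c("circRNA", "miRNA", "mRNA")))
  tt[is.na(tt)] <- 0L
  cat(sprintf(
    "ceRNA network: %d triples; %d circRNAs, %d miRNAs, %d mRNAs; %d edges\n",
    nrow(x$triples), tt[["circRNA"]], tt[["miRNA"]], tt[["mRNA"]],
    nrow(x$edges)))
  invisible(x)
}

#' @export
summary.cerna_network <- function(object, top_k = 10, ...) {
  print(object)
  rk <- connectivity_rank(object, top_k = top_k)
  for (ty in names(rk)) {
    cat(sprintf("Top %s by connectivity:\n", ty))
    print(rk[[ty]], row.names = FALSE)
  }
  invisible(rk)
}

#' @export
plot.cerna_network <- function(x, top_k = 10, ...) {
  rk <- do.call(rbind, connectivity_rank(x, top_k = top_k))
  graphics::barplot(rk$degree, names.arg = rk$id, las = 2,
                    col = c(circRNA = "steelblue", miRNA = "grey60",
                            mRNA = "indianred")[rk$type],
                    ylab = "connectivity (distinct partners)", ...)
  invisible(x)
}

#' Rank network nodes by connectivity
#'
#' Descending degree within each node type; ties broken lexicographically
#' by node id so rankings are deterministic.
#'
#' @param network A `cerna_network`.
#' @param top_k Rows per type (default 10; larger than the node count
#'   returns all nodes).
#' @return Named list of data.frames (`circRNA`, `miRNA`, `mRNA`) with
#'   `id`, `type`, `degree`.
#' @export
connectivity_rank <- function(network, top_k = 10) {
  nodes <- network$nodes
  out <- lapply(c(circRNA = "circRNA", miRNA = "miRNA", mRNA = "mRNA"),
                function(ty) {
    sub <- nodes[nodes$type == ty, , drop = FALSE]
    sub <- sub[order(-sub$degree, sub$id), , drop = FALSE]
    rownames(sub) <- NULL
    head(sub, top_k)
  })
  out
}

#' Export a ceRNA network for Cytoscape and Sankey plotting
#'
#' Writes the full edge table (`source`, `interaction`, `target`; directly
#' importable into Cytoscape) and, optionally, a Sankey flow table
#' (`source`, `target`, `value` = number of supporting triples) restricted
#' to the top-`top_k` circRNAs and mRNAs by connectivity.
#'
#' @param network A `cerna_network`.
#' @param edge_path Path for the edge TSV.
#' @param sankey_path Optional path for the Sankey TSV.
#' @param top_k Connectivity cut for the Sankey table (default 10).
#' @return Invisibly, `edge_path`.
#' @export
export_network <- function(network, edge_path, sankey_path = NULL,
                           top_k = 10) {
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(sankey_path)) {
    rk <- connectivity_rank(network, top_k = top_k)
    tr <- network$triples
    tr <- tr[tr$circ %in% rk$circRNA$id & tr$mrna %in% rk$mRNA$id, ,
             drop = FALSE]
    flows <- rbind(data.frame(source = tr$circ, target = tr$mirna),
                   data.frame(source = tr$mirna, target = tr$mrna))
    if (nrow(flows)) {
      agg <- stats::aggregate(cbind(value = rep(1L, nrow(flows))) ~
                                source + target, flows, sum)
    } else {
      agg <- data.frame(source = character(), target = character(),
                        value = integer())
    }
    write.table(agg, sankey_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(edge_path)
}

#' Re-import an exported network edge table
#'
#' Round-trips [export_network()] output back into a `cerna_network`
#' edge data.frame.
#'
#' @param path Edge TSV path.
#' @return Data.frame with `source`, `interaction`, `target`.
#' @export
read_network_edges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
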