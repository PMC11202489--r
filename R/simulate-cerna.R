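#' Simulate expression matrices with planted ceRNA triples
#'
#' Generates miRNA, circRNA and mRNA expression matrices over a study design
#' in which a configurable number of circRNA--miRNA--mRNA triples carry the
#' correlation structure a competing-endogenous-RNA screen looks for: for
#' each planted triple a latent per-sample signal drives the miRNA up and
#' both the circRNA and the mRNA down (log-linear with slope `coupling`,
#' plus independent Gaussian log-noise of standard deviation `noise_sd`), so
#' miRNA-partner Spearman correlations are strongly negative and the
#' circRNA--mRNA correlation strongly positive. Decoy triples have the same
#' target-edge wiring but fully independent expression.
#'
#' Values are real-valued expression levels (lognormal around `baseline`),
#' i.e. already-normalised abundances as consumed by a rank-correlation
#' screen, not raw integer counts.
#'
#' @param design A `study_design`; needs at least 6 samples for a Spearman
#'   screen at |rho| >= 0.5 to be meaningful.
#' @param n_triples Number of planted triples (default 15). Each planted
#'   triple has its own miRNA, circRNA and mRNA.
#' @param n_decoys Number of decoy triples (default 200).
#' @param coupling Latent-signal slope in (0, 1] (default 0.9).
#' @param noise_sd Log-scale noise standard deviation (>= 0, default 0.2).
#' @param baseline Median expression level (default 100).
#' @param seed Optional integer seed.
#' @return A list: `mirna`, `circ`, `mrna` (numeric matrices, features x
#'   samples), `edges` (data.frame `mirna`, `target`, `target_class` --
#'   the miRNA target wiring for planted and decoy triples alike), `truth`
#'   (data.frame of the planted triples), and `design`.
#' @examples
#' sim <- simulate_cerna_expression(make_design(), n_triples = 2,
#'                                  n_decoys = 5, seed = 1)
#' cor(sim$mirna[1, ], sim$mrna[1, ], method = "spearman")
#' @export
simulate_cerna_expression <- function(design, n_triples = 15, n_decoys = 200,
                                      coupling = 0.9, noise_sd = 0.2,
                                      baseline = 100, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (nrow(design) < 6L)
    stop("need at least 6 samples for a +/-0.5 Spearman screen")
  .assert_scalar_number(coupling, "coupling", lower = 0, upper = 1,
                        strict_lower = TRUE)
  .assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  ns <- nrow(design)
  .set_seed(seed)

  ids <- function(prefix, tag, n) sprintf("%s_%s%03d", prefix, tag, seq_len(n))
  mir_ids  <- c(ids("mir", "P", n_triples),  ids("mir", "D", n_decoys))
  circ_ids <- c(ids("circ", "P", n_triples), ids("circ", "D", n_decoys))
  mrna_ids <- c(ids("mrna", "P", n_triples), ids("mrna", "D", n_decoys))
  n_all <- n_triples + n_decoys

  # Marginal log-sd of decoys matched to the planted features so the two
  # populations are indistinguishable by spread alone.
  decoy_sd <- sqrt(coupling^2 + noise_sd^2)
  latent <- matrix(rnorm(n_triples * ns), n_triples, ns)
  gen <- function(sign_coupling) {
    planted <- baseline * exp(sign_coupling * coupling * latent +
                              noise_sd * matrix(rnorm(n_triples * ns),
                                                n_triples, ns))
    decoy <- baseline * exp(decoy_sd * matrix(rnorm(n_decoys * ns),
                                              n_decoys, ns))
    rbind(planted, decoy)
  }
  mirna <- gen(+1); circ <- gen(-1); mrna <- gen(-1)
  dimnames(mirna) <- list(mir_ids, design$sample)
  dimnames(circ)  <- list(circ_ids, design$sample)
  dimnames(mrna)  <- list(mrna_ids, design$sample)

  edges <- data.frame(
    mirna = rep(mir_ids, 2L),
    target = c(circ_ids, mrna_ids),
    target_class = rep(c("circRNA", "mRNA"), each = n_all),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(circ = circ_ids[seq_len(n_triples)],
                      mirna = mir_ids[seq_len(n_triples)],
                      mrna = mrna_ids[seq_len(n_triples)],
                      stringsAsFactors = FALSE)
  list(mirna = mirna, circ = circ, mrna = mrna, edges = edges,
       truth = truth, design = design)
}
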