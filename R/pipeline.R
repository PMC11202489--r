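# End-to-end orchestration: synthetic data -> junction calling ->
# quantification -> differential expression -> target edges -> ceRNA
# network -> enrichment, with a manifest for reproducibility.

#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end run with validated defaults.
#' All randomness flows from `seed` through fixed per-stage offsets, so a
#' configuration determines its outputs byte for byte.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (default 1).
#' @param n_genes,n_circ,read_length,junction_depth,n_linear Genome/read
#'   simulation settings (see [simulate_genome_and_reads()]).
#' @param anchor_length,min_unique Junction-caller settings.
#' @param n_features,n_de,de_log2fc,baseline_mean,dispersion Count
#'   simulation and DE settings: `n_de` features are planted per
#'   comparison at `de_log2fc` (alternating sign).
#' @param comparisons Ordered group comparisons (default the four used in
#'   the eggshell study).
#' @param de_mode `"fdr"` or `"pvalue"`.
#' @param n_triples,n_decoys,coupling,noise_sd ceRNA simulation settings.
#' @param neg_cutoff,pos_cutoff,alpha ceRNA screen thresholds.
#' @param top_k Connectivity ranking depth.
#' @param n_terms Simulated annotation terms for the enrichment stage.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("cernet_run_"), seed = 1,
                            n_genes = 24, n_circ = 30, read_length = 100,
                            junction_depth = 3, n_linear = 5000,
                            anchor_length = 20, min_unique = 2,
                            n_features = 300, n_de = 10, de_log2fc = 3,
                            baseline_mean = 100, dispersion = 0.1,
                            comparisons = c("DB_vs_PK", "LB_vs_PK",
                                            "DP_vs_PK", "DB_vs_DP"),
                            de_mode = "fdr",
                            n_triples = 15, n_decoys = 200, coupling = 0.9,
                            noise_sd = 0.2, neg_cutoff = -0.5,
                            pos_cutoff = 0.5, alpha = 0.05, top_k = 10,
                            n_terms = 30) {
  cfg <- as.list(environment())
  .assert_scalar_number(cfg$seed, "seed")
  stopifnot(cfg$read_length >= 2 * cfg$anchor_length,
            cfg$junction_depth >= cfg$min_unique,
            cfg$de_mode %in% c("fdr", "pvalue"),
            cfg$neg_cutoff < 0, cfg$pos_cutoff > 0,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# Stage seeds derived from the master seed (kept well below 2^31).
.stage_seed <- function(seed, offset) {
  (as.integer(seed) * 101L + offset) %% 2000000011L
}

#' Run the full synthetic-demo pipeline
#'
#' Executes every stage on simulated inputs with planted truth: genome and
#' read simulation, back-splice junction calling with GT/AG validation and
#' support filtering, RPM/TPM quantification, exact-NB differential
#' expression over the configured comparisons, target-edge wiring, the
#' Spearman + hypergeometric ceRNA screen, connectivity ranking, and
#' over-representation analysis of the network mRNAs. All tables are
#' written under `config$out_dir` and a JSON manifest records the seed,
#' a parameter hash and per-stage row counts.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"cernet_run"` holding the per-stage results
#'   (`circ`, `de`, `triples`, `network`, `enrichment`, ...), the planted
#'   `truth`, and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- make_design()

  # Stage 1: toy genome and reads with planted junctions.
  sim <- simulate_genome_and_reads(
    n_genes = config$n_genes, n_circ = config$n_circ,
    read_length = config$read_length,
    junction_depth = config$junction_depth, n_linear = config$n_linear,
    anchor_length = config$anchor_length, samples = design$sample,
    seed = .stage_seed(config$seed, 1L))
  write_genome_fasta(sim$genome, file.path(config$out_dir, "genome.fa"))
  write_annotation_gtf(sim$annotation,
                       file.path(config$out_dir, "annotation.gtf"))
  write_reads_fastq(sim$reads, file.path(config$out_dir, "reads"))

  # Stage 2: junction calling, support filtering, annotation, RPM.
  circ <- detect_circrna(sim$genome, sim$reads, annotation = sim$annotation,
                         anchor_length = config$anchor_length,
                         min_unique = config$min_unique)
  write_circ_bed(circ, file.path(config$out_dir, "junctions.bed"))
  write_count_matrix(circ$support,
                     file.path(config$out_dir, "circ_support.tsv"))
  write_count_matrix(circ$rpm, file.path(config$out_dir, "circ_rpm.tsv"))

  # Stage 3: count simulation with planted DE, TPM, DE testing.
  de_truth <- do.call(rbind, lapply(seq_along(config$comparisons),
                                    function(ci) {
    idx <- (ci - 1L) * config$n_de + seq_len(config$n_de)
    data.frame(feature = sprintf("feat_%04d", idx),
               comparison = config$comparisons[ci],
               log2fc = config$de_log2fc * rep_len(c(1, -1), config$n_de),
               stringsAsFactors = FALSE)
  }))
  counts <- simulate_counts(design, config$n_features, truth = de_truth,
                            baseline_mean = config$baseline_mean,
                            dispersion = config$dispersion,
                            seed = .stage_seed(config$seed, 2L))
  write_count_matrix(counts, file.path(config$out_dir, "mirna_counts.tsv"))
  write_count_matrix(tpm(counts), file.path(config$out_dir,
                                            "mirna_tpm.tsv"))
  de <- do.call(rbind, lapply(config$comparisons, function(cmp)
    de_test(counts, design, cmp, mode = config$de_mode)))
  write.table(de, file.path(config$out_dir, "de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # Stage 4: ceRNA expression, negative screen, triples, network.
  cer <- simulate_cerna_expression(design, n_triples = config$n_triples,
                                   n_decoys = config$n_decoys,
                                   coupling = config$coupling,
                                   noise_sd = config$noise_sd,
                                   seed = .stage_seed(config$seed, 3L))
  for (cls in c("mirna", "circ", "mrna"))
    write_count_matrix(cer[[cls]],
                       file.path(config$out_dir,
                                 paste0("cerna_", cls, "_expr.tsv")))
  write.table(cer$edges, file.path(config$out_dir, "target_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  neg <- screen_negative_pairs(cer$mirna, rbind(cer$circ, cer$mrna),
                               cer$edges, cutoff = config$neg_cutoff)
  triples <- build_cerna_triples(neg, cer$circ, cer$mrna,
                                 pos_cutoff = config$pos_cutoff,
                                 alpha = config$alpha)
  write.table(triples, file.path(config$out_dir, "cerna_triples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  network <- cerna_network(triples)
  export_network(network, file.path(config$out_dir, "network_edges.tsv"),
                 file.path(config$out_dir, "network_sankey.tsv"),
                 top_k = config$top_k)
  ranks <- connectivity_rank(network, top_k = config$top_k)
  write.table(do.call(rbind, ranks),
              file.path(config$out_dir, "connectivity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # Stage 5: enrichment of the network mRNAs against a simulated term map.
  term_map <- simulate_term_map(rownames(cer$mrna),
                                n_terms = config$n_terms,
                                seed = .stage_seed(config$seed, 4L))
  enr <- enrich(unique(network$triples$mrna), term_map,
                universe = rownames(cer$mrna))
  write.table(top_terms(enr), file.path(config$out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    seed = config$seed,
    parameter_hash = .param_hash(config),
    stages = list(
      reads = nrow(sim$reads),
      planted_junctions = nrow(sim$truth),
      called_junctions = nrow(circ$candidates),
      ambiguous_reads = circ$n_ambiguous,
      de_features = nrow(counts),
      de_significant = sum(de$status != "ns"),
      screened_pairs = nrow(neg),
      triples = nrow(triples),
      network_nodes = nrow(network$nodes),
      enriched_terms = sum(enr$p < 0.05)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(config = config, design = design, genome_sim = sim,
                 circ = circ, counts = counts, de = de, cerna_sim = cer,
                 neg_pairs = neg, triples = triples, network = network,
                 enrichment = enr, manifest = manifest,
                 truth = list(junctions = sim$truth, de = de_truth,
                              triples = cer$truth)),
            class = "cernet_run")
}

# Deterministic parameter hash: md5 of the deparsed config, excluding the
# output location (two runs of the same parameters hash identically).
.param_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.cernet_run <- function(x, ...) {
  cat("cernet pipeline run\n")
  str(x$manifest$stages, no.list = TRUE)
  invisible(x)
}

#' Compare pipeline outputs with the planted truth
#'
#' Scores a synthetic run against its generator's ground truth: junction
#' sensitivity and precision (exact-coordinate matches), differential
#' expression sensitivity and sign accuracy over the planted features,
#' ceRNA triple sensitivity and the decoy fraction among emitted triples.
#'
#' @param run A `cernet_run` from [run_pipeline()].
#' @return A list of recovery statistics.
#' @export
validate_against_truth <- function(run) {
  stopifnot(inherits(run, "cernet_run"))
  jt <- run$truth$junctions
  called <- run$circ$candidates
  jkey <- function(d) paste(d$chrom, d$start, d$end, d$strand, sep = ":")
  junction_sensitivity <- if (nrow(jt)) mean(jkey(jt) %in% jkey(called))
                          else NA_real_
  junction_precision <- if (nrow(called)) mean(jkey(called) %in% jkey(jt))
                        else NA_real_

  det <- run$truth$de
  de <- run$de
  m <- merge(det, de, by = c("feature", "comparison"),
             suffixes = c("_true", ""))
  planted_called <- m$status != "ns"
  sign_ok <- ifelse(m$log2fc_true > 0, m$status == "up", m$status == "down")
  de_sensitivity <- mean(sign_ok)
  de_sign_accuracy <- if (any(planted_called))
    mean(sign_ok[planted_called]) else NA_real_

  tt <- run$truth$triples
  tkey <- function(d, a, b, c) paste(d[[a]], d[[b]], d[[c]], sep = ":")
  emitted <- run$triples
  triple_sensitivity <- if (nrow(tt))
    mean(tkey(tt, "circ", "mirna", "mrna") %in%
           tkey(emitted, "circ", "mirna", "mrna")) else NA_real_
  decoy_fraction <- if (nrow(emitted))
    mean(!tkey(emitted, "circ", "mirna", "mrna") %in%
           tkey(tt, "circ", "mirna", "mrna")) else 0

  list(junction_sensitivity = junction_sensitivity,
       junction_precision = junction_precision,
       de_sensitivity = de_sensitivity,
       de_sign_accuracy = de_sign_accuracy,
       triple_sensitivity = triple_sensitivity,
       decoy_fraction = decoy_fraction)
}
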