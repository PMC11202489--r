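test_that("planted breakpoints are GT/AG-flanked in the emitted sequence", {
  sim <- simulate_genome_and_reads(n_genes = 8, n_circ = 10,
                                   n_linear = 0, seed = 21)
  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(sim$truth))) {
    A <- sim$truth$start[i] + 1  # 1-based acceptor
    D <- sim$truth$end[i]        # 1-based donor
    if (sim$truth$strand[i] == "+") {
      expect_identical(substr(g, A - 2, A - 1), "AG")
      expect_identical(substr(g, D + 1, D + 2), "GT")
    } else {
      expect_identical(substr(g, A - 2, A - 1), "AC")
      expect_identical(substr(g, D + 1, D + 2), "CT")
    }
  }
})

test_that("each planted circle contributes the requested distinct reads", {
  sim <- simulate_genome_and_reads(n_genes = 8, n_circ = 5,
                                   junction_depth = 4, n_linear = 10,
                                   seed = 22)
  junc <- sim$reads[grepl("^junc_", sim$reads$read_id), ]
  expect_equal(nrow(junc), 20L)
  per_circle <- split(junc$sequence, sub("^junc_(\\d+)_.*", "\\1",
                                         junc$read_id))
  for (seqs in per_circle)
    expect_equal(length(unique(seqs)), 4L)
})

test_that("zero planted circles yields a purely collinear read set", {
  sim <- simulate_genome_and_reads(n_genes = 4, n_circ = 0,
                                   n_linear = 50, seed = 23)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(grepl("^lin_", sim$reads$read_id)))
})

test_that("generators are byte-deterministic under a fixed seed", {
  s1 <- simulate_genome_and_reads(n_genes = 5, n_circ = 3, n_linear = 20,
                                  seed = 24)
  s2 <- simulate_genome_and_reads(n_genes = 5, n_circ = 3, n_linear = 20,
                                  seed = 24)
  expect_identical(s1, s2)
  c1 <- simulate_cerna_expression(make_design(), n_triples = 3,
                                  n_decoys = 5, seed = 24)
  c2 <- simulate_cerna_expression(make_design(), n_triples = 3,
                                  n_decoys = 5, seed = 24)
  expect_identical(c1, c2)
})

test_that("read length below two anchors is rejected", {
  expect_error(simulate_genome_and_reads(read_length = 39),
               "twice the anchor")
})

test_that("emitted files round-trip through the package's own readers", {
  sim <- simulate_genome_and_reads(n_genes = 4, n_circ = 2, n_linear = 15,
                                   samples = c("S1", "S2"), seed = 25)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa")
  write_genome_fasta(sim$genome, fa)
  expect_identical(read_genome_fasta(fa), sim$genome)

  write_reads_fastq(sim$reads, file.path(dir, "reads"))
  back <- read_reads_fastq(file.path(dir, "reads"))
  ord <- function(d) {
    d <- d[order(d$read_id), ]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(back), ord(sim$reads))

  gtf <- file.path(dir, "ann.gtf")
  write_annotation_gtf(sim$annotation, gtf)
  back_ann <- read_annotation_gtf(gtf)
  expect_identical(back_ann[c("gene_id", "type", "chrom", "start", "end",
                              "strand", "exon_number")],
                   sim$annotation[c("gene_id", "type", "chrom", "start",
                                    "end", "strand", "exon_number")])

  m <- simulate_counts(make_design(), 6, seed = 26)
  cm <- file.path(dir, "counts.tsv")
  write_count_matrix(m, cm)
  expect_identical(read_count_matrix(cm), matrix(as.integer(m), nrow(m),
                                                 dimnames = dimnames(m)))
})

test_that("planted ceRNA triples carry the intended correlation signs", {
  sim <- simulate_cerna_expression(make_design(), n_triples = 5,
                                   n_decoys = 0, coupling = 1,
                                   noise_sd = 0, seed = 27)
  for (i in 1:5) {
    expect_equal(cor(sim$mirna[i, ], sim$mrna[i, ], method = "spearman"), -1)
    expect_equal(cor(sim$mirna[i, ], sim$circ[i, ], method = "spearman"), -1)
    expect_equal(cor(sim$circ[i, ], sim$mrna[i, ], method = "spearman"), 1)
  }
})

test_that("decoy pairs are uncorrelated on average", {
  rho <- vapply(1:60, function(r) {
    sim <- simulate_cerna_expression(make_design(), n_triples = 1,
                                     n_decoys = 20, seed = 500 + r)
    dec <- grep("_D", rownames(sim$mirna))
    mean(vapply(dec, function(i)
      cor(sim$mirna[i, ], sim$mrna[i, ], method = "spearman"), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rho)), 0.03)
})

test_that("coupling outside (0, 1] is rejected", {
  expect_error(simulate_cerna_expression(make_design(), coupling = 0),
               "range")
  expect_error(simulate_cerna_expression(make_design(), coupling = 1.5),
               "range")
  expect_error(simulate_cerna_expression(make_design(c(2, 2, 0, 0))),
               "at least 2")
})
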