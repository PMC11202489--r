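# A tiny hand-built genome used by several blocks: one plus-strand circle
# with AG|...circle...|GT flanks planted in random sequence. Offsets are
# chosen so anchor extension has a unique breakpoint.
make_toy_junction <- function(seed = 31, span = c(201, 400)) {
  set.seed(seed)
  g <- random_dna_str(1200)
  A <- span[1]; D <- span[2]
  substr(g, A - 2, A - 1) <- "AG"
  substr(g, D + 1, D + 2) <- "GT"
  # Kill accidental microhomology across the junction so extension is
  # unambiguous: base after donor (G of GT) differs from the acceptor base,
  # and the base before the acceptor (G of AG) differs from the donor base.
  substr(g, A, A) <- "A"
  substr(g, D, D) <- "T"
  read <- paste0(substr(g, D - 49, D), substr(g, A, A + 49))  # 100 nt, j=50
  list(genome = c(chr1 = g), A = A, D = D, read = read)
}

test_that("anchor extraction takes the terminal k-mers and validates length", {
  r <- strrep("ACGT", 25)  # 100 nt
  a <- extract_anchors(r, 20)
  expect_identical(a$left, substr(r, 1, 20))
  expect_identical(a$right, substr(r, 81, 100))
  a40 <- extract_anchors(substr(r, 1, 40), 20)
  expect_identical(paste0(a40$left, a40$right), substr(r, 1, 40))
  expect_error(extract_anchors(substr(r, 1, 39), 20), "anchors")
})

test_that("anchor mapping finds exact occurrences on both strands", {
  set.seed(32)
  g <- c(chr1 = random_dna_str(10000))
  idx <- genome_kmer_index(g, k = 20)
  p <- 4321
  anchor <- substr(g[["chr1"]], p, p + 19)
  hit <- map_anchor(anchor, idx)
  expect_true(any(hit$pos == p & hit$strand == "+"))
  rc_hit <- map_anchor(cernet:::revcomp(anchor), idx)
  expect_true(any(rc_hit$pos == p & rc_hit$strand == "-"))

  # Random anchors absent from the genome agree with an exhaustive scan.
  all_kmers <- substring(g[["chr1"]], 1:(10000 - 19), 20:10000)
  for (i in 1:25) {
    a <- random_dna_str(20)
    expected <- sum(all_kmers == a) + sum(all_kmers == cernet:::revcomp(a))
    expect_equal(nrow(map_anchor(a, idx)), expected)
  }
})

test_that("a junction-spanning read is called at exact coordinates", {
  toy <- make_toy_junction()
  cand <- call_backsplice(toy$read, toy$genome)
  expect_equal(cand$start, toy$A - 1)
  expect_equal(cand$end, toy$D)
  expect_identical(cand$strand, "+")
})

test_that("collinear reads and flank-less junctions yield no call", {
  toy <- make_toy_junction()
  linear <- substr(toy$genome[["chr1"]], 501, 600)
  expect_null(call_backsplice(linear, toy$genome))

  # Mutate the acceptor's AG flank away: the same read must now be
  # rejected, while disabling the flank check restores the call.
  g2 <- toy$genome
  substr(g2[["chr1"]], toy$A - 2, toy$A - 1) <- "CC"
  expect_null(call_backsplice(toy$read, g2))
  relaxed <- call_backsplice(toy$read, g2, require_splice_flank = FALSE)
  expect_equal(relaxed$start, toy$A - 1)
  expect_equal(relaxed$end, toy$D)
})

test_that("calling is invariant under reverse-complementing the read", {
  toy <- make_toy_junction(seed = 33)
  fwd <- call_backsplice(toy$read, toy$genome)
  rev <- call_backsplice(cernet:::revcomp(toy$read), toy$genome)
  # The reverse-complemented read reports the same span; its strand is the
  # opposite orientation but the flank check only passes on the planted one.
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$end, fwd$end)
  expect_identical(fwd$strand, "+")
  expect_identical(rev$strand, "+")
})

test_that("support filtering requires unique reads within one sample", {
  sup <- matrix(c(2L, 0L, 1L, 1L, 0L, 0L), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("DB1", "LB1")))
  expect_equal(filter_candidates(sup, 2), c(TRUE, FALSE, FALSE))

  # Two identical duplicate reads collapse to unique support 1.
  toy <- make_toy_junction(seed = 34)
  reads <- data.frame(read_id = c("r1", "r2"),
                      sequence = c(toy$read, toy$read),
                      sample = "S1", stringsAsFactors = FALSE)
  res <- detect_circrna(toy$genome, reads, min_unique = 2)
  expect_equal(nrow(res$candidates), 0L)
  res1 <- detect_circrna(toy$genome, reads, min_unique = 1)
  expect_equal(unname(res1$support[1, "S1"]), 1L)
})

test_that("planted junctions are recovered exactly from a full read set", {
  sim <- simulate_genome_and_reads(n_genes = 10, n_circ = 8,
                                   n_linear = 800,
                                   samples = c("S1", "S2"), seed = 35)
  res <- detect_circrna(sim$genome, sim$reads, annotation = sim$annotation)
  expect_setequal(junction_key(res$candidates), junction_key(sim$truth))
  expect_true(all(res$candidates$start < res$candidates$end))
  expect_true(all(res$candidates$end <= nchar(sim$genome[["chr1"]])))
  # Deterministic naming: ordered by chrom then start, zero-padded.
  expect_equal(res$candidates$circ_id,
               sprintf("novel_circ_%06d", seq_len(nrow(res$candidates))))
  expect_false(is.unsorted(res$candidates$start))
})

test_that("annotation classes partition the candidates", {
  cls <- c("annot_exons", "one_exon", "exon_intron", "intronic",
           "intergenic", "antisense")
  sim <- simulate_genome_and_reads(n_genes = 12, n_circ = 12,
                                   n_linear = 200, circ_classes = cls,
                                   seed = 36)
  res <- detect_circrna(sim$genome, sim$reads, annotation = sim$annotation)
  expect_false(anyNA(res$candidates$class))
  expect_equal(sum(table(res$candidates$class)), nrow(res$candidates))
  m <- merge(data.frame(k = junction_key(sim$truth),
                        planted = sim$truth$class),
             data.frame(k = junction_key(res$candidates),
                        called = res$candidates$class))
  expect_equal(m$called, m$planted)
})

test_that("RPM scales support by per-sample mapped totals", {
  sup <- matrix(c(5L, 0L, 3L), nrow = 1,
                dimnames = list("c1", c("S1", "S2", "S3")))
  rpm <- quantify_rpm(sup, c(S1 = 1e6, S2 = 1e6, S3 = 2e6))
  expect_equal(as.vector(rpm), c(5, 0, 1.5))
  expect_error(quantify_rpm(sup, c(S1 = 0, S2 = 1, S3 = 1)), "positive")
})
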