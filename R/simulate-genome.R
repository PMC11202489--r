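# Toy genome + read simulator for the back-splice junction caller.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Vectorised reverse complement on character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a toy genome with planted circRNAs and a spanning read set
#'
#' Builds a single-chromosome genome of multi-exon genes (random strand,
#' canonical GT/AG intron boundaries on the coding strand), plants
#' back-splice junctions of chosen genomic classes, forces the GT/AG (RNA
#' GU/AG) dinucleotides that flank a credible back-splice breakpoint into
#' the sequence, and then samples reads: for every planted circRNA,
#' `junction_depth` reads crossing the head-to-tail join at distinct
#' offsets (hence distinct sequences, so "unique" support is well defined),
#' plus a background of collinear linear-transcript reads.
#'
#' Planted junction reads are formed by concatenating the circle's 3' end
#' (the genomic segment ending at the donor) to its 5' start (the segment
#' beginning at the acceptor); reads from minus-strand circles are reverse
#' complemented. Coordinates in the returned truth table are 0-based
#' half-open `[start, end)` with `start` = acceptor and `end` = donor.
#'
#' @param n_genes Number of genes (default 24, giving a genome of roughly
#'   50 kb).
#' @param n_circ Number of planted circRNAs (default 30).
#' @param read_length Read length; must be at least twice `anchor_length`.
#' @param junction_depth Distinct junction-spanning reads per circle
#'   (>= 2, the unique-support filter's minimum; default 3).
#' @param n_linear Number of background collinear reads (default 5000).
#' @param circ_classes Genomic classes to plant, recycled over `n_circ`:
#'   any of `"annot_exons"`, `"one_exon"`, `"exon_intron"`, `"intronic"`,
#'   `"intergenic"`, `"antisense"` (default all `"annot_exons"`).
#' @param anchor_length Anchor length the downstream caller will use
#'   (default 20).
#' @param samples Sample names; junction reads of one circle all land in a
#'   single sample (cycling over samples), linear reads round-robin.
#' @param seed Optional integer seed.
#' @return A list: `genome` (named character vector of chromosome
#'   sequences), `annotation` (data.frame of gene/exon records, 1-based
#'   inclusive), `reads` (data.frame `read_id`, `sequence`, `sample`), and
#'   `truth` (data.frame of planted junctions: `circ_id`, `chrom`, `start`,
#'   `end`, `strand`, `class`).
#' @export
simulate_genome_and_reads <- function(n_genes = 24, n_circ = 30,
                                      read_length = 100, junction_depth = 3,
                                      n_linear = 5000,
                                      circ_classes = "annot_exons",
                                      anchor_length = 20,
                                      samples = "S1", seed = NULL) {
  if (read_length < 2 * anchor_length)
    stop("read_length must be at least twice the anchor length")
  if (n_circ > 0 && junction_depth < 2)
    stop("junction_depth must be at least 2 (the unique-support minimum)")
  .set_seed(seed)

  layout <- .gene_layout(n_genes)
  seq <- random_dna(layout$length)
  seq <- .force_intron_signals(seq, layout$exons)
  circles <- .place_circles(layout, n_circ, circ_classes)
  seq <- .force_circle_flanks(seq, circles)

  reads <- .sample_reads(seq, circles, read_length, junction_depth,
                         n_linear, anchor_length, samples)
  truth <- if (nrow(circles)) {
    data.frame(circ_id = sprintf("planted_%03d", seq_len(nrow(circles))),
               chrom = "chr1", start = circles$A - 1L, end = circles$D,
               strand = circles$strand, class = circles$class,
               stringsAsFactors = FALSE)
  } else {
    data.frame(circ_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               class = character(), stringsAsFactors = FALSE)
  }
  list(genome = c(chr1 = seq), annotation = layout$annotation,
       reads = reads, truth = truth)
}

# Sequential gene layout: exons/introns/gaps with realistic toy sizes.
.gene_layout <- function(n_genes) {
  pos <- 1L
  gene_rows <- list(); exon_rows <- list(); gaps <- list()
  for (g in seq_len(n_genes)) {
    gap <- sample(200:400, 1L)
    gaps[[g]] <- c(pos, pos + gap - 1L)
    pos <- pos + gap
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(3:5, 1L)
    starts <- ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      if (e > 1L) pos <- pos + sample(150:250, 1L)  # intron
      len <- sample(200:350, 1L)
      starts[e] <- pos; ends[e] <- pos + len - 1L
      pos <- pos + len
    }
    gid <- sprintf("gene_%02d", g)
    gene_rows[[g]] <- data.frame(gene_id = gid, type = "gene",
                                 chrom = "chr1", start = starts[1L],
                                 end = ends[n_ex], strand = strand,
                                 exon_number = NA_integer_,
                                 stringsAsFactors = FALSE)
    exon_rows[[g]] <- data.frame(gene_id = gid, type = "exon",
                                 chrom = "chr1", start = starts,
                                 end = ends, strand = strand,
                                 exon_number = seq_len(n_ex),
                                 stringsAsFactors = FALSE)
  }
  annotation <- rbind(do.call(rbind, gene_rows), do.call(rbind, exon_rows))
  annotation <- annotation[order(annotation$start, annotation$type != "gene"), ]
  rownames(annotation) <- NULL
  list(length = pos + 300L, annotation = annotation,
       exons = do.call(rbind, exon_rows),
       gaps = do.call(rbind, lapply(gaps, function(x)
         data.frame(start = x[1L], end = x[2L]))))
}

# Canonical splice signals at every intron boundary, on the gene's strand.
.force_intron_signals <- function(seq, exons) {
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      s <- ex$end[i] + 1L; e <- ex$start[i + 1L] - 1L  # intron, plus coords
      if (ex$strand[1L] == "+") {
        substr(seq, s, s + 1L) <- "GT"; substr(seq, e - 1L, e) <- "AG"
      } else {
        substr(seq, s, s + 1L) <- "CT"; substr(seq, e - 1L, e) <- "AC"
      }
    }
  }
  seq
}

# Choose circle spans [A, D] (1-based inclusive) for the requested classes.
.place_circles <- function(layout, n_circ, circ_classes) {
  if (n_circ == 0L)
    return(data.frame(A = integer(), D = integer(), strand = character(),
                      class = character(), stringsAsFactors = FALSE))
  classes <- rep_len(circ_classes, n_circ)
  bad <- setdiff(classes, c("annot_exons", "one_exon", "exon_intron",
                            "intronic", "intergenic", "antisense"))
  if (length(bad)) stop("unknown circRNA class: ", bad[1L])
  exons <- layout$exons
  genes <- unique(exons$gene_id)
  pair_used <- list()  # gene -> used first-exon indices for annot_exons
  gene_cursor <- 0L
  next_gene <- function() {
    gene_cursor <<- gene_cursor %% length(genes) + 1L
    genes[gene_cursor]
  }
  out <- vector("list", n_circ)
  for (i in seq_len(n_circ)) {
    cls <- classes[i]
    repeat {
      gid <- next_gene()
      ex <- exons[exons$gene_id == gid, ]
      ex <- ex[order(ex$start), ]
      strand <- ex$strand[1L]
      if (cls == "annot_exons") {
        avail <- setdiff(seq_len(nrow(ex) - 1L), pair_used[[gid]])
        if (!length(avail)) next
        j <- avail[1L]
        pair_used[[gid]] <- c(pair_used[[gid]], j)
        row <- data.frame(A = ex$start[j], D = ex$end[j + 1L],
                          strand = strand, class = cls)
      } else if (cls == "one_exon") {
        row <- data.frame(A = ex$start[1L] + 30L, D = ex$start[1L] + 179L,
                          strand = strand, class = cls)
      } else if (cls == "exon_intron") {
        row <- data.frame(A = ex$start[1L], D = ex$end[1L] + 80L,
                          strand = strand, class = cls)
      } else if (cls == "intronic") {
        s <- ex$end[1L] + 1L  # first intron
        row <- data.frame(A = s + 15L, D = s + 114L, strand = strand,
                          class = cls)
      } else if (cls == "antisense") {
        row <- data.frame(A = ex$start[2L] + 20L, D = ex$start[2L] + 159L,
                          strand = if (strand == "+") "-" else "+",
                          class = cls)
      } else {  # intergenic
        gap <- layout$gaps[min(i %% nrow(layout$gaps) + 1L,
                               nrow(layout$gaps)), ]
        row <- data.frame(A = gap$start + 30L, D = gap$start + 149L,
                          strand = sample(c("+", "-"), 1L), class = cls)
      }
      out[[i]] <- row
      break
    }
  }
  circles <- do.call(rbind, out)
  rownames(circles) <- NULL
  circles
}

# Write the back-splice flank dinucleotides into the genome: on the plus
# strand AG immediately before the acceptor and GT immediately after the
# donor; the reverse-complement pattern (AC / CT in plus coordinates) for
# minus-strand circles.
.force_circle_flanks <- function(seq, circles) {
  for (i in seq_len(nrow(circles))) {
    A <- circles$A[i]; D <- circles$D[i]
    if (circles$strand[i] == "+") {
      substr(seq, A - 2L, A - 1L) <- "AG"
      substr(seq, D + 1L, D + 2L) <- "GT"
    } else {
      substr(seq, A - 2L, A - 1L) <- "AC"
      substr(seq, D + 1L, D + 2L) <- "CT"
    }
  }
  seq
}

.sample_reads <- function(seq, circles, read_length, junction_depth,
                          n_linear, anchor_length, samples) {
  L <- read_length; k <- anchor_length
  ids <- character(0); seqs <- character(0); samp <- character(0)
  for (i in seq_len(nrow(circles))) {
    A <- circles$A[i]; D <- circles$D[i]
    offs <- sample(seq(k, L - k), junction_depth)
    rd <- vapply(offs, function(j) {
      paste0(substr(seq, D - j + 1L, D), substr(seq, A, A + (L - j) - 1L))
    }, character(1))
    if (circles$strand[i] == "-") rd <- revcomp(rd)
    ids <- c(ids, sprintf("junc_%03d_%02d", i, seq_along(offs)))
    seqs <- c(seqs, rd)
    samp <- c(samp, rep(samples[(i - 1L) %% length(samples) + 1L],
                        junction_depth))
  }
  if (n_linear > 0L) {
    pos <- sample.int(nchar(seq) - L + 1L, n_linear, replace = TRUE)
    strand <- sample(c("+", "-"), n_linear, replace = TRUE)
    rd <- substring(seq, pos, pos + L - 1L)
    rd[strand == "-"] <- revcomp(rd[strand == "-"])
    ids <- c(ids, sprintf("lin_%05d", seq_len(n_linear)))
    seqs <- c(seqs, rd)
    samp <- c(samp, samples[(seq_len(n_linear) - 1L) %% length(samples) + 1L])
  }
  data.frame(read_id = ids, sequence = seqs, sample = samp,
             stringsAsFactors = FALSE)
}
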