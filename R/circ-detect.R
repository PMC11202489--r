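# Anchor-based back-splice junction calling.
#
# The caller mirrors the find_circ-style procedure: take the terminal
# k-mers (anchors) of each read, map them exactly to the genome on both
# strands, keep reads whose anchors align head-to-tail (left anchor
# downstream of the right anchor), extend both anchors inward until the
# complete read is explained by two genomic segments meeting at one
# breakpoint pair, and require the canonical GT/AG (RNA GU/AG) splice
# dinucleotides at the breakpoints. Internal coordinates are 0-based
# half-open [start, end): start = acceptor, end = donor.

#' Extract the terminal anchors of a read
#'
#' @param read Read sequence (ACGT).
#' @param k Anchor length (default 20).
#' @return List with `left` (first `k` bases) and `right` (last `k` bases).
#' @export
extract_anchors <- function(read, k = 20) {
  n <- nchar(read)
  if (n < 2 * k)
    stop(sprintf("read of length %d cannot host two %d-mer anchors", n, k))
  list(left = substr(read, 1L, k), right = substr(read, n - k + 1L, n))
}

#' Build an exact-match k-mer index of a genome
#'
#' Hashes every plus-strand k-mer of every chromosome; reverse-strand hits
#' are resolved at query time by looking up the query's reverse complement.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k K-mer length (default 20).
#' @return An opaque index object for [map_anchor()] and [detect_circrna()].
#' @export
genome_kmer_index <- function(genome, k = 20) {
  tabs <- lapply(names(genome), function(chrom) {
    n <- nchar(genome[[chrom]])
    if (n < k) return(NULL)
    data.frame(chrom = chrom, pos = seq_len(n - k + 1L),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  kmers <- unlist(lapply(names(genome), function(chrom) {
    n <- nchar(genome[[chrom]])
    if (n < k) return(character(0))
    substring(genome[[chrom]], 1:(n - k + 1L), k:n)
  }))
  env <- list2env(split(seq_len(nrow(tab)), kmers), hash = TRUE)
  structure(list(env = env, tab = tab, k = k, genome = genome,
                 genome_int = lapply(genome, utf8ToInt)),
            class = "kmer_index")
}

.index_lookup <- function(index, kmer) {
  rows <- index$env[[kmer]]
  if (is.null(rows)) return(NULL)
  index$tab[rows, , drop = FALSE]
}

#' Map an anchor sequence to the genome
#'
#' Reports every exact occurrence of `anchor` (strand `+`) and of its
#' reverse complement (strand `-`), as 1-based plus-strand positions.
#'
#' @param anchor Anchor sequence, length equal to the index k.
#' @param index A [genome_kmer_index()] (or a genome vector, indexed on the
#'   fly).
#' @return Data.frame with columns `chrom`, `pos`, `strand` (zero rows if
#'   unmapped).
#' @export
map_anchor <- function(anchor, index) {
  if (!inherits(index, "kmer_index"))
    index <- genome_kmer_index(index, k = nchar(anchor))
  if (nchar(anchor) != index$k) stop("anchor length does not match index k")
  hit <- function(km, strand) {
    h <- .index_lookup(index, km)
    if (is.null(h)) return(NULL)
    h$strand <- strand
    h
  }
  out <- rbind(hit(anchor, "+"), hit(revcomp(anchor), "-"))
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Length of the exact match between `seq` starting at position `from_seq`
# and chromosome `chrom_seq` starting at `from_chrom`, up to `max_len`.
.match_len <- function(seq_int, from_seq, chrom_int, from_chrom, max_len) {
  n <- min(max_len, length(seq_int) - from_seq + 1L,
           length(chrom_int) - from_chrom + 1L)
  if (n <= 0L) return(0L)
  a <- seq_int[from_seq:(from_seq + n - 1L)]
  b <- chrom_int[from_chrom:(from_chrom + n - 1L)]
  mism <- which(a != b)
  if (length(mism)) mism[1L] - 1L else n
}

# All validated breakpoint pairs explaining one read, over both
# orientations. Returns a data.frame (possibly 0 or >1 rows) with columns
# chrom, start (0-based), end, strand.
.bsj_candidates <- function(read, rc_read, index, k, require_splice_flank) {
  L <- nchar(read)
  genome <- index$genome
  out <- list()
  for (ori in c("+", "-")) {
    seq <- if (ori == "+") read else rc_read
    left <- .index_lookup(index, substr(seq, 1L, k))
    right <- .index_lookup(index, substr(seq, L - k + 1L, L))
    if (is.null(left) || is.null(right)) next
    seq_int <- utf8ToInt(seq)
    for (i in seq_len(nrow(left))) {
      p <- left$pos[i]; chrom <- left$chrom[i]
      qs <- right$pos[right$chrom == chrom]
      if (!length(qs)) next
      chrom_int <- index$genome_int[[chrom]]
      # Longest inward extension of the left anchor.
      pmax_j <- k + .match_len(seq_int, k + 1L, chrom_int, p + k, L - 2L * k)
      for (q in qs) {
        if (p <= q) next  # collinear or overlapping: not head-to-tail
        # Longest backward extension of the right anchor: suffix of length
        # k + s matches genome ending at q + k - 1.
        smax <- 0L
        while (smax < L - 2L * k &&
               q - smax - 1L >= 1L &&
               seq_int[L - k - smax] == chrom_int[q - smax - 1L])
          smax <- smax + 1L
        j_lo <- max(k, L - k - smax)
        j_hi <- min(L - k, pmax_j)
        if (j_lo > j_hi) next
        for (j in j_lo:j_hi) {
          A <- q + k - L + j       # 1-based acceptor (first base of circle)
          D <- p + j - 1L          # 1-based donor (last base of circle)
          if (A > D || A < 3L || D + 2L > length(chrom_int)) next
          # The candidate strand is decided by which splice pattern
          # validates at the breakpoints (GT/AG in plus coordinates for a
          # plus-strand circle, its reverse complement AC/CT for a
          # minus-strand one), not by the read's scan orientation -- so
          # calling is invariant under reverse-complementing the read.
          g <- genome[[chrom]]
          strands <- if (require_splice_flank) {
            c("+", "-")[c(substr(g, D + 1L, D + 2L) == "GT" &&
                            substr(g, A - 2L, A - 1L) == "AG",
                          substr(g, A - 2L, A - 1L) == "AC" &&
                            substr(g, D + 1L, D + 2L) == "CT")]
          } else {
            ori
          }
          for (strand in strands)
            out[[length(out) + 1L]] <-
              data.frame(chrom = chrom, start = A - 1L, end = D,
                         strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Call a back-splice junction from a single read
#'
#' Returns a one-row candidate when the read's anchors map head-to-tail on
#' one chromosome and strand, inward extension explains the complete read
#' with a single breakpoint pair, and (by default) the donor is immediately
#' followed by GT and the acceptor immediately preceded by AG on the
#' candidate strand. Reads explained by more than one consistent breakpoint
#' pair are rejected as ambiguous.
#'
#' @param read Read sequence (length at least `2 * anchor_length`).
#' @param genome Named character vector of chromosomes, or a
#'   [genome_kmer_index()].
#' @param anchor_length Anchor length (default 20).
#' @param require_splice_flank Enforce the GT/AG flank check (default TRUE).
#' @return A data.frame with columns `chrom`, `start` (0-based), `end`,
#'   `strand`, or `NULL` with attribute `status` (`"unmapped"` or
#'   `"ambiguous"`).
#' @export
call_backsplice <- function(read, genome, anchor_length = 20,
                            require_splice_flank = TRUE) {
  if (nchar(read) < 2 * anchor_length)
    stop("read shorter than two anchors")
  index <- if (inherits(genome, "kmer_index")) genome
           else genome_kmer_index(genome, k = anchor_length)
  cand <- .bsj_candidates(read, revcomp(read), index, anchor_length,
                          require_splice_flank)
  if (nrow(cand) == 1L) cand else NULL
}

#' Detect circRNAs from a read set
#'
#' Runs [call_backsplice()] over every read, collapses duplicate reads
#' (identical sequence and breakpoint within a sample count once), filters
#' candidates by unique-read support, optionally annotates their genomic
#' context, and quantifies expression in back-spliced reads per million
#' mapped reads (RPM, with the per-sample read totals as mapped totals).
#' Candidates are named `novel_circ_NNNNNN`, ordered by chromosome then
#' start.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param reads Data.frame with columns `read_id`, `sequence`, `sample`.
#' @param annotation Optional annotation data.frame (see
#'   [read_annotation_gtf()]) used to classify candidates.
#' @param anchor_length Anchor length (default 20).
#' @param min_unique Minimum unique back-spliced reads required in at least
#'   one sample (default 2).
#' @param require_splice_flank Enforce the GT/AG flank check (default TRUE).
#' @return A list of class `"circ_result"`: `candidates` (data.frame
#'   `circ_id`, `chrom`, `start`, `end`, `strand`, `class`), `support`
#'   (unique-read count matrix, candidates x samples), `rpm` (RPM matrix),
#'   `mapped_totals`, and `n_ambiguous` (reads discarded for mapping to
#'   more than one consistent breakpoint pair).
#' @export
detect_circrna <- function(genome, reads, annotation = NULL,
                           anchor_length = 20, min_unique = 2,
                           require_splice_flank = TRUE) {
  index <- genome_kmer_index(genome, k = anchor_length)
  rc_all <- revcomp(reads$sequence)
  hits <- vector("list", nrow(reads))
  n_ambiguous <- 0L
  for (i in seq_len(nrow(reads))) {
    cand <- .bsj_candidates(reads$sequence[i], rc_all[i], index,
                            anchor_length, require_splice_flank)
    if (nrow(cand) == 1L) {
      cand$sample <- reads$sample[i]
      cand$sequence <- reads$sequence[i]
      hits[[i]] <- cand
    } else if (nrow(cand) > 1L) {
      n_ambiguous <- n_ambiguous + 1L
    }
  }
  hits <- do.call(rbind, hits)
  samples <- unique(reads$sample)
  mapped_totals <- vapply(samples, function(s) sum(reads$sample == s),
                          integer(1))

  if (is.null(hits) || nrow(hits) == 0L) {
    cand <- data.frame(circ_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), class = character(),
                       stringsAsFactors = FALSE)
    support <- matrix(0L, 0L, length(samples),
                      dimnames = list(NULL, samples))
    return(structure(list(candidates = cand, support = support,
                          rpm = support, mapped_totals = mapped_totals,
                          n_ambiguous = n_ambiguous),
                     class = "circ_result"))
  }

  # Unique read = unique (sequence, breakpoint) pair within a sample.
  hits <- unique(hits)
  key <- paste(hits$chrom, hits$start, hits$end, hits$strand, sep = ":")
  support <- table(key, factor(hits$sample, levels = samples))
  support <- matrix(as.integer(support), nrow = nrow(support),
                    dimnames = dimnames(support))
  cand <- unique(hits[c("chrom", "start", "end", "strand")])
  cand_key <- paste(cand$chrom, cand$start, cand$end, cand$strand, sep = ":")
  support <- support[match(cand_key, rownames(support)), , drop = FALSE]

  keep <- filter_candidates(support, min_unique = min_unique)
  cand <- cand[keep, , drop = FALSE]
  support <- support[keep, , drop = FALSE]
  ord <- order(cand$chrom, cand$start, cand$end)
  cand <- cand[ord, , drop = FALSE]
  support <- support[ord, , drop = FALSE]
  cand <- data.frame(circ_id = sprintf("novel_circ_%06d",
                                       seq_len(nrow(cand))),
                     cand, stringsAsFactors = FALSE)
  rownames(cand) <- rownames(support) <- cand$circ_id
  cand$class <- if (!is.null(annotation)) annotate_circ(cand, annotation)
                else rep(NA_character_, nrow(cand))
  structure(list(candidates = cand, support = support,
                 rpm = quantify_rpm(support, mapped_totals),
                 mapped_totals = mapped_totals, n_ambiguous = n_ambiguous),
            class = "circ_result")
}

#' @export
print.circ_result <- function(x, ...) {
  cat(sprintf(
    "circRNA detection: %d candidates across %d samples (%d ambiguous reads discarded)\n",
    nrow(x$candidates), ncol(x$support), x$n_ambiguous))
  invisible(x)
}

#' Filter back-splice candidates by unique-read support
#'
#' A candidate is kept when its unique back-spliced read count reaches
#' `min_unique` in at least one sample.
#'
#' @param support Integer matrix, candidates x samples.
#' @param min_unique Support threshold (default 2).
#' @return Logical vector over candidates.
#' @export
filter_candidates <- function(support, min_unique = 2) {
  if (nrow(support) == 0L) return(logical(0))
  apply(support, 1L, max) >= min_unique
}

#' Classify back-splice candidates by genomic context
#'
#' Assigns exactly one class per candidate: `annot_exons` (both breakpoints
#' on exon boundaries of one same-strand gene, spanning at least two
#' exons), `one_exon` (contained in a single exon), `exon_intron`
#' (same-strand gene, spanning exon and intron), `intronic` (fully within
#' an intron), `antisense` (overlapping gene on the opposite strand only)
#' or `intergenic` (no gene overlap).
#'
#' @param candidates Data.frame with `chrom`, `start` (0-based), `end`,
#'   `strand`.
#' @param annotation Annotation data.frame of gene/exon records.
#' @return Character vector of classes, one per candidate.
#' @export
annotate_circ <- function(candidates, annotation) {
  genes <- annotation[annotation$type == "gene", ]
  exons <- annotation[annotation$type == "exon", ]
  vapply(seq_len(nrow(candidates)), function(i) {
    A <- candidates$start[i] + 1L; D <- candidates$end[i]
    chrom <- candidates$chrom[i]; strand <- candidates$strand[i]
    ov <- genes$chrom == chrom & genes$start <= D & genes$end >= A
    if (!any(ov)) return("intergenic")
    same <- ov & genes$strand == strand
    if (!any(same)) return("antisense")
    # Same-strand gene with the largest overlap decides the class.
    cov <- pmin(genes$end, D) - pmax(genes$start, A) + 1L
    cov[!same] <- -1L
    g <- genes$gene_id[which.max(cov)]
    ex <- exons[exons$gene_id == g, ]
    ex_ov <- ex$start <= D & ex$end >= A
    if (any(A >= ex$start & D <= ex$end)) return("one_exon")
    if (A %in% ex$start && D %in% ex$end && sum(ex_ov) >= 2L)
      return("annot_exons")
    if (!any(ex_ov)) return("intronic")
    "exon_intron"
  }, character(1))
}

#' Quantify circRNA expression in RPM
#'
#' Back-spliced reads per million mapped reads: unique back-spliced read
#' support scaled by each sample's mapped-read total.
#'
#' @param support Integer matrix, candidates x samples.
#' @param mapped_totals Named numeric vector of per-sample mapped totals
#'   (all > 0), covering the support columns.
#' @return Numeric RPM matrix of the same shape as `support`.
#' @export
quantify_rpm <- function(support, mapped_totals) {
  totals <- mapped_totals[colnames(support)]
  if (anyNA(totals)) stop("mapped_totals missing for some samples")
  if (any(totals <= 0)) stop("mapped totals must be positive")
  sweep(support, 2L, totals, "/") * 1e6
}

#' Write called junctions as BED6
#'
#' Zero-based BED with the maximum per-sample unique support as score.
#'
#' @param result A `circ_result` from [detect_circrna()].
#' @param path File path.
#' @export
write_circ_bed <- function(result, path) {
  cand <- result$candidates
  score <- if (nrow(cand)) apply(result$support, 1L, max) else integer(0)
  writeLines(paste(cand$chrom, cand$start, cand$end, cand$circ_id,
                   score, cand$strand, sep = "\t"), path)
  invisible(path)
}
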