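# Readers/writers for the plain-text formats the pipeline exchanges.

#' Write and read genome FASTA
#'
#' Thin wrappers around Biostrings for the package's named-character-vector
#' genome representation.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path File path.
#' @return `read_genome_fasta` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write and read per-sample FASTQ read sets
#'
#' `write_reads_fastq` writes one FASTQ per sample (dummy base quality "I")
#' plus a `samples.tsv` map (columns `sample`, `fastq`);
#' `read_reads_fastq` reads such a directory back into the read table.
#'
#' @param reads Data.frame with columns `read_id`, `sequence`, `sample`.
#' @param dir Output directory (created if absent).
#' @return `read_reads_fastq` returns a data.frame like `reads`.
#' @export
write_reads_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(reads$sample)
  files <- file.path(dir, paste0(samples, ".fastq"))
  for (i in seq_along(samples)) {
    r <- reads[reads$sample == samples[i], ]
    writeLines(as.vector(rbind(paste0("@", r$read_id), r$sequence, "+",
                               strrep("I", nchar(r$sequence)))),
               files[i])
  }
  write.table(data.frame(sample = samples, fastq = basename(files)),
              file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(dir) {
  map <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(map)), function(i) {
    x <- Biostrings::readDNAStringSet(file.path(dir, map$fastq[i]),
                                      format = "fastq")
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               sequence = as.character(x), sample = map$sample[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write and read gene/exon annotation as GTF
#'
#' The package's annotation table (columns `gene_id`, `type`, `chrom`,
#' `start`, `end`, `strand`, `exon_number`; 1-based inclusive coordinates)
#' is written as standard GTF; reading goes through rtracklayer.
#'
#' @param annotation Annotation data.frame.
#' @param path File path.
#' @return `read_annotation_gtf` returns an annotation data.frame.
#' @export
write_annotation_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s";', annotation$gene_id)
  ex <- !is.na(annotation$exon_number)
  attrs[ex] <- paste0(attrs[ex],
                      sprintf(' exon_number "%d";', annotation$exon_number[ex]))
  writeLines(paste(annotation$chrom, "cernet", annotation$type,
                   annotation$start, annotation$end, ".",
                   annotation$strand, ".", attrs, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  out <- data.frame(gene_id = df$gene_id, type = as.character(df$type),
                    chrom = as.character(df$seqnames), start = df$start,
                    end = df$end, strand = as.character(df$strand),
                    exon_number =
                      if ("exon_number" %in% names(df))
                        as.integer(df$exon_number) else NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write and read feature-by-sample matrices as TSV
#'
#' First column `feature`, remaining columns one per sample.
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path File path.
#' @return `read_count_matrix` returns a numeric matrix.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}
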