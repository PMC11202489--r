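# miRNA target prediction: canonical seed matching (internal predictor)
# and import of externally predicted target tables.

.check_na_seq <- function(x, name) {
  x <- toupper(chartr("Uu", "Tt", x))
  if (grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains characters outside ACGU/ACGT", name))
  x
}

#' Find canonical seed-match target sites
#'
#' Scans a target sequence (5'->3') for reverse complements of the miRNA
#' seed and grades each site by the canonical hierarchy: `8mer` (perfect
#' match to miRNA positions 2-8 plus an A opposite position 1), `7mer-m8`
#' (positions 2-8), `7mer-A1` (positions 2-7 plus the A), `6mer`
#' (positions 2-7). Only the strongest type is reported per locus, so an
#' 8mer site is never additionally listed as a weaker type. U and T are
#' interchangeable on input.
#'
#' @param mirna miRNA sequence, 5'->3', length >= 8.
#' @param target Target RNA sequence, 5'->3'.
#' @param mirna_id,target_id Identifiers recorded in the output.
#' @return Data.frame of target edges: `mirna`, `target`, `site_type`,
#'   `position` (0-based start of the matched site in the target),
#'   `provenance` (`"internal"`). Zero rows when no seed match exists.
#' @examples
#' find_seed_matches("UGGAGUGUGACAAUGGUGUUUG", "AAGCACTTTA",
#'                   "let-7", "t1")
#' @export
find_seed_matches <- function(mirna, target, mirna_id = "mirna",
                              target_id = "target") {
  mirna <- .check_na_seq(mirna, "mirna")
  target <- .check_na_seq(target, "target")
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  core <- revcomp(substr(mirna, 2L, 7L))      # 6mer site, target 5'->3'
  m8 <- revcomp(substr(mirna, 8L, 8L))        # extra 5' match of the site
  # matchPattern reports overlapping occurrences, which gregexpr would miss
  hits <- Biostrings::start(
    Biostrings::matchPattern(core, Biostrings::DNAString(target)))
  if (!length(hits))
    return(data.frame(mirna = character(), target = character(),
                      site_type = character(), position = integer(),
                      provenance = character(), stringsAsFactors = FALSE))
  rows <- lapply(as.integer(hits), function(p) {   # p: 1-based core start
    has_m8 <- p > 1L && substr(target, p - 1L, p - 1L) == m8
    has_a1 <- p + 6L <= nchar(target) &&
      substr(target, p + 6L, p + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer"
            else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1"
            else "6mer"
    start <- if (has_m8) p - 1L else p
    data.frame(mirna = mirna_id, target = target_id, site_type = type,
               position = start - 1L, provenance = "internal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict seed-match targets for sets of sequences
#'
#' Applies [find_seed_matches()] over every miRNA/target combination.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @return Combined edge data.frame (see [find_seed_matches()]).
#' @export
predict_targets <- function(mirnas, targets) {
  combos <- expand.grid(m = names(mirnas), t = names(targets),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    find_seed_matches(mirnas[[combos$m[i]]], targets[[combos$t[i]]],
                      combos$m[i], combos$t[i])))
  rownames(out) <- NULL
  out
}

#' Import an externally predicted miRNA-target table
#'
#' Reads a TSV with columns `mirna` and `target` (extra columns such as
#' `site_type` or `position` are carried through), collapses duplicate
#' rows, marks provenance as `"imported"`, and reports malformed rows with
#' their line numbers. When an expression matrix is supplied, edges whose
#' miRNA is absent from it are kept but flagged with a warning.
#'
#' @param path TSV file path.
#' @param expressed Optional character vector (or matrix with rownames) of
#'   expressed miRNA ids used for the consistency warning.
#' @return Data.frame of target edges with `provenance = "imported"`.
#' @export
load_target_table <- function(path, expressed = NULL) {
  raw <- readLines(path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  n_col <- length(fields[[1L]])
  bad <- which(lengths(fields) != n_col)
  if (length(bad))
    stop(sprintf("malformed rows in '%s' at lines: %s", path,
                 paste(bad, collapse = ", ")))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "target") %in% names(df)))
    stop("target table needs 'mirna' and 'target' columns")
  blank <- which(!nzchar(df$mirna) | !nzchar(df$target))
  if (length(blank))
    stop(sprintf("malformed rows in '%s' at lines: %s", path,
                 paste(blank + 1L, collapse = ", ")))
  df <- unique(df)
  df$provenance <- "imported"
  if (!is.null(expressed)) {
    if (is.matrix(expressed)) expressed <- rownames(expressed)
    missing <- setdiff(unique(df$mirna), expressed)
    if (length(missing))
      warning(sprintf("%d imported miRNA id(s) not in the expression set: %s",
                      length(missing),
                      paste(head(missing, 3L), collapse = ", ")))
  }
  rownames(df) <- NULL
  df
}

#' Combine target-edge tables
#'
#' Unions or intersects two predictors' edge sets on the (miRNA, target)
#' pair, keeping first-table site annotations where present.
#'
#' @param x,y Target-edge data.frames with `mirna` and `target` columns.
#' @param op `"union"` (default) or `"intersect"`.
#' @return Combined edge data.frame.
#' @export
combine_target_tables <- function(x, y, op = c("union", "intersect")) {
  op <- match.arg(op)
  key <- function(d) paste(d$mirna, d$target, sep = "\r")
  if (op == "union") {
    out <- rbind(x[c("mirna", "target")], y[c("mirna", "target")])
    out <- unique(out)
  } else {
    out <- unique(x[key(x) %in% key(y), c("mirna", "target")])
  }
  rownames(out) <- NULL
  out
}
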