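# Independent oracles used across the suite. These re-derive expected
# values from first principles and must stay independent of the package's
# own code paths.

# Upper-tail hypergeometric probability by exhaustive subset enumeration:
# draw n from N with K marked, P(overlap >= m).
hyper_tail_enum <- function(m, n, K, N) {
  if (n == 0L) return(as.numeric(m <= 0))
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= m)
}

# Midranks by explicit sort-and-average (no call to rank()).
midrank_oracle <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Definitional Pearson correlation (no call to cor()).
pearson_oracle <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

spearman_oracle <- function(x, y) {
  pearson_oracle(midrank_oracle(x), midrank_oracle(y))
}

# Step-up BH: adjusted(i) = min_{j >= i} p(j) * m / j, clipped at 1,
# computed directly from the definition on the sorted vector.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m / seq(i, m)) * sorted[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force seed-site scan: test every target offset against explicit
# site strings for the four canonical types, strongest type per core locus.
seed_site_oracle <- function(mirna, target) {
  mirna <- chartr("Uu", "Tt", toupper(mirna))
  target <- chartr("Uu", "Tt", toupper(target))
  comp <- function(s) chartr("ACGT", "TGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  core <- rc(substr(mirna, 2, 7))
  m8 <- comp(substr(mirna, 8, 8))
  n <- nchar(target)
  hits <- list()
  for (p in seq_len(max(0, n - 5))) {
    if (substr(target, p, p + 5) != core) next
    has_m8 <- p > 1 && substr(target, p - 1, p - 1) == m8
    has_a1 <- p + 6 <= n && substr(target, p + 6, p + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    start0 <- if (has_m8) p - 2 else p - 1
    hits[[length(hits) + 1]] <- data.frame(site_type = type,
                                           position = start0)
  }
  if (!length(hits))
    return(data.frame(site_type = character(), position = integer()))
  do.call(rbind, hits)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

junction_key <- function(d) paste(d$chrom, d$start, d$end, d$strand, sep = ":")
triple_key <- function(d) paste(d$circ, d$mirna, d$mrna, sep = ":")
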