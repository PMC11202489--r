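test_that("Spearman correlation matches the definitional midrank formula", {
  expect_equal(spearman_rho(1:10, 2 * (1:10) + 3), 1)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               spearman_oracle(c(1, 2, 2, 3), c(1, 3, 2, 4)))
  # Invariance under strictly monotone transforms.
  set.seed(71)
  x <- rnorm(13); y <- rnorm(13)
  expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
  expect_equal(spearman_rho(x, y^3 + 5 * y), spearman_rho(x, y))
  expect_message(r0 <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_equal(r0, 0)
  expect_error(spearman_rho(1:4, 1:5), "length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("negative screening keeps predicted pairs at rho <= cutoff", {
  sim <- simulate_cerna_expression(make_design(), n_triples = 4,
                                   n_decoys = 30, coupling = 1,
                                   noise_sd = 0, seed = 72)
  neg <- screen_negative_pairs(sim$mirna, rbind(sim$circ, sim$mrna),
                               sim$edges)
  planted <- neg[grepl("_P", neg$target), ]
  expect_equal(sort(unique(planted$mirna)), sort(sim$truth$mirna))
  expect_equal(unname(planted$rho), rep(-1, nrow(planted)))
  expect_true(all(neg$rho <= -0.5))

  # Boundary is non-strict: rho == -0.5 is retained; the permutation
  # (3,4,5,1,2) of ranks 1..5 gives exactly -0.5.
  perm <- c(3, 4, 5, 1, 2)
  rho <- cor(1:5, perm, method = "spearman")
  expect_equal(rho, -0.5)  # guard: the chosen permutation hits -0.5
  em <- matrix(1:5, 1, 5, dimnames = list("m1", paste0("S", 1:5)))
  er <- matrix(perm, 1, 5, dimnames = list("g1", paste0("S", 1:5)))
  kept <- screen_negative_pairs(em, er,
                                data.frame(mirna = "m1", target = "g1"))
  expect_equal(nrow(kept), 1L)
})

test_that("hypergeometric identities hold and p is monotone in overlap", {
  expect_equal(hypergeom_shared_test(0, 3, 4, 10), 1)
  expect_equal(hypergeom_shared_test(4, 4, 4, 4), 1)
  expect_equal(hypergeom_shared_test(4, 4, 5, 10), 1 / 42)
  expect_error(hypergeom_shared_test(5, 4, 5, 10), "inconsistent")
  for (N in c(8, 11)) for (n in c(3, 5)) for (K in c(4, 6)) {
    p <- hypergeom_shared_test(0:min(n, K), n, K, N)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("triple assembly enforces all three screens", {
  sim <- simulate_cerna_expression(make_design(), n_triples = 5,
                                   n_decoys = 60, coupling = 1,
                                   noise_sd = 0, seed = 73)
  neg <- screen_negative_pairs(sim$mirna, rbind(sim$circ, sim$mrna),
                               sim$edges)
  # With only 5 planted miRNAs the screened universe is small, so use the
  # full expressed-miRNA universe for the shared-miRNA test.
  tri <- build_cerna_triples(neg, sim$circ, sim$mrna,
                             universe = "expressed", expr_mirna = sim$mirna)
  expect_setequal(triple_key(tri), triple_key(sim$truth))
  expect_true(all(tri$rho_circ_mrna > 0.5))
  expect_true(all(tri$p < 0.05))
  expect_true(all(tri$rho_mirna_circ <= -0.5 & tri$rho_mirna_mrna <= -0.5))
  expect_true(all(tri$shared <= pmin(tri$n_circ_mirnas, tri$n_mrna_mirnas)))

  # A pair sharing every universe miRNA has hypergeometric p = 1 and is
  # rejected even under perfect correlations.
  em <- matrix(c(13:1), 1, 13,
               dimnames = list("m1", make_design()$sample))
  ec <- matrix(1:13, 1, 13, dimnames = list("c1", make_design()$sample))
  eg <- matrix(2 * (1:13), 1, 13, dimnames = list("g1", make_design()$sample))
  edges <- data.frame(mirna = "m1", target = c("c1", "g1"))
  neg1 <- screen_negative_pairs(em, rbind(ec, eg), edges)
  expect_equal(nrow(build_cerna_triples(neg1, ec, eg)), 0L)
  # With a larger universe the same pair becomes significant.
  expect_equal(nrow(build_cerna_triples(neg1, ec, eg, universe = 50)), 1L)
})

test_that("connectivity ranking counts distinct partners deterministically", {
  tri <- data.frame(
    circ = c("c1", "c1", "c2", "c3"),
    mirna = c("m1", "m2", "m1", "m3"),
    mrna = c("g1", "g1", "g2", "g3"),
    stringsAsFactors = FALSE)
  net <- cerna_network(tri)
  rk <- connectivity_rank(net, top_k = 10)
  expect_equal(rk$mRNA$id[1], "g1")
  expect_equal(rk$mRNA$degree[1], 2L)  # g1 <- m1, m2
  expect_equal(rk$circRNA$degree[rk$circRNA$id == "c1"], 2L)
  expect_equal(rk$miRNA$degree[rk$miRNA$id == "m1"], 4L)  # c1, c2, g1, g2
  # Brute-force recount from the edge list.
  for (ty in names(rk)) {
    for (i in seq_len(nrow(rk[[ty]]))) {
      id <- rk[[ty]]$id[i]
      partners <- unique(c(net$edges$target[net$edges$source == id],
                           net$edges$source[net$edges$target == id]))
      expect_equal(rk[[ty]]$degree[i], length(partners))
    }
  }
  # Ties break lexicographically; top_k beyond the node count returns all.
  expect_equal(rk$circRNA$id[2:3], c("c2", "c3"))
  expect_equal(nrow(rk$miRNA), 3L)
})

test_that("a star network ranks its hub first", {
  tri <- data.frame(circ = paste0("c", 1:5), mirna = paste0("m", 1:5),
                    mrna = c(rep("hub", 5)))
  rk <- connectivity_rank(cerna_network(tri))
  expect_equal(rk$mRNA$id[1], "hub")
  expect_equal(rk$mRNA$degree[1], 5L)
})

test_that("network export round-trips and counts edges correctly", {
  tri <- data.frame(circ = c("c1", "c1"), mirna = c("m1", "m2"),
                    mrna = c("g1", "g1"))
  net <- cerna_network(tri)
  # 1 triple -> 2 edges; here 2 triples share the circ and mRNA.
  expect_equal(nrow(net$edges), 4L)
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "edges.tsv"); sp <- file.path(dir, "sankey.tsv")
  export_network(net, ep, sp)
  back <- read_network_edges(ep)
  expect_equal(back, net$edges)
  sank <- read.delim(sp)
  expect_true(all(sank$value >= 1))
  # Oracle: edge count = distinct (circ, mirna) + distinct (mirna, mrna).
  expect_equal(nrow(net$edges),
               nrow(unique(tri[c("circ", "mirna")])) +
                 nrow(unique(tri[c("mirna", "mrna")])))
})
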