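# Bulk transcriptome: TPM, size factors, stringent DEG calling, correlation,
# centroid, embedding, over-representation and the kappa agreement statistic.

test_that("TPM normalizes by length and scales columns to one million", {
  expect_equal(unname(counts_to_tpm(cbind(s = 5), c(g = 500))[1, 1]), 1e6)
  tpm <- counts_to_tpm(cbind(s1 = c(10, 10)), c(g1 = 1000, g2 = 2000))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(41)
  cnt <- matrix(rpois(50 * 4, 20), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  tpm2 <- counts_to_tpm(cnt, setNames(rep(1000, 50), rownames(cnt)))
  # equal lengths: TPM proportional to counts
  expect_equal(tpm2, sweep(cnt, 2, colSums(cnt) / 1e6, "/"), tolerance = 1e-9)
  expect_equal(unname(colSums(tpm2)), rep(1e6, 4), tolerance = 1e-6)
  cnt0 <- cnt; cnt0[, 2] <- 0
  expect_error(counts_to_tpm(cnt0, setNames(rep(1000, 50), rownames(cnt))),
               "s2")
})

test_that("median-of-ratios size factors behave on constructed designs", {
  set.seed(42)
  a <- rpois(100, 50) + 1
  m <- cbind(s1 = a, s2 = a)
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = a, s2 = 2 * a)
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(size_factors(cbind(only = a))), 1)
  k <- cbind(a, a, a, a); colnames(k) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(k)), rep(1, 4))
  disjoint <- rbind(c(1, 0), c(0, 1))
  colnames(disjoint) <- c("x", "y")
  expect_error(size_factors(disjoint), "pseudocount")
})

test_that("bulk DEG handles identical groups and all-zero genes", {
  set.seed(43)
  a <- matrix(rnbinom(200 * 3, mu = 100, size = 50), nrow = 200)
  cnt <- cbind(a, a)
  cnt[17, ] <- 0
  dimnames(cnt) <- list(sprintf("g%03d", 1:200), paste0("s", 1:6))
  grp <- rep(c("GBM-DC", "ic-GSC"), each = 3)
  res <- bulk_deg(cnt, setNames(grp, colnames(cnt)))
  expect_equal(sum(res$is_deg), 0L)
  expect_equal(res$p[res$gene == "g017"], 1)
  expect_equal(res$effect[res$gene == "g017"], 0)
})

test_that("bulk DEG recovers planted effects at the stringent rule", {
  cfg <- synthetic_config(n_genes = 500, n_probes = 1000, seed = 44)
  sim <- simulate_bulk(cfg)
  res <- bulk_deg(sim$counts, sim$design)
  recall <- mean(res$is_deg[sim$planted])
  expect_gte(recall, 0.8)
  expect_equal(sum(res$is_deg & !sim$planted), 0L)
  up <- res$direction[res$gene %in% cfg$markers]
  expect_true(all(up == "up"))
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(45)
  x <- matrix(rpois(100 * 4, 30), nrow = 100,
              dimnames = list(NULL, paste0("s", 1:4)))
  cm <- correlation_matrix(x)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 4))
  lin <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_equal(correlation_matrix(lin, log_transform = FALSE)["a", "b"], 1)
  const <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  cc <- correlation_matrix(const)
  expect_true(is.na(cc["a", "b"]))
  expect_equal(unname(diag(cc)), c(1, 1))
})

test_that("within-group correlation exceeds between-group on planted data", {
  sim <- simulate_bulk(small_config(seed = 46))
  tpm <- counts_to_tpm(sim$counts, sim$gene_lengths)
  cm <- correlation_matrix(tpm)
  gv <- sim$design$group
  same <- outer(gv, gv, "==") & row(cm) != col(cm)
  expect_gt(mean(cm[same]), mean(cm[!same & row(cm) != col(cm)]))
})

test_that("the c-GSC centroid is the mean over c-GSC cells on the DEG set", {
  m <- toy_matrix()
  flags <- setNames(c(TRUE, TRUE, FALSE, FALSE), colnames(m))
  cen <- build_centroid(m, flags, c("OCT4", "HLA-A"))
  expect_equal(cen, c(OCT4 = 8.5, `HLA-A` = 1.5))
  single <- build_centroid(m, setNames(c(TRUE, FALSE, FALSE, FALSE),
                                       colnames(m)), rownames(m))
  expect_equal(single, m[, 1])
  expect_error(build_centroid(m, flags, "ABSENT"), "intersection")
  # centroid sits nearer the planted-cell mean than the background mean
  cfg <- small_config(seed = 47, n_cells = 800)
  sim <- simulate_sc_cohort(cfg)
  genes <- c(cfg$markers, cfg$hla_genes)
  cen2 <- build_centroid(sim$counts, sim$planted, genes)
  mu_p <- rowMeans(sim$counts[genes, sim$planted])
  mu_b <- rowMeans(sim$counts[genes, !sim$planted])
  sdv <- apply(sim$counts[genes, ], 1, sd)
  expect_lt(sqrt(sum(((cen2 - mu_p) / sdv)^2)),
            sqrt(sum(((cen2 - mu_b) / sdv)^2)))
})

test_that("the exact t-SNE embedding is deterministic and sane", {
  set.seed(48)
  X <- matrix(rnorm(7 * 5), nrow = 7)
  y1 <- tsne_exact(X, perplexity = 2, seed = 9)
  y2 <- tsne_exact(X, perplexity = 2, seed = 9)
  expect_identical(y1, y2)
  expect_error(tsne_exact(X, perplexity = 3), "perplexity")
  # three identical points: affinities are uniform, so the embedded
  # triangle is close to equilateral
  Z <- matrix(1, nrow = 3, ncol = 4)
  yz <- tsne_exact(Z, perplexity = 0.6, seed = 2)
  d <- as.numeric(dist(yz))
  expect_lt((max(d) - min(d)) / mean(d), 0.2)
})

test_that("samples embed with the centroid near its own group", {
  cfg <- small_config(seed = 49, n_cells = 800)
  sc <- simulate_sc_cohort(cfg)
  bulk <- simulate_bulk(cfg)
  deg <- bulk_deg(bulk$counts, bulk$design)
  genes <- deg$gene[deg$is_deg]
  # make the centroid ic-GSC-like in bulk space: use the ic-GSC group mean
  tpm <- log2(counts_to_tpm(bulk$counts, bulk$gene_lengths) + 1)
  cen <- rowMeans(tpm[genes, bulk$design$group == "ic-GSC"]) +
    rnorm(length(genes), 0, 0.05)
  names(cen) <- genes
  wins <- sum(vapply(1:10, function(s) {
    emb <- embed_with_centroid(tpm[genes, ], cen, seed = s)
    xy <- as.matrix(emb[, c("x", "y")])
    grp <- c(bulk$design$group, "centroid")
    cen_xy <- xy[grp == "centroid", ]
    d_ic <- sqrt(sum((cen_xy - colMeans(xy[grp == "ic-GSC", ]))^2))
    d_dc <- sqrt(sum((cen_xy - colMeans(xy[grp == "GBM-DC", ]))^2))
    d_ic < d_dc
  }, logical(1)))
  expect_gte(wins, 8)
})

test_that("over-representation matches the hypergeometric oracle", {
  u <- sprintf("g%03d", 1:100)
  sets <- list(S = u[1:10], TINY = u[1:2])
  # overlap 5 of query 10 with set 10 in universe 100
  q <- c(u[1:5], u[51:55])
  er <- ora_enrichment(q, sets, u)
  expect_equal(nrow(er), 1L)          # TINY dropped by min_size
  oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(er$p, oracle, tolerance = 1e-12)
  expect_equal(er$overlap, 5L)
  # overlap at expectation: not significant
  er2 <- ora_enrichment(c(u[1], u[51:59]), list(S = u[1:10]), u)
  expect_gt(er2$p, 0.05)
  # degenerate: query = set = universe
  er3 <- ora_enrichment(u, list(S = u), u)
  expect_equal(er3$p, 1)
  expect_true(is.infinite(er3$odds_ratio))
  expect_error(ora_enrichment("zzz", sets, u), "subset")
})

test_that("pathway agreement reproduces kappa, OR and Fisher p", {
  u <- paste0("p", 1:100)
  res <- pathway_agreement(u[1:7], u[c(1:5, 8:10)], u)
  expect_equal(c(res$a, res$b, res$c, res$d), c(5, 2, 3, 90))
  expect_equal(res$po, 0.95)
  expect_equal(res$pe, 0.8612)
  expect_equal(res$kappa, (0.95 - 0.8612) / (1 - 0.8612), tolerance = 1e-12)
  expect_equal(res$odds_ratio, 75)
  expect_false(res$haldane)
  # perfect agreement
  perf <- pathway_agreement(u[1:10], u[1:10], u)
  expect_equal(perf$kappa, 1)
  expect_true(perf$haldane)   # b = c = 0 triggers the correction
  # Fisher p equals hypergeometric enumeration on a small table
  small <- pathway_agreement(paste0("p", 1:6)[1:4], paste0("p", c(1:3, 5)),
                             paste0("p", 1:12))
  a <- small$a; b <- small$b; cc <- small$c; d <- small$d
  kA <- a + b; kB <- a + cc; n <- a + b + cc + d
  probs <- dhyper(0:kA, kA, n - kA, kB)
  expect_equal(small$fisher_p,
               sum(probs[probs <= probs[a + 1] * (1 + 1e-7)]),
               tolerance = 1e-9)
})

test_that("kappa vanishes for independent random classifications", {
  set.seed(50)
  u <- paste0("p", 1:60)
  kap <- replicate(300, {
    pathway_agreement(sample(u, 20), sample(u, 15), u)$kappa
  })
  expect_lt(abs(mean(kap)), 0.03)
})
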