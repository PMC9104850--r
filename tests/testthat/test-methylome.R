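# Methylome: beta standardization, the DMS rule with exact small-sample
# Wilcoxon p-values, promoter windows, consensus intervals and metaprofiles.

test_that("beta standardization divides by sample means and is idempotent", {
  b <- cbind(s1 = c(0.2, 0.6), s2 = c(0.5, 0.5))
  std <- standardize_beta(b)
  expect_equal(unname(std[, "s1"]), c(0.5, 1.5))
  expect_equal(unname(std[, "s2"]), c(1, 1))
  set.seed(61)
  B <- matrix(runif(500 * 4, 0.05, 0.95), 500,
              dimnames = list(sprintf("cg%03d", 1:500), paste0("s", 1:4)))
  S <- standardize_beta(B)
  expect_equal(unname(colMeans(S)), rep(1, 4), tolerance = 1e-9)
  # scale invariance of the transform (as a map on columns)
  expect_equal(sweep(sweep(B, 2, c(2, 1, 0.5, 1), "*"), 2,
                     colMeans(sweep(B, 2, c(2, 1, 0.5, 1), "*")), "/"),
               S, tolerance = 1e-12)
  expect_equal(sweep(S, 2, colMeans(S), "/"), S, tolerance = 1e-12)
  expect_error(standardize_beta(cbind(s1 = c(0, 0))), "all-zero")
})

test_that("exact 3-vs-3 Wilcoxon p-values live on the enumerated support", {
  combos <- combn(6, 3)
  support <- 2 * (1:10) / 20
  vals <- apply(combos, 2L, function(idx) {
    g2 <- rep(FALSE, 6); g2[idx] <- TRUE
    x <- matrix(1:6, nrow = 1)       # distinct values = pure rank pattern
    p <- row_wilcoxon(x, g2)
    ref <- wilcox.test((1:6)[g2], (1:6)[!g2], exact = TRUE)$p.value
    expect_equal(p, ref, tolerance = 1e-12)
    p
  })
  expect_true(all(vapply(vals, function(v) {
    any(abs(v - support) < 1e-12)
  }, logical(1))))
  expect_equal(min(vals), 0.1)       # complete separation: 2 / C(6,3)
})

test_that("the DMS rule needs both complete separation and a large delta", {
  # complete rank separation at 3 vs 3 gives exactly p = 0.1, which passes
  std <- rbind(sep = c(1, 1.1, 1.2, 3, 3.1, 3.2),
               flat = c(1, 1.1, 1.2, 1.05, 1.15, 1.08))
  colnames(std) <- paste0("s", 1:6)
  grp <- setNames(rep(c("GBM-DC", "ic-GSC"), each = 3), colnames(std))
  dms <- call_dms(std, grp)
  expect_equal(dms$p[1], 0.1)
  expect_true(dms$is_dms[1])
  expect_equal(dms$sign[1], "hyper")
  expect_false(dms$is_dms[2])
  # identical groups: no DMS
  same <- cbind(std[, 1:3], std[, 1:3])
  colnames(same) <- paste0("s", 1:6)
  expect_equal(sum(call_dms(same, grp)$is_dms), 0L)
  expect_error(call_dms(std[, c(1, 4)], grp[c(1, 4)]), "two groups|at least 2")
})

test_that("planted methylome effects are recovered by the DMS caller", {
  sim <- simulate_methylome(small_config(seed = 62, n_probes = 5000))
  std <- standardize_beta(sim$beta)
  dms <- call_dms(std, sim$design)
  hyper <- sim$planted == "hyper"
  hypo <- sim$planted == "hypo"
  expect_gte(mean(dms$is_dms[hyper]), 0.8)
  expect_gte(mean(dms$is_dms[hypo]), 0.8)
  expect_true(all(dms$sign[dms$is_dms & hyper] == "hyper"))
  expect_true(all(dms$sign[dms$is_dms & hypo] == "hypo"))
  expect_lte(mean(dms$is_dms[sim$planted == "none"]), 0.01)
})

test_that("promoter windows are inclusive at +/-1500 and match brute force", {
  ann <- data.frame(probe = c("a", "b", "d"), chrom = "chr1",
                    pos = c(10000 + 1500, 10000 + 1501, 10000 - 1500))
  tss <- data.frame(chrom = "chr1", position = 10000, strand = "+",
                    gene = "G1")
  pm <- promoter_probes(ann, tss, 1500)
  expect_setequal(pm$G1, c("a", "d"))
  set.seed(63)
  ann2 <- data.frame(probe = sprintf("cg%04d", 1:1000), chrom = "chr1",
                     pos = sample.int(2e5, 1000))
  tss2 <- data.frame(chrom = "chr1",
                     position = sample.int(2e5, 50), strand = "+",
                     gene = sprintf("G%02d", 1:50))
  pm2 <- promoter_probes(ann2, tss2, 1500)
  for (i in seq_len(nrow(tss2))) {
    oracle <- ann2$probe[abs(ann2$pos - tss2$position[i]) <= 1500]
    expect_setequal(pm2[[tss2$gene[i]]], oracle)
  }
})

test_that("consensus intervals equal the per-base coverage oracle", {
  o <- data.frame(chrom = "chr1", start = 0, end = 100)
  s <- data.frame(chrom = "chr1", start = 50, end = 150)
  n <- data.frame(chrom = "chr1", start = 80, end = 120)
  cons <- consensus_binding_sites(o, s, n)
  expect_equal(cons, data.frame(chrom = "chr1", start = 80, end = 100))
  expect_equal(consensus_binding_sites(o, o, o)[, c("start", "end")],
               data.frame(start = 0, end = 100))
  far <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_equal(nrow(consensus_binding_sites(o, s, far)), 0L)
  set.seed(64)
  for (i in 1:100) {
    O <- random_intervals(sample(1:6, 1))
    S <- random_intervals(sample(1:6, 1))
    N <- random_intervals(sample(1:6, 1))
    got <- consensus_binding_sites(O, S, N)
    want <- consensus_oracle(O, S, N)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    covered <- function(df) sum(df$end - df$start)
    expect_lte(covered(got), min(covered(O), covered(S), covered(N)))
  }
})

test_that("malformed BED lines are rejected with their line number", {
  tf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t150"), tf)
  expect_error(read_bed(tf), "line 2")
})

test_that("metaprofiles bin by signed distance from anchor midpoints", {
  anchors <- data.frame(chrom = "chr1", start = 50000, end = 51000)
  mid0 <- floor((50000 + 51000) / 2)              # 50500, 0-based
  ann <- data.frame(probe = c("center", "left", "out"), chrom = "chr1",
                    pos = c(mid0 + 1, mid0 + 1 - 5000, mid0 + 1 + 15000))
  beta <- matrix(0.5, 3, 4, dimnames = list(ann$probe, paste0("s", 1:4)))
  grp <- setNames(rep(c("GBM-DC", "ic-GSC"), each = 2), colnames(beta))
  prof <- metaprofile(beta, ann, anchors, grp)
  expect_equal(nrow(prof), 100 * 2)               # 100 bins x 2 groups
  filled <- prof[prof$n > 0 & prof$group == "GBM-DC", ]
  expect_equal(nrow(filled), 2L)                  # "out" beyond the flank
  expect_true(all(filled$mean == 0.5))            # flat signal stays flat
  center_bin <- prof[prof$bin_start == 0 & prof$group == "GBM-DC", ]
  expect_equal(center_bin$n, 1L)                  # midpoint probe, central bin
  left_bin <- prof[prof$bin_start == -5000 & prof$group == "GBM-DC", ]
  expect_equal(left_bin$n, 1L)
})

test_that("planted hypomethylation shows as a centered, symmetric dip", {
  sim <- simulate_methylome(small_config(seed = 65, n_probes = 5000))
  std <- standardize_beta(sim$beta)
  prof <- metaprofile(std, sim$annotation, sim$consensus_truth, sim$design)
  ic <- prof[prof$group == "ic-GSC", ]
  center <- ic$mean[abs(ic$bin_mid) <= 600]
  flank <- ic$mean[abs(ic$bin_mid) >= 5000]
  expect_lt(mean(center, na.rm = TRUE), mean(flank, na.rm = TRUE))
  # same construction in the reference group dips the other way (0.6 > 0.2)
  dc <- prof[prof$group == "GBM-DC", ]
  expect_gt(mean(dc$mean[abs(dc$bin_mid) <= 600], na.rm = TRUE),
            mean(dc$mean[abs(dc$bin_mid) >= 5000], na.rm = TRUE))
  # symmetric planted signal: left and right halves mirror within tolerance
  ic_sym <- ic[!is.na(ic$mean), ]
  left <- mean(ic_sym$mean[ic_sym$bin_mid < 0])
  right <- mean(ic_sym$mean[ic_sym$bin_mid > 0])
  expect_lt(abs(left - right), 0.15)
})

test_that("starburst quadrants follow the sign pair of significant genes", {
  deg <- data.frame(gene = c("up_hypo", "down_hyper", "ns"),
                    effect = c(2, -2, 2), p = 0, q = 0,
                    direction = c("up", "down", "up"),
                    is_deg = c(TRUE, TRUE, FALSE))
  psum <- data.frame(gene = c("up_hypo", "down_hyper", "ns"),
                     n_probes = 2, delta = c(-1.5, 1.5, 1.5),
                     any_dms = c(TRUE, TRUE, TRUE))
  sb <- starburst(deg, psum)
  expect_equal(sb$quadrant, c("hypo-up", "hyper-down", "null"))
  expect_error(starburst(deg, psum[0, ]), "shared")
})

test_that("planted HLA-like genes land in the hyper-down quadrant", {
  cfg <- small_config(seed = 66, n_probes = 5000)
  bulk <- simulate_bulk(cfg)
  meth <- simulate_methylome(cfg)
  deg <- bulk_deg(bulk$counts, bulk$design)
  std <- standardize_beta(meth$beta)
  dms <- call_dms(std, meth$design)
  pmap <- promoter_probes(meth$annotation, meth$tss)
  psum <- promoter_dms_summary(dms, pmap)
  sb <- starburst(deg, psum)
  hla <- sb[sb$gene %in% cfg$hla_genes, ]
  expect_equal(hla$quadrant, rep("hyper-down", 3))
})
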