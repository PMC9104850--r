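#' Standardize a beta-value matrix per sample
#'
#' Divides every probe's beta value by the mean beta value of its sample, so
#' each standardized column has mean exactly 1. Probe order is preserved and
#' the transform is idempotent.
#'
#' @param beta probes x samples matrix with values in `[0, 1]`.
#' @return matrix of the same shape, column means 1.
#' @examples
#' standardize_beta(cbind(s = c(0.2, 0.6)))  # 0.5, 1.5
#' @export
standardize_beta <- function(beta) {
  .assert(is.matrix(beta) && all(beta >= 0) && all(beta <= 1 + 1e-9),
          "beta values must lie in [0, 1]")
  mu <- colMeans(beta)
  zero <- mu == 0
  .assert(!any(zero), "all-zero sample(s): %s",
          paste(colnames(beta)[zero], collapse = ", "))
  sweep(beta, 2L, mu, "/")
}

#' Call differentially methylated sites
#'
#' Per-probe group difference on the standardized scale,
#' `delta = mean(ic-GSC) - mean(GBM-DC)` (or second level minus first), with
#' a two-sided Wilcoxon rank-sum p-value (exact for group sizes up to 10,
#' normal approximation with tie correction above). A probe is a DMS iff
#' `|delta| > delta_threshold` and `p <= p_threshold` (defaults 1 and 0.1).
#' No multiplicity correction is applied by default -- the strict delta
#' filter is the primary gate -- but `adjust = TRUE` switches the p rule to
#' Benjamini-Hochberg q-values.
#'
#' The default `delta_threshold = 1` is only meaningful on the standardized
#' scale of [standardize_beta()] (raw betas differ by at most 1), so pass a
#' standardized matrix.
#'
#' @param std probes x samples standardized beta matrix.
#' @param group group labels per sample (two levels) or a design data.frame
#'   with `sample` and `group` columns.
#' @param delta_threshold absolute difference threshold (default 1).
#' @param p_threshold p-value threshold (default 0.1).
#' @param adjust apply BH correction before thresholding (default FALSE).
#' @return data.frame of class `cgsc_dms`: `probe`, `mean_ref`, `mean_alt`,
#'   `delta`, `p`, `is_dms`, `sign` ("hyper"/"hypo" in the alternative
#'   group, `NA` when delta is 0).
#' @export
call_dms <- function(std, group, delta_threshold = 1, p_threshold = 0.1,
                     adjust = FALSE) {
  if (is.data.frame(group)) {
    .assert(all(colnames(std) %in% group$sample),
            "design is missing samples present in the matrix")
    group <- setNames(group$group, group$sample)[colnames(std)]
  }
  g <- .resolve_groups(group)
  .assert(sum(g$is_alt) >= 2 && sum(!g$is_alt) >= 2,
          "each group needs at least 2 samples")
  mean_ref <- rowMeans(std[, !g$is_alt, drop = FALSE])
  mean_alt <- rowMeans(std[, g$is_alt, drop = FALSE])
  delta <- mean_alt - mean_ref
  p <- row_wilcoxon(std, g$is_alt)
  crit <- if (adjust) p.adjust(p, "BH") else p
  out <- data.frame(probe = rownames(std), mean_ref = mean_ref,
                    mean_alt = mean_alt, delta = delta, p = p,
                    is_dms = abs(delta) > delta_threshold & crit <= p_threshold,
                    sign = ifelse(delta > 0, "hyper",
                                  ifelse(delta < 0, "hypo", NA)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- c(reference = g$ref, alternative = g$alt)
  class(out) <- c("cgsc_dms", class(out))
  out
}

## annotation data.frame -> GRanges of probe positions (1-based points)
.probe_granges <- function(annotation) {
  .assert(all(c("probe", "chrom", "pos") %in% names(annotation)),
          "annotation needs columns probe, chrom, pos")
  .assert(all(annotation$pos >= 1), "probe positions must be 1-based (>= 1)")
  if ("masked" %in% names(annotation)) {
    annotation <- annotation[!annotation$masked, , drop = FALSE]
  }
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(annotation$pos, annotation$pos),
                         probe = annotation$probe)
}

## interval data.frame (0-based half-open) or GRanges -> GRanges
.interval_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  .assert(all(c("chrom", "start", "end") %in% names(x)),
          "intervals need columns chrom, start, end")
  .assert(all(x$start >= 0 & x$start < x$end),
          "intervals must satisfy 0 <= start < end (0-based half-open)")
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

#' Map genes to promoter-window probes
#'
#' Assigns a probe to a gene iff the probe lies within `window` bp of the
#' gene's TSS, inclusive on both boundaries and strand-agnostic. Probes can
#' map to several genes; genes without probes map to an empty vector.
#'
#' @param annotation probe annotation data.frame (probe, chrom, pos; masked
#'   probes excluded).
#' @param tss TSS table (chrom, position (1-based), strand, gene).
#' @param window half-width of the promoter window in bp (default 1500).
#' @return named list, gene -> character vector of probe ids.
#' @export
promoter_probes <- function(annotation, tss, window = 1500) {
  pg <- .probe_granges(annotation)
  tg <- GenomicRanges::GRanges(tss$chrom,
                               IRanges::IRanges(pmax(1, tss$position - window),
                                                tss$position + window))
  hits <- GenomicRanges::findOverlaps(pg, tg)
  out <- setNames(vector("list", nrow(tss)), tss$gene)
  out[] <- list(character(0))
  sp <- split(pg$probe[S4Vectors::queryHits(hits)],
              tss$gene[S4Vectors::subjectHits(hits)])
  out[names(sp)] <- lapply(sp, unique)
  out
}

#' Per-gene promoter methylation summary
#'
#' Aggregates a DMS table over the promoter probes of each gene: the mean
#' delta across promoter probes (default) or the delta of largest magnitude,
#' plus whether any promoter probe passed the DMS rule.
#'
#' @param dms output of [call_dms()].
#' @param promoter_map output of [promoter_probes()].
#' @param method "mean" (default) or "max" (largest |delta|).
#' @return data.frame: `gene`, `n_probes`, `delta`, `any_dms`.
#' @export
promoter_dms_summary <- function(dms, promoter_map,
                                 method = c("mean", "max")) {
  method <- match.arg(method)
  rows <- lapply(names(promoter_map), function(gene) {
    idx <- match(promoter_map[[gene]], dms$probe)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) {
      return(data.frame(gene = gene, n_probes = 0L, delta = NA_real_,
                        any_dms = FALSE, stringsAsFactors = FALSE))
    }
    d <- dms$delta[idx]
    data.frame(gene = gene, n_probes = length(idx),
               delta = if (method == "mean") mean(d) else d[which.max(abs(d))],
               any_dms = any(dms$is_dms[idx]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Triple-consensus transcription-factor binding sites
#'
#' Maximal genomic intervals covered by at least one peak from each of the
#' three input collections: the interval intersection
#' `(O intersect S) intersect N`, computed per chromosome. Output intervals
#' are sorted, non-overlapping and reported in BED convention (0-based
#' half-open).
#'
#' @param peaks_O,peaks_S,peaks_N peak collections: data.frames with
#'   `chrom`, `start`, `end` (0-based half-open; e.g. [read_bed()]) or
#'   `GRanges`.
#' @return data.frame with `chrom`, `start`, `end`, sorted.
#' @examples
#' o <- data.frame(chrom = "chr1", start = 0, end = 100)
#' s <- data.frame(chrom = "chr1", start = 50, end = 150)
#' n <- data.frame(chrom = "chr1", start = 80, end = 120)
#' consensus_binding_sites(o, s, n)  # chr1:80-100
#' @export
consensus_binding_sites <- function(peaks_O, peaks_S, peaks_N) {
  grs <- lapply(list(peaks_O, peaks_S, peaks_N), function(p) {
    GenomicRanges::reduce(.interval_granges(p))
  })
  cons <- GenomicRanges::intersect(GenomicRanges::intersect(grs[[1]], grs[[2]]),
                                   grs[[3]])
  cons <- GenomicRanges::sort(cons)
  data.frame(chrom = as.character(GenomicRanges::seqnames(cons)),
             start = GenomicRanges::start(cons) - 1,
             end = GenomicRanges::end(cons),
             stringsAsFactors = FALSE)
}

#' Methylation metaprofile around anchor intervals
#'
#' Averages methylation as a function of signed distance from anchor
#' midpoints: every (probe, anchor) pair with the probe within `flank` bp of
#' the anchor's midpoint contributes the probe's per-group mean to the
#' distance bin it falls in. Bins of width `bin_width` tile
#' `[-flank, flank)` exactly; the midpoint is `floor((start + end) / 2)` in
#' 0-based coordinates and probe positions are converted to 0-based for the
#' distance arithmetic. Empty bins are reported as `NA`.
#'
#' @param beta probes x samples matrix (standardized or raw; both layers are
#'   meaningful, standardized is what [call_dms()] uses).
#' @param annotation probe annotation (probe, chrom, pos).
#' @param anchors anchor intervals (data.frame chrom/start/end, 0-based
#'   half-open, or GRanges), e.g. [consensus_binding_sites()] output.
#' @param group group labels per sample or a design data.frame.
#' @param flank half-window in bp (default 10000).
#' @param bin_width bin width in bp (default 200).
#' @return data.frame: `bin_start`, `bin_mid` (bp relative to midpoint),
#'   `group`, `mean`, `n` (probe-anchor assignments in the bin).
#' @export
metaprofile <- function(beta, annotation, anchors, group, flank = 10000,
                        bin_width = 200) {
  if (is.data.frame(group)) {
    group <- setNames(group$group, group$sample)[colnames(beta)]
  }
  group <- as.character(group)
  ag <- .interval_granges(anchors)
  .assert(length(ag) > 0, "anchors must be non-empty")
  mid0 <- floor((GenomicRanges::start(ag) - 1 + GenomicRanges::end(ag)) / 2)
  win <- GenomicRanges::GRanges(GenomicRanges::seqnames(ag),
                                IRanges::IRanges(pmax(1, mid0 + 1 - flank),
                                                 mid0 + flank))
  pg <- .probe_granges(annotation)
  hits <- GenomicRanges::findOverlaps(pg, win)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  n_bins <- as.integer(2 * flank / bin_width)
  bin_start <- -flank + (seq_len(n_bins) - 1L) * bin_width
  if (length(qi) == 0) {
    warning("no probe falls within the flank of any anchor")
    out <- expand.grid(bin_start = bin_start, group = unique(group),
                       stringsAsFactors = FALSE)
    out$bin_mid <- out$bin_start + bin_width / 2
    out$mean <- NA_real_; out$n <- 0L
    return(out[, c("bin_start", "bin_mid", "group", "mean", "n")])
  }
  dist0 <- (GenomicRanges::start(pg)[qi] - 1) - mid0[si]
  keep <- dist0 >= -flank & dist0 < flank
  qi <- qi[keep]; dist0 <- dist0[keep]
  bin <- floor((dist0 + flank) / bin_width) + 1L
  probe_idx <- match(pg$probe[qi], rownames(beta))
  ok <- !is.na(probe_idx)
  bin <- bin[ok]; probe_idx <- probe_idx[ok]

  rows <- lapply(unique(group), function(gr) {
    gm <- rowMeans(beta[, group == gr, drop = FALSE])
    v <- gm[probe_idx]
    mean_by_bin <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
    n_by_bin <- tapply(v, factor(bin, levels = seq_len(n_bins)), length)
    data.frame(bin_start = bin_start, bin_mid = bin_start + bin_width / 2,
               group = gr, mean = as.numeric(mean_by_bin),
               n = ifelse(is.na(n_by_bin), 0L, as.integer(n_by_bin)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Joint expression-methylation starburst classification
#'
#' Joins a bulk DEG table with a per-gene promoter methylation summary and
#' assigns each shared gene to a quadrant: genes significant on both axes
#' (DEG rule on expression, any promoter DMS on methylation) are labelled by
#' the sign pair (`hyper-up`, `hyper-down`, `hypo-up`, `hypo-down`); all
#' other genes are `null`.
#'
#' @param deg output of [bulk_deg()].
#' @param promoter_summary output of [promoter_dms_summary()].
#' @return data.frame: `gene`, `expr_effect`, `expr_sig`, `meth_delta`,
#'   `meth_sig`, `quadrant`.
#' @export
starburst <- function(deg, promoter_summary) {
  genes <- intersect(deg$gene, promoter_summary$gene)
  .assert(length(genes) > 0, "no shared genes between DEG and promoter tables")
  di <- match(genes, deg$gene)
  mi <- match(genes, promoter_summary$gene)
  expr_effect <- deg$effect[di]
  expr_sig <- deg$is_deg[di]
  meth_delta <- promoter_summary$delta[mi]
  meth_sig <- promoter_summary$any_dms[mi]
  quadrant <- ifelse(
    expr_sig & meth_sig & !is.na(meth_delta),
    paste0(ifelse(meth_delta > 0, "hyper", "hypo"), "-",
           ifelse(expr_effect > 0, "up", "down")),
    "null")
  data.frame(gene = genes, expr_effect = expr_effect, expr_sig = expr_sig,
             meth_delta = meth_delta, meth_sig = meth_sig,
             quadrant = quadrant, row.names = NULL, stringsAsFactors = FALSE)
}
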