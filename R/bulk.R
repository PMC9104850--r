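#' Convert raw counts to TPM
#'
#' Transcripts per million: per sample, each gene's count is divided by its
#' length in bp, and the resulting rates are scaled to sum to one million.
#'
#' @param counts genes x samples non-negative count matrix.
#' @param gene_lengths positive lengths (bp), named by gene or in row order.
#' @return TPM matrix of the same shape; every column sums to 1e6.
#' @examples
#' counts_to_tpm(cbind(s1 = c(10, 10)), c(g1 = 1000, g2 = 2000))
#' @export
counts_to_tpm <- function(counts, gene_lengths) {
  .assert(is.matrix(counts) && all(counts >= 0), "counts must be non-negative")
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    .assert(all(rownames(counts) %in% names(gene_lengths)),
            "gene_lengths missing for some genes")
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  .assert(length(gene_lengths) == nrow(counts) && all(gene_lengths > 0),
          "gene_lengths must be positive, one per gene")
  rate <- counts / gene_lengths
  tot <- colSums(rate)
  zero <- tot == 0
  .assert(!any(zero), "sample(s) with all-zero counts: %s",
          paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2L, tot / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference genes of the ratio between the
#' sample's count and the gene's geometric mean across samples; reference
#' genes are those with nonzero counts in every sample.
#'
#' @param counts genes x samples count matrix.
#' @return positive numeric vector, one size factor per sample.
#' @examples
#' m <- cbind(a = c(10, 20), b = c(20, 40))
#' size_factors(m)  # proportional to (1, 2)
#' @export
size_factors <- function(counts) {
  .assert(is.matrix(counts) && ncol(counts) >= 1, "counts must be a matrix")
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  .assert(any(ref), paste("no gene has nonzero counts in every sample;",
                          "consider adding a pseudocount"))
  loggeo <- rowMeans(log(counts[ref, , drop = FALSE]))
  sf <- apply(counts[ref, , drop = FALSE], 2L, function(s) {
    median(exp(log(s) - loggeo))
  })
  sf
}

#' Bulk differential expression at stringent thresholds
#'
#' Calls DEGs between the two bulk groups. Counts are normalized by
#' median-of-ratios [size_factors()]; the effect size is the log2 ratio of
#' pseudocounted normalized group means (second group over reference;
#' "ic-GSC" over "GBM-DC" when those labels are present). P-values come from
#' the negative-binomial Wald test of DESeq2 (using the same size factors),
#' adjusted by Benjamini-Hochberg; a gene is a DEG iff `q < q_threshold` and
#' `|effect| > lfc_threshold` (defaults 1e-10 and 1.5). Genes with zero
#' counts in all samples get `p = 1` and effect 0.
#'
#' @param counts genes x samples integer count matrix.
#' @param group character/factor of group labels per sample (two levels),
#'   or a data.frame with `sample` and `group` columns.
#' @param q_threshold FDR threshold (default 1e-10).
#' @param lfc_threshold absolute log2 fold-change threshold (default 1.5).
#' @param pseudocount pseudocount on normalized counts (default 1).
#' @return data.frame of class `cgsc_bulk_deg`: `gene`, `mean_ref`,
#'   `mean_alt` (normalized group means), `effect`, `p`, `q`, `direction`,
#'   `is_deg`; attribute `groups` records the (reference, alternative) pair.
#' @export
bulk_deg <- function(counts, group, q_threshold = 1e-10,
                     lfc_threshold = 1.5, pseudocount = 1) {
  if (is.data.frame(group)) {
    .assert(all(colnames(counts) %in% group$sample),
            "design is missing samples present in the count matrix")
    group <- setNames(group$group, group$sample)[colnames(counts)]
  }
  g <- .resolve_groups(group)
  .assert(sum(g$is_alt) >= 2 && sum(!g$is_alt) >= 2,
          "each group needs at least 2 samples")
  counts <- round(counts)
  storage.mode(counts) <- "integer"

  sf <- size_factors(counts)
  nrm <- sweep(counts, 2L, sf, "/")
  mean_ref <- rowMeans(nrm[, !g$is_alt, drop = FALSE])
  mean_alt <- rowMeans(nrm[, g$is_alt, drop = FALSE])
  effect <- .log2_ratio(mean_alt, mean_ref, pseudocount)

  ## syntactic level names for the model matrix only; outputs keep the
  ## user's labels
  cd <- S4Vectors::DataFrame(group = factor(ifelse(g$is_alt, "alt", "ref"),
                                            levels = c("ref", "alt")))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(counts, cd, ~group))
  DESeq2::sizeFactors(dds) <- sf
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, independentFiltering = FALSE,
                         cooksCutoff = FALSE)
  p <- res$pvalue
  p[is.na(p)] <- 1
  all_zero <- rowSums(counts) == 0
  p[all_zero] <- 1
  effect[all_zero] <- 0
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(counts), mean_ref = mean_ref,
                    mean_alt = mean_alt, effect = effect, p = p, q = q,
                    direction = ifelse(effect > 0, "up", "down"),
                    is_deg = q < q_threshold & abs(effect) > lfc_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- c(reference = g$ref, alternative = g$alt)
  class(out) <- c("cgsc_bulk_deg", class(out))
  out
}

#' Sample-sample Pearson correlation matrix
#'
#' Pearson correlation between samples on `log2(x + 1)`-transformed
#' expression (set `log_transform = FALSE` to correlate raw values).
#' Constant samples yield `NA` off-diagonal entries; the diagonal is 1.
#'
#' @param expr genes x samples matrix (e.g. TPM).
#' @param log_transform log2(x+1)-transform first (default TRUE).
#' @return symmetric samples x samples correlation matrix.
#' @export
correlation_matrix <- function(expr, log_transform = TRUE) {
  .assert(is.matrix(expr) && ncol(expr) >= 2, "need at least 2 samples")
  x <- if (log_transform) log2(expr + 1) else expr
  cc <- suppressWarnings(cor(x))
  diag(cc) <- 1
  cc
}

#' Representative c-GSC centroid
#'
#' A pseudo-sample obtained by averaging expression over all c-GSC cells,
#' restricted to the DEG gene set (optionally further intersected with the
#' genes available in a bulk matrix).
#'
#' @param sc_matrix genes x cells single-cell expression matrix.
#' @param cgsc_flags logical per cell (or [classify_osn()] output).
#' @param deg_genes character vector of c-GSC DEG gene ids.
#' @param bulk_genes optional character vector to intersect with.
#' @return named numeric vector, one mean per retained gene.
#' @export
build_centroid <- function(sc_matrix, cgsc_flags, deg_genes,
                           bulk_genes = NULL) {
  if (is.data.frame(cgsc_flags)) {
    cgsc_flags <- setNames(cgsc_flags$is_cgsc, cgsc_flags$cell)
  }
  if (!is.null(names(cgsc_flags))) cgsc_flags <- cgsc_flags[colnames(sc_matrix)]
  .assert(sum(cgsc_flags) >= 1, "at least one c-GSC cell is required")
  genes <- intersect(deg_genes, rownames(sc_matrix))
  if (!is.null(bulk_genes)) genes <- intersect(genes, bulk_genes)
  .assert(length(genes) > 0, "empty gene intersection for the centroid")
  rowMeans(sc_matrix[genes, cgsc_flags, drop = FALSE])
}

#' Embed bulk samples and the c-GSC centroid in two dimensions
#'
#' Joins the bulk samples with the centroid pseudo-sample on their shared
#' genes, z-scores each gene over the joint set (constant genes dropped) and
#' runs the package's exact t-SNE ([tsne_exact()]). Deterministic for a
#' fixed seed.
#'
#' @param bulk_expr genes x samples matrix (e.g. log2 TPM).
#' @param centroid named numeric vector from [build_centroid()].
#' @param seed integer seed for the embedding initialization.
#' @param perplexity t-SNE perplexity; default `min(30, (n - 1) / 3)`.
#' @param max_iter gradient-descent iterations (default 500).
#' @return data.frame with `label`, `type` ("sample"/"centroid"), `x`, `y`.
#' @export
embed_with_centroid <- function(bulk_expr, centroid, seed = 1,
                                perplexity = NULL, max_iter = 500) {
  genes <- intersect(rownames(bulk_expr), names(centroid))
  .assert(length(genes) >= 2, "too few shared genes between bulk and centroid")
  joint <- cbind(bulk_expr[genes, , drop = FALSE], centroid = centroid[genes])
  n <- ncol(joint)
  .assert(n >= 3, "need at least 3 points to embed")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  .assert(perplexity <= (n - 1) / 3,
          "perplexity too large for %d points; choose <= %.2f",
          n, (n - 1) / 3)
  mu <- rowMeans(joint); sdev <- apply(joint, 1L, sd)
  keep <- sdev > 0
  z <- (joint[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  coords <- tsne_exact(t(z), perplexity = perplexity, seed = seed,
                       max_iter = max_iter)
  data.frame(label = colnames(joint),
             type = c(rep("sample", n - 1), "centroid"),
             x = coords[, 1], y = coords[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Over-representation analysis of gene sets
#'
#' One-sided Fisher exact enrichment of a query gene list in each gene set,
#' over a fixed universe, with Benjamini-Hochberg correction across sets.
#' Sets are intersected with the universe first and sets smaller than
#' `min_size` members in the universe are dropped. Run it separately on up-
#' and down-regulated query lists to attach directions.
#'
#' @param query_genes character vector, a subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all testable genes.
#' @param min_size minimum set size within the universe (default 5).
#' @return data.frame: `set`, `set_size`, `overlap`, `odds_ratio`
#'   (sample odds ratio ad/bc, `Inf` when b*c = 0), `p`, `q`.
#' @export
ora_enrichment <- function(query_genes, gene_sets, universe, min_size = 5) {
  .assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  .assert(all(query_genes %in% universe), "query must be a subset of universe")
  sets <- lapply(gene_sets, intersect, universe)
  sets <- sets[lengths(sets) >= min_size]
  .assert(length(sets) > 0, "no gene set passes the minimum-size filter")
  n_u <- length(universe); n_q <- length(query_genes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    a <- length(intersect(query_genes, s))
    b <- n_q - a
    cc <- length(s) - a
    d <- n_u - n_q - cc
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(set = nm, set_size = length(s), overlap = a,
               odds_ratio = if (b * cc == 0) Inf else (a * d) / (b * cc),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Pathway-set agreement between two enrichment analyses
#'
#' Builds the 2x2 concordance table over a shared pathway universe: `a` sets
#' enriched in both analyses, `b` only in A, `c` only in B, `d` in neither,
#' and reports observed agreement, expected agreement, Cohen's kappa, the
#' odds ratio (Haldane 0.5 correction iff any cell is zero) and the
#' two-sided Fisher exact p-value.
#'
#' Kappa: with `n = a + b + c + d`, `po = (a + d) / n`,
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`, `kappa = (po - pe) / (1 - pe)`
#' (1 when `pe = 1`, i.e. perfect degenerate agreement).
#'
#' @param enriched_A,enriched_B character vectors of enriched pathway names.
#' @param universe character vector of all pathways tested in both analyses.
#' @return list of class `cgsc_agreement`: `table` (2x2 matrix), `a`, `b`,
#'   `c`, `d`, `po`, `pe`, `kappa`, `odds_ratio`, `haldane`, `fisher_p`.
#' @examples
#' u <- paste0("path", 1:100)
#' res <- pathway_agreement(u[1:7], u[c(1:5, 8:10)], u)
#' res$kappa       # 0.6397695
#' res$odds_ratio  # 75
#' @export
pathway_agreement <- function(enriched_A, enriched_B, universe) {
  universe <- unique(universe)
  .assert(length(universe) > 0, "empty pathway universe")
  .assert(all(enriched_A %in% universe) && all(enriched_B %in% universe),
          "enriched sets must be subsets of the universe")
  inA <- universe %in% enriched_A
  inB <- universe %in% enriched_B
  a <- sum(inA & inB); b <- sum(inA & !inB)
  cc <- sum(!inA & inB); d <- sum(!inA & !inB)
  n <- a + b + cc + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  haldane <- any(c(a, b, cc, d) == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE,
                dimnames = list(A = c("enriched", "not"),
                                B = c("enriched", "not")))
  p <- fisher.test(tab)$p.value
  structure(list(table = tab, a = a, b = b, c = cc, d = d, po = po, pe = pe,
                 kappa = kappa, odds_ratio = or, haldane = haldane,
                 fisher_p = p),
            class = "cgsc_agreement")
}

#' @export
print.cgsc_agreement <- function(x, ...) {
  cat(sprintf("pathway agreement over %d sets: a=%d b=%d c=%d d=%d\n",
              sum(x$table), x$a, x$b, x$c, x$d))
  cat(sprintf("  kappa = %.3f, OR = %.2f%s, Fisher p = %.3g\n",
              x$kappa, x$odds_ratio,
              if (x$haldane) " (Haldane-corrected)" else "", x$fisher_p))
  invisible(x)
}
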