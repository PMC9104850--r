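#' Remove genes with excessive zero fractions
#'
#' Drops every gene whose expression is zero in more than `max_zero_frac` of
#' cells; a gene is retained iff it is expressed (value > 0) in at least
#' `1 - max_zero_frac` of cells. The cell set is unchanged.
#'
#' @param matrix genes x cells non-negative expression matrix.
#' @param max_zero_frac maximum tolerated zero fraction, in (0,1)
#'   (default 0.95).
#' @return the filtered matrix.
#' @examples
#' m <- rbind(a = c(1, 0, 0, 0), b = c(1, 2, 3, 0))
#' colnames(m) <- paste0("c", 1:4)
#' filter_genes(m, max_zero_frac = 0.5)
#' @export
filter_genes <- function(matrix, max_zero_frac = 0.95) {
  .assert(is.numeric(max_zero_frac) && max_zero_frac > 0 && max_zero_frac < 1,
          "max_zero_frac must lie in (0, 1)")
  .assert(is.matrix(matrix) && all(matrix >= 0), "matrix must be non-negative")
  zero_frac <- rowMeans(matrix == 0)
  keep <- zero_frac <= max_zero_frac
  .assert(any(keep),
          "every gene is unexpressed in more than %.0f%% of cells; none retained",
          100 * max_zero_frac)
  matrix[keep, , drop = FALSE]
}

#' Upper-quartile thresholds for marker genes
#'
#' Computes the 75th percentile of each marker's expression over all cells
#' (linear interpolation between order statistics, i.e. quantile type 7).
#' With `by_patient = TRUE` thresholds are computed within each patient
#' instead (one row per patient); the pooled mode is the default.
#'
#' @param matrix genes x cells expression matrix.
#' @param markers character vector of three marker gene ids.
#' @param by_patient logical; per-patient thresholds (requires `patient_of`).
#' @param patient_of named character vector cell -> patient.
#' @return object of class `cgsc_thresholds`: named numeric vector of Q3
#'   per marker (pooled mode), or a patients x markers matrix.
#' @examples
#' m <- rbind(OCT4 = c(0, 0, 0, 1, 2, 3, 4, 10),
#'            SOX2 = 1:8, NANOG = 8:1)
#' colnames(m) <- paste0("c", 1:8)
#' marker_thresholds(m, c("OCT4", "SOX2", "NANOG"))  # OCT4 Q3 = 3.25
#' @export
marker_thresholds <- function(matrix, markers, by_patient = FALSE,
                              patient_of = NULL) {
  missing <- setdiff(markers, rownames(matrix))
  .assert(length(missing) == 0, "marker gene(s) not in matrix: %s",
          paste(missing, collapse = ", "))
  if (!by_patient) {
    q3 <- apply(matrix[markers, , drop = FALSE], 1L, quantile, probs = 0.75,
                type = 7, names = FALSE)
    out <- setNames(q3, markers)
  } else {
    .assert(!is.null(patient_of), "by_patient = TRUE requires patient_of")
    pts <- patient_of[colnames(matrix)]
    out <- t(vapply(split(colnames(matrix), pts), function(cells) {
      apply(matrix[markers, cells, drop = FALSE], 1L, quantile, probs = 0.75,
            type = 7, names = FALSE)
    }, numeric(length(markers))))
    colnames(out) <- markers
  }
  structure(out, class = c("cgsc_thresholds", class(out)))
}

#' Classify cells into the eight OSN marker categories
#'
#' A marker is "high" in a cell iff its expression is strictly greater than
#' the marker's upper-quartile threshold (ties at the threshold are low).
#' The cell's category is the combination of the three high/low states,
#' written e.g. `O+S-N+`; a cell is a c-GSC iff all three markers are high.
#'
#' @param matrix genes x cells expression matrix (the same matrix the
#'   thresholds were computed from).
#' @param thresholds output of [marker_thresholds()] (pooled vector or
#'   per-patient matrix; the latter requires `patient_of`).
#' @param patient_of named character vector cell -> patient, needed only for
#'   per-patient thresholds.
#' @return data.frame with `cell`, `category` (factor over the 8
#'   combinations) and `is_cgsc`.
#' @examples
#' m <- rbind(OCT4 = c(5, 0), SOX2 = c(5, 0), NANOG = c(5, 0))
#' colnames(m) <- c("a", "b")
#' th <- setNames(c(1, 1, 1), c("OCT4", "SOX2", "NANOG"))
#' class(th) <- "cgsc_thresholds"
#' classify_osn(m, th)
#' @export
classify_osn <- function(matrix, thresholds, patient_of = NULL) {
  markers <- if (is.matrix(thresholds)) colnames(thresholds) else names(thresholds)
  .assert(length(markers) == 3L, "thresholds must cover three markers")
  .assert(all(markers %in% rownames(matrix)),
          "thresholds refer to markers absent from the matrix")
  expr <- matrix[markers, , drop = FALSE]
  if (is.matrix(thresholds)) {
    .assert(!is.null(patient_of), "per-patient thresholds require patient_of")
    th <- t(thresholds[patient_of[colnames(matrix)], markers, drop = FALSE])
    high <- expr > th
  } else {
    high <- expr > as.numeric(thresholds[markers])
  }
  letters3 <- c("O", "S", "N")
  lab <- apply(high, 2L, function(h) {
    paste0(letters3, ifelse(h, "+", "-"), collapse = "")
  })
  lv <- apply(expand.grid(rep(list(c("-", "+")), 3))[, 3:1], 1L, function(s) {
    paste0(letters3, s, collapse = "")
  })
  data.frame(cell = colnames(matrix),
             category = factor(lab, levels = lv),
             is_cgsc = unname(colSums(high) == 3L),
             stringsAsFactors = FALSE)
}

#' Cohort-level c-GSC summary
#'
#' Pooled and per-patient c-GSC fractions. The pooled fraction is
#' `100 * n_cgsc / n_cells`; per-patient fractions are computed over each
#' patient's cells; the across-patient mean is reported with both SEM and SD
#' (patients with zero cells are excluded). With a single patient the SEM is
#' undefined and reported as 0 with a warning.
#'
#' @param labels output of [classify_osn()] (or a logical is_cgsc vector
#'   named by cell).
#' @param patient_of named character vector cell -> patient.
#' @return list of class `cgsc_cohort_summary`: `pooled_fraction` (percent),
#'   `per_patient` (data.frame patient/n_cells/n_cgsc/fraction),
#'   `mean_fraction`, `sem_fraction`, `sd_fraction`, `n_patients`,
#'   `n_patients_with_cgsc`, `pct_patients_with_cgsc`.
#' @examples
#' flags <- setNames(c(TRUE, FALSE, FALSE, TRUE), paste0("c", 1:4))
#' pts <- setNames(c("P1", "P1", "P2", "P2"), paste0("c", 1:4))
#' cohort_summary(flags, pts)$pooled_fraction  # 50
#' @export
cohort_summary <- function(labels, patient_of) {
  if (is.data.frame(labels)) {
    flags <- setNames(labels$is_cgsc, labels$cell)
  } else {
    flags <- labels
    .assert(!is.null(names(flags)), "logical labels must be named by cell")
  }
  .assert(all(names(flags) %in% names(patient_of)),
          "every cell needs a patient label")
  pts <- patient_of[names(flags)]
  per <- do.call(rbind, lapply(split(flags, pts), function(f) {
    data.frame(n_cells = length(f), n_cgsc = sum(f),
               fraction = 100 * mean(f))
  }))
  per <- data.frame(patient = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  n_pat <- nrow(per)
  if (n_pat < 2) {
    warning("SEM undefined with a single patient; reported as 0")
    sem <- 0; sdv <- 0
  } else {
    sdv <- sd(per$fraction)
    sem <- sdv / sqrt(n_pat)
  }
  structure(list(
    pooled_fraction = 100 * mean(flags),
    per_patient = per,
    mean_fraction = mean(per$fraction),
    sem_fraction = sem, sd_fraction = sdv,
    n_patients = n_pat,
    n_patients_with_cgsc = sum(per$n_cgsc > 0),
    pct_patients_with_cgsc = 100 * mean(per$n_cgsc > 0)
  ), class = "cgsc_cohort_summary")
}

#' @export
print.cgsc_cohort_summary <- function(x, ...) {
  cat(sprintf("c-GSC cohort summary: %.2f%% pooled (%d/%d cells)\n",
              x$pooled_fraction, sum(x$per_patient$n_cgsc),
              sum(x$per_patient$n_cells)))
  cat(sprintf("  %d/%d patients with >=1 c-GSC (%.1f%%)\n",
              x$n_patients_with_cgsc, x$n_patients, x$pct_patients_with_cgsc))
  cat(sprintf("  per-patient: %.2f%% +/- %.2f (SEM; SD %.2f)\n",
              x$mean_fraction, x$sem_fraction, x$sd_fraction))
  invisible(x)
}

#' HLA expression gradient over the eight OSN categories
#'
#' Mean expression of each HLA gene within each OSN category, plus the same
#' values rescaled relative to the triple-positive (`O+S+N+`) category, the
#' track a radar plot of antigen-presentation decline would display.
#' Categories with no cells get `NA` means (not zero).
#'
#' @param matrix genes x cells expression matrix.
#' @param labels output of [classify_osn()].
#' @param hla_genes character vector of HLA gene ids present in the matrix.
#' @return data.frame with `category`, `gene`, `mean_expr`, `rescaled`
#'   (`mean_expr` divided by the O+S+N+ mean of that gene; `NA` when that
#'   mean is zero or missing).
#' @export
hla_gradient <- function(matrix, labels, hla_genes) {
  missing <- setdiff(hla_genes, rownames(matrix))
  .assert(length(missing) == 0, "HLA gene(s) not in matrix: %s",
          paste(missing, collapse = ", "))
  cats <- levels(labels$category)
  out <- expand.grid(category = cats, gene = hla_genes,
                     stringsAsFactors = FALSE)
  out$mean_expr <- mapply(function(cat, g) {
    cells <- labels$cell[labels$category == cat]
    if (length(cells) == 0) return(NA_real_)
    mean(matrix[g, cells])
  }, out$category, out$gene)
  ref <- setNames(out$mean_expr[out$category == "O+S+N+"],
                  out$gene[out$category == "O+S+N+"])
  out$rescaled <- ifelse(is.na(ref[out$gene]) | ref[out$gene] == 0,
                         NA_real_, out$mean_expr / ref[out$gene])
  out
}

#' Wilcoxon differential expression between c-GSCs and the tumor bulk
#'
#' Per-gene two-sided Wilcoxon rank-sum test (exact for small groups,
#' normal approximation with tie correction otherwise) comparing c-GSC cells
#' against all remaining cells, with Benjamini-Hochberg FDR across the
#' retained genes. The effect size is a pseudocounted log2 ratio of group
#' means; a gene is a DEG iff `q < q_threshold` and
#' `|effect| > lfc_threshold` (defaults 0.05 and 0.5).
#'
#' @param matrix genes x cells expression matrix (already filtered).
#' @param is_cgsc logical vector over cells (or [classify_osn()] output).
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.5).
#' @param pseudocount pseudocount in the fold-change ratio (default 1).
#' @return data.frame of class `cgsc_deg`: `gene`, `mean_cgsc`, `mean_bulk`,
#'   `effect` (log2 fold change, c-GSC over bulk), `p`, `q`, `direction`,
#'   `is_deg`.
#' @export
wilcoxon_deg <- function(matrix, is_cgsc, q_threshold = 0.05,
                         lfc_threshold = 0.5, pseudocount = 1) {
  if (is.data.frame(is_cgsc)) is_cgsc <- setNames(is_cgsc$is_cgsc, is_cgsc$cell)
  if (!is.null(names(is_cgsc))) is_cgsc <- is_cgsc[colnames(matrix)]
  is_cgsc <- as.logical(is_cgsc)
  .assert(length(is_cgsc) == ncol(matrix) && !anyNA(is_cgsc),
          "is_cgsc must flag every cell")
  .assert(sum(is_cgsc) >= 2 && sum(!is_cgsc) >= 2,
          "both groups need at least 2 cells")
  p <- row_wilcoxon(matrix, is_cgsc)
  mean_cgsc <- rowMeans(matrix[, is_cgsc, drop = FALSE])
  mean_bulk <- rowMeans(matrix[, !is_cgsc, drop = FALSE])
  effect <- .log2_ratio(mean_cgsc, mean_bulk, pseudocount)
  constant <- apply(matrix, 1L, function(r) all(r == r[1]))
  effect[constant] <- 0
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(matrix), mean_cgsc = mean_cgsc,
                    mean_bulk = mean_bulk, effect = effect, p = p, q = q,
                    direction = ifelse(effect > 0, "up", "down"),
                    is_deg = q < q_threshold & abs(effect) > lfc_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cgsc_deg", class(out))
  out
}
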