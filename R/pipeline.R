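#' Assemble a pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()]. All
#' thresholds default to the package's standard rules: 95% zero-fraction
#' gene filter; single-cell DEG at q < 0.05 and |log2FC| > 0.5; bulk DEG at
#' q < 1e-10 and |log2FC| > 1.5; DMS at |delta| > 1 (standardized scale) and
#' p <= 0.1; promoter window +/-1500 bp; metaprofile flank +/-10 kb. Stages
#' whose inputs are absent are skipped by [run_pipeline()].
#'
#' @param paths named list of input paths, as produced by
#'   [simulate_bundle()]: `matrix`/`features`/`barcodes` (or a dense
#'   `matrix` TSV) and `cell_meta` for the single-cell stage; `bulk_counts`,
#'   `bulk_design`, `gene_lengths`, optionally `gene_sets` for the bulk
#'   stage; `beta`, `meth_design`, `probe_annotation`, `tss`,
#'   `peaks_OCT4`/`peaks_SOX2`/`peaks_NANOG` for the methylation stage.
#' @param markers three marker gene ids (default OCT4, SOX2, NANOG).
#' @param hla_genes three HLA gene ids (default HLA-A, HLA-B, HLA-C).
#' @param max_zero_frac gene filter threshold (default 0.95).
#' @param sc_q,sc_lfc single-cell DEG rule (defaults 0.05, 0.5).
#' @param bulk_q,bulk_lfc bulk DEG rule (defaults 1e-10, 1.5).
#' @param dms_delta,dms_p DMS rule on the standardized scale
#'   (defaults 1, 0.1).
#' @param promoter_window promoter half-window bp (default 1500).
#' @param flank,bin_width metaprofile geometry (defaults 10000, 200).
#' @param ora_q enrichment significance threshold (default 0.05).
#' @param min_set_size minimum gene-set size in the universe (default 5).
#' @param seed integer seed for the embedding (default 1).
#' @return list of class `cgsc_pipeline_config`.
#' @export
pipeline_config <- function(paths, markers = c("OCT4", "SOX2", "NANOG"),
                            hla_genes = c("HLA-A", "HLA-B", "HLA-C"),
                            max_zero_frac = 0.95, sc_q = 0.05, sc_lfc = 0.5,
                            bulk_q = 1e-10, bulk_lfc = 1.5, dms_delta = 1,
                            dms_p = 0.1, promoter_window = 1500,
                            flank = 10000, bin_width = 200, ora_q = 0.05,
                            min_set_size = 5, seed = 1) {
  cfg <- list(paths = lapply(paths, as.character), markers = markers,
              hla_genes = hla_genes, max_zero_frac = max_zero_frac,
              sc_q = sc_q, sc_lfc = sc_lfc, bulk_q = bulk_q,
              bulk_lfc = bulk_lfc, dms_delta = dms_delta, dms_p = dms_p,
              promoter_window = promoter_window, flank = flank,
              bin_width = bin_width, ora_q = ora_q,
              min_set_size = min_set_size, seed = as.integer(seed))
  class(cfg) <- "cgsc_pipeline_config"
  cfg
}

.has_paths <- function(cfg, keys) {
  all(vapply(keys, function(k) {
    !is.null(cfg$paths[[k]]) && file.exists(cfg$paths[[k]])
  }, logical(1)))
}

.read_sc_stage_matrix <- function(cfg) {
  p <- cfg$paths
  if (grepl("\\.mtx$", p$matrix)) {
    read_expression_matrix(p$matrix, p$features, p$barcodes)
  } else {
    read_expression_matrix(p$matrix)
  }
}

#' Run the end-to-end pipeline
#'
#' Executes the single-cell, bulk and methylation stages whose inputs are
#' present in `config`, writes every stage output (TSV, headed with the tool
#' version and config hash) plus a machine-readable `summary.json` into
#' `out_dir`, and returns the summary invisibly. A rerun with an identical
#' configuration produces an identical summary. Stage failures abort with
#' the failing stage named; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  .assert(inherits(config, "cgsc_pipeline_config"),
          "config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(unclass(config))
  summary <- list(config_hash = hash,
                  version = as.character(packageVersion("cgsc")),
                  stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sc_deg <- NULL; sc_mat <- NULL; sc_labels <- NULL; bulk_res <- NULL
  universe <- NULL

  ## ---- single-cell stage ----
  if (.has_paths(config, c("matrix", "cell_meta"))) {
    stage("sc", {
      sc_mat <- .read_sc_stage_matrix(config)
      patient_of <- read_cell_meta(config$paths$cell_meta)
      sc_mat <- filter_genes(sc_mat, config$max_zero_frac)
      th <- marker_thresholds(sc_mat, config$markers)
      sc_labels <- classify_osn(sc_mat, th)
      cs <- cohort_summary(sc_labels, patient_of)
      grad <- hla_gradient(sc_mat, sc_labels,
                           intersect(config$hla_genes, rownames(sc_mat)))
      sc_deg <- wilcoxon_deg(sc_mat, sc_labels, config$sc_q, config$sc_lfc)
      write_output_tsv(sc_labels, file.path(out_dir, "sc_labels.tsv"), hash)
      write_output_tsv(grad, file.path(out_dir, "sc_hla_gradient.tsv"), hash)
      write_output_tsv(as.data.frame(sc_deg),
                       file.path(out_dir, "sc_deg.tsv"), hash)
      write_output_tsv(cs$per_patient,
                       file.path(out_dir, "sc_per_patient.tsv"), hash)
      summary$stages$sc <- list(
        n_cells = ncol(sc_mat), n_genes_retained = nrow(sc_mat),
        pooled_cgsc_pct = cs$pooled_fraction,
        mean_patient_cgsc_pct = cs$mean_fraction,
        sem_patient_cgsc_pct = cs$sem_fraction,
        n_patients = cs$n_patients,
        n_patients_with_cgsc = cs$n_patients_with_cgsc,
        pct_patients_with_cgsc = cs$pct_patients_with_cgsc,
        n_deg = sum(sc_deg$is_deg))
    })
  } else {
    summary$stages$sc <- list(skipped = "single-cell inputs not provided")
    message("sc stage skipped: inputs not provided")
  }

  ## ---- bulk stage ----
  if (.has_paths(config, c("bulk_counts", "bulk_design", "gene_lengths"))) {
    stage("bulk", {
      counts <- read_matrix_tsv(config$paths$bulk_counts)
      design <- .read_tsv(config$paths$bulk_design)
      gl <- .read_tsv(config$paths$gene_lengths)
      gene_lengths <- setNames(gl$length, gl$gene)
      tpm <- counts_to_tpm(counts, gene_lengths)
      cm <- correlation_matrix(tpm)
      bulk_res <- bulk_deg(counts, design, config$bulk_q, config$bulk_lfc)
      write_matrix_tsv(cm, file.path(out_dir, "bulk_correlation.tsv"),
                       "sample", hash)
      write_output_tsv(as.data.frame(bulk_res),
                       file.path(out_dir, "bulk_deg.tsv"), hash)
      summary$stages$bulk <- list(
        n_genes = nrow(counts), n_samples = ncol(counts),
        n_deg = sum(bulk_res$is_deg),
        n_deg_up = sum(bulk_res$is_deg & bulk_res$direction == "up"),
        n_deg_down = sum(bulk_res$is_deg & bulk_res$direction == "down"),
        mean_within_group_cor = {
          gv <- design$group[match(colnames(cm), design$sample)]
          same <- outer(gv, gv, "==")
          mean(cm[same & row(cm) != col(cm)], na.rm = TRUE)
        })

      ## centroid embedding, when the sc stage ran and produced DEGs
      if (!is.null(sc_deg) && sum(sc_deg$is_deg) >= 2) {
        cen <- build_centroid(sc_mat, sc_labels, sc_deg$gene[sc_deg$is_deg],
                              rownames(tpm))
        emb <- embed_with_centroid(log2(tpm[names(cen), , drop = FALSE] + 1),
                                   cen, seed = config$seed)
        write_output_tsv(emb, file.path(out_dir, "bulk_embedding.tsv"), hash)
        summary$stages$bulk$embedded <- TRUE
      }

      ## enrichment agreement, when gene sets and both DEG tables exist
      if (.has_paths(config, "gene_sets") && !is.null(sc_deg)) {
        sets <- read_gmt(config$paths$gene_sets)
        shared <- intersect(sc_deg$gene, bulk_res$gene)
        enriched_names <- function(deg_tab) {
          up <- intersect(deg_tab$gene[deg_tab$is_deg &
                                         deg_tab$direction == "up"], shared)
          dn <- intersect(deg_tab$gene[deg_tab$is_deg &
                                         deg_tab$direction == "down"], shared)
          hit <- character(0)
          for (qg in list(up, dn)) {
            if (length(qg) == 0) next
            er <- ora_enrichment(qg, sets, shared, config$min_set_size)
            hit <- union(hit, er$set[er$q < config$ora_q])
          }
          list(hits = hit)
        }
        er_universe <- names(which(lengths(lapply(sets, intersect, shared)) >=
                                     config$min_set_size))
        a_sets <- enriched_names(sc_deg)$hits
        b_sets <- enriched_names(bulk_res)$hits
        agr <- pathway_agreement(a_sets, b_sets, er_universe)
        summary$stages$bulk$agreement <- list(
          a = agr$a, b = agr$b, c = agr$c, d = agr$d, kappa = agr$kappa,
          odds_ratio = agr$odds_ratio, fisher_p = agr$fisher_p)
      }
    })
  } else {
    summary$stages$bulk <- list(skipped = "bulk inputs not provided")
    message("bulk stage skipped: inputs not provided")
  }

  ## ---- methylation stage ----
  meth_keys <- c("beta", "meth_design", "probe_annotation", "tss",
                 "peaks_OCT4", "peaks_SOX2", "peaks_NANOG")
  if (.has_paths(config, meth_keys)) {
    stage("meth", {
      beta <- read_matrix_tsv(config$paths$beta)
      design <- .read_tsv(config$paths$meth_design)
      ann <- read_probe_annotation(config$paths$probe_annotation)
      tss <- read_tss(config$paths$tss)
      std <- standardize_beta(beta)
      dms <- call_dms(std, design, config$dms_delta, config$dms_p)
      pmap <- promoter_probes(ann, tss, config$promoter_window)
      psum <- promoter_dms_summary(dms, pmap)
      cons <- consensus_binding_sites(read_bed(config$paths$peaks_OCT4),
                                      read_bed(config$paths$peaks_SOX2),
                                      read_bed(config$paths$peaks_NANOG))
      prof <- metaprofile(std, ann, cons, design, config$flank,
                          config$bin_width)
      write_output_tsv(as.data.frame(dms),
                       file.path(out_dir, "meth_dms.tsv"), hash)
      write_output_tsv(psum, file.path(out_dir, "meth_promoters.tsv"), hash)
      write_bed(cons, file.path(out_dir, "meth_consensus.bed"))
      write_output_tsv(prof, file.path(out_dir, "meth_metaprofile.tsv"), hash)
      summary$stages$meth <- list(
        n_probes = nrow(beta), n_dms = sum(dms$is_dms),
        n_dms_hyper = sum(dms$is_dms & dms$sign == "hyper", na.rm = TRUE),
        n_dms_hypo = sum(dms$is_dms & dms$sign == "hypo", na.rm = TRUE),
        n_consensus = nrow(cons))
      if (!is.null(bulk_res)) {
        sb <- starburst(bulk_res, psum)
        write_output_tsv(sb, file.path(out_dir, "starburst.tsv"), hash)
        summary$stages$meth$starburst_quadrants <-
          as.list(table(sb$quadrant))
      }
    })
  } else {
    summary$stages$meth <- list(skipped = "methylation inputs not provided")
    message("meth stage skipped: inputs not provided")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Validate pipeline inputs
#'
#' Per-file format and consistency checks: readability, id uniqueness, beta
#' range, BED coordinate sanity, marker presence. Unreadable or malformed
#' files become error entries rather than crashes.
#'
#' @param config a [pipeline_config()].
#' @return data.frame of class `cgsc_validation` with `file`, `check`,
#'   `status` ("ok"/"error") and `message`; attribute `n_errors`.
#' @export
validate_inputs <- function(config) {
  rows <- list()
  add <- function(file, check, status, message = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, check = check, status = status, message = message,
      stringsAsFactors = FALSE)
  }
  try_check <- function(file, check, expr) {
    tryCatch({ expr; add(file, check, "ok") },
             error = function(e) add(file, check, "error",
                                     conditionMessage(e)))
  }
  p <- config$paths
  if (!is.null(p$matrix) && file.exists(p$matrix)) {
    try_check(p$matrix, "sc matrix parses / unique ids", {
      m <- .read_sc_stage_matrix(config)
      .assert(!anyDuplicated(rownames(m)), "duplicate gene id")
      .assert(!anyDuplicated(colnames(m)), "duplicate cell id")
      .assert(all(m >= 0), "negative expression values")
      .assert(all(config$markers %in% rownames(m)),
              "marker gene(s) missing: %s",
              paste(setdiff(config$markers, rownames(m)), collapse = ", "))
    })
    if (!is.null(p$cell_meta)) {
      try_check(p$cell_meta, "cell metadata covers all cells", {
        m <- .read_sc_stage_matrix(config)
        meta <- read_cell_meta(p$cell_meta)
        .assert(all(colnames(m) %in% names(meta)),
                "cells without patient label")
      })
    }
  }
  if (!is.null(p$bulk_counts) && file.exists(p$bulk_counts)) {
    try_check(p$bulk_counts, "bulk counts parse / unique genes", {
      m <- read_matrix_tsv(p$bulk_counts)
      .assert(!anyDuplicated(rownames(m)), "duplicate gene id")
      .assert(all(m >= 0), "negative counts")
    })
  }
  if (!is.null(p$beta) && file.exists(p$beta)) {
    try_check(p$beta, "beta values in [0, 1], unique probes", {
      b <- read_matrix_tsv(p$beta)
      .assert(!anyDuplicated(rownames(b)), "duplicate probe id")
      bad <- which(b < 0 | b > 1, arr.ind = TRUE)
      .assert(nrow(bad) == 0, "beta out of [0,1] at probe %s, sample %s",
              rownames(b)[bad[1, 1]], colnames(b)[bad[1, 2]])
    })
  }
  for (k in c("peaks_OCT4", "peaks_SOX2", "peaks_NANOG")) {
    if (!is.null(p[[k]]) && file.exists(p[[k]])) {
      try_check(p[[k]], "BED parses, sorted starts", {
        bed <- read_bed(p[[k]])
        for (ch in unique(bed$chrom)) {
          s <- bed$start[bed$chrom == ch]
          .assert(!is.unsorted(s), "BED not sorted within %s", ch)
        }
      })
    }
  }
  if (!is.null(p$tss) && file.exists(p$tss)) {
    try_check(p$tss, "TSS table parses, unique gene/position", {
      tss <- read_tss(p$tss)
      .assert(!anyDuplicated(tss[, c("gene", "position")]),
              "duplicate (gene, position) pair")
    })
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), check = character(0),
               status = character(0), message = character(0))
  attr(out, "n_errors") <- sum(out$status == "error")
  class(out) <- c("cgsc_validation", class(out))
  out
}
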