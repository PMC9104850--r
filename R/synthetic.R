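#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic single-cell, bulk and methylome
#' generators. The defaults emulate the study conditions the pipeline is
#' designed for: a ~8,000-cell scRNA-seq cohort pooled over 28 patients with
#' a planted ~4% triple-high OCT4/SOX2/NANOG subpopulation showing HLA-A/B/C
#' suppression; a 3-vs-3 bulk RNA-seq design with planted stemness-up /
#' immune-down genes; and an EPIC-like beta-value matrix with planted
#' promoter hypermethylation at HLA genes and hypomethylation inside
#' triple-consensus binding intervals.
#'
#' @param n_cells number of single cells (default 8000).
#' @param n_patients number of patients cells are assigned to (default 28).
#' @param n_genes number of genes in the shared gene universe (default 2000).
#' @param planted_fraction target proportion of triple-high cells, in (0,1)
#'   (default 0.04). The planted count is `round(n_cells * planted_fraction)`.
#' @param marker_effect multiplicative boost of the three marker means in
#'   planted cells (default 8).
#' @param hla_effect multiplicative suppression of HLA-A/B/C means in planted
#'   cells, in (0,1) (default 0.2).
#' @param nb_dispersion negative-binomial dispersion of single-cell counts
#'   (variance = mu + dispersion * mu^2; default 0.2).
#' @param seed integer master seed; each generator stream derives its own
#'   sub-seed so stages are individually reproducible.
#' @param n_probes number of methylation probes (default 20000, >= 1000).
#' @param n_bulk_reps replicates per bulk group (default 3, >= 2).
#' @param beta_noise_sd logit-scale standard deviation of beta-value noise
#'   (default 0.25; 0 allowed for degenerate checks).
#' @param marker_base_mean baseline single-cell mean count of the three
#'   markers (default 4).
#' @param hla_base_mean baseline single-cell mean count of HLA genes
#'   (default 20).
#' @param bulk_dispersion NB dispersion of bulk replicate counts
#'   (default 0.02, cell-line replicate regime).
#' @param n_bulk_deg number of planted bulk DEGs, split half up / half down
#'   (default 50).
#' @param bulk_log2_effect absolute log2 effect of planted bulk DEGs
#'   (default 4).
#' @param n_dms number of probes planted hypermethylated in HLA promoter
#'   windows (default 50).
#' @param dms_delta raw beta-value gain of planted hypermethylated probes
#'   (default 0.3).
#' @param n_consensus number of triple-consensus binding intervals
#'   (default 30).
#' @param markers gene ids of the three pluripotency markers.
#' @param hla_genes gene ids of the three class I HLA genes.
#' @return an object of class `cgsc_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_cells = 200, n_genes = 100, n_probes = 1000,
#'                         seed = 1)
#' @export
synthetic_config <- function(n_cells = 8000, n_patients = 28, n_genes = 2000,
                             planted_fraction = 0.04, marker_effect = 8,
                             hla_effect = 0.2, nb_dispersion = 0.2, seed = 1,
                             n_probes = 20000, n_bulk_reps = 3,
                             beta_noise_sd = 0.25,
                             marker_base_mean = 4, hla_base_mean = 20,
                             bulk_dispersion = 0.02, n_bulk_deg = 50,
                             bulk_log2_effect = 4, n_dms = 50,
                             dms_delta = 0.3, n_consensus = 30,
                             markers = c("OCT4", "SOX2", "NANOG"),
                             hla_genes = c("HLA-A", "HLA-B", "HLA-C")) {
  .assert(.is_count(n_cells), "n_cells must be a positive integer")
  .assert(.is_count(n_patients), "n_patients must be a positive integer")
  .assert(.is_count(n_genes) && n_genes >= 10,
          "n_genes must be a positive integer >= 10")
  .assert(is.numeric(planted_fraction) && planted_fraction > 0 &&
            planted_fraction < 1, "planted_fraction must lie in (0, 1)")
  .assert(is.numeric(marker_effect) && marker_effect > 0,
          "marker_effect must be > 0")
  .assert(is.numeric(hla_effect) && hla_effect > 0 && hla_effect <= 1,
          "hla_effect must lie in (0, 1]")
  .assert(is.numeric(nb_dispersion) && nb_dispersion > 0,
          "nb_dispersion must be > 0")
  .assert(.is_count(abs(seed) + 1), "seed must be an integer")
  .assert(.is_count(n_probes) && n_probes >= 1000, "n_probes must be >= 1000")
  .assert(.is_count(n_bulk_reps) && n_bulk_reps >= 2, "n_bulk_reps must be >= 2")
  .assert(is.numeric(beta_noise_sd) && beta_noise_sd >= 0,
          "beta_noise_sd must be >= 0")
  .assert(length(markers) == 3L, "exactly three marker genes are required")
  .assert(length(hla_genes) == 3L, "exactly three HLA genes are required")

  cfg <- list(n_cells = as.integer(n_cells), n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              planted_fraction = planted_fraction,
              marker_effect = marker_effect, hla_effect = hla_effect,
              nb_dispersion = nb_dispersion, seed = as.integer(seed),
              n_probes = as.integer(n_probes),
              n_bulk_reps = as.integer(n_bulk_reps),
              beta_noise_sd = beta_noise_sd,
              marker_base_mean = marker_base_mean,
              hla_base_mean = hla_base_mean,
              bulk_dispersion = bulk_dispersion,
              n_bulk_deg = as.integer(n_bulk_deg),
              bulk_log2_effect = bulk_log2_effect,
              n_dms = as.integer(n_dms), dms_delta = dms_delta,
              n_consensus = as.integer(n_consensus),
              markers = as.character(markers),
              hla_genes = as.character(hla_genes))
  class(cfg) <- "cgsc_config"
  cfg
}

#' @export
print.cgsc_config <- function(x, ...) {
  cat("cgsc synthetic config:\n")
  cat(sprintf("  sc: %d cells / %d patients / %d genes, planted %.1f%% (x%g markers, x%g HLA)\n",
              x$n_cells, x$n_patients, x$n_genes, 100 * x$planted_fraction,
              x$marker_effect, x$hla_effect))
  cat(sprintf("  bulk: %d vs %d reps, %d planted DEGs at |log2| = %g\n",
              x$n_bulk_reps, x$n_bulk_reps, x$n_bulk_deg, x$bulk_log2_effect))
  cat(sprintf("  meth: %d probes, %d planted hyper, %d consensus intervals\n",
              x$n_probes, x$n_dms, x$n_consensus))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

## derive independent per-stream sub-seeds from the master seed (kept < 2^31)
.stream_seed <- function(cfg, stream) {
  offset <- c(sc = 101, bulk = 202, meth = 303, sets = 404)[[stream]]
  as.integer((abs(as.numeric(cfg$seed)) * 1009 + offset) %%
               .Machine$integer.max)
}

## shared gene universe: markers and HLA genes first, then numbered genes
.gene_universe <- function(cfg) {
  n_other <- cfg$n_genes - 6L
  c(cfg$markers, cfg$hla_genes, sprintf("gene%04d", seq_len(n_other)))
}

#' Simulate a single-cell cohort with a planted triple-high subpopulation
#'
#' Draws negative-binomial counts for `n_genes` genes over `n_cells` cells
#' assigned round-robin to `n_patients` patients. The first
#' `round(n_cells * planted_fraction)` cells are "planted": their three
#' marker genes have mean multiplied by `marker_effect` and their HLA genes
#' by `hla_effect`. Because cells are laid out cyclically over patients, the
#' planted cells are spread round-robin as well, making per-patient planted
#' fractions essentially uniform.
#'
#' Per-gene baseline means: markers at `marker_base_mean`, HLA genes at
#' `hla_base_mean`, all other genes log-normal (meanlog 0, sdlog 1.5) so a
#' realistic share of genes is near-silent and removed by the 95%-zero filter.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (genes x cells integer matrix), `gene_ids`,
#'   `cell_ids`, `patient_of` (named character vector cell -> patient) and
#'   `planted` (named logical ground-truth flags).
#' @examples
#' sim <- simulate_sc_cohort(synthetic_config(n_cells = 300, n_genes = 100,
#'                                            seed = 1))
#' sum(sim$planted)  # round(300 * 0.04) = 12
#' @export
simulate_sc_cohort <- function(config) {
  .assert(inherits(config, "cgsc_config"), "config must come from synthetic_config()")
  set.seed(.stream_seed(config, "sc"))
  genes <- .gene_universe(config)
  n_g <- length(genes); n_c <- config$n_cells

  base_mean <- rlnorm(n_g, meanlog = 0, sdlog = 1.5)
  names(base_mean) <- genes
  base_mean[config$markers] <- config$marker_base_mean
  base_mean[config$hla_genes] <- config$hla_base_mean

  n_planted <- round(n_c * config$planted_fraction)
  planted <- rep(FALSE, n_c)
  planted[seq_len(n_planted)] <- TRUE
  patients <- sprintf("P%02d", rep_len(seq_len(config$n_patients), n_c))

  mu <- matrix(base_mean, nrow = n_g, ncol = n_c,
               dimnames = list(genes, NULL))
  if (n_planted > 0) {
    mu[config$markers, planted] <- mu[config$markers, planted] * config$marker_effect
    mu[config$hla_genes, planted] <- mu[config$hla_genes, planted] * config$hla_effect
  }
  counts <- matrix(rnbinom(n_g * n_c, mu = mu, size = 1 / config$nb_dispersion),
                   nrow = n_g, ncol = n_c)
  cell_ids <- sprintf("cell%05d", seq_len(n_c))
  dimnames(counts) <- list(genes, cell_ids)
  structure(list(counts = counts, gene_ids = genes, cell_ids = cell_ids,
                 patient_of = setNames(patients, cell_ids),
                 planted = setNames(planted, cell_ids)),
            class = "cgsc_sc_sim")
}

#' Simulate a two-group bulk RNA-seq experiment with planted DEGs
#'
#' Two groups ("GBM-DC" and "ic-GSC") with `n_bulk_reps` negative-binomial
#' replicates each, over the same gene universe as [simulate_sc_cohort()].
#' `n_bulk_deg` genes are planted differential: half up-regulated in ic-GSC
#' by `2^bulk_log2_effect` (this set always contains the three marker genes,
#' mirroring a stemness program) and half down-regulated (always containing
#' the three HLA genes, mirroring antigen-presentation loss). Planted effects
#' are placed on genes with baseline mean >= 20 so the planted truth concerns
#' genes expressed at detectable levels.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (genes x samples), `gene_lengths` (bp),
#'   `design` (data.frame sample/group), `planted` (logical flags),
#'   `direction` ("up"/"down"/"none") and `gene_sets` (a named list of gene
#'   sets over the universe: a stemness set and an antigen-presentation set
#'   covering the planted programs plus random background sets, for
#'   enrichment/agreement runs).
#' @examples
#' sim <- simulate_bulk(synthetic_config(n_genes = 200, seed = 1))
#' table(sim$direction)
#' @export
simulate_bulk <- function(config) {
  .assert(inherits(config, "cgsc_config"), "config must come from synthetic_config()")
  .assert(config$n_bulk_deg %% 2 == 0, "n_bulk_deg must be even")
  set.seed(.stream_seed(config, "bulk"))
  genes <- .gene_universe(config)
  n_g <- length(genes); n_r <- config$n_bulk_reps

  base_mean <- rlnorm(n_g, meanlog = log(100), sdlog = 1.2)
  names(base_mean) <- genes
  ## markers / HLA are well expressed so their planted effects are detectable
  base_mean[c(config$markers, config$hla_genes)] <-
    pmax(base_mean[c(config$markers, config$hla_genes)], 50)

  if (config$n_bulk_deg == 0) {
    up_genes <- character(0)
    down_genes <- character(0)
  } else {
    .assert(config$n_bulk_deg >= 6,
            "n_bulk_deg must be 0 or at least 6 (markers + HLA are planted)")
    n_half <- config$n_bulk_deg %/% 2
    eligible <- setdiff(genes[base_mean >= 20],
                        c(config$markers, config$hla_genes))
    .assert(length(eligible) >= config$n_bulk_deg - 6,
            "too few well-expressed genes to plant %d DEGs", config$n_bulk_deg)
    extra <- sample(eligible, config$n_bulk_deg - 6L)
    up_genes <- c(config$markers, extra[seq_len(n_half - 3L)])
    down_genes <- c(config$hla_genes, extra[-seq_len(n_half - 3L)])
  }

  effect <- setNames(rep(1, n_g), genes)
  effect[up_genes] <- 2^config$bulk_log2_effect
  effect[down_genes] <- 2^(-config$bulk_log2_effect)

  size <- 1 / config$bulk_dispersion
  dc <- matrix(rnbinom(n_g * n_r, mu = rep(base_mean, n_r), size = size), n_g)
  ic <- matrix(rnbinom(n_g * n_r, mu = rep(base_mean * effect, n_r), size = size), n_g)
  counts <- cbind(dc, ic)
  samples <- c(sprintf("GBM-DC%d", seq_len(n_r)), sprintf("ic-GSC%d", seq_len(n_r)))
  dimnames(counts) <- list(genes, samples)
  design <- data.frame(sample = samples,
                       group = rep(c("GBM-DC", "ic-GSC"), each = n_r),
                       stringsAsFactors = FALSE)
  gene_lengths <- setNames(round(rlnorm(n_g, log(2000), 0.6)) + 200, genes)

  direction <- setNames(rep("none", n_g), genes)
  direction[up_genes] <- "up"; direction[down_genes] <- "down"

  set.seed(.stream_seed(config, "sets"))
  gene_sets <- c(
    list(STEMNESS_CORE = unique(c(up_genes, sample(genes, 5))),
         ANTIGEN_PRESENTATION = unique(c(down_genes, sample(genes, 5)))),
    setNames(lapply(seq_len(30), function(i) sample(genes, 15)),
             sprintf("RANDOM_SET_%02d", seq_len(30))))

  structure(list(counts = counts, gene_lengths = gene_lengths, design = design,
                 planted = setNames(direction != "none", genes),
                 direction = direction, gene_sets = gene_sets),
            class = "cgsc_bulk_sim")
}

#' Simulate an EPIC-like methylome with planted promoter and binding-site effects
#'
#' Builds a single-chromosome probe layout, a TSS table whose genes are drawn
#' from the shared gene universe (always including the three HLA genes and
#' the three markers), and three transcription-factor peak collections whose
#' triple intersection is known exactly. Beta values are logit-normal around
#' planted group means, clipped to `[1e-6, 1 - 1e-6]`:
#' \itemize{
#'   \item background probes: mean 0.2 in both groups (promoter-focused CpGs
#'     are mostly unmethylated);
#'   \item `n_dms` probes inside +/-1.5 kb of the HLA TSSs: mean
#'     `0.2 + dms_delta` in the ic-GSC group (planted hypermethylation);
#'   \item probes inside consensus intervals: mean 0.6 in GBM-DC, 0.15 in
#'     ic-GSC (planted hypomethylation at triple-bound sites).
#' }
#'
#' @param config a [synthetic_config()].
#' @return list with `beta` (probes x samples matrix), `annotation`
#'   (data.frame probe/chrom/pos/masked), `design`, `planted`
#'   ("hyper"/"hypo"/"none" per probe), `peaks` (named list of three
#'   data.frames chrom/start/end, 0-based half-open), `consensus_truth`
#'   (the exact triple intersection) and `tss` (chrom/position/strand/gene).
#' @examples
#' sim <- simulate_methylome(synthetic_config(n_probes = 1000, seed = 1))
#' range(sim$beta)
#' @export
simulate_methylome <- function(config) {
  .assert(inherits(config, "cgsc_config"), "config must come from synthetic_config()")
  set.seed(.stream_seed(config, "meth"))
  genes <- .gene_universe(config)
  n_p <- config$n_probes; n_r <- config$n_bulk_reps
  n_cons <- config$n_consensus
  chrom <- "chr1"
  chrom_len <- max(2e7, (n_cons + 1) * 6e5 + 1e6)

  ## consensus intervals (0-based half-open), 1 kb wide, regularly spaced
  cons_start <- 5e5 + (seq_len(n_cons) - 1L) * 6e5
  cons_end <- cons_start + 1000L
  consensus_truth <- data.frame(chrom = chrom, start = cons_start,
                                end = cons_end,
                                name = sprintf("OSNbs_%03d", seq_len(n_cons)),
                                stringsAsFactors = FALSE)
  ## per-factor peaks: consensus intervals extended asymmetrically so the
  ## triple intersection is exactly [start, end), plus factor-private peaks
  mk_peaks <- function(left, right, own_offset) {
    own_start <- 5e5 + (seq_len(20) - 1L) * 6e5 + own_offset
    df <- rbind(
      data.frame(chrom = chrom, start = cons_start - left,
                 end = cons_end + right, stringsAsFactors = FALSE),
      data.frame(chrom = chrom, start = own_start, end = own_start + 500L,
                 stringsAsFactors = FALSE))
    df[order(df$start), , drop = FALSE]
  }
  peaks <- list(OCT4 = mk_peaks(300L, 0L, 2e5),
                SOX2 = mk_peaks(0L, 300L, 3e5),
                NANOG = mk_peaks(100L, 100L, 4e5))

  ## TSS table: HLA genes + markers + background genes, between consensus sites
  n_tss <- 20L
  tss_genes <- c(config$hla_genes, config$markers,
                 genes[!genes %in% c(config$hla_genes, config$markers)][seq_len(n_tss - 6L)])
  tss_pos <- 5e5 + (seq_len(n_tss) - 1L) * 6e5 + 3e5 + 1L   # 1-based
  tss <- data.frame(chrom = chrom, position = tss_pos,
                    strand = rep(c("+", "-"), length.out = n_tss),
                    gene = tss_genes, stringsAsFactors = FALSE)

  ## probe layout
  hla_tss <- tss_pos[match(config$hla_genes, tss_genes)]
  n_dms <- config$n_dms
  hyper_pos <- unlist(lapply(seq_along(hla_tss), function(i) {
    k <- n_dms %/% 3 + (i <= n_dms %% 3)
    hla_tss[i] + as.integer(round(seq(-1400, 1400, length.out = k)))
  }))
  n_per_cons <- 4L
  hypo_pos <- as.integer(rep(cons_start, each = n_per_cons) +
                           rep(seq(200L, 800L, length.out = n_per_cons),
                               times = n_cons) + 1L)   # 1-based, inside peaks
  ## probes in promoters of non-HLA TSS genes (background for the starburst)
  other_tss <- tss_pos[!tss_genes %in% config$hla_genes]
  prom_pos <- as.integer(rep(other_tss, each = 3L) +
                           rep(c(-900L, 0L, 900L), times = length(other_tss)))
  n_bg <- n_p - length(hyper_pos) - length(hypo_pos) - length(prom_pos)
  .assert(n_bg > 0, "n_probes too small for the planted layout")
  bg_pos <- sort(sample.int(chrom_len - 1L, n_bg)) + 1L

  pos <- c(hyper_pos, hypo_pos, prom_pos, bg_pos)
  planted <- c(rep("hyper", length(hyper_pos)), rep("hypo", length(hypo_pos)),
               rep("none", length(prom_pos) + n_bg))
  ord <- order(pos)
  pos <- pos[ord]; planted <- planted[ord]
  probe_ids <- sprintf("cg%07d", seq_len(n_p))
  annotation <- data.frame(probe = probe_ids, chrom = chrom, pos = pos,
                           masked = FALSE, stringsAsFactors = FALSE)

  base <- rep(0.2, n_p)
  base[planted == "hypo"] <- 0.6
  mean_dc <- base
  mean_ic <- base
  mean_ic[planted == "hyper"] <- 0.2 + config$dms_delta
  mean_ic[planted == "hypo"] <- 0.15

  beta <- cbind(matrix(plogis(qlogis(rep(mean_dc, n_r)) +
                                rnorm(n_p * n_r, 0, config$beta_noise_sd)), n_p),
                matrix(plogis(qlogis(rep(mean_ic, n_r)) +
                                rnorm(n_p * n_r, 0, config$beta_noise_sd)), n_p))
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  samples <- c(sprintf("GBM-DC%d", seq_len(n_r)), sprintf("ic-GSC%d", seq_len(n_r)))
  dimnames(beta) <- list(probe_ids, samples)
  design <- data.frame(sample = samples,
                       group = rep(c("GBM-DC", "ic-GSC"), each = n_r),
                       stringsAsFactors = FALSE)

  structure(list(beta = beta, annotation = annotation, design = design,
                 planted = setNames(planted, probe_ids), peaks = peaks,
                 consensus_truth = consensus_truth, tss = tss),
            class = "cgsc_meth_sim")
}
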