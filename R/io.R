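## Readers and writers for the plain-text formats the pipeline consumes:
## MatrixMarket + TSV sidecars for single-cell counts, TSV matrices for bulk
## counts and beta values, BED3 peaks, TSS tables, GMT gene sets. All TSV
## outputs carry a "# cgsc <version> config=<hash>" header comment; readers
## skip '#' comment lines.

.header_lines <- function(hash = NULL) {
  sprintf("# cgsc %s%s", as.character(packageVersion("cgsc")),
          if (is.null(hash)) "" else paste0(" config=", hash))
}

#' Write a data frame as a commented TSV
#'
#' @param df data frame.
#' @param path output path.
#' @param hash optional config hash recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_lines(hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE, quote = "", ...)
}

#' Read a single-cell expression matrix
#'
#' Accepts either MatrixMarket format (`.mtx`) with `features`/`barcodes`
#' TSV sidecars (one id per line, first column used), or a dense TSV/CSV with
#' gene rows and a leading gene-id column.
#'
#' @param path matrix file (`.mtx`, `.tsv` or `.csv`).
#' @param features,barcodes sidecar paths, required for MTX input.
#' @return numeric matrix, genes x cells, with dimnames.
#' @export
read_expression_matrix <- function(path, features = NULL, barcodes = NULL) {
  .assert(file.exists(path), "matrix file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    .assert(!is.null(features) && !is.null(barcodes),
            "MTX input requires features and barcodes sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rn <- read.table(features, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cn <- read.table(barcodes, sep = "\t", stringsAsFactors = FALSE)[[1]]
    .assert(nrow(m) == length(rn) && ncol(m) == length(cn),
            "sidecar lengths do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(m)
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read per-cell metadata
#'
#' TSV with a `cell` column and a required `patient` column.
#' @param path metadata TSV.
#' @return named character vector, cell -> patient.
#' @export
read_cell_meta <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("cell", "patient") %in% names(df)),
          "cell metadata needs columns 'cell' and 'patient'")
  setNames(as.character(df$patient), df$cell)
}

#' Write single-cell counts as MTX plus sidecars
#'
#' @param counts genes x cells matrix.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths.
#' @export
write_sc_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), paths["matrix"])
  writeLines(rownames(counts), paths["features"])
  writeLines(colnames(counts), paths["barcodes"])
  paths
}

#' Read a dense numeric matrix TSV (gene or probe rows)
#' @param path TSV with id column first, one column per sample.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a matrix as TSV with an id column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the id column.
#' @param hash optional config hash for the header.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", hash = NULL) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_output_tsv(df, path, hash)
}

#' Read a BED3+ file of peak intervals
#'
#' Validates every line (three or more columns, numeric 0-based half-open
#' coordinates with start < end) and reports the first malformed line by
#' number.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  .assert(file.exists(path), "BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ok <- length(p) >= 3 && !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[3]))) &&
      as.numeric(p[2]) >= 0 && as.numeric(p[2]) < as.numeric(p[3])
    .assert(ok, "malformed BED line %d in %s: '%s'", idx[i], path, lines[idx[i]])
  }
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.numeric(vapply(parts, `[`, "", 2L)),
             end = as.numeric(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Write intervals as BED3
#' @param df data.frame with chrom/start/end (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  write.table(df[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS table (chrom, position, strand, gene)
#' @param path TSV with those four columns; positions 1-based.
#' @return data.frame.
#' @export
read_tss <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("chrom", "position", "strand", "gene") %in% names(df)),
          "TSS table needs columns chrom, position, strand, gene")
  .assert(all(df$position >= 1), "TSS positions must be 1-based (>= 1)")
  df
}

#' Read probe annotation (probe, chrom, pos, optional masked flag)
#' @param path TSV.
#' @return data.frame; masked probes are dropped with a message.
#' @export
read_probe_annotation <- function(path) {
  df <- .read_tsv(path)
  .assert(all(c("probe", "chrom", "pos") %in% names(df)),
          "probe annotation needs columns probe, chrom, pos")
  if ("masked" %in% names(df) && any(df$masked)) {
    message(sum(df$masked), " masked probes removed from annotation")
    df <- df[!df$masked, , drop = FALSE]
  }
  df
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .assert(all(lengths(parts) >= 3), "GMT lines need name, description, genes")
  setNames(lapply(parts, function(p) unique(p[-c(1, 2)])),
           vapply(parts, `[`, "", 1L))
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic input bundle to disk
#'
#' Runs all three generators for `config` and writes every file the pipeline
#' consumes (single-cell MTX + sidecars + metadata, bulk counts, gene
#' lengths, design, beta matrix, probe annotation, three peak BEDs, TSS
#' table, GMT gene sets) together with the planted-truth flags.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return named list of file paths (also usable as [pipeline_config()]
#'   input paths), invisibly.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(unclass(config))
  sc <- simulate_sc_cohort(config)
  bulk <- simulate_bulk(config)
  meth <- simulate_methylome(config)

  paths <- as.list(write_sc_matrix(sc$counts, file.path(dir, "sc")))
  paths$cell_meta <- file.path(dir, "sc", "cell_meta.tsv")
  write_output_tsv(data.frame(cell = sc$cell_ids,
                              patient = unname(sc$patient_of)),
                   paths$cell_meta, hash)
  paths$sc_truth <- file.path(dir, "sc", "truth.tsv")
  write_output_tsv(data.frame(cell = sc$cell_ids,
                              planted = unname(sc$planted)),
                   paths$sc_truth, hash)

  dir.create(file.path(dir, "bulk"), showWarnings = FALSE)
  paths$bulk_counts <- file.path(dir, "bulk", "counts.tsv")
  write_matrix_tsv(bulk$counts, paths$bulk_counts, "gene", hash)
  paths$gene_lengths <- file.path(dir, "bulk", "gene_lengths.tsv")
  write_output_tsv(data.frame(gene = names(bulk$gene_lengths),
                              length = unname(bulk$gene_lengths)),
                   paths$gene_lengths, hash)
  paths$bulk_design <- file.path(dir, "bulk", "design.tsv")
  write_output_tsv(bulk$design, paths$bulk_design, hash)
  paths$bulk_truth <- file.path(dir, "bulk", "truth.tsv")
  write_output_tsv(data.frame(gene = names(bulk$planted),
                              planted = unname(bulk$planted),
                              direction = unname(bulk$direction)),
                   paths$bulk_truth, hash)
  paths$gene_sets <- file.path(dir, "bulk", "gene_sets.gmt")
  write_gmt(bulk$gene_sets, paths$gene_sets)

  dir.create(file.path(dir, "meth"), showWarnings = FALSE)
  paths$beta <- file.path(dir, "meth", "beta.tsv")
  write_matrix_tsv(meth$beta, paths$beta, "probe", hash)
  paths$probe_annotation <- file.path(dir, "meth", "probe_annotation.tsv")
  write_output_tsv(meth$annotation, paths$probe_annotation, hash)
  paths$meth_design <- file.path(dir, "meth", "design.tsv")
  write_output_tsv(meth$design, paths$meth_design, hash)
  paths$meth_truth <- file.path(dir, "meth", "truth.tsv")
  write_output_tsv(data.frame(probe = names(meth$planted),
                              planted = unname(meth$planted)),
                   paths$meth_truth, hash)
  for (f in names(meth$peaks)) {
    paths[[paste0("peaks_", f)]] <- file.path(dir, "meth",
                                              paste0("peaks_", f, ".bed"))
    write_bed(meth$peaks[[f]], paths[[paste0("peaks_", f)]])
  }
  paths$tss <- file.path(dir, "meth", "tss.tsv")
  write_output_tsv(meth$tss, paths$tss, hash)
  invisible(paths)
}
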