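# Small fixtures shared across test files. Everything is built in code;
# nothing is read from disk except files the tests themselves write.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(n_cells = 600, n_patients = 10,
                                 n_genes = 200, n_probes = 2000, seed = seed),
                            list(...))
  do.call(synthetic_config, args)
}

# tiny labelled expression matrix: 2 markers-high cells, 2 low cells
toy_matrix <- function() {
  m <- rbind(OCT4 = c(9, 8, 0, 0), SOX2 = c(7, 9, 1, 0),
             NANOG = c(8, 9, 0, 1),
             `HLA-A` = c(1, 2, 8, 9), `HLA-B` = c(2, 1, 9, 8),
             `HLA-C` = c(1, 1, 9, 9))
  colnames(m) <- paste0("c", 1:4)
  m
}

# brute-force per-base coverage consensus oracle on integer coordinates
consensus_oracle <- function(o, s, n, max_coord = 10000) {
  cov_of <- function(df) {
    covered <- rep(FALSE, max_coord)
    for (i in seq_len(nrow(df))) {
      lo <- df$start[i] + 1; hi <- min(df$end[i], max_coord)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    covered
  }
  all3 <- cov_of(o) & cov_of(s) & cov_of(n)
  r <- rle(all3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  data.frame(chrom = "chr1", start = starts[keep] - 1, end = ends[keep],
             stringsAsFactors = FALSE)
}

random_intervals <- function(k, max_coord = 10000) {
  start <- sample.int(max_coord - 50, k)
  data.frame(chrom = "chr1", start = start,
             end = start + sample.int(400, k, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
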