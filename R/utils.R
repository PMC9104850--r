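## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

#' Row-wise two-sided Wilcoxon rank-sum tests
#'
#' Vectorized rank-sum test applied independently to every row of a matrix,
#' comparing the columns flagged by `group2` against the remaining columns.
#' For group sizes of at most `exact_max` per group and rows without ties the
#' exact null distribution is used (via [stats::pwilcox()]); otherwise the
#' normal approximation with tie and continuity correction. Matches
#' [stats::wilcox.test()] in both regimes.
#'
#' Rows that are constant across all columns carry no rank information and
#' get p = 1.
#'
#' @param x numeric matrix (features x observations).
#' @param group2 logical vector over columns; `TRUE` marks the second group.
#' @param exact_max largest per-group size for which the exact distribution
#'   is used (default 10).
#' @return numeric vector of two-sided p-values, one per row.
#' @keywords internal
row_wilcoxon <- function(x, group2, exact_max = 10L) {
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  group2 <- as.logical(group2)
  .assert(length(group2) == ncol(x) && !anyNA(group2),
          "group2 must be a logical vector over the columns of x")
  n2 <- sum(group2); n1 <- sum(!group2)
  .assert(n1 >= 2 && n2 >= 2, "each group needs at least 2 observations")
  n <- n1 + n2

  rk <- t(apply(x, 1L, rank))           # mid-ranks, handles ties
  if (nrow(x) == 1L) rk <- matrix(rk, nrow = 1L)
  ## U statistic for group2 relative to group1
  U <- rowSums(rk[, group2, drop = FALSE]) - n2 * (n2 + 1) / 2
  mu <- n1 * n2 / 2

  ## per-row tie term sum(t^3 - t)
  tie_term <- apply(x, 1L, function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
  })
  constant <- tie_term >= n^3 - n - 1e-9   # single tie group covering the row

  p <- rep(NA_real_, nrow(x))
  use_exact <- n1 <= exact_max && n2 <= exact_max
  exact_rows <- use_exact & tie_term == 0
  if (any(exact_rows)) {
    u <- U[exact_rows]
    lo <- pwilcox(u, n2, n1)                 # P(U <= u)
    hi <- pwilcox(u - 1, n2, n1, lower.tail = FALSE)  # P(U >= u)
    p[exact_rows] <- pmin(1, 2 * pmin(lo, hi))
  }
  approx_rows <- which(!exact_rows & !constant)
  if (length(approx_rows)) {
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term[approx_rows] / (n * (n - 1)))
    z <- U[approx_rows] - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p[approx_rows] <- pmin(1, 2 * pnorm(-abs(z)))
  }
  p[constant] <- 1
  p
}

## log2 fold change with pseudocount, second group over first
.log2_ratio <- function(mean2, mean1, pseudocount = 1) {
  log2((mean2 + pseudocount) / (mean1 + pseudocount))
}

## canonical group handling: two-level design, reference = GBM-DC when present
.resolve_groups <- function(group) {
  group <- as.character(group)
  lev <- unique(group)
  .assert(length(lev) == 2L, "exactly two groups are required, got: %s",
          paste(lev, collapse = ", "))
  if (all(c("GBM-DC", "ic-GSC") %in% lev)) lev <- c("GBM-DC", "ic-GSC")
  list(ref = lev[1L], alt = lev[2L], is_alt = group == lev[2L])
}

## md5 hash of an R object via its canonical JSON rendering
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
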