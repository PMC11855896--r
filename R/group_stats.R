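#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test with midranks for ties. The p-value is exact
#' (from the null U distribution) when there are no ties and
#' `n_x * n_y <= 400`; otherwise a normal approximation with tie correction
#' and (by default) continuity correction is used. A combined sample with no
#' variation returns p = 1 with a warning.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` chooses automatically. Exact is unavailable with ties.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return List with `U` (statistic for the first sample), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided p = 0.1
mann_whitney_u <- function(x, y, exact = NULL, continuity = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  comb <- c(x, y)
  if (diff(range(comb)) == 0) {
    warning("combined sample is constant; p = 1")
    return(list(U = nx * ny / 2, p = 1, method = "degenerate"))
  }
  r <- rank(comb)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(comb))
  if (is.null(exact)) exact <- !ties && nx * ny <= 400
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  mn <- nx * ny
  if (exact) {
    p <- if (U == mn / 2) 1
         else if (U < mn / 2) 2 * stats::pwilcox(U, nx, ny)
         else 2 * (1 - stats::pwilcox(U - 1, nx, ny))
    p <- min(1, p)
    return(list(U = U, p = p, method = "exact"))
  }
  tie_tab <- table(comb)
  sigma2 <- mn / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("zero variance after tie correction; p = 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }
  z <- U - mn / 2
  if (continuity) z <- z - sign(z) * 0.5
  p <- min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  list(U = U, p = p, method = "normal")
}

#' Bonferroni-corrected significance threshold
#'
#' alpha divided by the family size. The unrounded value is used for
#' significance decisions; the value rounded to four decimals is what gets
#' printed in result tables (0.05 over families of 6, 13 and 20 features
#' prints as 0.0083, 0.0038 and 0.0025).
#'
#' @param alpha family-wise error rate (in (0, 1)).
#' @param m family size (number of tests, >= 1).
#' @return List with `threshold` (exact) and `display` (rounded to 4 dp).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(m) != 1L || is.na(m) || m < 1) stop("family size m must be >= 1", call. = FALSE)
  th <- alpha / m
  list(threshold = th, display = round_half_up(th, 4))
}

#' Pearson chi-squared test on a count table
#'
#' Pearson chi-squared without Yates continuity correction by default
#' (df = (r-1)(c-1)); a warning is raised when any expected count is below 5.
#'
#' @param counts matrix of non-negative integer counts (at least 2 columns).
#' @param correct apply the Yates correction (default `FALSE`).
#' @return List with `statistic`, `p`, `df`, `expected`.
#' @export
chi_squared <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (ncol(counts) < 2L || nrow(counts) < 2L) {
    stop("need at least a 2x2 count table", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in count table", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warning("expected count below 5; chi-squared approximation may be poor")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter), expected = expected)
}

#' Compare every feature between stable and labile groups
#'
#' Runs the two-sided Mann-Whitney test per feature with a family-wise
#' Bonferroni threshold. The family size defaults to the number of features
#' supplied, matching the convention of a separate correction per table
#' (6 genomic features, 13 protein properties, 20 residues). Missing values
#' are dropped per feature; features leaving an empty group are skipped with
#' a warning.
#'
#' @param features data.frame with a `gene_id` (or `seq_id`) column and one
#'   numeric column per feature.
#' @param labels data.frame with `gene_id` and `class` columns
#'   (`"stable"` / `"labile"`; other classes are ignored).
#' @param family character vector of feature names to test (defaults to all
#'   numeric columns); also sets the Bonferroni family size `m`.
#' @param alpha family-wise error rate (default 0.05).
#' @param ... passed to [mann_whitney_u()].
#' @return data.frame with one row per feature: `feature`, `median_stable`,
#'   `median_labile`, `n_stable`, `n_labile`, `U`, `p`, `alpha_corr`
#'   (4-dp display value), `significant` (decision against the unrounded
#'   threshold).
#' @export
compare_groups <- function(features, labels, family = NULL, alpha = 0.05, ...) {
  id_col <- intersect(c("gene_id", "seq_id"), names(features))[1L]
  if (is.na(id_col)) stop("features must carry a gene_id or seq_id column", call. = FALSE)
  if (is.null(family)) {
    family <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                      id_col)
  }
  missing_feats <- setdiff(family, names(features))
  if (length(missing_feats)) {
    stop(sprintf("feature(s) not in table: %s", paste(missing_feats, collapse = ", ")),
         call. = FALSE)
  }
  cls <- labels$class[match(features[[id_col]], labels$gene_id)]
  th <- bonferroni_threshold(alpha, length(family))
  rows <- lapply(family, function(feat) {
    v <- features[[feat]]
    xs <- v[cls == "stable" & !is.na(v) & !is.na(cls)]
    yl <- v[cls == "labile" & !is.na(v) & !is.na(cls)]
    if (!length(xs) || !length(yl)) {
      warning(sprintf("feature '%s': a group is empty after NA removal; skipped", feat))
      return(NULL)
    }
    mw <- suppressWarnings(mann_whitney_u(xs, yl, ...))
    data.frame(feature = feat,
               median_stable = stats::median(xs),
               median_labile = stats::median(yl),
               n_stable = length(xs), n_labile = length(yl),
               U = mw$U, p = mw$p,
               alpha_corr = th$display,
               significant = mw$p < th$threshold,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(feature = character(0), median_stable = numeric(0),
                      median_labile = numeric(0), n_stable = integer(0),
                      n_labile = integer(0), U = numeric(0), p = numeric(0),
                      alpha_corr = numeric(0), significant = logical(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
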