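#' Differential abundance between two groups (volcano statistics)
#'
#' Per feature: log2 fold change of group means (positive = higher in
#' the first-named group), two-sided Welch (unequal variance) t-test,
#' Benjamini-Hochberg adjustment across tested features, significance at
#' `alpha`. Features are expected on a log scale; samples should already
#' be collapsed to the experimental unit (beers, not injections). A
#' feature missing in an entire group is flagged and excluded from
#' testing but retained in the output with undefined p.
#'
#' @param m features x samples matrix on log scale.
#' @param labels group label per sample (exactly 2 levels, each with at
#'   least 2 samples).
#' @param group1 which level is the "first-named" group for the fold
#'   change sign; default the first level encountered.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame `feature`, `log2fc`, `p`, `p_adj`, `significant`,
#'   `tested`.
#' @export
volcano <- function(m, labels, group1 = NULL, alpha = 0.05) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly 2 levels")
  if (is.null(group1)) group1 <- lv[1L]
  group2 <- setdiff(lv, group1)
  i1 <- which(labels == group1); i2 <- which(labels == group2)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("both groups need >= 2 samples")
  nfeat <- nrow(m)
  log2fc <- p <- rep(NA_real_, nfeat)
  tested <- rep(FALSE, nfeat)
  # data are log10; fold change reported in log2 units
  for (f in seq_len(nfeat)) {
    x1 <- m[f, i1]; x2 <- m[f, i2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2L || length(x2) < 2L) next
    log2fc[f] <- (mean(x1) - mean(x2)) / log10(2)
    p[f] <- tryCatch(stats::t.test(x1, x2, var.equal = FALSE)$p.value,
                     error = function(e) NA_real_)
    tested[f] <- !is.na(p[f])
  }
  p_adj <- rep(NA_real_, nfeat)
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(feature = if (is.null(rownames(m))) as.character(seq_len(nfeat))
             else rownames(m),
             log2fc = log2fc, p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha,
             tested = tested, stringsAsFactors = FALSE)
}

#' Summed normalized abundance per protein class and beer
#'
#' @param pa protein abundance table from [protein_abundance()].
#' @param class_map named character vector accession -> class, or a
#'   two-column data.frame/TSV path (accession, class). Accessions not
#'   in the map are ignored.
#' @param value which abundance column to sum (default `norm_total`).
#' @return data.frame `sample_id`, `class`, `abundance`.
#' @export
class_abundance <- function(pa, class_map, value = "norm_total") {
  if (is.character(class_map) && length(class_map) == 1 &&
      file.exists(class_map))
    class_map <- utils::read.delim(class_map, stringsAsFactors = FALSE)
  if (is.data.frame(class_map))
    class_map <- stats::setNames(class_map[[2]], class_map[[1]])
  pa$class <- unname(class_map[pa$accession])
  dt <- data.table::as.data.table(pa[!is.na(pa$class), ])
  if (!nrow(dt)) {
    warning("no accession matched the class map")
    return(data.frame(sample_id = character(0), class = character(0),
                      abundance = numeric(0)))
  }
  out <- dt[, .(abundance = sum(.SD[[1]], na.rm = TRUE)),
            by = .(sample_id, class), .SDcols = value]
  empty <- setdiff(unique(class_map), unique(out$class))
  if (length(empty))
    warning("class(es) with no detected protein: ",
            paste(empty, collapse = ", "))
  as.data.frame(out[order(sample_id, class)])
}

#' Ordinary least squares of a foam variable on class abundance
#'
#' Simple linear regression `y ~ x` on per-beer means, reporting slope,
#' intercept, coefficient of determination and the two-sided p-value for
#' the slope.
#'
#' @param x,y numeric vectors (one value per beer; >= 3 complete pairs).
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
foam_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete (x, y) pairs")
  if (stats::var(x) == 0) stop("zero-variance predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2L, 4L]),
       n = n)
}

#' Adjusted Rand index between two partitions
#' @param a,b label vectors of equal length.
#' @return scalar between -1 and 1; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_a <- ch2(rowSums(tab)); sum_b <- ch2(colSums(tab))
  nC2 <- ch2(length(a))
  expected <- sum_a * sum_b / nC2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
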