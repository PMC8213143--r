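# Statistical comparison stage: Spearman feature-volume correlation,
# Wilcoxon rank-sum screening of pathological vs co-lateral control VOIs,
# significance counting and R^2 map tables.

statRecord <- function(kind, value, n, degenerate = FALSE, extra = list()) {
  c(list(kind = kind, value = value, n = n, degenerate = degenerate), extra)
}

#' Spearman correlation between a texture index and lesion volume
#'
#' Spearman rho with average-rank tie handling; \code{r2} is reported as
#' \code{rho^2}. A constant feature or constant volume vector yields a
#' degenerate record (rho undefined, excluded from maps rather than coerced
#' to 0). The p-value uses the t approximation (ties allowed).
#'
#' @param values per-lesion feature values.
#' @param volumes per-lesion volumes (mm^3), same length, >= 3 pairs.
#' @return list with \code{rho}, \code{r2}, \code{p}, \code{n},
#'   \code{degenerate}.
#' @examples
#' spearmanFeatureVolume(c(10, 20, 30), c(1, 2, 3))$rho  # 1
#' @export
spearmanFeatureVolume <- function(values, volumes) {
  ok <- is.finite(values) & is.finite(volumes)
  values <- values[ok]; volumes <- volumes[ok]
  n <- length(values)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(values) == 0 || stats::sd(volumes) == 0)
    return(list(rho = NA_real_, r2 = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  rho <- stats::cor(values, volumes, method = "spearman")
  p <- suppressWarnings(
    stats::cor.test(values, volumes, method = "spearman",
                    exact = FALSE)$p.value)
  list(rho = rho, r2 = rho^2, p = p, n = n, degenerate = FALSE)
}

#' Wilcoxon rank-sum test: pathological vs control values
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p-value. The exact null
#' enumeration is used when the combined sample size is at most 10 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. Two identical constant samples are degenerate and
#' return p = 1.
#'
#' @param patho,control numeric samples, each of size >= 2.
#' @return list with \code{p}, \code{exact} (logical branch taken),
#'   \code{n1}, \code{n2}, \code{degenerate}.
#' @examples
#' ranksumDiseaseVsControl(c(1, 2), c(3, 4))$p  # exact: 1/3
#' @export
ranksumDiseaseVsControl <- function(patho, control) {
  patho <- patho[is.finite(patho)]; control <- control[is.finite(control)]
  n1 <- length(patho); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
  pooled <- c(patho, control)
  if (max(pooled) == min(pooled))
    return(list(p = 1, exact = FALSE, n1 = n1, n2 = n2, degenerate = TRUE))
  ties <- anyDuplicated(pooled) > 0
  useExact <- (n1 + n2 <= 10) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(patho, control, alternative = "two.sided",
                       exact = useExact, correct = TRUE))
  list(p = wt$p.value, exact = useExact, n1 = n1, n2 = n2,
       degenerate = FALSE)
}

#' Count significant screening tests per design cell
#'
#' Counts rank-sum records with p strictly below \code{alpha} (no
#' multiple-testing correction, matching the reporting convention of the
#' screening stage); degenerate records count as non-significant.
#'
#' @param records data.frame with columns \code{p}, \code{degenerate}, and
#'   the grouping columns \code{method}, \code{param}, \code{segmentation}.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (method, param, segmentation):
#'   \code{n_tests}, \code{n_significant}, \code{alpha}.
#' @export
countSignificant <- function(records, alpha = 0.05) {
  sig <- !is.na(records$p) & records$p < alpha &
    !(records$degenerate %in% TRUE)
  agg <- stats::aggregate(
    cbind(n_tests = rep(1L, nrow(records)), n_significant = as.integer(sig)),
    by = records[, c("method", "param", "segmentation"), drop = FALSE],
    FUN = sum)
  agg$alpha <- alpha
  agg[order(agg$method, agg$param, agg$segmentation), ]
}

#' Wide R-squared map of feature-volume correlations
#'
#' Reshapes Spearman records of one (method, param, segmentation) cell into
#' a wide table: features as rows, one column per group x contrast, holding
#' \code{rho^2}. Cells with \code{R^2 > 0.5} (i.e. \code{|R| > sqrt(0.5)},
#' about 0.71) are flagged as highly volume-correlated in a parallel logical
#' table. Degenerate records are emitted as \code{NA}.
#'
#' @param records data.frame with columns \code{feature}, \code{group},
#'   \code{contrast}, \code{r2}, \code{degenerate}.
#' @param r2Threshold high-correlation threshold on R^2 (default 0.5).
#' @return list with \code{r2} (wide data.frame), \code{high} (logical
#'   data.frame of flags), \code{threshold_abs_r = sqrt(r2Threshold)},
#'   \code{n_cells}.
#' @export
correlationMatrixTable <- function(records, r2Threshold = 0.5) {
  records$col <- paste(records$group, records$contrast, sep = ".")
  feats <- unique(records$feature)
  cols <- unique(records$col)
  r2 <- matrix(NA_real_, length(feats), length(cols),
               dimnames = list(feats, cols))
  for (k in seq_len(nrow(records))) {
    v <- records$r2[k]
    if (records$degenerate[k] %in% TRUE) v <- NA_real_
    r2[records$feature[k], records$col[k]] <- v
  }
  miss <- sum(is.na(r2) & TRUE)
  list(r2 = as.data.frame(r2),
       high = as.data.frame(!is.na(r2) & r2 > r2Threshold),
       threshold_abs_r = sqrt(r2Threshold),
       n_cells = length(feats) * length(cols),
       n_missing_or_degenerate = miss)
}
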