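# Group-comparison statistics: pairwise Wilcoxon rank-sum with
# Benjamini-Hochberg false-discovery-rate control for linear quantities
# (SASA, shell densities), and Watson's two-sample U^2 homogeneity test for
# circular quantities (chi dihedrals).

#' Pairwise Wilcoxon rank-sum tests with FDR control
#'
#' Two-sided rank-sum test for every pair of groups (exact enumeration for
#' small tie-free samples, normal approximation with tie correction
#' otherwise, as provided by [stats::wilcox.test()]); raw p-values are
#' adjusted by Benjamini-Hochberg within the family.
#'
#' @param values numeric vector of observations.
#' @param groups group labels (same length as `values`).
#' @param family family identifier recorded on the output (one family per
#'   figure-panel analogue).
#' @return Data frame: group pair, W statistic, `p`, `p_adj`, `family`.
#' @export
pairwise_wilcoxon_fdr <- function(values, groups, family = "default") {
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2) abort_class("ContractViolation", "need at least two groups")
  split_vals <- split(values, groups)
  if (any(vapply(split_vals, length, 1L) == 0)) {
    abort_class("ContractViolation", "empty group")
  }
  pairs <- utils::combn(levels, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- split_vals[[pairs[1, j]]]
    b <- split_vals[[pairs[2, j]]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$family <- family
  out
}

# asymptotic upper critical values for Watson's U^2 (two-sample); standard
# circular-statistics tabulation
WATSON_U2_TABLE <- data.frame(alpha = c(0.001, 0.01, 0.05, 0.10),
                              critical = c(0.385, 0.268, 0.187, 0.152))

#' Watson's two-sample U^2 statistic
#'
#' Rotation-invariant Cramer-von Mises-type statistic comparing two samples
#' of angles on the circle.
#'
#' @param sample1,sample2 angles in degrees.
#' @return The U^2 statistic.
#' @export
watson_u2_statistic <- function(sample1, sample2) {
  a1 <- sample1 %% 360
  a2 <- sample2 %% 360
  n1 <- length(a1); n2 <- length(a2); n <- n1 + n2
  all_angles <- c(a1, a2)
  ord <- order(all_angles)
  from1 <- c(rep(TRUE, n1), rep(FALSE, n2))[ord]
  f1 <- cumsum(from1) / n1
  f2 <- cumsum(!from1) / n2
  d <- f1 - f2
  (n1 * n2 / n^2) * (sum(d^2) - sum(d)^2 / n)
}

#' Watson's two-sample U^2 homogeneity test
#'
#' Tests whether two circular samples come from a common distribution. The
#' tabulated mode brackets the p-value between asymptotic critical levels
#' (the test natively yields p-value ranges, not point p-values); the
#' permutation mode estimates an exact p-value by random relabeling.
#'
#' @param sample1,sample2 angles in degrees.
#' @param method "table" or "permutation".
#' @param n_perm permutation count.
#' @param min_n sample size under which the tabulated critical values are
#'   unreliable; smaller samples fall back to permutation with a warning.
#' @return List: `u2`, `p_lower`, `p_upper`, `p_perm` (permutation mode),
#'   `method`.
#' @export
watsons_u2 <- function(sample1, sample2, method = c("table", "permutation"),
                       n_perm = 2000, min_n = 8) {
  method <- match.arg(method)
  if (method == "table" && (length(sample1) < min_n || length(sample2) < min_n)) {
    warning(structure(class = c("SmallSampleWarning", "warning", "condition"),
                      list(message = "small sample; using permutation p-value",
                           call = sys.call())))
    method <- "permutation"
  }
  u2 <- watson_u2_statistic(sample1, sample2)
  if (method == "table") {
    tab <- WATSON_U2_TABLE[order(WATSON_U2_TABLE$critical), ]
    below <- tab$alpha[tab$critical <= u2]
    above <- tab$alpha[tab$critical > u2]
    p_upper <- if (length(below)) min(below) else 1
    p_lower <- if (length(above)) max(above) else 0
    return(list(u2 = u2, p_lower = p_lower, p_upper = p_upper,
                p_perm = NA_real_, method = "table"))
  }
  pooled <- c(sample1, sample2)
  n1 <- length(sample1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pick <- sample.int(length(pooled), n1)
    u2b <- watson_u2_statistic(pooled[pick], pooled[-pick])
    if (u2b >= u2) count <- count + 1L
  }
  p <- (count + 1) / (n_perm + 1)
  list(u2 = u2, p_lower = p, p_upper = p, p_perm = p, method = "permutation")
}
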