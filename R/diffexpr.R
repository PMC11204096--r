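#' Median-of-ratios size factors
#'
#' Per-sample normalization constants following the median-of-ratios
#' convention: each sample's counts are divided by the per-feature
#' geometric mean over samples, and the sample's size factor is the median
#' of those ratios over features, computed over features with all-positive
#' counts. Factors are rescaled so their geometric mean is exactly 1.
#'
#' @param counts a [count_matrix()] or named numeric matrix
#'   (features x samples).
#' @param pseudo_reference if no feature has all-positive counts, setting
#'   this to `TRUE` falls back to a pseudo-reference built from positive
#'   counts only (geometric mean over the positive entries of each
#'   feature, medians taken over the positive cells of each sample).
#' @return Numeric vector of positive size factors, one per sample, with
#'   `exp(mean(log(sf))) == 1` within 1e-9.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  x <- as_counts(counts)
  if (ncol(x) < 1L) abort("'counts' has no samples")
  all_pos <- rowSums(x > 0) == ncol(x)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      abort(paste(
        "no feature has all-positive counts; rerun with",
        "pseudo_reference = TRUE to use a positive-count pseudo-reference"
      ))
    }
    some_pos <- rowSums(x > 0) > 0
    if (!any(some_pos)) abort("all counts are zero; size factors undefined")
    xp <- x[some_pos, , drop = FALSE]
    ref <- apply(xp, 1L, function(r) exp(mean(log(r[r > 0]))))
    sf <- apply(xp / ref, 2L, function(col) median(col[col > 0]))
  } else {
    xa <- x[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(xa)))
    sf <- apply(xa / ref, 2L, median)
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(x)
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving with
#' the input vector.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("'p' must be numeric")
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("'p' must contain values in [0, 1] with no missing entries")
  }
  p.adjust(p, method = "BH")
}

row_group_stats <- function(x, idx) {
  n <- length(idx)
  m <- rowMeans(x[, idx, drop = FALSE])
  v <- rowSums((x[, idx, drop = FALSE] - m)^2) / (n - 1L)
  list(mean = m, var = v, n = n)
}

# Method-of-moments NB dispersion. Per feature: solves Var = mu + a*mu^2
# within groups. Pooled: ratio estimator over all features with an E[m^2]
# bias correction, appropriate when features share a common dispersion.
mom_dispersion <- function(g1, g2, floor = 1e-8) {
  num <- (g1$n - 1L) * (g1$var - g1$mean) + (g2$n - 1L) * (g2$var - g2$mean)
  den <- (g1$n - 1L) * g1$mean^2 + (g2$n - 1L) * g2$mean^2
  per <- ifelse(den > 0, num / den, 0)
  den_pool <- (g1$n - 1L) * pmax(g1$mean^2 - g1$var / g1$n, 0) +
    (g2$n - 1L) * pmax(g2$mean^2 - g2$var / g2$n, 0)
  pooled <- if (sum(den_pool) > 0) sum(num) / sum(den_pool) else 0
  list(per_feature = pmax(per, floor), pooled = max(pooled, floor))
}

#' Simplified negative-binomial differential expression test
#'
#' A DESeq2-like two-group comparison without shrinkage estimators:
#' median-of-ratios normalization, log2 fold change with pseudocount,
#' method-of-moments NB dispersion, and a Wald-type statistic whose
#' two-sided p-value comes from the normal approximation. P-values are
#' Benjamini-Hochberg adjusted over the tested features, and features are
#' called `up` / `down` when `p_adj < alpha` and the log2 fold change
#' exceeds `lfc_threshold` in magnitude. Features with zero counts in all
#' samples are excluded from testing and reported with call
#' `not_expressed`.
#'
#' @param counts a [count_matrix()] or named numeric matrix.
#' @param meta metadata data.frame covering the matrix samples (matched by
#'   `sample_id`).
#' @param grouping `"diet"` (HFD vs SD), `"mmi"` or `"ph"` (lesion present
#'   vs absent, regardless of diet).
#' @param alpha adjusted-p significance level (0.05 for kidney analyses,
#'   0.1 for urine analyses).
#' @param lfc_threshold minimum absolute log2 fold change for a call.
#' @param pseudocount added to normalized group means before the log2
#'   ratio, bounding fold changes in the presence of zeros.
#' @param dispersion_mode `"pooled"` (default) shares one
#'   method-of-moments dispersion across features; `"per_feature"` uses
#'   each feature's own (noisier) estimate.
#' @param pseudo_reference passed to [size_factors()].
#' @return A data.frame (class `de_result`) with columns `feature_id`,
#'   `base_mean`, `log2fc` (group2 vs group1), `stat`, `p_raw`, `p_adj`,
#'   `call`; attributes record the groups and parameters.
#' @export
de_test <- function(counts, meta, grouping = c("diet", "mmi", "ph"),
                    alpha = 0.05, lfc_threshold = 1, pseudocount = 0.5,
                    dispersion_mode = c("pooled", "per_feature"),
                    pseudo_reference = FALSE) {
  grouping <- match.arg(grouping)
  dispersion_mode <- match.arg(dispersion_mode)
  assert_probability(alpha, "alpha")
  assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  x <- as_counts(counts)
  idx <- match(colnames(x), meta$sample_id)
  if (anyNA(idx)) {
    abort("metadata is missing sample(s): ",
          paste(colnames(x)[is.na(idx)], collapse = ", "))
  }
  meta <- meta[idx, , drop = FALSE]
  grp2 <- switch(grouping,
    diet = meta$diet == "HFD",
    mmi = meta$mmi,
    ph = meta$ph
  )
  if (anyNA(grp2)) {
    abort(sprintf("grouping '%s' has missing labels for some samples", grouping))
  }
  if (length(unique(grp2)) < 2L) {
    abort(sprintf("grouping '%s' is degenerate: only one class present", grouping))
  }
  if (sum(grp2) < 2L || sum(!grp2) < 2L) {
    abort(sprintf("grouping '%s' needs >= 2 samples per class", grouping))
  }
  labels <- switch(grouping, diet = c("SD", "HFD"),
                   mmi = c("no_mmi", "mmi"), ph = c("no_ph", "ph"))

  expressed <- rowSums(x) > 0
  sf <- size_factors(x[expressed, , drop = FALSE], pseudo_reference = pseudo_reference)
  norm <- sweep(x[expressed, , drop = FALSE], 2L, sf, "/")

  g1 <- row_group_stats(norm, which(!grp2))
  g2 <- row_group_stats(norm, which(grp2))
  disp <- mom_dispersion(g1, g2)
  alpha_nb <- if (dispersion_mode == "pooled") disp$pooled else disp$per_feature

  c0 <- pseudocount
  lfc <- log2((g2$mean + c0) / (g1$mean + c0))
  # Var of a group mean of normalized NB counts, mu/dispersion plug-in
  inv_s1 <- mean(1 / sf[!grp2])
  inv_s2 <- mean(1 / sf[grp2])
  v1 <- (g1$mean * inv_s1 + alpha_nb * g1$mean^2) / g1$n
  v2 <- (g2$mean * inv_s2 + alpha_nb * g2$mean^2) / g2$n
  v_lfc <- (v1 / (g1$mean + c0)^2 + v2 / (g2$mean + c0)^2) / log(2)^2
  se <- sqrt(v_lfc)
  stat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p_raw <- 2 * pnorm(-abs(stat))
  p_adj <- bh_adjust(p_raw)
  call <- rep("ns", length(lfc))
  call[p_adj < alpha & lfc > lfc_threshold] <- "up"
  call[p_adj < alpha & lfc < -lfc_threshold] <- "down"

  res <- data.frame(
    feature_id = rownames(x),
    base_mean = NA_real_, log2fc = NA_real_, stat = NA_real_,
    p_raw = NA_real_, p_adj = NA_real_, call = "not_expressed",
    stringsAsFactors = FALSE
  )
  res$base_mean[expressed] <- rowMeans(norm)
  res$log2fc[expressed] <- lfc
  res$stat[expressed] <- stat
  res$p_raw[expressed] <- p_raw
  res$p_adj[expressed] <- p_adj
  res$call[expressed] <- call
  rownames(res) <- NULL
  structure(res, class = c("de_result", "data.frame"),
            grouping = grouping, groups = labels, alpha = alpha,
            lfc_threshold = lfc_threshold, dispersion = alpha_nb,
            dispersion_mode = dispersion_mode)
}

#' Features called differentially expressed
#' @param de a `de_result` from [de_test()].
#' @return Character vector of feature ids with call `up` or `down`.
#' @export
de_features <- function(de) {
  de$feature_id[de$call %in% c("up", "down")]
}

#' Complete-linkage hierarchical clustering of features
#'
#' Agglomerative clustering of features on squared Euclidean distances of
#' log2-transformed normalized counts (the transform used for heatmap row
#' ordering), with complete linkage.
#'
#' @param counts a [count_matrix()] or named numeric matrix with >= 2
#'   features.
#' @param normalize divide by median-of-ratios size factors first.
#' @param log_transform apply `log2(x + pseudocount)`.
#' @param pseudocount pseudocount for the log transform.
#' @param pseudo_reference passed to [size_factors()].
#' @return List with `order` (feature ids in dendrogram leaf order),
#'   `merge`, `height` (squared-Euclidean merge heights) and the
#'   underlying [stats::hclust] object.
#' @export
cluster_features <- function(counts, normalize = TRUE, log_transform = TRUE,
                             pseudocount = 0.5, pseudo_reference = FALSE) {
  x <- as_counts(counts)
  if (nrow(x) < 2L) abort("clustering needs at least 2 features")
  if (normalize) {
    sf <- size_factors(x, pseudo_reference = pseudo_reference)
    x <- sweep(x, 2L, sf, "/")
  }
  if (log_transform) x <- log2(x + pseudocount)
  d <- dist(x)^2
  hc <- hclust(d, method = "complete")
  list(order = rownames(x)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}
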