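#' Relative expression of one gene across samples
#'
#' Normalized counts divided by the gene's overall normalized mean, so the
#' output averages to exactly 1. This is the scale on which the
#' lesion-association statistic is computed.
#'
#' @param x non-negative counts vector (one gene, all samples).
#' @param size_factors per-sample size factors; defaults to 1.
#' @return Numeric vector with `mean(out) == 1`.
#' @export
relative_expression <- function(x, size_factors = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort("'x' must be a finite non-negative counts vector")
  }
  sf <- size_factors %||% rep(1, length(x))
  if (length(sf) != length(x) || any(sf <= 0)) {
    abort("'size_factors' must be positive and match the length of 'x'")
  }
  norm <- x / sf
  m <- mean(norm)
  if (m == 0) abort("all-zero gene: relative expression undefined")
  norm / m
}

#' Lesion-association statistic
#'
#' Difference between the average relative expression of samples with and
#' without the lesion: `t = mean(rel | lesion) - mean(rel | no lesion)`.
#'
#' @param rel relative-expression vector (see [relative_expression()]).
#' @param lesion logical vector of the same length.
#' @return The statistic `t`.
#' @export
lesion_statistic <- function(rel, lesion) {
  if (!is.logical(lesion) || anyNA(lesion)) {
    abort("'lesion' must be a logical vector without missing values")
  }
  if (length(rel) != length(lesion)) {
    abort("'rel' and 'lesion' must have equal length")
  }
  if (!any(lesion) || all(lesion)) {
    abort("single-class lesion labels: statistic undefined")
  }
  mean(rel[lesion]) - mean(rel[!lesion])
}

# weight vector turning rel %*% w into the lesion statistic
lesion_weights <- function(lesion) {
  ifelse(lesion, 1 / sum(lesion), -1 / sum(!lesion))
}

#' Permutation test for lesion-expression association
#'
#' For every gene, compares the observed lesion-association statistic on
#' relative expression against an empirical null obtained by uniformly
#' resampling the lesion-label assignment while preserving class sizes.
#' The same resampled label sequence is shared by all genes, preserving
#' cross-gene dependence. Two-sided Monte-Carlo p-values use the +1
#' correction, `p = (1 + #{|T*| >= |t_obs|}) / (B + 1)`; when the number
#' of distinct label assignments is at most `B` the test switches to
#' exhaustive enumeration (`exhaustive = TRUE`, seed-independent,
#' `p = #{|T*| >= |t_obs|} / N` including the identity assignment).
#'
#' @param counts a [count_matrix()] or named numeric matrix.
#' @param meta metadata data.frame matched by `sample_id`; only kidney
#'   samples carry lesion labels.
#' @param lesion `"mmi"` or `"ph"`.
#' @param B number of random label assignments (study default 100000).
#' @param seed integer seed for Monte-Carlo mode.
#' @param mode `"auto"` (exhaustive when feasible), `"monte_carlo"`, or
#'   `"exhaustive"` (error if the enumeration exceeds `B`).
#' @param pseudo_reference passed to [size_factors()].
#' @return A data.frame (class `permutation_result`) with columns
#'   `gene_id`, `t_obs`, `null_mean`, `null_sd`, `p_emp`,
#'   `n_permutations`, `exhaustive`. All-zero genes are excluded; their
#'   ids are kept in attribute `excluded`.
#' @export
permutation_test <- function(counts, meta, lesion = c("mmi", "ph"),
                             B = 100000L, seed = NULL,
                             mode = c("auto", "monte_carlo", "exhaustive"),
                             pseudo_reference = FALSE) {
  lesion <- match.arg(lesion)
  mode <- match.arg(mode)
  B <- assert_count(B, "B", min = 1L)
  low_b <- B < 100L
  if (low_b) {
    warning("B < 100 gives a very coarse empirical null; recorded in provenance",
            call. = FALSE)
  }
  x <- as_counts(counts)
  idx <- match(colnames(x), meta$sample_id)
  if (anyNA(idx)) {
    abort("metadata is missing sample(s): ",
          paste(colnames(x)[is.na(idx)], collapse = ", "))
  }
  lab <- meta[[lesion]][idx]
  if (anyNA(lab)) abort(sprintf("lesion '%s' has missing labels", lesion))
  n1 <- sum(lab)
  n0 <- sum(!lab)
  if (n1 < 2L || n0 < 2L) {
    abort(sprintf("lesion '%s' needs >= 2 samples per class (found %d / %d)",
                  lesion, n1, n0))
  }
  n <- length(lab)

  expressed <- rowSums(x) > 0
  excluded <- rownames(x)[!expressed]
  xe <- x[expressed, , drop = FALSE]
  if (nrow(xe) == 0L) abort("no expressed genes: permutation test undefined")
  sf <- size_factors(xe, pseudo_reference = pseudo_reference)
  norm <- sweep(xe, 2L, sf, "/")
  rel <- norm / rowMeans(norm)

  t_obs <- as.vector(rel %*% lesion_weights(lab))

  n_assign <- choose(n, n1)
  exhaustive <- switch(mode,
    auto = n_assign <= B,
    monte_carlo = FALSE,
    exhaustive = TRUE
  )
  if (mode == "exhaustive" && n_assign > B) {
    abort(sprintf("exhaustive enumeration needs %s assignments but B = %d",
                  format(n_assign, big.mark = ","), B))
  }

  g <- nrow(rel)
  # relative expression is on a unit-mean scale, so an absolute tolerance
  # guards the >= comparison against BLAS rounding (identity/complement
  # assignments must tie with the observed statistic exactly)
  abs_obs <- abs(t_obs) - 1e-9
  if (exhaustive) {
    combos <- combn(n, n1)
    W <- matrix(-1 / n0, n, ncol(combos))
    W[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- 1 / n1
    T_null <- rel %*% W
    exceed <- rowSums(abs(T_null) >= abs_obs)
    p_emp <- exceed / ncol(combos)
    null_mean <- rowMeans(T_null)
    null_sd <- sqrt(rowSums((T_null - null_mean)^2) / (ncol(combos) - 1L))
    n_perm <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- numeric(g)
    s1 <- numeric(g)
    s2 <- numeric(g)
    done <- 0L
    chunk <- max(1L, min(B, as.integer(2e6 / n)))
    while (done < B) {
      b <- min(chunk, B - done)
      W <- matrix(-1 / n0, n, b)
      les_idx <- vapply(seq_len(b), function(i) sample.int(n, n1), integer(n1))
      W[cbind(as.vector(les_idx), rep(seq_len(b), each = n1))] <- 1 / n1
      T_null <- rel %*% W
      exceed <- exceed + rowSums(abs(T_null) >= abs_obs)
      s1 <- s1 + rowSums(T_null)
      s2 <- s2 + rowSums(T_null^2)
      done <- done + b
    }
    p_emp <- (1 + exceed) / (B + 1)
    null_mean <- s1 / B
    null_sd <- sqrt(pmax(s2 / B - null_mean^2, 0) * B / (B - 1L))
    n_perm <- B
  }

  res <- data.frame(
    gene_id = rownames(rel), t_obs = t_obs, null_mean = null_mean,
    null_sd = null_sd, p_emp = p_emp, n_permutations = n_perm,
    exhaustive = exhaustive, stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res, class = c("permutation_result", "data.frame"),
            lesion = lesion, n_lesion = n1, n_no_lesion = n0,
            excluded = excluded, low_b = low_b, seed = seed)
}
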