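# Independent brute-force oracles. Each deliberately uses a different code
# path from the implementation it checks.

# rank-then-Pearson Spearman: explicit average ranks and the raw Pearson sum
# formula, no call to cor()
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# median-of-ratios size factors, loop form
oracle_size_factors <- function(x) {
  pos <- apply(x, 1L, function(r) all(r > 0))
  stopifnot(any(pos))
  xp <- x[pos, , drop = FALSE]
  geo <- numeric(nrow(xp))
  for (i in seq_len(nrow(xp))) geo[i] <- prod(xp[i, ])^(1 / ncol(xp))
  sf <- numeric(ncol(xp))
  for (j in seq_len(ncol(xp))) sf[j] <- median(xp[, j] / geo)
  sf / prod(sf)^(1 / length(sf))
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (k in rev(seq_len(m))) {
    running <- min(running, p[o[k]] * m / k)
    adj[o[k]] <- running
  }
  adj
}

# naive O(n^3) agglomerative complete linkage on a squared Euclidean
# distance matrix; returns the sorted merge heights
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))^2
  n <- nrow(d)
  active <- seq_len(n)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b && d[active[a], active[b]] < best) {
          best <- d[active[a], active[b]]
          bi <- a; bj <- b
        }
      }
    }
    heights[step] <- best
    ci <- active[bi]; cj <- active[bj]
    for (k in active) { # complete linkage: max distance to the new cluster
      d[ci, k] <- d[k, ci] <- max(d[ci, k], d[cj, k])
    }
    d[ci, ci] <- 0
    active <- active[-bj]
  }
  sort(heights)
}

# two-group mean difference via explicit sums
oracle_mean_diff <- function(v, grp) {
  s1 <- 0; n1 <- 0; s0 <- 0; n0 <- 0
  for (i in seq_along(v)) {
    if (grp[i]) { s1 <- s1 + v[i]; n1 <- n1 + 1 }
    else { s0 <- s0 + v[i]; n0 <- n0 + 1 }
  }
  s1 / n1 - s0 / n0
}

# exhaustive two-sided permutation p for one gene, independent enumeration
oracle_exhaustive_p <- function(rel, lesion) {
  n <- length(rel)
  n1 <- sum(lesion)
  combos <- combn(n, n1)
  t_obs <- oracle_mean_diff(rel, lesion)
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    grp <- seq_len(n) %in% combos[, j]
    if (abs(oracle_mean_diff(rel, grp)) >= abs(t_obs) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# whole-word case-insensitive keyword scan, token-by-token (no regex)
oracle_categorize <- function(text, scheme) {
  toks <- strsplit(tolower(gsub("[^a-z0-9]+", " ", tolower(text))), " +")[[1]]
  toks <- toks[toks != ""]
  padded <- paste0(" ", paste(toks, collapse = " "), " ")
  cats <- unique(scheme$category)
  hit <- vapply(cats, function(cat) {
    kws <- tolower(scheme$keyword[scheme$category == cat])
    any(vapply(kws, function(k) {
      ktoks <- strsplit(gsub("[^a-z0-9]+", " ", k), " +")[[1]]
      grepl(paste0(" ", paste(ktoks, collapse = " "), " "), padded, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  if (any(hit)) paste(cats[hit], collapse = ";") else "uncategorized"
}
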