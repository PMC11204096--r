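test_that("Spearman rho handles exact monotone cases and rejects constants", {
  expect_equal(spearman_rho(1:4, 4:1), -1)
  expect_equal(spearman_rho(c(2, 9, 4, 7), c(2, 9, 4, 7)), 1)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(spearman_rho(1:3, c(5, 5, 5)), "undefined correlation")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(1:4, 1:3), "equal length")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "no missing")
})

test_that("Spearman rho matches the rank-then-Pearson oracle on tied data", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:25, 1)
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- sample(1:6, n, replace = TRUE) + runif(n, 0, 0.01)
    if (min(x) == max(x) || min(y) == max(y)) next
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("a gene anti-correlated with four DE miRNAs becomes a multiplicity-4 hub", {
  # crafted panel: four miRNAs rise with an index variable, PTEN falls with
  # it, one decoy miRNA is flat noise
  set.seed(3)
  n <- 12
  idx <- seq_len(n)
  # flat ballast features keep the median-of-ratios size factors near 1 so
  # the engineered trends survive normalization
  ballast <- function(k, prefix) {
    b <- matrix(rpois(k * n, 100) + 1, k, n)
    rownames(b) <- sprintf("%s%02d", prefix, seq_len(k))
    b
  }
  mi <- rbind(
    "miR-22-3p" = 50 + 10 * idx + rpois(n, 4),
    "miR-22-5p" = 30 + 8 * idx + rpois(n, 4),
    "miR-144-3p" = 20 + 12 * idx + rpois(n, 4),
    "miR-205" = 80 + 15 * idx + rpois(n, 4),
    "miR-null" = rpois(n, 60) + 1,
    ballast(20, "miR-flat")
  )
  mr <- rbind(
    PTEN = round(4000 / idx) + rpois(n, 3),
    OTHER = rpois(n, 200) + 1,
    SILENT = rep(0L, n),
    ballast(20, "geneflat")
  )
  colnames(mi) <- colnames(mr) <- sprintf("s%02d", idx)
  map <- data.frame(
    mirna_id = c("miR-22-3p", "miR-22-5p", "miR-144-3p", "miR-205", "miR-null",
                 "miR-205"),
    gene_id = c("PTEN", "PTEN", "PTEN", "PTEN", "OTHER", "SILENT"),
    evidence = c(rep("validated", 4), "predicted", "predicted"),
    source_db = "miRTarBase", stringsAsFactors = FALSE
  )
  de <- c("miR-22-3p", "miR-22-5p", "miR-144-3p", "miR-205")
  tg <- build_targetome(de, mr, mi, map)
  pten <- tg[tg$gene_id == "PTEN", ]
  expect_equal(pten$multiplicity, 4L)
  expect_equal(pten$mirnas, "miR-144-3p,miR-205,miR-22-3p,miR-22-5p")
  expect_lt(pten$min_rho, -0.5)
  expect_true(pten$expressed)
  # the all-zero mapped target is recorded unexpressed without correlation
  silent <- tg[tg$gene_id == "SILENT", ]
  expect_false(silent$expressed)
  expect_true(is.na(silent$multiplicity) && is.na(silent$min_rho))
  # hub selection
  expect_equal(hub_targets(tg, 4), "PTEN")
  expect_equal(hub_targets(tg, 1), "PTEN")
  # miR-null is not DE, so OTHER never enters via it
  expect_false("OTHER" %in% tg$gene_id)
  expect_error(build_targetome(c(de, "miR-ghost"), mr, mi, map),
               "miR-ghost")
})

test_that("multiplicity accounting matches exhaustive edge enumeration on a simulated study", {
  st <- simulate_study(signal_config(seed = 13, n_genes = 300, n_mirnas = 25))
  meta <- kidney_meta(st)
  de <- de_test(st$mirna_kidney, meta, "diet", pseudo_reference = TRUE)
  de_ids <- de_features(de)
  tg <- build_targetome(de, st$mrna, st$mirna_kidney, st$map)

  # independent nested-loop recomputation from raw pieces
  sf_mr <- oracle_size_factors(st$mrna$counts[rowSums(st$mrna$counts) > 0, ])
  sf_mi <- oracle_size_factors(st$mirna_kidney$counts)
  lmr <- log2(sweep(st$mrna$counts, 2, sf_mr, "/") + 0.5)
  lmi <- log2(sweep(st$mirna_kidney$counts, 2, sf_mi, "/") + 0.5)
  counts_per_gene <- list()
  n_pairs <- 0L
  edges <- unique(st$map[st$map$mirna_id %in% de_ids, c("mirna_id", "gene_id")])
  for (i in seq_len(nrow(edges))) {
    g <- edges$gene_id[i]
    if (sum(st$mrna$counts[g, ]) == 0) next
    rho <- oracle_spearman(lmi[edges$mirna_id[i], ], lmr[g, ])
    if (rho < -0.5) {
      counts_per_gene[[g]] <- (counts_per_gene[[g]] %||% 0L) + 1L
      n_pairs <- n_pairs + 1L
    }
  }
  got <- tg$multiplicity[tg$expressed]
  names(got) <- tg$gene_id[tg$expressed]
  expect_equal(sort(names(got)), sort(names(counts_per_gene)))
  expect_equal(got[sort(names(got))],
               unlist(counts_per_gene)[sort(names(counts_per_gene))],
               ignore_attr = TRUE)
  # pair/gene accounting: multiplicities sum to the retained pair count
  expect_equal(sum(tg$multiplicity[tg$expressed]), n_pairs)
  expect_equal(nrow(attr(tg, "pairs")), n_pairs)
})

test_that("targetome is invariant to edge order and monotone in the rho threshold", {
  st <- simulate_study(signal_config(seed = 21, n_genes = 200, n_mirnas = 20))
  meta <- kidney_meta(st)
  de <- de_test(st$mirna_kidney, meta, "diet", pseudo_reference = TRUE)
  tg1 <- build_targetome(de, st$mrna, st$mirna_kidney, st$map)
  map_shuffled <- st$map[sample(nrow(st$map)), ]
  tg2 <- build_targetome(de, st$mrna, st$mirna_kidney, map_shuffled)
  expect_equal(as.data.frame(tg1), as.data.frame(tg2))
  # removing a non-supporting edge changes nothing
  pairs <- attr(tg1, "pairs")
  keys <- paste(st$map$mirna_id, st$map$gene_id)
  non_support <- which(!(keys %in% paste(pairs$mirna_id, pairs$gene_id)) &
                         !(st$map$gene_id %in% tg1$gene_id[!tg1$expressed]))
  tg3 <- build_targetome(de, st$mrna, st$mirna_kidney,
                         st$map[-non_support[1], ])
  expect_equal(as.data.frame(tg1), as.data.frame(tg3))
  # tightening the threshold never increases multiplicity
  tg_tight <- build_targetome(de, st$mrna, st$mirna_kidney, st$map,
                              rho_threshold = -0.7)
  for (g in tg_tight$gene_id[tg_tight$expressed]) {
    expect_lte(tg_tight$multiplicity[tg_tight$gene_id == g],
               tg1$multiplicity[tg1$gene_id == g])
  }
})

test_that("embedded hubs are recovered across replicate simulations", {
  hits <- 0L
  n_seeds <- 50L
  for (s in 1:n_seeds) {
    st <- simulate_study(signal_config(seed = 100 + s))
    de <- de_test(st$mirna_kidney, kidney_meta(st), "diet",
                  pseudo_reference = TRUE)
    tg <- build_targetome(de, st$mrna, st$mirna_kidney, st$map)
    hub <- st$truth$edges$gene_id[1] # first four truth edges share the hub
    if (hub %in% hub_targets(tg, 4)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("DE-set overlap is an exact sorted intersection", {
  kidney <- c("miR-205", "miR-140-5p", "miR-185-5p", "miR-128-3p")
  urine <- c("miR-101b-3p", "miR-205", "miR-30a-5p")
  expect_equal(de_overlap(kidney, urine), "miR-205")
  expect_equal(de_overlap(c("a", "b"), c("c")), character(0))
  expect_equal(de_overlap(kidney, kidney), sort(kidney))
})
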