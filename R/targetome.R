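#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive their mean rank).
#' Unlike [stats::cor()] alone, constant input is rejected rather than
#' silently producing `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("'x' and 'y' must be numeric")
  if (length(x) != length(y)) abort("'x' and 'y' must have equal length")
  if (length(x) < 3L) abort("Spearman correlation needs at least 3 paired observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("'x' and 'y' must be finite with no missing values")
  }
  if (min(x) == max(x) || min(y) == max(y)) {
    abort("undefined correlation: constant input vector")
  }
  cor(x, y, method = "spearman")
}

normalize_log2 <- function(x, pseudocount = 0.5, pseudo_reference = TRUE) {
  sf <- size_factors(x, pseudo_reference = pseudo_reference)
  log2(sweep(x, 2L, sf, "/") + pseudocount)
}

#' Build the DE-miRNA targetome
#'
#' Intersects the target map with the differentially expressed miRNAs and
#' keeps the (miRNA, gene) pairs whose expression profiles are
#' anti-correlated across the shared sample panel: Spearman rho of
#' log2-normalized counts strictly below `rho_threshold` (default -0.5),
#' computed across all samples with both diets pooled. Map targets with
#' all-zero counts (or absent from the mRNA matrix) are recorded as
#' unexpressed and carry no correlation evidence. Retained pairs are
#' aggregated per gene into entries with their supporting miRNA set,
#' multiplicity, strongest (most negative) rho and evidence levels,
#' sorted by multiplicity (descending) then gene id.
#'
#' @param de_mirnas character vector of DE miRNA ids, or a `de_result`
#'   from [de_test()] (rows called `up`/`down` are used).
#' @param mrna_counts,mirna_counts [count_matrix()] objects (or named
#'   matrices) sharing a sample panel.
#' @param map target-map data.frame as from [read_target_map()].
#' @param rho_threshold strict upper bound on rho for a pair to be kept.
#' @param validated_only restrict the map to `validated` evidence.
#' @param pseudocount for the log2 transform.
#' @return A data.frame (class `targetome`) with columns `gene_id`,
#'   `multiplicity`, `mirnas` (comma-joined supporting set), `min_rho`,
#'   `evidence`, `expressed`. Unexpressed map targets of DE miRNAs get
#'   `expressed = FALSE` and `NA` multiplicity/rho. Attribute `pairs`
#'   holds the retained (miRNA, gene, rho) pairs for edge-level
#'   accounting.
#' @export
build_targetome <- function(de_mirnas, mrna_counts, mirna_counts, map,
                            rho_threshold = -0.5, validated_only = FALSE,
                            pseudocount = 0.5) {
  if (inherits(de_mirnas, "de_result")) de_mirnas <- de_features(de_mirnas)
  if (!is.character(de_mirnas)) {
    abort("'de_mirnas' must be a character vector or a de_result")
  }
  assert_scalar_number(rho_threshold, "rho_threshold", lower = -1, upper = 1)
  mr <- as_counts(mrna_counts)
  mi <- as_counts(mirna_counts)
  empty <- data.frame(
    gene_id = character(0), multiplicity = integer(0), mirnas = character(0),
    min_rho = numeric(0), evidence = character(0), expressed = logical(0),
    stringsAsFactors = FALSE
  )
  pairs0 <- data.frame(mirna_id = character(0), gene_id = character(0),
                       rho = numeric(0), stringsAsFactors = FALSE)
  if (length(de_mirnas) == 0L) {
    return(structure(empty, class = c("targetome", "data.frame"), pairs = pairs0))
  }
  missing <- setdiff(de_mirnas, rownames(mi))
  if (length(missing)) {
    abort("DE miRNA(s) absent from the miRNA matrix: ",
          paste(missing, collapse = ", "))
  }
  shared <- intersect(colnames(mr), colnames(mi))
  if (length(shared) < 3L) {
    abort("mRNA and miRNA matrices share fewer than 3 samples")
  }
  if (validated_only) map <- map[map$evidence == "validated", , drop = FALSE]
  map <- map[map$mirna_id %in% de_mirnas, , drop = FALSE]
  if (nrow(map) == 0L) {
    return(structure(empty, class = c("targetome", "data.frame"), pairs = pairs0))
  }
  # collapse multi-database rows into one edge carrying the evidence union
  key <- paste(map$mirna_id, map$gene_id, sep = "\r")
  ev_by_pair <- tapply(map$evidence, key, function(e) sort(unique(e)))
  pair_keys <- sort(unique(key))
  pair_mirna <- sub("\r.*$", "", pair_keys)
  pair_gene <- sub("^.*\r", "", pair_keys)

  in_matrix <- pair_gene %in% rownames(mr)
  zero_gene <- rownames(mr)[rowSums(mr[, shared, drop = FALSE]) == 0]
  unexpressed_pair <- !in_matrix | pair_gene %in% zero_gene

  log_mr <- normalize_log2(mr[, shared, drop = FALSE], pseudocount)
  log_mi <- normalize_log2(mi[, shared, drop = FALSE], pseudocount)

  rho <- rep(NA_real_, length(pair_keys))
  for (i in which(!unexpressed_pair)) {
    rho[i] <- tryCatch(
      spearman_rho(log_mi[pair_mirna[i], ], log_mr[pair_gene[i], ]),
      error = function(e) NA_real_ # constant profile: no usable evidence
    )
  }
  keep <- !is.na(rho) & rho < rho_threshold

  entries <- empty
  if (any(keep)) {
    kept_genes <- sort(unique(pair_gene[keep]))
    rows <- lapply(kept_genes, function(g) {
      sel <- keep & pair_gene == g
      mir <- sort(pair_mirna[sel])
      data.frame(
        gene_id = g, multiplicity = length(mir),
        mirnas = paste(mir, collapse = ","),
        min_rho = min(rho[sel]),
        evidence = paste(sort(unique(unlist(ev_by_pair[pair_keys[sel]]))),
                         collapse = ","),
        expressed = TRUE, stringsAsFactors = FALSE
      )
    })
    entries <- do.call(rbind, rows)
  }
  unexp_genes <- sort(unique(pair_gene[unexpressed_pair]))
  if (length(unexp_genes)) {
    rows <- lapply(unexp_genes, function(g) {
      sel <- unexpressed_pair & pair_gene == g
      data.frame(
        gene_id = g, multiplicity = NA_integer_,
        mirnas = paste(sort(pair_mirna[sel]), collapse = ","),
        min_rho = NA_real_,
        evidence = paste(sort(unique(unlist(ev_by_pair[pair_keys[sel]]))),
                         collapse = ","),
        expressed = FALSE, stringsAsFactors = FALSE
      )
    })
    entries <- rbind(entries, do.call(rbind, rows))
  }
  ord <- order(!entries$expressed,
               -ifelse(is.na(entries$multiplicity), 0L, entries$multiplicity),
               entries$gene_id)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  pairs <- data.frame(mirna_id = pair_mirna[keep], gene_id = pair_gene[keep],
                      rho = rho[keep], stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$mirna_id, pairs$gene_id), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(entries, class = c("targetome", "data.frame"),
            pairs = pairs, rho_threshold = rho_threshold,
            n_unexpressed = length(unexp_genes))
}

#' Hub targets: genes supported by many DE miRNAs
#'
#' @param entries a `targetome` from [build_targetome()].
#' @param min_multiplicity minimum number of supporting DE miRNAs.
#' @return Character vector of gene ids in the entries' (stable) order.
#' @export
hub_targets <- function(entries, min_multiplicity = 2L) {
  min_multiplicity <- assert_count(min_multiplicity, "min_multiplicity", min = 1L)
  sel <- entries$expressed & !is.na(entries$multiplicity) &
    entries$multiplicity >= min_multiplicity
  entries$gene_id[sel]
}

#' Overlap of two DE feature sets
#'
#' Exact sorted set intersection, e.g. of kidney and urine DE miRNA
#' rosters.
#'
#' @param set_a,set_b character vectors of feature ids.
#' @return Sorted character vector of common ids.
#' @export
de_overlap <- function(set_a, set_b) {
  sort(intersect(set_a, set_b))
}
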