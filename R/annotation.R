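#' Default keyword scheme for target-gene categorization
#'
#' Five functional categories relevant to obesity-related glomerulopathy,
#' each with a keyword list (singular and plural variants included). The
#' published vocabulary behind these categories is not fully enumerated
#' anywhere, so this scheme is an explicit reconstruction; supply your own
#' scheme table to override it.
#'
#' @return data.frame with columns `category`, `keyword`.
#' @export
default_keyword_scheme <- function() {
  scheme <- list(
    "inflammatory response" = c(
      "inflammation", "inflammatory", "adhesion", "leukocyte", "leukocytes",
      "chemokine", "chemokines", "adipokine", "adipokines"
    ),
    "kidney damage" = c(
      "extracellular matrix", "renal injury", "kidney injury", "renal damage",
      "kidney damage", "nephropathy"
    ),
    "mitochondria" = c(
      "mitochondria", "mitochondrial", "mitochondrion", "metabolism",
      "metabolic", "respiratory chain"
    ),
    "adipose tissue" = c("adipose", "adipocyte", "adipocytes"),
    "nerve-related tissue" = c(
      "nerve", "nerves", "nervous system", "neuron", "neurons", "neuronal",
      "axon", "axons"
    )
  )
  data.frame(
    category = rep(names(scheme), lengths(scheme)),
    keyword = unlist(scheme, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Read a keyword scheme from TSV
#' @param path TSV with columns `category`, `keyword`.
#' @return data.frame with `category`, `keyword`.
#' @export
read_keyword_scheme <- function(path) {
  df <- read_tsv_checked(path, required = c("category", "keyword"),
                         what = "keyword scheme")
  validate_scheme(df[c("category", "keyword")])
}

validate_scheme <- function(scheme) {
  if (!all(c("category", "keyword") %in% names(scheme))) {
    abort("scheme must have columns 'category' and 'keyword'")
  }
  if (any(scheme$keyword == "")) abort("scheme keywords must be non-empty")
  if (nrow(scheme) == 0L) abort("scheme must define at least one keyword")
  scheme
}

#' Categorize genes by keyword search of their summaries
#'
#' Assigns each gene the set of categories for which any keyword occurs as
#' a case-insensitive whole-word match in the gene's summary text. Genes
#' matching no keyword are assigned `uncategorized`. The search is
#' idempotent and insensitive to keyword order, and adding a keyword can
#' only add categories, never remove them.
#'
#' @param summaries data.frame with `gene_id`, `summary_text` (see
#'   [read_gene_summaries()]).
#' @param scheme keyword scheme data.frame (`category`, `keyword`);
#'   defaults to [default_keyword_scheme()].
#' @return data.frame with `gene_id` and `categories` (semicolon-joined,
#'   in the scheme's category order).
#' @export
categorize_genes <- function(summaries, scheme = default_keyword_scheme()) {
  scheme <- validate_scheme(scheme)
  if (!all(c("gene_id", "summary_text") %in% names(summaries))) {
    abort("'summaries' must have columns 'gene_id' and 'summary_text'")
  }
  if (nrow(summaries) == 0L) {
    return(data.frame(gene_id = character(0), categories = character(0),
                      stringsAsFactors = FALSE))
  }
  cats <- unique(scheme$category)
  # one whole-word alternation regex per category
  rx <- vapply(cats, function(cat) {
    kw <- scheme$keyword[scheme$category == cat]
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw)
    paste0("\\b(", paste(esc, collapse = "|"), ")\\b")
  }, character(1))
  txt <- ifelse(is.na(summaries$summary_text), "", summaries$summary_text)
  hit <- vapply(rx, function(r) grepl(r, txt, ignore.case = TRUE, perl = TRUE),
                logical(length(txt)))
  if (length(txt) == 1L) hit <- matrix(hit, nrow = 1L)
  categories <- apply(hit, 1L, function(h) {
    if (any(h)) paste(cats[h], collapse = ";") else "uncategorized"
  })
  data.frame(gene_id = summaries$gene_id, categories = categories,
             stringsAsFactors = FALSE)
}

assert_ct <- function(ct, name) {
  assert_scalar_number(ct, name, lower = 0, upper = 45, strict_lower = TRUE)
}

#' Relative abundance by the 2^-dCT method
#'
#' `2^-(ct_target - ct_housekeeping)`, the relative abundance of a target
#' versus a housekeeping assay, in arbitrary units.
#'
#' @param ct_target,ct_housekeeping cycle thresholds in (0, 45].
#' @return Relative abundance (arbitrary units).
#' @export
relative_abundance_2dct <- function(ct_target, ct_housekeeping) {
  assert_ct(ct_target, "ct_target")
  assert_ct(ct_housekeeping, "ct_housekeeping")
  2^(-(ct_target - ct_housekeeping))
}

#' Spike-in normalized Ct for miRNA qPCR
#'
#' `normalized Ct = Ct(UniSp6 spike-in) - Ct(measured miRNA)`; larger
#' values mean higher miRNA abundance.
#'
#' @param ct_unisp6,ct_mirna cycle thresholds in (0, 45].
#' @return Normalized Ct.
#' @export
normalized_ct <- function(ct_unisp6, ct_mirna) {
  assert_ct(ct_unisp6, "ct_unisp6")
  assert_ct(ct_mirna, "ct_mirna")
  ct_unisp6 - ct_mirna
}

#' Hematocrit from a centrifuged capillary tube
#'
#' `(h1 / h2) * 100`, where `h1` is the height of the red-cell column and
#' `h2` the total column height (red cells plus plasma).
#'
#' @param h1,h2 column heights, `0 < h1 <= h2`.
#' @return Hematocrit in percent.
#' @export
hematocrit_percent <- function(h1, h2) {
  assert_scalar_number(h1, "h1", lower = 0, strict_lower = TRUE)
  assert_scalar_number(h2, "h2", lower = 0, strict_lower = TRUE)
  if (h1 > h2) abort("'h1' (red cell column) cannot exceed 'h2' (total column)")
  (h1 / h2) * 100
}

#' Plasma concentration from whole-blood concentration
#'
#' `c_plasma = c_blood / (1 - hematocrit)`, the correction applied when an
#' analyte (e.g. iohexol) is measured in whole blood but distributes in
#' plasma.
#'
#' @param c_blood whole-blood concentration (>= 0).
#' @param hct_fraction hematocrit as a fraction in \[0, 1).
#' @return Plasma concentration in the units of `c_blood`.
#' @export
plasma_from_blood <- function(c_blood, hct_fraction) {
  assert_scalar_number(c_blood, "c_blood", lower = 0)
  assert_scalar_number(hct_fraction, "hct_fraction", lower = 0, upper = 1,
                       strict_upper = TRUE)
  c_blood / (1 - hct_fraction)
}

#' Summarize a replicate-level qPCR table
#'
#' Averages technical replicates per (sample, assay), reports the
#' replicate SD, and computes relative quantities: for mRNA-style assays,
#' `2^-dCT` against the designated housekeeping assay of the same sample;
#' for miRNA-style assays, the spike-in normalized Ct against the
#' designated spike-in assay. Exactly one housekeeping assay (and at most
#' one spike-in assay) must be designated per normalization run.
#'
#' @param qpcr replicate-level data.frame from [read_qpcr()].
#' @return data.frame with `sample_id`, `assay_id`, `ct_mean`,
#'   `replicate_sd`, `n_replicates`, `rel_abundance_2dct` (NA where no
#'   housekeeping assay applies) and `normalized_ct` (NA where no
#'   spike-in applies).
#' @export
summarize_qpcr <- function(qpcr) {
  need <- c("sample_id", "assay_id", "ct", "is_spike_in", "is_housekeeping")
  if (!all(need %in% names(qpcr))) {
    abort("'qpcr' must have columns: ", paste(need, collapse = ", "))
  }
  hk <- unique(qpcr$assay_id[qpcr$is_housekeeping])
  if (length(hk) != 1L) {
    abort(sprintf(
      "exactly one housekeeping assay must be designated per run (found %d)",
      length(hk)
    ))
  }
  sp <- unique(qpcr$assay_id[qpcr$is_spike_in])
  if (length(sp) > 1L) {
    abort(sprintf("at most one spike-in assay may be designated (found %d)",
                  length(sp)))
  }
  key <- interaction(qpcr$sample_id, qpcr$assay_id, drop = TRUE)
  agg <- data.frame(
    sample_id = tapply(qpcr$sample_id, key, `[`, 1L),
    assay_id = tapply(qpcr$assay_id, key, `[`, 1L),
    ct_mean = as.numeric(tapply(qpcr$ct, key, mean)),
    replicate_sd = as.numeric(tapply(qpcr$ct, key, function(v)
      if (length(v) > 1L) sd(v) else 0)),
    n_replicates = as.integer(tapply(qpcr$ct, key, length)),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(agg$sample_id, agg$assay_id), , drop = FALSE]
  rownames(agg) <- NULL
  hk_ct <- agg$ct_mean[agg$assay_id == hk]
  names(hk_ct) <- agg$sample_id[agg$assay_id == hk]
  agg$rel_abundance_2dct <- ifelse(
    agg$assay_id != hk & agg$sample_id %in% names(hk_ct),
    2^(-(agg$ct_mean - hk_ct[agg$sample_id])), NA_real_
  )
  if (length(sp) == 1L) {
    sp_ct <- agg$ct_mean[agg$assay_id == sp]
    names(sp_ct) <- agg$sample_id[agg$assay_id == sp]
    agg$normalized_ct <- ifelse(
      agg$assay_id != sp & agg$sample_id %in% names(sp_ct),
      sp_ct[agg$sample_id] - agg$ct_mean, NA_real_
    )
  } else {
    agg$normalized_ct <- NA_real_
  }
  agg
}
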