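#' Configuration for the paired-study simulator
#'
#' Defines the statistical conditions of a simulated diet-induced obesity
#' study: two diet groups (SD / HFD) of equal size, negative-binomial
#' counts with sample-specific library sizes, a set of truly up-regulated
#' miRNAs whose mapped target genes are suppressed in the HFD group
#' (inducing negative cross-sample correlation), diet-dependent prevalence
#' of two histological lesions (mesangial matrix increase, podocyte
#' hypertrophy), a fraction of map targets not expressed in the tissue,
#' decoy map edges between unperturbed features, and a urine miRNA matrix
#' sharing one perturbed miRNA with the kidney (the miR-205 analogue).
#'
#' The negative-binomial parameterization is mean/dispersion with
#' `Var = mu + dispersion * mu^2`; baseline feature means are drawn
#' log-uniformly over \[5, 5000\] counts.
#'
#' @param n_per_group samples per diet group (>= 2).
#' @param n_genes number of genes in the mRNA matrix.
#' @param n_mirnas number of miRNAs in the kidney small-RNA matrix.
#' @param n_true_regulations number of embedded miRNA-to-gene
#'   suppressions. When >= 4, the first four regulations converge on a
#'   single hub gene (the PTEN analogue) targeted by four distinct miRNAs.
#' @param effect_log2 magnitude (log2 scale) of the embedded miRNA
#'   up-regulation and target down-regulation in the HFD group.
#' @param dispersion negative-binomial dispersion (squared biological CV).
#' @param libsize_range min and max relative library size per sample.
#' @param lesion_prev_sd,lesion_prev_hfd named probabilities
#'   `c(mmi = , ph = )` of each lesion per diet group.
#' @param frac_unexpressed_targets fraction of target-map genes forced to
#'   zero expression in the kidney (they stay in the map, emulating
#'   database targets that are not expressed in the tissue).
#' @param n_decoy_edges number of map edges connecting unperturbed
#'   miRNA/gene pairs.
#' @param n_lesion_genes number of genes given a lesion-linked expression
#'   shift (independent of diet except through lesion prevalence).
#' @param lesion_effect_log2 magnitude (log2) of the lesion-linked shift;
#'   signs alternate so both directions occur.
#' @param urine_fraction fraction of the miRNA roster also detected in
#'   urine.
#' @param n_urine_only_de number of urine-only miRNAs up-regulated in the
#'   HFD group (beyond the shared kidney/urine miRNA).
#' @param seed integer seed; identical configurations (including the
#'   seed) yield byte-identical written studies.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 8L,
                       n_genes = 2000L,
                       n_mirnas = 150L,
                       n_true_regulations = 50L,
                       effect_log2 = 2,
                       dispersion = 0.1,
                       libsize_range = c(0.7, 1.4),
                       lesion_prev_sd = c(mmi = 0.5, ph = 0.35),
                       lesion_prev_hfd = c(mmi = 0.9, ph = 0.8),
                       frac_unexpressed_targets = 0.11,
                       n_decoy_edges = 200L,
                       n_lesion_genes = 20L,
                       lesion_effect_log2 = 1,
                       urine_fraction = 0.6,
                       n_urine_only_de = 5L,
                       seed = 1L) {
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 2L)
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  n_mirnas <- assert_count(n_mirnas, "n_mirnas", min = 0L)
  n_true_regulations <- assert_count(n_true_regulations, "n_true_regulations")
  if (n_true_regulations > n_mirnas * n_genes) {
    abort("'n_true_regulations' exceeds n_mirnas * n_genes")
  }
  if (n_true_regulations > 0 && n_true_regulations - 3L > n_genes) {
    abort("'n_true_regulations' requires more distinct target genes than 'n_genes'")
  }
  assert_scalar_number(effect_log2, "effect_log2", lower = 0)
  assert_scalar_number(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  if (!is.numeric(libsize_range) || length(libsize_range) != 2L ||
      any(libsize_range <= 0) || libsize_range[1L] > libsize_range[2L]) {
    abort("'libsize_range' must be two positive numbers (min, max) with min <= max")
  }
  for (nm in c("mmi", "ph")) {
    assert_probability(lesion_prev_sd[[nm]], paste0("lesion_prev_sd[", nm, "]"))
    assert_probability(lesion_prev_hfd[[nm]], paste0("lesion_prev_hfd[", nm, "]"))
  }
  assert_scalar_number(frac_unexpressed_targets, "frac_unexpressed_targets",
                       lower = 0, upper = 1, strict_upper = TRUE)
  n_decoy_edges <- assert_count(n_decoy_edges, "n_decoy_edges")
  n_lesion_genes <- assert_count(n_lesion_genes, "n_lesion_genes")
  assert_scalar_number(lesion_effect_log2, "lesion_effect_log2", lower = 0)
  assert_scalar_number(urine_fraction, "urine_fraction", lower = 0, upper = 1)
  n_urine_only_de <- assert_count(n_urine_only_de, "n_urine_only_de")
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(
      n_per_group = n_per_group, n_genes = n_genes, n_mirnas = n_mirnas,
      n_true_regulations = n_true_regulations, effect_log2 = effect_log2,
      dispersion = dispersion, libsize_range = as.numeric(libsize_range),
      lesion_prev_sd = lesion_prev_sd[c("mmi", "ph")],
      lesion_prev_hfd = lesion_prev_hfd[c("mmi", "ph")],
      frac_unexpressed_targets = frac_unexpressed_targets,
      n_decoy_edges = n_decoy_edges, n_lesion_genes = n_lesion_genes,
      lesion_effect_log2 = lesion_effect_log2,
      urine_fraction = urine_fraction, n_urine_only_de = n_urine_only_de,
      seed = seed
    ),
    class = "sim_config"
  )
}

# Text fragments used to build synthetic Entrez-like gene summaries. The
# categorized pools deliberately contain whole-word matches for the default
# keyword scheme; fillers match nothing.
SUMMARY_POOLS <- list(
  "inflammatory response" = c(
    "involved in chemokine ligand signaling",
    "mediates leukocyte adhesion at sites of inflammation",
    "modulates adipokine secretion during the inflammatory response"
  ),
  "kidney damage" = c(
    "participates in extracellular matrix remodeling",
    "up-regulated after renal injury",
    "marker of tubular kidney damage"
  ),
  "mitochondria" = c(
    "component of the mitochondrial respiratory chain",
    "regulates lipid metabolism in mitochondria",
    "metabolic enzyme of the oxidative pathway"
  ),
  "adipose tissue" = c(
    "highly expressed in adipose tissue",
    "drives adipocyte differentiation"
  ),
  "nerve-related tissue" = c(
    "required for axon guidance in the nervous system",
    "supports neuronal survival",
    "expressed in peripheral nerve fibers"
  )
)
SUMMARY_FILLERS <- c(
  "protein coding locus of unknown function",
  "ubiquitously transcribed housekeeping component",
  "member of a large paralogous family",
  "putative transmembrane protein"
)

simulate_summaries <- function(gene_ids) {
  phrases <- unlist(SUMMARY_POOLS, use.names = FALSE)
  txt <- vapply(gene_ids, function(g) {
    k <- sample(0:2, 1L, prob = c(0.35, 0.4, 0.25))
    parts <- c(sample(SUMMARY_FILLERS, 1L),
               if (k > 0) sample(phrases, k))
    paste(parts, collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
  data.frame(gene_id = gene_ids, summary_text = txt, stringsAsFactors = FALSE)
}

nb_counts <- function(mu, dispersion, feature_ids, sample_ids) {
  matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    nrow = length(feature_ids), ncol = length(sample_ids),
    dimnames = list(feature_ids, sample_ids)
  )
}

#' Simulate a paired kidney/urine expression study
#'
#' Draws sample metadata (diet group, lesion indicators, weight,
#' albuminuria), an mRNA count matrix, kidney and urine miRNA count
#' matrices, a miRNA-to-gene target map with truth and decoy edges,
#' synthetic gene summaries, and a truth table recording every embedded
#' effect. For each truth edge the miRNA mean is multiplied by
#' `2^effect_log2` in the HFD group and the target gene mean divided by
#' `2^effect_log2` (once per edge, so a 4-miRNA hub gene is suppressed
#' four-fold on the log2 scale). One RNG stream is split per matrix, so
#' adding or dropping a matrix does not perturb the others.
#'
#' @param config a [sim_config()].
#' @return An object of class `paired_study`: a list with elements
#'   `mrna`, `mirna_kidney`, `mirna_urine` ([count_matrix()] objects),
#'   `meta` (metadata data.frame covering kidney and urine samples),
#'   `map` (target-map data.frame), `gene_summaries`, and `truth`
#'   (class `truth_table`: `edges`, `lesion_genes`, `unexpressed_genes`,
#'   `shared_mirna`, `urine_de_mirnas`).
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("'config' must be created by sim_config()")
  }
  set.seed(config$seed)
  sub <- sample.int(2^31 - 2, 6L)

  n <- config$n_per_group
  ns <- 2L * n
  animal <- sprintf("R%02d", seq_len(ns))
  diet <- rep(DIETS, each = n)
  kid_ids <- paste0(animal, "_K")
  ur_ids <- paste0(animal, "_U")
  id_pad <- function(k, prefix) sprintf("%s%0*d", prefix, max(4L, nchar(k)), seq_len(k))
  gene_ids <- id_pad(config$n_genes, "g")
  mirna_ids <- if (config$n_mirnas > 0) {
    sprintf("miR-sim-%03d", seq_len(config$n_mirnas))
  } else character(0)

  ## --- design / metadata -------------------------------------------------
  set.seed(sub[1L])
  prev <- rbind(SD = config$lesion_prev_sd, HFD = config$lesion_prev_hfd)
  mmi <- runif(ns) < prev[diet, "mmi"]
  ph <- runif(ns) < prev[diet, "ph"]
  weight <- rnorm(ns, mean = ifelse(diet == "SD", 461, 544),
                  sd = ifelse(diet == "SD", 37, 44))
  alb <- pmax(rnorm(ns, mean = ifelse(diet == "SD", 5845, 10384),
                    sd = ifelse(diet == "SD", 2617, 1168)), 50)
  meta <- rbind(
    data.frame(sample_id = kid_ids, animal_id = animal, diet = diet,
               mmi = mmi, ph = ph, weight_g = round(weight, 1),
               albuminuria_ng_ml = round(alb, 1), compartment = "kidney",
               stringsAsFactors = FALSE),
    data.frame(sample_id = ur_ids, animal_id = animal, diet = diet,
               mmi = mmi, ph = ph, weight_g = round(weight, 1),
               albuminuria_ng_ml = round(alb, 1), compartment = "urine",
               stringsAsFactors = FALSE)
  )

  ## --- baseline means ----------------------------------------------------
  set.seed(sub[2L])
  gene_mu <- exp(runif(config$n_genes, log(5), log(5000)))
  names(gene_mu) <- gene_ids
  mirna_mu <- exp(runif(config$n_mirnas, log(5), log(5000)))
  names(mirna_mu) <- mirna_ids

  ## --- target map, truth edges, lesion genes -----------------------------
  set.seed(sub[3L])
  n_tr <- config$n_true_regulations
  has_hub <- n_tr >= 4L && config$n_mirnas >= 4L
  n_true_mirnas <- if (n_tr == 0L) 0L else
    min(config$n_mirnas, max(min(4L, n_tr), ceiling(n_tr / 5)))
  true_mirnas <- if (n_true_mirnas > 0) sample(mirna_ids, n_true_mirnas) else character(0)

  edges <- data.frame(mirna_id = character(0), gene_id = character(0),
                      effect_log2 = numeric(0), stringsAsFactors = FALSE)
  hub_gene <- NA_character_
  if (n_tr > 0L) {
    if (has_hub) {
      # the hub analogue is a well-expressed gene targeted by 4 distinct miRNAs
      eligible <- gene_ids[gene_mu >= 50]
      hub_gene <- sample(eligible, 1L)
      edges <- data.frame(mirna_id = true_mirnas[1:4], gene_id = hub_gene,
                          effect_log2 = config$effect_log2,
                          stringsAsFactors = FALSE)
    }
    m_rest <- n_tr - nrow(edges)
    if (m_rest > 0L) {
      rest_genes <- sample(setdiff(gene_ids, hub_gene), m_rest)
      edges <- rbind(edges, data.frame(
        mirna_id = rep_len(true_mirnas, m_rest), gene_id = rest_genes,
        effect_log2 = config$effect_log2, stringsAsFactors = FALSE
      ))
    }
  }

  lesion_genes <- data.frame(gene_id = character(0), lesion = character(0),
                             effect_log2 = numeric(0), stringsAsFactors = FALSE)
  if (config$n_lesion_genes > 0L) {
    pool <- setdiff(gene_ids, edges$gene_id)
    lg <- sample(pool, min(config$n_lesion_genes, length(pool)))
    lesion_genes <- data.frame(
      gene_id = lg,
      lesion = rep_len(c("mmi", "ph"), length(lg)),
      effect_log2 = config$lesion_effect_log2 * rep_len(c(1, -1), length(lg)),
      stringsAsFactors = FALSE
    )
  }

  decoys <- data.frame(mirna_id = character(0), gene_id = character(0),
                       stringsAsFactors = FALSE)
  if (config$n_decoy_edges > 0L) {
    cm <- setdiff(mirna_ids, true_mirnas)
    cg <- setdiff(gene_ids, c(edges$gene_id, lesion_genes$gene_id))
    total <- length(cm) * length(cg)
    if (config$n_decoy_edges > total) {
      abort("'n_decoy_edges' exceeds the number of available unperturbed pairs")
    }
    idx <- sample(total, config$n_decoy_edges)
    decoys <- data.frame(
      mirna_id = cm[(idx - 1L) %% length(cm) + 1L],
      gene_id = cg[(idx - 1L) %/% length(cm) + 1L],
      stringsAsFactors = FALSE
    )
  }

  map_genes <- unique(c(edges$gene_id, decoys$gene_id))
  n_unexp <- round(config$frac_unexpressed_targets * length(map_genes))
  decoy_only <- setdiff(decoys$gene_id, edges$gene_id)
  unexpressed <- head(sample(decoy_only), min(n_unexp, length(decoy_only)))
  gene_mu[unexpressed] <- 0
  # database targets of the DE miRNAs that the tissue does not express:
  # give each unexpressed gene one extra edge from a true miRNA so the
  # targetome's unexpressed bookkeeping is exercised
  unexp_edges <- NULL
  if (length(unexpressed) && length(true_mirnas)) {
    unexp_edges <- data.frame(
      mirna_id = sample(true_mirnas, length(unexpressed), replace = TRUE),
      gene_id = unexpressed, stringsAsFactors = FALSE
    )
  }

  evid <- function(k) sample(EVIDENCE_LEVELS, k, replace = TRUE)
  edge_evid <- if (nrow(edges)) {
    e <- evid(nrow(edges))
    if (has_hub) e[1:4] <- "validated" # hub interactions are database-validated
    e
  } else character(0)
  decoy_evid <- evid(nrow(decoys))
  map <- rbind(
    data.frame(mirna_id = edges$mirna_id, gene_id = edges$gene_id,
               evidence = edge_evid, stringsAsFactors = FALSE),
    data.frame(mirna_id = decoys$mirna_id, gene_id = decoys$gene_id,
               evidence = decoy_evid, stringsAsFactors = FALSE),
    if (!is.null(unexp_edges))
      data.frame(mirna_id = unexp_edges$mirna_id,
                 gene_id = unexp_edges$gene_id,
                 evidence = evid(nrow(unexp_edges)), stringsAsFactors = FALSE)
  )
  map$source_db <- ifelse(map$evidence == "validated", "miRTarBase", "TargetScan")

  gene_summaries <- simulate_summaries(gene_ids)

  hfd <- diet == "HFD"

  ## --- mRNA counts -------------------------------------------------------
  set.seed(sub[4L])
  lib <- runif(ns, config$libsize_range[1L], config$libsize_range[2L])
  mu <- outer(gene_mu, lib)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) { # one division per truth edge
      mu[edges$gene_id[i], hfd] <- mu[edges$gene_id[i], hfd] / 2^edges$effect_log2[i]
    }
  }
  if (nrow(lesion_genes)) {
    for (i in seq_len(nrow(lesion_genes))) {
      has <- if (lesion_genes$lesion[i] == "mmi") mmi else ph
      mu[lesion_genes$gene_id[i], has] <-
        mu[lesion_genes$gene_id[i], has] * 2^lesion_genes$effect_log2[i]
    }
  }
  mrna <- count_matrix(nb_counts(mu, config$dispersion, gene_ids, kid_ids), "mrna")

  ## --- kidney miRNA counts ----------------------------------------------
  set.seed(sub[5L])
  lib_mi <- runif(ns, config$libsize_range[1L], config$libsize_range[2L])
  mu_mi <- outer(mirna_mu, lib_mi)
  if (length(true_mirnas)) {
    mu_mi[true_mirnas, hfd] <- mu_mi[true_mirnas, hfd] * 2^config$effect_log2
  }
  mirna_kidney <- count_matrix(
    nb_counts(mu_mi, config$dispersion, mirna_ids, kid_ids), "mirna"
  )

  ## --- urine miRNA counts ------------------------------------------------
  set.seed(sub[6L])
  shared <- if (length(true_mirnas)) true_mirnas[1L] else
    if (length(mirna_ids)) mirna_ids[1L] else NA_character_
  n_ur <- min(config$n_mirnas, max(as.integer(!is.na(shared)),
                                   round(config$urine_fraction * config$n_mirnas)))
  roster <- character(0)
  if (n_ur > 0L) {
    others <- sample(setdiff(mirna_ids, shared), n_ur - 1L)
    roster <- mirna_ids[mirna_ids %in% c(shared, others)]
  }
  urine_de <- character(0)
  if (length(roster)) {
    extra_pool <- setdiff(roster, c(true_mirnas, shared))
    urine_de <- c(shared, head(sample(extra_pool),
                               min(config$n_urine_only_de, length(extra_pool))))
  }
  ur_mu_base <- exp(runif(length(roster), log(5), log(5000)))
  names(ur_mu_base) <- roster
  lib_ur <- runif(ns, config$libsize_range[1L], config$libsize_range[2L])
  mu_ur <- outer(ur_mu_base, lib_ur)
  if (length(urine_de)) { # urine DE miRNAs are all up in HFD
    mu_ur[urine_de, hfd] <- mu_ur[urine_de, hfd] * 2^config$effect_log2
  }
  mirna_urine <- count_matrix(
    nb_counts(mu_ur, config$dispersion, roster, ur_ids), "mirna"
  )

  truth <- structure(
    list(edges = edges, lesion_genes = lesion_genes,
         unexpressed_genes = sort(unexpressed),
         shared_mirna = shared, urine_de_mirnas = sort(urine_de)),
    class = "truth_table"
  )

  structure(
    list(mrna = mrna, mirna_kidney = mirna_kidney, mirna_urine = mirna_urine,
         meta = meta, map = map, gene_summaries = gene_summaries,
         truth = truth, config = config),
    class = "paired_study"
  )
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf(
    "paired_study: %d genes, %d kidney miRNAs, %d urine miRNAs, %d samples/compartment\n",
    length(x$mrna$feature_ids), length(x$mirna_kidney$feature_ids),
    length(x$mirna_urine$feature_ids), sum(x$meta$compartment == "kidney")
  ))
  cat(sprintf("  truth: %d regulation edges, %d lesion genes, %d unexpressed map targets\n",
              nrow(x$truth$edges), nrow(x$truth$lesion_genes),
              length(x$truth$unexpressed_genes)))
  invisible(x)
}

truth_to_long <- function(truth) {
  n_e <- nrow(truth$edges)
  n_l <- nrow(truth$lesion_genes)
  rows <- list(
    data.frame(record_type = rep("edge", n_e), mirna_id = truth$edges$mirna_id,
               gene_id = truth$edges$gene_id, lesion = rep("", n_e),
               effect_log2 = truth$edges$effect_log2, stringsAsFactors = FALSE),
    data.frame(record_type = rep("lesion_gene", n_l), mirna_id = rep("", n_l),
               gene_id = truth$lesion_genes$gene_id,
               lesion = truth$lesion_genes$lesion,
               effect_log2 = truth$lesion_genes$effect_log2,
               stringsAsFactors = FALSE),
    if (length(truth$unexpressed_genes))
      data.frame(record_type = "unexpressed", mirna_id = "",
                 gene_id = truth$unexpressed_genes, lesion = "",
                 effect_log2 = NA_real_, stringsAsFactors = FALSE),
    if (!is.na(truth$shared_mirna))
      data.frame(record_type = "shared_mirna", mirna_id = truth$shared_mirna,
                 gene_id = "", lesion = "", effect_log2 = NA_real_,
                 stringsAsFactors = FALSE),
    if (length(truth$urine_de_mirnas))
      data.frame(record_type = "urine_de", mirna_id = truth$urine_de_mirnas,
                 gene_id = "", lesion = "", effect_log2 = NA_real_,
                 stringsAsFactors = FALSE)
  )
  do.call(rbind, Filter(Negate(is.null), rows))
}

long_to_truth <- function(df) {
  num <- function(x) suppressWarnings(as.numeric(x))
  e <- df[df$record_type == "edge", , drop = FALSE]
  l <- df[df$record_type == "lesion_gene", , drop = FALSE]
  structure(
    list(
      edges = data.frame(mirna_id = e$mirna_id, gene_id = e$gene_id,
                         effect_log2 = num(e$effect_log2),
                         stringsAsFactors = FALSE),
      lesion_genes = data.frame(gene_id = l$gene_id, lesion = l$lesion,
                                effect_log2 = num(l$effect_log2),
                                stringsAsFactors = FALSE),
      unexpressed_genes = df$gene_id[df$record_type == "unexpressed"],
      shared_mirna = if (any(df$record_type == "shared_mirna"))
        df$mirna_id[df$record_type == "shared_mirna"][1L] else NA_character_,
      urine_de_mirnas = df$mirna_id[df$record_type == "urine_de"]
    ),
    class = "truth_table"
  )
}

#' Write a simulated study to a directory
#'
#' Emits `counts_mrna.tsv`, `counts_mirna_kidney.tsv`,
#' `counts_mirna_urine.tsv`, `metadata.tsv`, `target_map.tsv`,
#' `gene_summaries.tsv` and `truth.tsv`. All files round-trip through the
#' package readers and are byte-identical across reruns of the same
#' configuration.
#'
#' @param study a `paired_study` from [simulate_study()].
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "paired_study")) abort("'study' must be a paired_study")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort(sprintf("cannot create study directory '%s'", dir))
  paths <- c(
    counts_mrna = file.path(dir, "counts_mrna.tsv"),
    counts_mirna_kidney = file.path(dir, "counts_mirna_kidney.tsv"),
    counts_mirna_urine = file.path(dir, "counts_mirna_urine.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    target_map = file.path(dir, "target_map.tsv"),
    gene_summaries = file.path(dir, "gene_summaries.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  wrap <- function(path, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("I/O failure writing '%s': %s", path, conditionMessage(e))))
  }
  wrap(paths["counts_mrna"], write_count_matrix(study$mrna, paths["counts_mrna"]))
  wrap(paths["counts_mirna_kidney"],
       write_count_matrix(study$mirna_kidney, paths["counts_mirna_kidney"]))
  wrap(paths["counts_mirna_urine"],
       write_count_matrix(study$mirna_urine, paths["counts_mirna_urine"]))
  wrap(paths["metadata"], write_metadata(study$meta, paths["metadata"]))
  wrap(paths["target_map"], write_tsv_with_header(study$map, paths["target_map"]))
  wrap(paths["gene_summaries"],
       write_tsv_with_header(study$gene_summaries, paths["gene_summaries"]))
  wrap(paths["truth"],
       write_tsv_with_header(truth_to_long(study$truth), paths["truth"], na = ""))
  invisible(paths)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir directory containing the study TSV files.
#' @return A `paired_study` (without the generating `config`, and with a
#'   `truth` element only if `truth.tsv` is present).
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- NULL
  if (file.exists(p("truth.tsv"))) {
    truth <- long_to_truth(read_tsv_checked(
      p("truth.tsv"),
      required = c("record_type", "mirna_id", "gene_id", "lesion", "effect_log2"),
      what = "truth table"
    ))
  }
  structure(
    list(
      mrna = read_count_matrix(p("counts_mrna.tsv"), "mrna"),
      mirna_kidney = read_count_matrix(p("counts_mirna_kidney.tsv"), "mirna"),
      mirna_urine = read_count_matrix(p("counts_mirna_urine.tsv"), "mirna"),
      meta = read_metadata(p("metadata.tsv")),
      map = read_target_map(p("target_map.tsv")),
      gene_summaries = read_gene_summaries(p("gene_summaries.tsv")),
      truth = truth, config = NULL
    ),
    class = "paired_study"
  )
}
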