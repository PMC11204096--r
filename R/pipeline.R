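#' Configuration for a full pipeline run
#'
#' Exactly one of `input_dir` (a study directory readable by
#' [read_study()]) or `simulate` (a [sim_config()]) must be supplied.
#'
#' @param out_dir output directory for all stage results.
#' @param input_dir directory with study TSV files, or `NULL`.
#' @param simulate a [sim_config()], or `NULL`.
#' @param alpha_kidney adjusted-p level for kidney analyses.
#' @param alpha_urine adjusted-p level for urine analyses.
#' @param lfc_threshold absolute log2 fold-change threshold for DE calls.
#' @param rho_threshold strict Spearman threshold for targetome edges.
#' @param B number of random label assignments for the lesion permutation
#'   null.
#' @param seed integer seed governing every stochastic stage.
#' @param validated_only restrict the targetome to validated map edges.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, simulate = NULL,
                       alpha_kidney = 0.05, alpha_urine = 0.1,
                       lfc_threshold = 1, rho_threshold = -0.5,
                       B = 100000L, seed = 1L, validated_only = FALSE) {
  if (is.null(input_dir) == is.null(simulate)) {
    abort("exactly one of 'input_dir' or 'simulate' must be supplied")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    abort("'simulate' must be a sim_config()")
  }
  assert_probability(alpha_kidney, "alpha_kidney")
  assert_probability(alpha_urine, "alpha_urine")
  assert_scalar_number(lfc_threshold, "lfc_threshold", lower = 0)
  assert_scalar_number(rho_threshold, "rho_threshold", lower = -1, upper = 1)
  B <- assert_count(B, "B", min = 1L)
  seed <- assert_count(seed, "seed", min = 0L)
  structure(
    list(out_dir = out_dir, input_dir = input_dir, simulate = simulate,
         alpha_kidney = alpha_kidney, alpha_urine = alpha_urine,
         lfc_threshold = lfc_threshold, rho_threshold = rho_threshold,
         B = B, seed = seed, validated_only = isTRUE(validated_only)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate:`
#' mapping holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` if given.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    sim_args <- y$simulate
    if (!is.null(sim_args$libsize_range)) {
      sim_args$libsize_range <- as.numeric(sim_args$libsize_range)
    }
    for (f in c("lesion_prev_sd", "lesion_prev_hfd")) {
      if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
    }
    sim <- do.call(sim_config, sim_args)
  }
  args <- y[setdiff(names(y), "simulate")]
  args$simulate <- sim
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

config_fingerprint <- function(config) {
  canon <- unclass(config)
  canon$out_dir <- NULL # the fingerprint covers the analysis, not its location
  canon$simulate <- if (!is.null(canon$simulate)) unclass(canon$simulate)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full integrated analysis pipeline
#'
#' Orchestrates one reproducible run: (optionally) simulate and export the
#' study, differential expression of kidney mRNA and kidney/urine miRNA,
#' targetome construction from the kidney DE miRNAs, lesion-permutation
#' tests on the mRNA matrix, kidney/urine DE-miRNA overlap, keyword
#' categorization of expressed targetome genes, truth-based recovery
#' metrics in simulate mode, and a `manifest.json` recording the package
#' version, configuration hash, seed and per-stage row counts. Rerunning
#' with an identical configuration reproduces byte-identical result files
#' (only `run.log`, which carries stage timings, may differ).
#'
#' @param config a [run_config()].
#' @param quiet suppress console stage messages.
#' @return Invisibly, a list with the in-memory stage results
#'   (`study`, `de_mrna_diet`, `de_mirna_kidney`, `de_mirna_urine`,
#'   `targetome`, `lesion_mmi`, `lesion_ph`, `overlap`, `categories`,
#'   `recovery`, `manifest`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort("'config' must be a run_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (!quiet) message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, input, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed on input '%s': %s",
                    name, input, conditionMessage(e)))
    })
    say("stage %-18s ok (%.2fs)", name, proc.time()[["elapsed"]] - t0)
    out
  }
  files <- character(0)
  counts_rows <- list()
  emit <- function(df, name, params = NULL) {
    path <- file.path(config$out_dir, name)
    write_result_table(df, path, params = params)
    files <<- c(files, path)
    counts_rows[[name]] <<- nrow(df)
    path
  }

  ## stage: obtain the study
  study <- if (!is.null(config$simulate)) {
    stage("simulate", "sim_config", {
      s <- simulate_study(config$simulate)
      data_dir <- file.path(config$out_dir, "data")
      write_study(s, data_dir)
      s
    })
  } else {
    stage("load", config$input_dir, read_study(config$input_dir))
  }
  meta_kidney <- study$meta[study$meta$compartment == "kidney", , drop = FALSE]

  ## stage: kidney DE (mRNA by diet)
  de_mrna <- stage("de_mrna_diet", "counts_mrna", de_test(
    study$mrna, meta_kidney, grouping = "diet",
    alpha = config$alpha_kidney, lfc_threshold = config$lfc_threshold,
    pseudo_reference = TRUE
  ))
  emit(de_mrna, "de_mrna_diet.tsv",
       params = list(grouping = "diet", alpha = config$alpha_kidney,
                     lfc = config$lfc_threshold))

  ## stage: kidney DE (miRNA by diet)
  de_mirna_kid <- stage("de_mirna_kidney", "counts_mirna_kidney", de_test(
    study$mirna_kidney, meta_kidney, grouping = "diet",
    alpha = config$alpha_kidney, lfc_threshold = config$lfc_threshold,
    pseudo_reference = TRUE
  ))
  emit(de_mirna_kid, "de_mirna_kidney.tsv",
       params = list(grouping = "diet", alpha = config$alpha_kidney,
                     lfc = config$lfc_threshold))

  ## stage: targetome from kidney DE miRNAs
  tg <- stage("targetome", "de_mirna_kidney", build_targetome(
    de_mirna_kid, study$mrna, study$mirna_kidney, study$map,
    rho_threshold = config$rho_threshold,
    validated_only = config$validated_only
  ))
  emit(as.data.frame(tg), "targetome.tsv",
       params = list(rho = config$rho_threshold,
                     validated_only = config$validated_only))

  ## stage: lesion permutation nulls on mRNA
  perm <- list()
  for (les in c("mmi", "ph")) {
    cls <- table(meta_kidney[[les]])
    if (length(cls) < 2L || any(cls < 2L)) {
      say("stage lesion_perm_%s skipped: degenerate %s labels", les, les)
      perm[[les]] <- NULL
      next
    }
    pr <- stage(paste0("lesion_perm_", les), "counts_mrna", permutation_test(
      study$mrna, meta_kidney, lesion = les, B = config$B,
      seed = config$seed + match(les, c("mmi", "ph")),
      pseudo_reference = TRUE
    ))
    emit(as.data.frame(pr), paste0("lesion_perm_", les, ".tsv"),
         params = list(lesion = les, B = config$B))
    perm[[les]] <- pr
  }

  ## stage: urine DE (miRNA by diet, relaxed alpha)
  meta_urine <- study$meta[study$meta$compartment == "urine", , drop = FALSE]
  de_mirna_ur <- stage("de_mirna_urine", "counts_mirna_urine", de_test(
    study$mirna_urine, meta_urine, grouping = "diet",
    alpha = config$alpha_urine, lfc_threshold = config$lfc_threshold,
    pseudo_reference = TRUE
  ))
  emit(de_mirna_ur, "de_mirna_urine.tsv",
       params = list(grouping = "diet", alpha = config$alpha_urine,
                     lfc = config$lfc_threshold))

  ## stage: kidney/urine DE overlap
  overlap <- stage("overlap", "de sets",
                   de_overlap(de_features(de_mirna_kid), de_features(de_mirna_ur)))
  emit(data.frame(mirna_id = overlap, stringsAsFactors = FALSE), "overlap.tsv")

  ## stage: keyword categorization of expressed targetome genes
  tg_genes <- tg$gene_id[tg$expressed]
  summ <- study$gene_summaries[study$gene_summaries$gene_id %in% tg_genes, ,
                               drop = FALSE]
  categories <- stage("annotate", "gene_summaries", categorize_genes(summ))
  emit(categories, "categories.tsv")

  ## stage: truth-based recovery (simulate mode only)
  recovery <- NULL
  if (!is.null(study$truth)) {
    recovery <- stage("recovery", "truth", recovery_report(tg, study$truth))
    emit(data.frame(metric = names(recovery), value = unlist(recovery)),
         "recovery.tsv")
  }

  manifest <- list(
    tool = "orgreg",
    version = as.character(packageVersion("orgreg")),
    config_hash = config_fingerprint(config),
    seed = config$seed,
    parameters = list(
      alpha_kidney = config$alpha_kidney, alpha_urine = config$alpha_urine,
      lfc_threshold = config$lfc_threshold,
      rho_threshold = config$rho_threshold, B = config$B,
      validated_only = config$validated_only
    ),
    stage_rows = counts_rows
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  writeLines(log_lines, log_path)

  invisible(list(
    study = study, de_mrna_diet = de_mrna, de_mirna_kidney = de_mirna_kid,
    de_mirna_urine = de_mirna_ur, targetome = tg,
    lesion_mmi = perm$mmi, lesion_ph = perm$ph, overlap = overlap,
    categories = categories, recovery = recovery, manifest = manifest,
    files = files
  ))
}

#' Edge-level recovery metrics against a simulation truth table
#'
#' Compares the retained targetome (miRNA, gene) pairs with the truth
#' edges of a simulation: sensitivity is the fraction of true edges
#' recovered, the false-discovery proportion the fraction of recovered
#' edges that are not true edges. With no recovered edges the FDP is the
#' 0/0 sentinel `NaN`.
#'
#' @param targetome a `targetome` from [build_targetome()] (its `pairs`
#'   attribute carries the retained edges), or a data.frame of pairs with
#'   columns `mirna_id`, `gene_id`.
#' @param truth a `truth_table` from [simulate_study()].
#' @return List with `sensitivity`, `fdp`, `n_true_edges`,
#'   `n_recovered`, `n_true_recovered`.
#' @export
recovery_report <- function(targetome, truth) {
  if (!inherits(truth, "truth_table")) abort("'truth' must be a truth_table")
  pairs <- if (inherits(targetome, "targetome")) {
    attr(targetome, "pairs")
  } else {
    targetome
  }
  if (!all(c("mirna_id", "gene_id") %in% names(pairs))) {
    abort("'targetome' pairs must have columns 'mirna_id' and 'gene_id'")
  }
  true_keys <- paste(truth$edges$mirna_id, truth$edges$gene_id, sep = "\r")
  got_keys <- paste(pairs$mirna_id, pairs$gene_id, sep = "\r")
  n_true <- length(true_keys)
  n_got <- length(got_keys)
  n_hit <- sum(got_keys %in% true_keys)
  list(
    sensitivity = if (n_true > 0) n_hit / n_true else NaN,
    fdp = if (n_got > 0) (n_got - n_hit) / n_got else NaN,
    n_true_edges = n_true,
    n_recovered = n_got,
    n_true_recovered = n_hit
  )
}
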