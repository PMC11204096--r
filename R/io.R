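#' Construct a validated count matrix
#'
#' A `count_matrix` holds a features-by-samples matrix of non-negative
#' integer counts together with the kind of feature it quantifies
#' (`"mrna"` or `"mirna"`). All readers and the simulator funnel through
#' this constructor so every downstream stage can rely on its invariants:
#' unique feature and sample identifiers, integral non-negative cells,
#' consistent dimensions.
#'
#' @param counts numeric matrix with feature rownames and sample colnames.
#' @param feature_kind `"mrna"` or `"mirna"`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer-valued matrix), `feature_ids`, `sample_ids`,
#'   `feature_kind`.
#' @export
count_matrix <- function(counts, feature_kind = c("mrna", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("'counts' must be a numeric matrix")
  }
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) && nrow(counts) == 0L) fid <- character(0) # R drops empty dimnames
  if (is.null(sid) && ncol(counts) == 0L) sid <- character(0)
  if (is.null(fid) || is.null(sid)) {
    abort("'counts' must carry feature rownames and sample colnames")
  }
  rownames(counts) <- fid
  colnames(counts) <- sid
  dup_f <- fid[duplicated(fid)]
  if (length(dup_f)) {
    abort("duplicate feature identifier(s): ", paste(unique(dup_f), collapse = ", "))
  }
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) {
    abort("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    abort(sprintf(
      "counts must be non-negative integers; offending cell at feature '%s', sample '%s' (value %s)",
      fid[i[1L]], sid[i[2L]], format(counts[bad[1L]])
    ))
  }
  storage.mode(counts) <- "double" # integral values, double storage for size
  structure(
    list(counts = counts, feature_ids = fid, sample_ids = sid,
         feature_kind = feature_kind),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s): %d features x %d samples\n",
              x$feature_kind, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

provenance_header <- function(params = NULL) {
  lines <- sprintf("# orgreg %s", as.character(packageVersion("orgreg")))
  if (length(params)) {
    kv <- paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), character(1)), sep = "=")
    lines <- c(lines, paste("#", paste(kv, collapse = " ")))
  }
  lines
}

write_tsv_with_header <- function(df, path, params = NULL, na = "NA") {
  con <- file(path, open = "wb") # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = na)
  invisible(path)
}

read_tsv_checked <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) {
    abort(sprintf("cannot read %s: file '%s' does not exist", what, path))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s '%s' is missing mandatory column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a count matrix from TSV
#'
#' Expects a tab-separated file whose first column is `feature_id` and whose
#' remaining columns are sample identifiers; cells must be non-negative
#' integers. Lines starting with `#` are provenance comments and skipped.
#' Parsing is total: any violation raises an error naming the offending
#' identifier or cell, and no partially loaded object is returned.
#'
#' @param path file path.
#' @param feature_kind `"mrna"` or `"mirna"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, feature_kind = c("mrna", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  df <- read_tsv_checked(path, required = "feature_id", what = "count matrix")
  if (names(df)[1L] != "feature_id") {
    abort(sprintf("count matrix '%s': first column must be 'feature_id', found '%s'",
                  path, names(df)[1L]))
  }
  sid <- names(df)[-1L]
  dup_s <- sid[duplicated(sid)]
  if (length(dup_s)) {
    abort(sprintf("count matrix '%s': duplicated sample column(s): %s",
                  path, paste(unique(dup_s), collapse = ", ")))
  }
  fid <- df[[1L]]
  m <- matrix(0, nrow = length(fid), ncol = length(sid),
              dimnames = list(fid, sid))
  for (j in seq_along(sid)) {
    raw <- df[[j + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | val < 0 | val != round(val))
    if (length(bad)) {
      abort(sprintf(
        "count matrix '%s': non-integer or negative cell at row %d (feature '%s'), column '%s' (value '%s')",
        path, bad[1L], fid[bad[1L]], sid[j], raw[bad[1L]]
      ))
    }
    m[, j] <- val
  }
  count_matrix(m, feature_kind)
}

#' Write a count matrix to TSV
#'
#' @param x a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature_id = x$feature_ids, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_with_header(df, path, params = list(feature_kind = x$feature_kind))
}

DIETS <- c("SD", "HFD")
COMPARTMENTS <- c("kidney", "urine")

parse_logical_field <- function(x, field, path, allow_na = FALSE) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "0")] <- FALSE
  unknown <- !is.na(x) & x != "" & is.na(out)
  if (any(unknown)) {
    abort(sprintf("metadata '%s': column '%s' has non-boolean value '%s'",
                  path, field, x[which(unknown)[1L]]))
  }
  if (!allow_na && anyNA(out)) {
    abort(sprintf("metadata '%s': column '%s' is mandatory but empty at row %d",
                  path, field, which(is.na(out))[1L]))
  }
  out
}

parse_optional_numeric <- function(x, field, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- x != "" & (is.na(out) | out <= 0)
  if (any(bad)) {
    abort(sprintf("metadata '%s': column '%s' must be a positive number or empty, found '%s'",
                  path, field, x[which(bad)[1L]]))
  }
  out[x == ""] <- NA_real_
  out
}

validate_metadata <- function(meta, path = "<in-memory>") {
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) {
    abort(sprintf("metadata '%s': duplicate sample_id(s): %s",
                  path, paste(unique(dup), collapse = ", ")))
  }
  bad_diet <- setdiff(unique(meta$diet), DIETS)
  if (length(bad_diet)) {
    abort(sprintf("metadata '%s': unknown diet value '%s'; allowed values: %s",
                  path, bad_diet[1L], paste(DIETS, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(meta$compartment), COMPARTMENTS)
  if (length(bad_comp)) {
    abort(sprintf("metadata '%s': unknown compartment value '%s'; allowed values: %s",
                  path, bad_comp[1L], paste(COMPARTMENTS, collapse = ", ")))
  }
  kid <- meta$compartment == "kidney"
  if (any(kid & (is.na(meta$mmi) | is.na(meta$ph)))) {
    abort(sprintf("metadata '%s': lesion flags (mmi, ph) are mandatory for kidney samples", path))
  }
  meta
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `diet` (SD/HFD), `mmi`, `ph` (booleans; mandatory
#' for kidney samples), `weight_g`, `albuminuria_ng_ml` (optional positive
#' reals; missing encoded as the empty string), `compartment`
#' (kidney/urine).
#'
#' @param path file path.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(
    path,
    required = c("sample_id", "diet", "mmi", "ph", "compartment"),
    what = "metadata"
  )
  meta <- data.frame(
    sample_id = df$sample_id,
    animal_id = if ("animal_id" %in% names(df)) df$animal_id else df$sample_id,
    diet = df$diet,
    mmi = parse_logical_field(df$mmi, "mmi", path, allow_na = TRUE),
    ph = parse_logical_field(df$ph, "ph", path, allow_na = TRUE),
    weight_g = if ("weight_g" %in% names(df))
      parse_optional_numeric(df$weight_g, "weight_g", path) else NA_real_,
    albuminuria_ng_ml = if ("albuminuria_ng_ml" %in% names(df))
      parse_optional_numeric(df$albuminuria_ng_ml, "albuminuria_ng_ml", path)
      else NA_real_,
    compartment = df$compartment,
    stringsAsFactors = FALSE
  )
  validate_metadata(meta, path)
}

#' Write sample metadata to TSV
#' @param meta metadata data.frame as returned by [read_metadata()].
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  # one canonical missing token: the empty string
  out[] <- lapply(out, function(x) {
    s <- if (is.numeric(x)) format(x, trim = TRUE, digits = 15) else as.character(x)
    s[is.na(x)] <- ""
    s
  })
  write_tsv_with_header(out, path, na = "")
}

EVIDENCE_LEVELS <- c("validated", "predicted")

#' Read a miRNA-to-gene target map from TSV
#'
#' Columns: `mirna_id`, `gene_id`, `evidence` (`validated` or `predicted`),
#' `source_db`. Edges must be unique on (mirna_id, gene_id, source_db).
#'
#' @param path file path.
#' @return A data.frame of directed miRNA-to-gene edges.
#' @export
read_target_map <- function(path) {
  df <- read_tsv_checked(
    path, required = c("mirna_id", "gene_id", "evidence", "source_db"),
    what = "target map"
  )
  bad <- setdiff(unique(df$evidence), EVIDENCE_LEVELS)
  if (length(bad)) {
    abort(sprintf("target map '%s': unknown evidence value '%s'; allowed values: %s",
                  path, bad[1L], paste(EVIDENCE_LEVELS, collapse = ", ")))
  }
  key <- paste(df$mirna_id, df$gene_id, df$source_db, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    abort(sprintf("target map '%s': duplicate edge (%s, %s, %s)",
                  path, d$mirna_id, d$gene_id, d$source_db))
  }
  df[c("mirna_id", "gene_id", "evidence", "source_db")]
}

#' Read per-gene summary text from TSV
#'
#' Columns: `gene_id`, `summary_text`. Used by [categorize_genes()].
#' @param path file path.
#' @return data.frame with `gene_id`, `summary_text`.
#' @export
read_gene_summaries <- function(path) {
  df <- read_tsv_checked(path, required = c("gene_id", "summary_text"),
                         what = "gene summaries")
  df[c("gene_id", "summary_text")]
}

#' Read a qPCR Ct table from CSV
#'
#' One row per technical replicate with columns `sample_id`, `assay_id`,
#' `ct` (cycle threshold, in (0, 45]), `is_spike_in`, `is_housekeeping`.
#' Replicates of the same (sample, assay) are aggregated by
#' [summarize_qpcr()].
#'
#' @param path file path.
#' @return data.frame of replicate-level Ct measurements.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read qPCR table: file '%s' does not exist", path))
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 comment.char = "#", na.strings = NULL)
  required <- c("sample_id", "assay_id", "ct", "is_spike_in", "is_housekeeping")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("qPCR table '%s' is missing mandatory column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    abort(sprintf("qPCR table '%s' has no replicate rows", path))
  }
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- which(is.na(ct) | ct <= 0 | ct > 45)
  if (length(bad)) {
    abort(sprintf("qPCR table '%s': ct must lie in (0, 45]; row %d has '%s'",
                  path, bad[1L], df$ct[bad[1L]]))
  }
  data.frame(
    sample_id = df$sample_id,
    assay_id = df$assay_id,
    ct = ct,
    is_spike_in = parse_logical_field(df$is_spike_in, "is_spike_in", path),
    is_housekeeping = parse_logical_field(df$is_housekeeping, "is_housekeeping", path),
    stringsAsFactors = FALSE
  )
}

#' Write a result table to TSV with a provenance header
#'
#' Emits the data.frame as UTF-8 TSV preceded by `#` comment lines
#' recording the package version and any parameters supplied. The header
#' carries no timestamps, so identical inputs produce byte-identical files.
#'
#' @param df data.frame to serialize.
#' @param path output file path.
#' @param params optional named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, params = NULL) {
  ok <- tryCatch(write_tsv_with_header(df, path, params), error = function(e) e)
  if (inherits(ok, "error")) {
    abort(sprintf("failed to write '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#' @param path file path.
#' @return data.frame with columns type-converted by [utils::type.convert()].
#' @export
read_result_table <- function(path) {
  df <- read_tsv_checked(path, what = "result table")
  utils::type.convert(df, as.is = TRUE, na.strings = "NA")
}
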