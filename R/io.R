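# Readers and writers for the interchange formats: binding tables
# (TSV/CSV), repertoires (plain text or FASTA), score tables, metric
# tables, folds, ground-truth descriptions and run configs.

.HEADER_ALIASES <- list(
  peptide = c("peptide", "antigen", "epitope"),
  cdr3b = c("cdr3b", "cdr3_beta", "cdr3.beta", "cdr3beta", "tcrb", "cdr3"),
  cdr3a = c("cdr3a", "cdr3_alpha", "cdr3.alpha", "cdr3alpha", "tcra"),
  label = c("label", "binder", "bind", "class"),
  source = c("source", "database", "origin")
)

.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a binding table
#'
#' Reads a tab- or comma-separated binding table (separator chosen by
#' file extension) with header columns `peptide`, `cdr3b`, `cdr3a`,
#' `label`, `source`; common header aliases (e.g. `cdr3_beta`,
#' `epitope`) are recognised and chain/source columns may be absent.
#'
#' @param path file path.
#' @return a record `data.frame` in the canonical schema.
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("binding table not found: %s", path))
  raw <- utils::read.delim(path, sep = .sep_for(path), header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(raw) <- tolower(names(raw))
  for (field in names(.HEADER_ALIASES)) {
    if (field %in% names(raw)) next
    hit <- intersect(.HEADER_ALIASES[[field]], names(raw))
    if (length(hit) > 0L) names(raw)[match(hit[1], names(raw))] <- field
  }
  .coerce_records(raw)
}

#' Write a binding table
#' @param records record table.
#' @param path output TSV path.
#' @export
write_binding_table <- function(records, path) {
  records <- .coerce_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a background repertoire
#'
#' Reads TCR sequences from a plain text file (one sequence per line)
#' or a FASTA file; the format is detected from the first character
#' (`>`) unless given. Duplicates are removed, first occurrence wins,
#' so the same file always yields the same repertoire.
#'
#' @param path file path.
#' @param format `"auto"`, `"text"` or `"fasta"`.
#' @param chain chain tag for the repertoire.
#' @return a [repertoire()].
#' @export
read_repertoire <- function(path, format = c("auto", "text", "fasta"),
                            chain = c("beta", "alpha", "alphabeta")) {
  format <- match.arg(format)
  chain <- match.arg(chain)
  if (!file.exists(path)) stop(sprintf("repertoire file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) > 0L && startsWith(first, ">")) "fasta" else "text"
  }
  seqs <- if (format == "fasta") {
    as.character(Biostrings::readAAStringSet(path))
  } else {
    x <- readLines(path)
    x[nzchar(trimws(x))]
  }
  repertoire(trimws(seqs), chain = chain)
}

#' Write a repertoire
#' @param rep a [repertoire()] or character vector.
#' @param path output path.
#' @param format `"text"` (one per line) or `"fasta"`.
#' @export
write_repertoire <- function(rep, path, format = c("text", "fasta")) {
  format <- match.arg(format)
  seqs <- .rep_seqs(rep)
  if (format == "text") {
    writeLines(seqs, path)
  } else {
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- sprintf("tcr_%06d", seq_along(seqs))
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Read a pre-computed score table
#'
#' TSV/CSV with columns `peptide`, `tcr`, `score`, as produced by an
#' external predictor run offline.
#'
#' @param path file path.
#' @return a `data.frame` for [score_table_scorer()].
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("score table not found: %s", path))
  tab <- utils::read.delim(path, sep = .sep_for(path), header = TRUE,
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("peptide", "tcr", "score")
  if (!all(need %in% names(tab))) {
    stop("score table must have columns peptide, tcr, score")
  }
  tab$score <- as.numeric(tab$score)
  tab[need]
}

#' Write metric records or summaries as TSV
#'
#' Numbers are written at full precision with deterministic formatting,
#' so identical runs produce byte-identical files.
#'
#' @param x a `data.frame` (metric records, aggregate summary, folds,
#'   curves).
#' @param path output TSV path.
#' @export
write_metrics_table <- function(x, path) {
  num <- vapply(x, is.numeric, NA) & !vapply(x, is.integer, NA)
  for (col in names(x)[num]) {
    x[[col]] <- sprintf("%.12g", x[[col]])
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a metric/fold TSV written by [write_metrics_table()]
#' @param path TSV path.
#' @return a `data.frame`.
#' @export
read_metrics_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write and read ground-truth descriptions
#'
#' The synthetic ground truth (per-peptide motifs, threshold, binder
#' sets) serialises to YAML so that simulated datasets round-trip
#' through files like real ones.
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param path YAML path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  yaml::write_yaml(list(
    motif_length = truth$motif_length,
    motif_mismatch = truth$motif_mismatch,
    binder_threshold = truth$binder_threshold,
    chains = truth$chains,
    noise_sd = truth$noise_sd,
    motifs = truth$motifs,
    binders = truth$binders
  ), path)
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()` returns the reconstructed `ground_truth`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop(sprintf("truth file not found: %s", path))
  y <- yaml::read_yaml(path)
  structure(list(
    motifs = y$motifs,
    motif_length = y$motif_length,
    motif_mismatch = y$motif_mismatch,
    binder_threshold = y$binder_threshold,
    binders = lapply(y$binders, as.character),
    chains = y$chains,
    noise_sd = y$noise_sd
  ), class = "ground_truth")
}

.default_run_config <- function() {
  list(
    seed = 1L,
    paths = list(records = NULL, repertoire = NULL, scores = NULL,
                 truth = NULL, out = "tcrbench_run"),
    thresholds = list(majority_min = 100L, fewshot_min = 5L),
    sampling = list(strategy = "background_drawing", ratio = 1L,
                    n_folds = 100L),
    bedroc = list(alpha = 20, variant = "relative"),
    k_grid = c(0.0001, 0.001, 0.01, 0.05, 0.1),
    classification_threshold = 0.5,
    chunk_size = 10000L,
    chain = "beta",
    scorer = list(kind = "random", noise_sd = NULL),
    synthetic = list()
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a run configuration
#'
#' Loads a YAML run configuration and fills unspecified fields with the
#' package defaults (paths, group thresholds, sampling spec, BEDROC
#' parameters, k-grid, scorer selection, synthetic-data settings).
#'
#' @param path YAML path, or `NULL` for pure defaults.
#' @return a nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config not found: %s", path))
    cfg <- .merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run in the output
#' directory: the full configuration, an MD5 hash of its canonical YAML
#' serialisation, the master seed and the package version.
#'
#' @param config run configuration list.
#' @param out_dir run output directory.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("tcrbench"))
  )
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
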