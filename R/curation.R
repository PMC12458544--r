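# Dataset construction for independent benchmarks: merging
# multi-source tables, quality filters, reference exclusion, and
# minimum-binder requirements.

#' Define a quality-filter rule
#'
#' One conjunctive predicate on a record field. Rules are
#' order-independent: a record is kept iff it satisfies every enabled
#' rule. Supported relations:
#' * `"min_nchar"` / `"max_nchar"` - length bounds on a sequence field,
#' * `"alphabet"` - field is a string over the 20-letter amino-acid
#'   alphabet,
#' * `"equals"` - field equals `value`,
#' * `"in"` - field is one of `value`.
#'
#' @param name rule label used in the filter report.
#' @param field record column the rule inspects.
#' @param relation one of the relations above.
#' @param value comparison value (unused for `"alphabet"`).
#' @param enabled disabled rules are reported but not applied.
#' @return a `filter_rule` object.
#' @export
filter_rule <- function(name, field,
                        relation = c("min_nchar", "max_nchar", "alphabet",
                                     "equals", "in"),
                        value = NULL, enabled = TRUE) {
  relation <- match.arg(relation)
  structure(list(name = name, field = field, relation = relation,
                 value = value, enabled = isTRUE(enabled)),
            class = "filter_rule")
}

.rule_pass <- function(records, rule) {
  x <- records[[rule$field]]
  if (is.null(x)) stop(sprintf("filter rule '%s': no column '%s'",
                               rule$name, rule$field))
  ok <- switch(rule$relation,
    min_nchar = !is.na(x) & nchar(x) >= rule$value,
    max_nchar = !is.na(x) & nchar(x) <= rule$value,
    alphabet = .is_aa(x),
    equals = !is.na(x) & x == rule$value,
    `in` = !is.na(x) & x %in% rule$value)
  ok
}

#' Default quality-control rules
#'
#' A reconstruction of typical curation defaults for CDR3 binding
#' tables: valid amino-acid alphabet for peptide and CDR3beta, and CDR3
#' length of at least 8. The exact criteria used by any given upstream
#' pipeline are not standardised, so these ship as configurable rules
#' rather than fixed behaviour, and reports label them as such.
#'
#' @return a list of [filter_rule()]s.
#' @export
default_filter_rules <- function() {
  list(filter_rule("peptide_alphabet", "peptide", "alphabet"),
       filter_rule("cdr3b_alphabet", "cdr3b", "alphabet"),
       filter_rule("cdr3b_min_length", "cdr3b", "min_nchar", 8L))
}

#' Merge multi-source binding tables
#'
#' Normalises each source table to the record schema via an optional
#' column mapping, concatenates them, and collapses exact duplicate
#' pairs (same peptide, chains and label), concatenating their source
#' tags with `";"`. Empty tables are skipped with a warning.
#'
#' @param tables list of `data.frame`s.
#' @param mappings optional list (same length) of named character
#'   vectors `schema_field = source_column`; `NULL` entries mean the
#'   table already uses schema names.
#' @return a merged record `data.frame`.
#' @export
merge_sources <- function(tables, mappings = NULL) {
  stopifnot(is.list(tables), length(tables) > 0L)
  if (!is.null(mappings)) stopifnot(length(mappings) == length(tables))
  norm <- list()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    if (is.null(tab) || nrow(tab) == 0L) {
      warning(sprintf("merge_sources: table %d is empty, skipping", i))
      next
    }
    map <- if (!is.null(mappings)) mappings[[i]] else NULL
    if (!is.null(map)) {
      missing_cols <- setdiff(unname(map), names(tab))
      if (length(missing_cols) > 0L) {
        stop(sprintf("table %d cannot be mapped: missing column(s) %s",
                     i, paste(missing_cols, collapse = ", ")))
      }
      renamed <- tab[unname(map)]
      names(renamed) <- names(map)
      tab <- renamed
    }
    norm[[length(norm) + 1L]] <- .coerce_records(tab)
  }
  if (length(norm) == 0L) stop("all source tables were empty")
  all_rec <- do.call(rbind, norm)
  key <- paste(all_rec$peptide, all_rec$cdr3b, all_rec$cdr3a, all_rec$label,
               sep = "\r")
  src <- vapply(split(all_rec$source, key), function(s) {
    s <- unique(s[!is.na(s)])
    if (length(s) == 0L) NA_character_ else paste(sort(s), collapse = ";")
  }, "")
  out <- all_rec[!duplicated(key), , drop = FALSE]
  out$source <- unname(src[paste(out$peptide, out$cdr3b, out$cdr3a, out$label,
                                 sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Apply quality-filter rules
#'
#' Keeps records satisfying the conjunction of all enabled rules and
#' attaches a per-rule report (attribute `"filter_report"`): for each
#' rule, how many input records fail it (counted independently, so
#' overlapping failures appear under every rule they trip).
#' Applying the same rules twice is a no-op.
#'
#' @param records record table.
#' @param rules list of [filter_rule()]s.
#' @return the filtered records with attribute `"filter_report"`.
#' @export
apply_filters <- function(records, rules = default_filter_rules()) {
  records <- .coerce_records(records)
  keep <- rep(TRUE, nrow(records))
  report <- data.frame(rule = character(0), enabled = logical(0),
                       n_failing = integer(0), stringsAsFactors = FALSE)
  for (rule in rules) {
    ok <- .rule_pass(records, rule)
    report <- rbind(report, data.frame(rule = rule$name, enabled = rule$enabled,
                                       n_failing = sum(!ok),
                                       stringsAsFactors = FALSE))
    if (rule$enabled) keep <- keep & ok
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' Exclude records matching a reference set
#'
#' Removes records that match a reference table (e.g. a model's
#' training and evaluation data) at the configured granularity:
#' `"pair"` (exact peptide + TCR, the default), `"peptide"`, or
#' `"tcr"`.
#'
#' @param records record table.
#' @param reference reference record table.
#' @param mode matching granularity.
#' @param chain which CDR3 chain defines the TCR for `"pair"`/`"tcr"`.
#' @return the records not matching the reference.
#' @export
exclude_reference <- function(records, reference,
                              mode = c("pair", "peptide", "tcr"),
                              chain = c("beta", "alpha")) {
  mode <- match.arg(mode)
  chain <- match.arg(chain)
  records <- .coerce_records(records)
  reference <- .coerce_records(reference)
  col <- .tcr_column(chain)
  hit <- switch(mode,
    pair = paste(records$peptide, records[[col]], sep = "\r") %in%
      paste(reference$peptide, reference[[col]], sep = "\r"),
    peptide = records$peptide %in% reference$peptide,
    tcr = records[[col]] %in% reference[[col]])
  out <- records[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop peptides below a minimum binder count
#'
#' Removes all records of peptides with fewer than `min_binders`
#' binder-labelled records, the usual admission requirement for
#' support/query protocols that need a minimum number of positives per
#' task.
#'
#' @param records record table.
#' @param min_binders minimum binder count a peptide must reach.
#' @param chain which chain identifies the TCR for counting.
#' @return the surviving records.
#' @export
min_binder_filter <- function(records, min_binders = 3L,
                              chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  min_binders <- .assert_scalar_int(min_binders, "min_binders", 1L)
  records <- .coerce_records(records)
  col <- .tcr_column(chain)
  pos <- records[records$label == "binder" & !is.na(records[[col]]), ]
  counts <- table(unique(pos[c("peptide", col)])$peptide)
  ok_pep <- names(counts)[counts >= min_binders]
  out <- records[records$peptide %in% ok_pep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
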