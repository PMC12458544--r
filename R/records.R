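# Core data model: binding records, repertoires, validation.

.RECORD_COLS <- c("peptide", "cdr3b", "cdr3a", "label", "source")

#' Construct a binding-record table
#'
#' A binding record is one peptide-TCR pair: the peptide sequence, the
#' CDR3 sequence of the beta and/or alpha chain, a binary label and an
#' optional free-text provenance tag. Records are stored as a plain
#' `data.frame` with columns `peptide`, `cdr3b`, `cdr3a`, `label`,
#' `source`; missing chains are `NA`.
#'
#' @param peptide character vector of peptide sequences.
#' @param cdr3b,cdr3a character vectors of CDR3 sequences (either may be
#'   `NA` per record, but not both).
#' @param label `"binder"`/`"non-binder"` (also accepts logical or 0/1).
#' @param source optional provenance tag.
#' @return a `data.frame` with the record schema.
#' @examples
#' binding_records("GILGFVFTL", "CASSIRSSYEQYF", label = "binder")
#' @export
binding_records <- function(peptide, cdr3b = NA_character_,
                            cdr3a = NA_character_, label,
                            source = NA_character_) {
  data.frame(peptide = as.character(peptide),
             cdr3b = as.character(cdr3b),
             cdr3a = as.character(cdr3a),
             label = .as_label(label),
             source = as.character(source),
             stringsAsFactors = FALSE)
}

.coerce_records <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  for (col in .RECORD_COLS) {
    if (!col %in% names(records)) {
      if (col %in% c("peptide", "label")) {
        stop(sprintf("records are missing required column '%s'", col))
      }
      records[[col]] <- NA_character_
    }
  }
  records <- records[.RECORD_COLS]
  records$peptide <- as.character(records$peptide)
  records$cdr3b <- as.character(records$cdr3b)
  records$cdr3a <- as.character(records$cdr3a)
  records$label <- .as_label(records$label)
  records$source <- as.character(records$source)
  records
}

#' Validate binding records
#'
#' Keeps records whose peptide and CDR3 sequences are uppercase strings
#' over the 20-letter amino-acid alphabet within configurable length
#' bounds, whose label is one of the two allowed values, and which carry
#' at least one CDR3 chain. Rejected records, with a reason each, are
#' attached as attribute `"rejects"` and their count is reported.
#'
#' @param records a record table (see [binding_records()]).
#' @param peptide_length,cdr3_length inclusive length bounds.
#' @param quiet suppress the reject-count message.
#' @return the validated subset, with attribute `"rejects"`.
#' @examples
#' r <- binding_records(c("GILGFVFTL", "GILGFVFTL"),
#'                      c("CASSIRSSYEQYF", "CASS1RS"), label = "binder")
#' validate_records(r)
#' @export
validate_records <- function(records, peptide_length = c(8L, 15L),
                             cdr3_length = c(6L, 30L), quiet = FALSE) {
  records <- .coerce_records(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  pep_ok <- .is_aa(records$peptide)
  flag(!pep_ok, "invalid peptide sequence")
  plen <- nchar(records$peptide)
  flag(pep_ok & (plen < peptide_length[1] | plen > peptide_length[2]),
       "peptide length out of bounds")

  has_b <- !is.na(records$cdr3b) & nzchar(records$cdr3b)
  has_a <- !is.na(records$cdr3a) & nzchar(records$cdr3a)
  flag(!has_b & !has_a, "no CDR3 chain")

  chain_bad <- rep(FALSE, n)
  for (col in c("cdr3b", "cdr3a")) {
    present <- !is.na(records[[col]]) & nzchar(records[[col]])
    ok <- .is_aa(records[[col]])
    len <- nchar(records[[col]])
    inb <- len >= cdr3_length[1] & len <= cdr3_length[2]
    chain_bad <- chain_bad | (present & (!ok | !inb))
  }
  flag(chain_bad, "invalid CDR3 sequence")

  flag(is.na(records$label), "invalid label")

  keep <- is.na(reason)
  rejects <- records[!keep, , drop = FALSE]
  rejects$reason <- reason[!keep]
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) stop("no valid records after validation")
  if (!quiet && nrow(rejects) > 0L) {
    tab <- table(rejects$reason)
    message(sprintf("validate_records: rejected %d of %d record(s) [%s]",
                    nrow(rejects), n,
                    paste(sprintf("%s: %d", names(tab), tab), collapse = "; ")))
  }
  attr(kept, "rejects") <- rejects
  kept
}

#' Construct a background repertoire
#'
#' A repertoire is the deduplicated library of TCR sequences used as
#' the screening universe of size `N`. Iteration order is the order of
#' first occurrence in the input, so a given input file always yields
#' the same repertoire.
#'
#' @param sequences character vector of CDR3 sequences.
#' @param chain `"beta"`, `"alpha"` or `"alphabeta"`.
#' @return a character vector of class `"repertoire"` with a `chain`
#'   attribute.
#' @export
repertoire <- function(sequences, chain = c("beta", "alpha", "alphabeta")) {
  chain <- match.arg(chain)
  sequences <- unique(as.character(sequences))
  sequences <- sequences[!is.na(sequences) & nzchar(sequences)]
  if (length(sequences) < 1L) stop("repertoire must contain at least one sequence")
  structure(sequences, class = "repertoire", chain = chain)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %d unique %s-chain sequences\n",
              length(x), attr(x, "chain")))
  invisible(x)
}

# Strip class/attributes for plain character use.
.rep_seqs <- function(x) as.character(unclass(x))
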