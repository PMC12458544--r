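# Internal helpers: amino-acid alphabet, deterministic string hashing,
# seed derivation.

# Standard 20-letter amino-acid alphabet (uppercase one-letter codes).
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.is_aa <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mersenne prime 2^31 - 1; all hash arithmetic stays below 2^53 so it is
# exact in doubles.
.HASH_P <- 2147483647

# (a * b) mod P without overflowing double precision; a, b < 2^31.
.mulmod <- function(a, b) {
  hi <- b %/% 32768
  lo <- b %% 32768
  (((a * hi) %% .HASH_P) * 32768 + a * lo) %% .HASH_P
}

.hash_weights_env <- new.env(parent = emptyenv())

# 33^k mod P for k = 0 .. n-1, memoised.
.hash_weights <- function(n) {
  w <- .hash_weights_env$w
  if (is.null(w) || length(w) < n) {
    w <- numeric(n)
    w[1] <- 1
    if (n > 1) for (k in 2:n) w[k] <- (w[k - 1] * 33) %% .HASH_P
    .hash_weights_env$w <- w
  }
  w[seq_len(n)]
}

# Polynomial rolling hash of each string, vectorised over the whole
# vector (single utf8ToInt call + grouped sum).
.hash_strings <- function(x) {
  x <- as.character(x)
  n <- nchar(x)
  if (any(n == 0L)) stop("cannot hash empty strings")
  codes <- utf8ToInt(paste(x, collapse = ""))
  pos <- sequence(n)
  w <- .hash_weights(max(n))
  grp <- rep.int(seq_along(x), n)
  as.numeric(rowsum(codes * w[pos], grp, reorder = TRUE)) %% .HASH_P
}

# Deterministic pseudo-uniform draw in [0, 1) per string, keyed by a
# salt (seed and/or context string). Three multiply-xor mixing rounds.
.hash_unit <- function(x, salt = "") {
  h <- .hash_strings(x)
  hs <- if (nzchar(salt)) .hash_strings(salt) else 0
  z <- (h + hs + 1) %% .HASH_P
  for (m in c(2654435761 %% .HASH_P, 1597334677, 887987685)) {
    z <- .mulmod(z + 1, m)
    z <- as.numeric(bitwXor(as.integer(z), as.integer(z %/% 65536)))
  }
  z / .HASH_P
}

# Derive a child seed below 2^31 from a base seed and a stream index.
.child_seed <- function(seed, stream) {
  as.integer((.mulmod((as.numeric(seed) %% .HASH_P) + 1,
                      (as.numeric(stream) %% .HASH_P) * 2 + 3)) %% 2147483647)
}

.assert_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    stop(sprintf("'%s' must be >= %d", name, min))
  }
  as.integer(x)
}

# Normalise label vectors to "binder" / "non-binder".
.as_label <- function(x) {
  if (is.logical(x)) return(ifelse(x, "binder", "non-binder"))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(ifelse(x == 1, "binder", "non-binder"))
  }
  x <- as.character(x)
  ok <- x %in% c("binder", "non-binder")
  x[!ok] <- NA_character_
  x
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lab <- .as_label(labels)
  if (anyNA(lab)) stop("labels must be 'binder'/'non-binder' (or 0/1)")
  as.integer(lab == "binder")
}

.tcr_column <- function(chain = c("beta", "alpha")) {
  chain <- match.arg(chain)
  if (chain == "beta") "cdr3b" else "cdr3a"
}
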