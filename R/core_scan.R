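#' @useDynLib ssrmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PRIME_MAP <- c(A = 2L, C = 3L, G = 5L, T = 7L)

#' Mining parameters
#'
#' Holds the motif-length thresholds and the compound-merge gap threshold
#' used throughout the mining pipeline. `thresholds` maps each motif length
#' `m` (in bp) to the minimum number of tandem copies (`MinExponent`)
#' required before a repeat is reported; `interval` is the maximum gap, in
#' bp, between two tracts that still merges them into one compound SSR.
#'
#' @param thresholds named integer vector; names are motif lengths, values
#'   the minimum exponent for that length. Every motif length must be >= 1
#'   and every minimum exponent >= 2.
#' @param interval non-negative integer, the compound-merge gap threshold
#'   (default 10).
#' @return an object of class `mining_params` with elements `thresholds`
#'   (named integer vector, sorted by motif length) and `interval`.
#' @examples
#' mining_params(c("1" = 12, "2" = 5, "3" = 4), interval = 10)
#' @export
mining_params <- function(thresholds, interval = 10L) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  m <- suppressWarnings(as.integer(names(thresholds)))
  v <- as.integer(thresholds)
  if (anyNA(m) || anyNA(v)) stop("thresholds must be a named integer vector")
  if (any(m < 1L)) stop("motif lengths must be >= 1")
  if (any(v < 2L)) stop("every MinExponent must be >= 2")
  if (anyDuplicated(m)) stop("duplicate motif length in thresholds")
  interval <- as.integer(interval)
  if (length(interval) != 1L || is.na(interval) || interval < 0L)
    stop("interval must be a single non-negative integer")
  o <- order(m)
  structure(list(thresholds = stats::setNames(v[o], m[o]), interval = interval),
            class = "mining_params")
}

#' @export
print.mining_params <- function(x, ...) {
  cat("Mining parameters\n")
  cat("  motif:minExponent  ",
      paste(names(x$thresholds), x$thresholds, sep = ":", collapse = ", "), "\n")
  cat("  interval (compound gap threshold):", x$interval, "bp\n")
  invisible(x)
}

#' Encode a nucleotide sequence as prime integers
#'
#' Maps A, C, G, T (case-insensitively) to the primes 2, 3, 5, 7 and every
#' other character (N, IUPAC ambiguity codes, gaps) to 1. A period-m tandem
#' repeat then shows up as a run of equal sliding-window products of the
#' encoded values.
#'
#' @param seq_id sequence identifier.
#' @param sequence nucleotide string; may be empty.
#' @return an object of class `encoded_seq`: list with `seq_id`, `residues`
#'   (the uppercased input) and `values` (integer vector, one per residue).
#' @examples
#' encode("s1", "ACGT")$values  # 2 3 5 7
#' @export
encode <- function(seq_id, sequence) {
  residues <- toupper(as.character(sequence))
  if (length(residues) != 1L) stop("sequence must be a single string")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  values <- unname(PRIME_MAP[chars])
  values[is.na(values)] <- 1L
  structure(list(seq_id = as.character(seq_id), residues = residues,
                 values = as.integer(values)),
            class = "encoded_seq")
}

#' Minimum equal-product run length for a repeat threshold
#'
#' A perfect tandem repeat of E copies of an m-bp motif spans m*E residues
#' and therefore m*E - m + 1 sliding windows of size m, all with equal
#' products. The minimum run length corresponding to `min_exponent` copies
#' is `m * min_exponent - (m - 1)`.
#'
#' @param m motif length in bp (>= 1).
#' @param min_exponent minimum repeat count (>= 2).
#' @return integer run-length threshold.
#' @examples
#' min_rep_multiples(2, 5)  # 9
#' @export
min_rep_multiples <- function(m, min_exponent) {
  m <- as.integer(m); min_exponent <- as.integer(min_exponent)
  if (any(is.na(m)) || any(m < 1L)) stop("m must be >= 1")
  if (any(is.na(min_exponent)) || any(min_exponent < 2L))
    stop("min_exponent must be >= 2")
  m * min_exponent - (m - 1L)
}

#' Maximal equal-product runs at one period
#'
#' Returns all maximal runs of consecutive equal values in the conceptual
#' sliding-window product list for period `m`. The default implementation
#' never materializes the products: adjacent window products are equal
#' exactly when the residue leaving the window equals the residue entering
#' it (all encoded values are nonzero). Setting `use_products = TRUE`
#' computes the products explicitly (exact 64-bit arithmetic, m <= 22);
#' both paths give identical results on every input.
#'
#' @param enc an `encoded_seq` (or bare integer vector of encoded values).
#' @param m period / motif length (>= 1).
#' @param use_products logical; materialize the product list.
#' @return data.frame with columns `m`, `start` (1-based position of the
#'   first window of the run) and `run_length`. Empty when the sequence is
#'   shorter than `m`.
#' @export
scan_period <- function(enc, m, use_products = FALSE) {
  values <- if (inherits(enc, "encoded_seq")) enc$values else as.integer(enc)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be a single integer >= 1")
  r <- .period_runs_cpp(values, m, use_products)
  data.frame(m = rep.int(m, length(r$start)), start = r$start,
             run_length = r$run_length)
}

empty_ssr_frame <- function() {
  data.frame(seq_id = character(), motif = character(), m = integer(),
             exponent = integer(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Detect perfect tandem repeats
#'
#' For each configured motif length m, finds every maximal run of equal
#' window products whose length reaches [min_rep_multiples()] for that
#' length, converts it to a repeat region (run windows plus m-1 trailing
#' residues), trims any trailing partial motif copy so only whole copies
#' are reported, and discards regions containing ambiguous (non-ACGT)
#' residues. Output is raw per-motif-length records; cross-length
#' redundancy (e.g. a mononucleotide run also satisfying period 2) is
#' resolved downstream by [remove_redundant()].
#'
#' @param enc an `encoded_seq` from [encode()].
#' @param params a `mining_params` object.
#' @return data.frame with columns `seq_id`, `motif`, `m`, `exponent`,
#'   `start`, `end` (1-based inclusive genomic coordinates).
#' @examples
#' p <- mining_params(c("2" = 5))
#' detect_perfect(encode("s1", "ATATATATAT"), p)  # (AT)5 at [1,10]
#' @export
detect_perfect <- function(enc, params) {
  stopifnot(inherits(enc, "encoded_seq"), inherits(params, "mining_params"))
  out <- list()
  for (k in seq_along(params$thresholds)) {
    m <- as.integer(names(params$thresholds)[k])
    min_exp <- params$thresholds[[k]]
    min_run <- min_rep_multiples(m, min_exp)
    runs <- scan_period(enc, m)
    runs <- runs[runs$run_length >= min_run, , drop = FALSE]
    if (nrow(runs) == 0L) next
    raw_len <- runs$run_length + m - 1L
    exponent <- raw_len %/% m
    start <- runs$start
    end <- start + m * exponent - 1L
    keep <- !vapply(seq_along(start), function(i)
      .has_ambiguous_cpp(enc$values, start[i], end[i]), logical(1))
    if (!any(keep)) next
    start <- start[keep]; end <- end[keep]; exponent <- exponent[keep]
    motif <- substring(enc$residues, start, start + m - 1L)
    out[[length(out) + 1L]] <- data.frame(
      seq_id = enc$seq_id, motif = motif, m = m, exponent = exponent,
      start = start, end = end, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_ssr_frame())
  do.call(rbind, out)
}
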