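#' Naive reference scan for perfect tandem repeats
#'
#' Straightforward reference implementation used to validate the
#' prime-product scanner and to certify synthetic genomes: for every motif
#' length it compares each residue with the residue one period ahead,
#' collects maximal match runs, applies the same exponent threshold and
#' trailing-copy trimming, discards regions touching non-ACGT residues,
#' and removes cross-length redundancy by an exhaustive any-pair rule.
#' It shares no code with [detect_perfect()] / [remove_redundant()].
#'
#' @param sequence nucleotide string.
#' @param params a `mining_params` object.
#' @param seq_id identifier for the output rows.
#' @return sorted non-redundant data.frame in the perfect-SSR layout.
#' @export
naive_repeat_scan <- function(sequence, params, seq_id = "seq") {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_acgt <- chars %in% c("A", "C", "G", "T")
  # all non-ACGT symbols collapse to one ambiguity class, mirroring the
  # many-to-one prime encoding
  cls <- ifelse(is_acgt, chars, ".")
  out <- list()
  for (k in seq_along(params$thresholds)) {
    m <- as.integer(names(params$thresholds)[k])
    min_exp <- params$thresholds[[k]]
    if (n < 2L * m) next
    eq <- cls[seq_len(n - m)] == cls[seq_len(n - m) + m]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      start <- pos[j]
      raw_len <- r$lengths[j] + m          # residues covered
      exponent <- raw_len %/% m
      if (exponent < min_exp) next
      end <- start + m * exponent - 1L
      if (any(!is_acgt[start:end])) next
      out[[length(out) + 1L]] <- data.frame(
        seq_id = seq_id, motif = substr(sequence, start, start + m - 1L),
        m = m, exponent = exponent, start = start, end = end,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_ssr_frame())
  recs <- do.call(rbind, out)
  # exhaustive redundancy rule: drop B if ANY record A with smaller
  # dividing motif length, periodic motif match and containment exists
  drop <- logical(nrow(recs))
  for (b in seq_len(nrow(recs))) {
    for (a in seq_len(nrow(recs))) {
      if (a == b) next
      if (recs$m[a] < recs$m[b] && recs$m[b] %% recs$m[a] == 0L &&
          strrep(recs$motif[a], recs$m[b] %/% recs$m[a]) == recs$motif[b] &&
          recs$start[a] <= recs$start[b] && recs$end[b] <= recs$end[a]) {
        drop[b] <- TRUE
        break
      }
    }
  }
  recs <- recs[!drop, , drop = FALSE]
  recs <- recs[order(recs$start, recs$m, -recs$end), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}
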