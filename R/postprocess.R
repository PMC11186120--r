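#' Sort perfect SSR records by genomic position
#'
#' The per-motif-length scans populate the record matrix one motif length
#' at a time, so records arrive unsorted across lengths. Sorting is stable
#' by start position ascending, breaking ties by motif length ascending and
#' then by end descending.
#'
#' @param records data.frame of perfect SSR records (one sequence).
#' @return the sorted data.frame.
#' @export
sort_ssrs <- function(records) {
  if (nrow(records) == 0L) return(records)
  records[order(records$start, records$m, -records$end), , drop = FALSE]
}

#' Remove cross-motif redundancy (smaller motif wins)
#'
#' A repeat detected at one period is often re-detected at a multiple of
#' that period: (AC)4 also satisfies period 4 as (ACAC)2, and a
#' mononucleotide run satisfies every period. A record B is dropped when a
#' kept record A has a smaller motif length that divides B's, A's motif
#' repeated gives B's motif, and B's region lies inside A's. Pairwise pass
#' over the sorted records (O(q^2) in the number of records q).
#'
#' @param records sorted data.frame of perfect SSR records (one sequence).
#' @return data.frame with redundant records removed.
#' @examples
#' recs <- data.frame(seq_id = "s", motif = c("AC", "ACAC"), m = c(2L, 4L),
#'                    exponent = c(4L, 2L), start = c(1L, 1L), end = c(8L, 8L))
#' remove_redundant(sort_ssrs(recs))  # keeps (AC)4 only
#' @export
remove_redundant <- function(records) {
  q <- nrow(records)
  if (q <= 1L) return(records)
  keep <- logical(q)
  kept_idx <- integer(0)
  for (i in seq_len(q)) {
    redundant <- FALSE
    for (j in kept_idx) {
      if (records$m[j] < records$m[i] &&
          records$m[i] %% records$m[j] == 0L &&
          strrep(records$motif[j], records$m[i] %/% records$m[j]) ==
            records$motif[i] &&
          records$start[j] <= records$start[i] &&
          records$end[i] <= records$end[j]) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  records[keep, , drop = FALSE]
}

#' Merge nearby repeats into compound tracts
#'
#' Greedy left-to-right chaining over the sorted, non-redundant records:
#' the gap between consecutive records is `start(next) - end(previous)`;
#' whenever the gap is at most `interval` the records join one tract. A
#' chain of two or more members is a compound SSR; singletons pass through
#' as perfect SSRs. Gap values are retained so the distance between member
#' motifs is not lost.
#'
#' @param records sorted non-redundant data.frame of perfect SSRs (one
#'   sequence).
#' @param interval non-negative integer gap threshold in bp.
#' @return an object of class `ssr_tracts`: a list of tracts, each a list
#'   with `seq_id`, `members` (data.frame of member records), `gaps`
#'   (integer vector, length members-1), `start`, `end`, and `type`
#'   (`"p<m>"` for a perfect tract, `"c"` for compound).
#' @export
merge_compound <- function(records, interval = 10L) {
  interval <- as.integer(interval)
  if (is.na(interval) || interval < 0L) stop("interval must be >= 0")
  tracts <- list()
  q <- nrow(records)
  i <- 1L
  while (i <= q) {
    j <- i
    while (j < q && records$start[j + 1L] - records$end[j] <= interval)
      j <- j + 1L
    members <- records[i:j, , drop = FALSE]
    rownames(members) <- NULL
    gaps <- if (j > i)
      members$start[-1L] - members$end[-nrow(members)] else integer(0)
    tracts[[length(tracts) + 1L]] <- list(
      seq_id = members$seq_id[1L],
      members = members,
      gaps = as.integer(gaps),
      start = members$start[1L],
      end = members$end[nrow(members)],
      type = if (nrow(members) >= 2L) "c" else paste0("p", members$m[1L]))
    i <- j + 1L
  }
  structure(tracts, class = "ssr_tracts")
}

#' @export
print.ssr_tracts <- function(x, ...) {
  cat(length(x), "SSR tract(s)\n")
  for (t in x)
    cat(sprintf("  %s %s [%d, %d] %s\n", t$seq_id, t$type, t$start, t$end,
                render_ssr_string(t)))
  invisible(x)
}

#' Render the SSR string of a tract
#'
#' Perfect tracts render as `(MOTIF)E`; compound tracts concatenate their
#' members with `-nK-` spacers, where K is the number of intervening bases
#' between consecutive members (gap - 1).
#'
#' @param tract one element of an `ssr_tracts` list.
#' @return character scalar.
#' @export
render_ssr_string <- function(tract) {
  parts <- sprintf("(%s)%d", tract$members$motif, tract$members$exponent)
  if (length(parts) == 1L) return(parts)
  spacers <- sprintf("-n%d-", tract$gaps - 1L)
  paste0(paste0(parts[-length(parts)], spacers, collapse = ""),
         parts[length(parts)])
}

#' Marker-matrix representation of merged tracts
#'
#' Reproduces the internal matrix convention in which compound membership
#' is marked by sign: within a chain, every boundary except the chain's
#' first start and last end is negated; the magnitudes keep the original
#' coordinates, so the distance between member motifs is recoverable.
#' Singleton tracts keep all-positive coordinates.
#'
#' @param tracts an `ssr_tracts` object.
#' @return data.frame with columns `ssr_id`, `m`, `exponent`,
#'   `start_marker`, `end_marker`, one row per member record in order.
#' @export
to_marker_matrix <- function(tracts) {
  rows <- list()
  for (t in tracts) {
    k <- nrow(t$members)
    sm <- t$members$start
    em <- t$members$end
    if (k >= 2L) {
      sm[-1L] <- -sm[-1L]
      em[-k] <- -em[-k]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      m = t$members$m, exponent = t$members$exponent,
      start_marker = sm, end_marker = em)
  }
  if (length(rows) == 0L)
    return(data.frame(ssr_id = integer(), m = integer(), exponent = integer(),
                      start_marker = integer(), end_marker = integer()))
  out <- do.call(rbind, rows)
  cbind(ssr_id = seq_len(nrow(out)), out)
}

#' Reconstruct tract grouping from a marker matrix
#'
#' Inverse of the sign convention of [to_marker_matrix()]: a row with a
#' positive start marker opens a tract, and the tract closes at the first
#' subsequent row with a positive end marker. Used to verify that the sign
#' pattern alone determines tract boundaries.
#'
#' @param mm data.frame as returned by [to_marker_matrix()].
#' @return integer vector assigning each row to a tract, plus per-tract
#'   `start`/`end` data.frame in attribute `"bounds"`.
#' @export
tracts_from_marker_matrix <- function(mm) {
  n <- nrow(mm)
  grp <- integer(n)
  g <- 0L
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    stopifnot(mm$start_marker[i] > 0L)
    g <- g + 1L
    j <- i
    while (mm$end_marker[j] < 0L) j <- j + 1L
    grp[i:j] <- g
    starts <- c(starts, mm$start_marker[i])
    ends <- c(ends, mm$end_marker[j])
    i <- j + 1L
  }
  structure(grp, bounds = data.frame(start = starts, end = ends))
}
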