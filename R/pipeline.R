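#' Mine one sequence end to end
#'
#' Convenience wrapper chaining [encode()], [detect_perfect()],
#' [sort_ssrs()], [remove_redundant()] and [merge_compound()].
#'
#' @param seq_id sequence identifier.
#' @param sequence nucleotide string.
#' @param params a `mining_params` object.
#' @return list with `perfect` (sorted, non-redundant perfect SSR
#'   data.frame) and `tracts` (the merged `ssr_tracts`).
#' @export
mine_sequence <- function(seq_id, sequence, params) {
  enc <- encode(seq_id, sequence)
  perfect <- remove_redundant(sort_ssrs(detect_perfect(enc, params)))
  rownames(perfect) <- NULL
  list(perfect = perfect, tracts = merge_compound(perfect, params$interval))
}

#' Mine every record of a FASTA data.frame
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param params a `mining_params` object.
#' @return list with `perfect` (row-bound across records) and `tracts`
#'   (concatenated `ssr_tracts` in record order).
#' @export
mine_records <- function(records, params) {
  per <- lapply(seq_len(nrow(records)), function(i)
    mine_sequence(records$seq_id[i], records$sequence[i], params))
  perfect <- do.call(rbind, c(lapply(per, `[[`, "perfect"),
                              list(empty_ssr_frame())))
  rownames(perfect) <- NULL
  tracts <- structure(do.call(c, lapply(per, function(x) unclass(x$tracts))),
                      class = "ssr_tracts")
  if (is.null(tracts)) tracts <- structure(list(), class = "ssr_tracts")
  list(perfect = perfect, tracts = tracts)
}
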