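test_that("records sort by start with motif-length and end tie-breaks", {
  expect_equal(nrow(sort_ssrs(make_ssr("A", 2, 1)[0, ])), 0L)
  recs <- rbind(make_ssr("AT", 3, 9), make_ssr("ATG", 2, 4))
  expect_equal(sort_ssrs(recs)$start, c(4L, 9L))
  # same start: smaller motif first
  recs <- rbind(make_ssr("AT", 6, 1), make_ssr("A", 12, 1))
  expect_equal(sort_ssrs(recs)$m, c(1L, 2L))
})

test_that("smaller-motif records absorb periodic multiples at the same region", {
  recs <- sort_ssrs(rbind(make_ssr("AC", 4, 1), make_ssr("ACAC", 2, 1)))
  kept <- remove_redundant(recs)
  expect_equal(kept$motif, "AC")
  # trimming gives different ends; containment still resolves it
  a13 <- make_ssr("A", 13, 1)
  recs <- sort_ssrs(rbind(a13, make_ssr("AA", 6, 1), make_ssr("AAA", 4, 1)))
  kept <- remove_redundant(recs)
  expect_equal(kept$motif, "A")
  expect_equal(kept$end, 13L)
  # unrelated records untouched
  recs <- sort_ssrs(rbind(make_ssr("AT", 6, 1), make_ssr("GC", 5, 20)))
  expect_equal(nrow(remove_redundant(recs)), 2L)
  # different motif, same length region: not redundant
  recs <- sort_ssrs(rbind(make_ssr("AC", 4, 1), make_ssr("CA", 4, 2)))
  expect_equal(nrow(remove_redundant(recs)), 2L)
})

test_that("redundancy removal never drops an uncovered record", {
  set.seed(55)
  p <- bench_params()
  n_dropped <- 0L
  for (i in 1:25) {
    # mononucleotide runs re-detect at every period, guaranteeing
    # redundancy for the pass to resolve
    s <- paste0(random_seq(500), strrep("A", 13L), random_seq(400),
                strrep("T", 14L), random_seq(500))
    raw <- sort_ssrs(detect_perfect(encode("r", s), p))
    kept <- remove_redundant(raw)
    dropped <- raw[!rownames(raw) %in% rownames(kept), , drop = FALSE]
    n_dropped <- n_dropped + nrow(dropped)
    for (b in seq_len(nrow(dropped))) {
      covered <- any(kept$start <= dropped$start[b] &
                       dropped$end[b] <= kept$end &
                       kept$m < dropped$m[b])
      expect_true(covered)
    }
  }
  expect_gt(n_dropped, 0L)
})

test_that("nearby tracts chain into one compound SSR at the gap threshold", {
  tr <- merge_compound(sort_ssrs(worked_example_records()), 10L)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$start, 4L)
  expect_equal(tr[[1]]$end, 35L)
  expect_equal(tr[[1]]$gaps, c(1L, 10L))
  expect_equal(tr[[1]]$type, "c")
  # gap 11 with interval 10: two separate perfect tracts
  recs <- sort_ssrs(rbind(make_ssr("AT", 5, 1), make_ssr("GC", 5, 21)))
  tr <- merge_compound(recs, 10L)
  expect_length(tr, 2L)
  expect_equal(vapply(tr, `[[`, "", "type"), c("p2", "p2"))
  # empty input
  expect_length(merge_compound(make_ssr("A", 2, 1)[0, ], 10L), 0L)
})

test_that("compound merging is idempotent and respects the gap threshold", {
  set.seed(77)
  p <- bench_params()
  for (i in 1:25) {
    s <- random_seq(2000)
    recs <- remove_redundant(sort_ssrs(detect_perfect(encode("r", s), p)))
    tr <- merge_compound(recs, p$interval)
    # re-merging the flattened members reproduces the same tracts
    flat <- do.call(rbind, lapply(tr, `[[`, "members"))
    if (!is.null(flat)) {
      tr2 <- merge_compound(flat, p$interval)
      expect_equal(unclass(tr2), unclass(tr))
    }
    # internal gaps <= interval; gaps between adjacent tracts > interval
    for (t in tr) expect_true(all(t$gaps <= p$interval))
    if (length(tr) > 1L) {
      starts <- vapply(tr, `[[`, 0L, "start")
      ends <- vapply(tr, `[[`, 0L, "end")
      expect_true(all(starts[-1L] - ends[-length(ends)] > p$interval))
    }
  }
})

test_that("marker matrix negates interior compound boundaries only", {
  tr <- merge_compound(sort_ssrs(worked_example_records()), 10L)
  mm <- to_marker_matrix(tr)
  expect_equal(mm$ssr_id, 1:3)
  expect_equal(mm$m, c(3L, 2L, 2L))
  expect_equal(mm$exponent, c(2L, 3L, 6L))
  expect_equal(mm$start_marker, c(4L, -9L, -24L))
  expect_equal(mm$end_marker, c(-8L, -14L, 35L))
  # singleton keeps positive coordinates
  mm <- to_marker_matrix(merge_compound(make_ssr("AT", 5, 1), 10L))
  expect_equal(mm$start_marker, 1L)
  expect_equal(mm$end_marker, 10L)
  expect_equal(nrow(to_marker_matrix(merge_compound(make_ssr("A", 2, 1)[0, ],
                                                    10L))), 0L)
})

test_that("marker-matrix signs alone reconstruct the tract boundaries", {
  set.seed(88)
  p <- bench_params()
  for (i in 1:20) {
    s <- random_seq(2500)
    recs <- remove_redundant(sort_ssrs(detect_perfect(encode("r", s), p)))
    tr <- merge_compound(recs, p$interval)
    if (length(tr) == 0L) next
    mm <- to_marker_matrix(tr)
    grp <- tracts_from_marker_matrix(mm)
    sizes <- vapply(tr, function(t) nrow(t$members), 0L)
    expect_equal(as.integer(table(grp)[as.character(seq_along(tr))]), sizes)
    bounds <- attr(grp, "bounds")
    expect_equal(bounds$start, vapply(tr, `[[`, 0L, "start"))
    expect_equal(bounds$end, vapply(tr, `[[`, 0L, "end"))
  }
})

test_that("overlapping and adjacent records always merge", {
  # gap formula start - end: adjacency gives 1, overlap gives <= 0
  recs <- sort_ssrs(rbind(make_ssr("AT", 5, 1), make_ssr("TA", 5, 10)))
  tr <- merge_compound(recs, 0L)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$gaps, 0L)
})
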