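coding_row <- function(seq_id, gene, ssr, start = 100L) {
  motif <- sub("^\\(([^)]*)\\).*$", "\\1", ssr)
  exponent <- as.integer(sub("^\\([^)]*\\)", "", ssr))
  data.frame(seq_id = seq_id, motif = motif, m = nchar(motif),
             exponent = exponent, start = start,
             end = start + nchar(motif) * exponent - 1L, ssr = ssr,
             gene = gene, locus_tag = paste0("lt_", gene), product = "x",
             strand = "+", stringsAsFactors = FALSE)
}

test_that("abundance counts exact SSR strings per gene per genome", {
  k12 <- rbind(coding_row("k1", "yqeJ", "(A)8", 100L),
               coding_row("k1", "yqeJ", "(A)8", 300L))
  o157 <- rbind(coding_row("o1", "yqeJ", "(A)8", 100L),
                coding_row("o1", "yqeJ", "(A)9", 300L))
  tab <- build_abundance(list(k1 = k12, o1 = o157))
  expect_equal(tab$gene, c("yqeJ", "yqeJ"))
  expect_equal(tab$ssr, c("(A)8", "(A)9"))
  expect_equal(tab$k1, c(2L, 0L))
  expect_equal(tab$o1, c(1L, 1L))
  # empty input
  expect_equal(nrow(build_abundance(list(g = k12[0, ]))), 0L)
  # column sums equal the number of coding records per genome
  expect_equal(sum(tab$k1), nrow(k12))
  expect_equal(sum(tab$o1), nrow(o157))
})

test_that("full separation of two groups of 51 gives chi-squared N - 1", {
  ids <- sprintf("g%03d", 1:102)
  tab <- data.frame(gene = "accC", ssr = "(CGG)5", stringsAsFactors = FALSE)
  tab[ids] <- as.list(c(rep(2L, 51), rep(3L, 51)))
  groups <- setNames(rep(c("K12", "O157"), each = 51), ids)
  st <- compare_groups(tab, groups)
  expect_equal(st$kruskal_chi_squared, 101)
  expect_lt(st$kruskal_p, 1e-15)
  expect_equal(st$sum_K12, 102)
  expect_equal(st$sum_O157, 153)
  expect_equal(st$anova_Df, 1)
  expect_gt(st$anova_F_value, 1e3)
  expect_equal(nrow(st$tukey[[1]]), 1L)
})

test_that("kruskal statistic is invariant under monotone count transforms", {
  set.seed(13)
  ids <- sprintf("g%02d", 1:20)
  groups <- setNames(rep(c("a", "b"), each = 10), ids)
  x <- rpois(20, 4)
  tab <- data.frame(gene = "g", ssr = "(A)8", stringsAsFactors = FALSE)
  tab[ids] <- as.list(x)
  tab2 <- tab
  tab2[ids] <- as.list(x^3 + 7L)  # strictly monotone on non-negative counts
  expect_equal(compare_groups(tab, groups)$kruskal_chi_squared,
               compare_groups(tab2, groups)$kruskal_chi_squared)
})

test_that("degenerate rows yield NA statistics, not failures", {
  ids <- sprintf("g%02d", 1:10)
  groups <- setNames(rep(c("a", "b"), each = 5), ids)
  tab <- data.frame(gene = "g", ssr = "(A)8", stringsAsFactors = FALSE)
  tab[ids] <- as.list(rep(1L, 10))
  st <- compare_groups(tab, groups)
  expect_true(is.na(st$kruskal_p))
  expect_true(is.na(st$shapiro_W))
  expect_true(is.na(st$anova_F_value))
  expect_equal(st$sum_a, 5)  # group sums still reported
  # a group with < 2 genomes warns and reports NA
  groups2 <- setNames(c(rep("a", 9), "b"), ids)
  tab2 <- tab
  tab2[ids] <- as.list(1:10)
  expect_warning(st2 <- compare_groups(tab2, groups2), "< 2 genomes")
  expect_true(is.na(st2$kruskal_p))
  # unlabeled genome is an error naming the id
  expect_error(compare_groups(tab, groups[-1]), "g01")
})

test_that("marker selection is a strict raw-p threshold, NA excluded", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   ssr = c("(A)8", "(C)8", "(G)8", "(T)8"),
                   kruskal_p = c(5e-4, 0.001, NA, 2e-5),
                   stringsAsFactors = FALSE)
  sel <- select_markers(st, 0.001)
  expect_equal(sel$gene, c("d", "a"))  # sorted by p ascending
  expect_false("b" %in% sel$gene)      # p == alpha not selected
  expect_false("c" %in% sel$gene)      # NA excluded
  expect_equal(nrow(select_markers(st[0, ], 0.001)), 0L)
  # alpha 1.0 selects every non-NA row
  expect_equal(nrow(select_markers(st, 1.0)), 3L)
})

test_that("statistics files are written per test family plus combined", {
  set.seed(17)
  ids <- sprintf("g%02d", 1:12)
  groups <- setNames(rep(c("a", "b"), each = 6), ids)
  tab <- data.frame(gene = c("x", "y", "z"),
                    ssr = c("(A)8", "(C)8", "(G)8"),
                    stringsAsFactors = FALSE)
  for (id in ids) tab[[id]] <- c(rpois(1, 3), rpois(1, 3), 1L)
  st <- compare_groups(tab, groups)
  d <- withr::local_tempdir()
  paths <- write_stats_files(st, d, abundance = tab)
  expect_true(all(file.exists(paths)))
  for (nm in c("shapiro", "kruskal", "anova", "sums", "combined"))
    expect_equal(nrow(read.delim(paths[[nm]])), 3L)
  comb <- read.delim(paths[["combined"]], check.names = FALSE)
  expect_true(all(c("F_value", "Mean_Sq", "Sum_Sq", "Df", "W",
                    "chi_squared", "p_value") %in% colnames(comb)))
  # constant row z serializes as NA
  expect_true(is.na(comb$chi_squared[comb$Gene == "z"]))
  cnt <- read_abundance(paths[["counting"]])
  expect_equal(cnt, tab, ignore_attr = TRUE)
})

test_that("a planted exponent shift is detected with high power at n = 20", {
  set.seed(23)
  ids <- sprintf("g%02d", 1:40)
  groups <- setNames(rep(c("a", "b"), each = 20), ids)
  hits <- 0L
  false_hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    # signal rows: group a carries (CGG)5, group b carries (CGG)4,
    # with a little dropout noise; null row: same distribution in both
    a5 <- rbinom(20, 1, 0.95); b5 <- rbinom(20, 1, 0.05)
    null_counts <- rpois(40, 2)
    tab <- data.frame(gene = c("accC", "accC", "null"),
                      ssr = c("(CGG)5", "(CGG)4", "(A)8"),
                      stringsAsFactors = FALSE)
    carrier5 <- c(a5, b5)
    for (i in seq_along(ids))
      tab[[ids[i]]] <- c(carrier5[i], 1L - carrier5[i], null_counts[i])
    sel <- select_markers(compare_groups(tab, groups), 0.001)
    if (all(c("(CGG)5", "(CGG)4") %in% sel$ssr)) hits <- hits + 1L
    if ("(A)8" %in% sel$ssr) false_hits <- false_hits + 1L
  }
  expect_gt(hits / reps, 0.95)
  # false selections at alpha 0.001 over 40 null rows: expect ~0
  expect_lte(false_hits, 1L)
})
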