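#' Build the per-gene SSR abundance table
#'
#' Counts, for every (gene, SSR string) pair and every genome, how many
#' times that exact repeat (motif and exponent) occurs inside that gene in
#' that genome. Genomes lacking a gene or a repeat score 0, keeping the
#' matrix rectangular. This is the quantity the group comparison tests:
#' repeat-length polymorphism moves counts between rows such as
#' `("accC", "(CGG)4")` and `("accC", "(CGG)5")`.
#'
#' @param coding_tables named list: genome id -> coding-SSR data.frame
#'   (from [map_to_cds()] or [read_coding_table()]).
#' @return data.frame with columns `gene`, `ssr`, then one integer count
#'   column per genome id, rows and columns in sorted order.
#' @export
build_abundance <- function(coding_tables) {
  ids <- names(coding_tables)
  if (is.null(ids) || anyDuplicated(ids))
    stop("coding_tables must be a uniquely named list of genome tables")
  ids <- sort(ids)
  counted <- lapply(ids, function(g) {
    tab <- coding_tables[[g]]
    if (nrow(tab) == 0L) return(NULL)
    gene <- ifelse(nzchar(tab$gene), tab$gene, tab$locus_tag)
    as.data.frame(table(gene = gene, ssr = tab$ssr),
                  stringsAsFactors = FALSE)
  })
  keys <- unique(do.call(rbind, lapply(counted, function(x)
    if (is.null(x)) NULL else x[x$Freq > 0L, c("gene", "ssr")])))
  if (is.null(keys) || nrow(keys) == 0L)
    return(data.frame(gene = character(), ssr = character(),
                      stringsAsFactors = FALSE))
  keys <- keys[order(keys$gene, keys$ssr), , drop = FALSE]
  rownames(keys) <- NULL
  out <- keys
  for (i in seq_along(ids)) {
    cnt <- integer(nrow(keys))
    tab <- counted[[i]]
    if (!is.null(tab)) {
      idx <- match(paste(keys$gene, keys$ssr, sep = "\r"),
                   paste(tab$gene, tab$ssr, sep = "\r"))
      cnt[!is.na(idx)] <- tab$Freq[idx[!is.na(idx)]]
    }
    out[[ids[i]]] <- cnt
  }
  out
}

#' Write / read the abundance table
#'
#' @param abundance data.frame from [build_abundance()].
#' @param path output path (conventionally `SSR_counting.txt`).
#' @return the path, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  utils::write.table(abundance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

na_row_stats <- function() {
  list(shapiro_W = NA_real_, shapiro_p = NA_real_,
       kruskal_chi_squared = NA_real_, kruskal_p = NA_real_,
       anova_Df = NA_integer_, anova_Sum_Sq = NA_real_,
       anova_Mean_Sq = NA_real_, anova_F_value = NA_real_,
       anova_p = NA_real_, tukey = list(NULL))
}

#' Group-differential statistics per abundance row
#'
#' For every (gene, SSR) row of the abundance table, runs the marker-screen
#' battery across genome groups: Shapiro-Wilk normality on the pooled
#' counts, one-way ANOVA, tie-corrected Kruskal-Wallis, Tukey HSD pairwise
#' contrasts, and per-group count sums. Rows whose counts have zero
#' variance overall carry NA statistics rather than failing. A
#' Benjamini-Hochberg adjusted Kruskal-Wallis p-value is added as an extra
#' column; selection (see [select_markers()]) uses the raw p-value.
#'
#' @param abundance data.frame from [build_abundance()].
#' @param groups named character vector genome id -> group label (see
#'   [read_groups()]); at least two groups, each column must be labeled.
#' @return data.frame with one row per abundance row: `gene`, `ssr`,
#'   Shapiro `shapiro_W`/`shapiro_p`, Kruskal-Wallis
#'   `kruskal_chi_squared`/`kruskal_p`, ANOVA `anova_Df`, `anova_Sum_Sq`,
#'   `anova_Mean_Sq`, `anova_F_value`, `anova_p`, one `sum_<group>` column
#'   per group, `kruskal_p_BH`, and a list-column `tukey` of pairwise
#'   contrast data.frames.
#' @export
compare_groups <- function(abundance, groups) {
  genome_cols <- setdiff(colnames(abundance), c("gene", "ssr"))
  missing <- setdiff(genome_cols, names(groups))
  if (length(missing))
    stop("genome id(s) without group label: ", paste(missing, collapse = ", "))
  g <- factor(groups[genome_cols])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  small <- table(g) < 2L
  if (any(small))
    warning("group(s) with < 2 genomes: ",
            paste(names(which(small)), collapse = ", "),
            "; statistics reported as NA")
  rows <- vector("list", nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    x <- as.numeric(abundance[i, genome_cols])
    sums <- tapply(x, g, sum)
    st <- na_row_stats()
    if (stats::var(x) > 0 && !any(small)) {
      sw <- tryCatch(stats::shapiro.test(x), error = function(e) NULL)
      if (!is.null(sw)) {
        st$shapiro_W <- unname(sw$statistic)
        st$shapiro_p <- sw$p.value
      }
      kw <- stats::kruskal.test(x, g)
      st$kruskal_chi_squared <- unname(kw$statistic)
      st$kruskal_p <- kw$p.value
      fit <- stats::aov(x ~ g)
      s1 <- summary(fit)[[1L]]
      st$anova_Df <- s1[1L, "Df"]
      st$anova_Sum_Sq <- s1[1L, "Sum Sq"]
      st$anova_Mean_Sq <- s1[1L, "Mean Sq"]
      st$anova_F_value <- s1[1L, "F value"]
      st$anova_p <- s1[1L, "Pr(>F)"]
      tk <- stats::TukeyHSD(fit)$g
      st$tukey <- list(data.frame(comparison = rownames(tk),
                                  diff = tk[, "diff"], lwr = tk[, "lwr"],
                                  upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                  row.names = NULL,
                                  stringsAsFactors = FALSE))
    }
    row <- data.frame(gene = abundance$gene[i], ssr = abundance$ssr[i],
                      shapiro_W = st$shapiro_W, shapiro_p = st$shapiro_p,
                      kruskal_chi_squared = st$kruskal_chi_squared,
                      kruskal_p = st$kruskal_p, anova_Df = st$anova_Df,
                      anova_Sum_Sq = st$anova_Sum_Sq,
                      anova_Mean_Sq = st$anova_Mean_Sq,
                      anova_F_value = st$anova_F_value,
                      anova_p = st$anova_p, stringsAsFactors = FALSE)
    for (lev in levels(g)) row[[paste0("sum_", lev)]] <- unname(sums[lev])
    row$tukey <- st$tukey
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$kruskal_p_BH <- stats::p.adjust(out$kruskal_p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Select candidate marker rows
#'
#' Rows whose raw Kruskal-Wallis p-value is strictly below `alpha`
#' (default 0.001), sorted by p ascending; NA rows are excluded.
#'
#' @param stats data.frame from [compare_groups()].
#' @param alpha significance threshold.
#' @return the selected subset of `stats`.
#' @export
select_markers <- function(stats, alpha = 0.001) {
  sel <- stats[!is.na(stats$kruskal_p) & stats$kruskal_p < alpha, ,
               drop = FALSE]
  sel <- sel[order(sel$kruskal_p), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Write the statistics result files
#'
#' One TSV per test family (shapiro, kruskal, anova, tukey, group sums), a
#' combined table carrying all statistics columns, and — when the abundance
#' table is supplied — `SSR_counting.txt` alongside. NA statistics are
#' serialized as `NA`.
#'
#' @param stats data.frame from [compare_groups()].
#' @param outdir output directory (created if needed).
#' @param abundance optional abundance table to write as
#'   `SSR_counting.txt`.
#' @return named character vector of paths written, invisibly.
#' @export
write_stats_files <- function(stats, outdir, abundance = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    p <- file.path(outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  key <- stats[, c("gene", "ssr")]
  sum_cols <- grep("^sum_", colnames(stats), value = TRUE)
  paths <- c(
    shapiro = wr(cbind(key, stats[, c("shapiro_W", "shapiro_p")]),
                 "shapiro.tsv"),
    kruskal = wr(cbind(key, stats[, c("kruskal_chi_squared", "kruskal_p",
                                      "kruskal_p_BH")]), "kruskal.tsv"),
    anova = wr(cbind(key, stats[, c("anova_Df", "anova_Sum_Sq",
                                    "anova_Mean_Sq", "anova_F_value",
                                    "anova_p")]), "anova.tsv"),
    sums = wr(cbind(key, stats[, sum_cols, drop = FALSE]),
              "group_sums.tsv"))
  tk <- do.call(rbind, lapply(seq_len(nrow(stats)), function(i) {
    t <- stats$tukey[[i]]
    if (is.null(t)) return(NULL)
    cbind(gene = stats$gene[i], ssr = stats$ssr[i], t)
  }))
  if (is.null(tk))
    tk <- data.frame(gene = character(), ssr = character(),
                     comparison = character(), diff = numeric(),
                     lwr = numeric(), upr = numeric(), p_adj = numeric())
  paths["tukey"] <- wr(tk, "tukey.tsv")
  combined <- data.frame(
    SSR = stats$ssr, Gene = stats$gene, `Pr(>F)` = stats$anova_p,
    F_value = stats$anova_F_value, Mean_Sq = stats$anova_Mean_Sq,
    Sum_Sq = stats$anova_Sum_Sq, Df = stats$anova_Df, W = stats$shapiro_W,
    `P-value` = stats$shapiro_p, chi_squared = stats$kruskal_chi_squared,
    p_value = stats$kruskal_p, check.names = FALSE,
    stringsAsFactors = FALSE)
  paths["combined"] <- wr(combined, "combined_stats.tsv")
  if (!is.null(abundance))
    paths["counting"] <- wr(abundance, "SSR_counting.txt")
  invisible(paths)
}
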