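#' Is a motif primitive (no shorter internal period)?
#'
#' @param motif nucleotide string.
#' @return logical.
#' @export
is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (strrep(substr(motif, 1L, d), m %/% d) == motif) return(FALSE)
  }
  TRUE
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with planted perfect repeats
#'
#' Builds a random ACGT background, overwrites it with the requested
#' repeats, and rejection-samples the background until the naive reference
#' scan finds exactly the planted repeats — so the returned truth list is
#' exhaustive: mining the genome under `params` must recover it exactly,
#' with no accidental extras.
#'
#' @param seed integer seed; the genome is deterministic given the seed.
#' @param length genome length in bp.
#' @param plants data.frame with columns `motif` (primitive), `exponent`
#'   (>= 2) and `position` (1-based insertion point); optional `gene_name`.
#'   Plants must not overlap and must be separated by more than
#'   `interval + longest motif` so the expected mining output is
#'   unambiguous.
#' @param params the `mining_params` the genome is certified against.
#' @param seq_id identifier for the genome.
#' @param max_tries rejection-sampling budget.
#' @return list with `record` (data.frame: `seq_id`, `sequence`,
#'   `source_file = NA`) and `truth` (perfect-SSR data.frame of the
#'   planted repeats, sorted).
#' @export
synth_genome <- function(seed, length, plants, params, seq_id = NULL,
                         max_tries = 300L) {
  if (is.null(seq_id)) seq_id <- paste0("synth_", seed)
  if (nrow(plants) > 0L) {
    if (!all(vapply(plants$motif, is_primitive_motif, logical(1))))
      stop("all planted motifs must be primitive")
    if (any(plants$exponent < 2L)) stop("planted exponents must be >= 2")
    plants <- plants[order(plants$position), , drop = FALSE]
    p_end <- plants$position + nchar(plants$motif) * plants$exponent - 1L
    if (any(p_end > length) || any(plants$position < 1L))
      stop("infeasible plant layout: plant outside genome")
    if (nrow(plants) > 1L) {
      sep <- plants$position[-1L] - p_end[-nrow(plants)]
      if (any(sep <= params$interval + max(nchar(plants$motif))))
        stop("infeasible plant layout: plants too close")
    }
  }
  truth <- if (nrow(plants) == 0L) empty_ssr_frame() else data.frame(
    seq_id = seq_id, motif = plants$motif, m = nchar(plants$motif),
    exponent = as.integer(plants$exponent),
    start = as.integer(plants$position),
    end = as.integer(plants$position +
                       nchar(plants$motif) * plants$exponent - 1L),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    chars <- strsplit(random_dna(length), "", fixed = TRUE)[[1L]]
    for (i in seq_len(nrow(plants))) {
      rep_chars <- strsplit(strrep(plants$motif[i], plants$exponent[i]),
                            "", fixed = TRUE)[[1L]]
      chars[plants$position[i] + seq_along(rep_chars) - 1L] <- rep_chars
    }
    sequence <- paste(chars, collapse = "")
    found <- naive_repeat_scan(sequence, params, seq_id)
    if (identical(found[, colnames(truth)], truth))
      return(list(record = data.frame(seq_id = seq_id, sequence = sequence,
                                      source_file = NA_character_,
                                      stringsAsFactors = FALSE),
                  truth = truth))
  }
  stop("infeasible plant layout: no clean background in ", max_tries,
       " tries")
}

#' Write a minimal GenBank flat file
#'
#' Writes LOCUS/VERSION headers, CDS features with gene, locus_tag and
#' product qualifiers, and the ORIGIN sequence block. The output is a
#' valid GenBank flat file readable by [read_genbank()] (and by standard
#' GenBank parsers).
#'
#' @param record data.frame row with `seq_id` and `sequence`.
#' @param features CDS data.frame (`gene`, `locus_tag`, `product`,
#'   `strand`, `start`, `end`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, features, path) {
  n <- nchar(record$sequence)
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2026",
            record$seq_id, n),
    "DEFINITION  synthetic genome with planted repeats.",
    sprintf("ACCESSION   %s", sub("\\.[0-9]+$", "", record$seq_id)),
    sprintf("VERSION     %s", record$seq_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  for (i in seq_len(nrow(features))) {
    loc <- sprintf("%d..%d", features$start[i], features$end[i])
    if (features$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf("                     /gene=\"%s\"", features$gene[i]),
               sprintf("                     /locus_tag=\"%s\"",
                       features$locus_tag[i]),
               sprintf("                     /product=\"%s\"",
                       features$product[i]))
  }
  lines <- c(lines, "ORIGIN")
  seq_lc <- tolower(record$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(seq_lc, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Generate a two-group synthetic genome cohort
#'
#' Emulates a marker-discovery cohort: every genome carries the same gene
#' set, each gene's CDS containing one planted repeat. Genes listed in
#' `diff_spec` carry a different exponent in each group (repeat-length
#' polymorphism, e.g. (CGG)4 in one group vs (CGG)5 in the other); genes
#' in `gene_templates` carry a fixed exponent, or — when `jitter` is set —
#' an exponent drawn iid from {exponent, exponent + 1} regardless of
#' group, providing null rows with variance. Backgrounds are
#' rejection-sampled per genome so the cohort's expected mining output is
#' exactly the planted truth. Genomes are written as minimal GenBank flat
#' files.
#'
#' @param seed integer seed.
#' @param n_per_group genomes per group (>= 2).
#' @param gene_templates data.frame: `gene`, `motif`, `exponent`, optional
#'   logical `jitter`.
#' @param diff_spec data.frame: `gene`, `motif`, `exp_group1`,
#'   `exp_group2` (may have zero rows).
#' @param dir output directory for the GenBank files (created).
#' @param params the `mining_params` the cohort is certified against.
#' @param absent_gene optional gene name omitted from a fraction of
#'   group-1 genomes.
#' @param absent_frac fraction of group-1 genomes lacking `absent_gene`.
#' @return list with `dir`, `files`, `groups` (named vector genome id ->
#'   `"group1"`/`"group2"`) and `truth_markers` (data.frame `gene`, `ssr`
#'   of the rows a group-differential screen must select).
#' @export
synth_cohort <- function(seed, n_per_group, gene_templates, diff_spec, dir,
                         params, absent_gene = NULL, absent_frac = 0) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (is.null(gene_templates$jitter)) gene_templates$jitter <- FALSE
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  ids <- c(sprintf("SYN_K%02d.1", seq_len(n_per_group)),
           sprintf("SYN_O%02d.1", seq_len(n_per_group)))
  grp <- rep(c("group1", "group2"), each = n_per_group)
  genes <- c(gene_templates$gene, diff_spec$gene)
  absent_in <- character(0)
  if (!is.null(absent_gene) && absent_frac > 0) {
    g1 <- ids[grp == "group1"]
    absent_in <- g1[seq_len(max(1L, floor(absent_frac * n_per_group)))]
  }
  files <- character(length(ids))
  for (i in seq_along(ids)) {
    my_genes <- setdiff(genes, if (ids[i] %in% absent_in) absent_gene else
      character(0))
    motifs <- exps <- stats::setNames(vector("list", length(my_genes)),
                                      my_genes)
    for (g in my_genes) {
      if (g %in% diff_spec$gene) {
        k <- match(g, diff_spec$gene)
        motifs[[g]] <- diff_spec$motif[k]
        exps[[g]] <- if (grp[i] == "group1") diff_spec$exp_group1[k] else
          diff_spec$exp_group2[k]
      } else {
        k <- match(g, gene_templates$gene)
        motifs[[g]] <- gene_templates$motif[k]
        e <- gene_templates$exponent[k]
        exps[[g]] <- if (gene_templates$jitter[k]) e + sample(0:1, 1L) else e
      }
    }
    # gene layout: fixed spacing, repeat planted 31 bp into each CDS
    pos <- 151L
    plants <- feats <- list()
    for (g in my_genes) {
      ssr_len <- nchar(motifs[[g]]) * exps[[g]]
      cds_len <- 3L * ((ssr_len + 90L) %/% 3L)
      feats[[g]] <- data.frame(
        gene = g, locus_tag = paste0("LT_", g),
        product = "hypothetical protein",
        strand = if (match(g, my_genes) %% 2L) "+" else "-",
        start = pos, end = pos + cds_len - 1L, stringsAsFactors = FALSE)
      plants[[g]] <- data.frame(motif = motifs[[g]], exponent = exps[[g]],
                                position = pos + 30L,
                                stringsAsFactors = FALSE)
      pos <- pos + cds_len + 150L
    }
    glen <- pos + 100L
    genome <- synth_genome(seed = sample.int(2^30, 1L), length = glen,
                           plants = do.call(rbind, plants), params = params,
                           seq_id = ids[i])
    files[i] <- file.path(dir, paste0(sub("\\.1$", "", ids[i]), ".gb"))
    write_genbank(genome$record, do.call(rbind, feats), files[i])
  }
  truth <- if (nrow(diff_spec) == 0L)
    data.frame(gene = character(), ssr = character(),
               stringsAsFactors = FALSE)
  else
    data.frame(
      gene = rep(diff_spec$gene, 2L),
      ssr = c(sprintf("(%s)%d", diff_spec$motif, diff_spec$exp_group1),
              sprintf("(%s)%d", diff_spec$motif, diff_spec$exp_group2)),
      stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene, truth$ssr), , drop = FALSE]
  rownames(truth) <- NULL
  list(dir = dir, files = files, groups = stats::setNames(grp, ids),
       truth_markers = truth)
}
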