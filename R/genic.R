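#' Map perfect SSRs to the CDS features that contain them
#'
#' Emits one row per (SSR, CDS) pair where the repeat is fully contained in
#' the feature's `[start, end]` — containment, not mere overlap, so repeats
#' straddling a gene boundary (ambiguous for marker design) are excluded.
#' Coordinates and motif stay in genome forward orientation; the CDS strand
#' is carried as a column.
#'
#' @param ssrs data.frame of perfect SSRs (from [mine_sequence()]).
#' @param features CDS data.frame (from [read_genbank()]), same sequence.
#' @return data.frame of coding SSRs: all SSR columns plus `ssr` (the
#'   `(MOTIF)E` string), `gene`, `locus_tag`, `product`, `strand`.
#' @export
map_to_cds <- function(ssrs, features) {
  empty <- cbind(empty_ssr_frame(),
                 data.frame(ssr = character(), gene = character(),
                            locus_tag = character(), product = character(),
                            strand = character(), stringsAsFactors = FALSE))
  if (nrow(ssrs) == 0L || nrow(features) == 0L) return(empty)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(ssrs$start, ssrs$end),
    IRanges::IRanges(features$start, features$end),
    type = "within")
  if (length(hits) == 0L) return(empty)
  si <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  out <- ssrs[si, , drop = FALSE]
  out$ssr <- sprintf("(%s)%d", out$motif, out$exponent)
  out$gene <- features$gene[fi]
  out$locus_tag <- features$locus_tag[fi]
  out$product <- features$product[fi]
  out$strand <- features$strand[fi]
  rownames(out) <- NULL
  out
}

#' Write the coding-SSR table
#'
#' Column layout: Start, End, SSR, Gene, Strand, Synonym (the locus_tag),
#' Product, ID (the genome accession).
#'
#' @param coding data.frame from [map_to_cds()].
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_coding_table <- function(coding, path) {
  tab <- data.frame(Start = coding$start, End = coding$end, SSR = coding$ssr,
                    Gene = coding$gene, Strand = coding$strand,
                    Synonym = coding$locus_tag, Product = coding$product,
                    ID = coding$seq_id, stringsAsFactors = FALSE,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read back a coding-SSR table
#'
#' @param path TSV written by [write_coding_table()].
#' @return data.frame in the internal coding-SSR layout (lower-case column
#'   names, motif/exponent recovered from the SSR string).
#' @export
read_coding_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  motif <- sub("^\\(([^)]*)\\)[0-9]+$", "\\1", tab$SSR)
  data.frame(seq_id = tab$ID, motif = motif, m = nchar(motif),
             exponent = as.integer(sub("^\\([^)]*\\)", "", tab$SSR)),
             start = as.integer(tab$Start), end = as.integer(tab$End),
             ssr = tab$SSR, gene = tab$Gene, locus_tag = tab$Synonym,
             product = tab$Product, strand = tab$Strand,
             stringsAsFactors = FALSE)
}

genbank_files <- function(folder) {
  sort(list.files(folder, pattern = "\\.(gb|gbk|gbff)$", ignore.case = TRUE,
                  full.names = TRUE))
}

#' Extract flanking regions of selected coding SSRs across genomes
#'
#' Re-mines every GenBank genome in a folder, locates each selected
#' (gene, SSR string) pair among its coding SSRs, and extracts the repeat
#' with `flank` bp of context on each side (clipped to chromosome bounds),
#' ready for primer design. Genomes lacking a selected gene are skipped
#' with a logged notice.
#'
#' @param folder directory of GenBank flat files.
#' @param selected data.frame with columns `gene` and `ssr` (e.g.
#'   `"(CGG)5"`).
#' @param params a `mining_params` object used to re-mine each genome.
#' @param flank non-negative flank length in bp (default 200).
#' @param path optional multi-FASTA output path.
#' @return data.frame of extracted entries (`genome`, `gene`, `ssr`,
#'   `start`, `end`, `header`, `sequence`); written as multi-FASTA when
#'   `path` is given.
#' @export
extract_flanks <- function(folder, selected, params, flank = 200L,
                           path = NULL) {
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) stop("flank must be >= 0")
  files <- genbank_files(folder)
  if (length(files) == 0L) stop("no GenBank files in ", folder)
  entries <- list()
  for (f in files) {
    gb <- read_genbank(f)
    mined <- mine_sequence(gb$record$seq_id, gb$record$sequence, params)
    coding <- map_to_cds(mined$perfect, gb$features)
    for (k in seq_len(nrow(selected))) {
      hit <- coding[coding$gene == selected$gene[k] &
                      coding$ssr == selected$ssr[k], , drop = FALSE]
      if (!selected$gene[k] %in% gb$features$gene) {
        message("gene ", selected$gene[k], " absent from ",
                gb$record$seq_id, "; skipped")
        next
      }
      for (r in seq_len(nrow(hit))) {
        a <- max(1L, hit$start[r] - flank)
        b <- min(nchar(gb$record$sequence), hit$end[r] + flank)
        entries[[length(entries) + 1L]] <- data.frame(
          genome = gb$record$seq_id, gene = selected$gene[k],
          ssr = selected$ssr[k], start = a, end = b,
          header = sprintf("%s|%s|%s|%d-%d", gb$record$seq_id,
                           selected$gene[k], selected$ssr[k], a, b),
          sequence = substr(gb$record$sequence, a, b),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(entries)) do.call(rbind, entries) else
    data.frame(genome = character(), gene = character(), ssr = character(),
               start = integer(), end = integer(), header = character(),
               sequence = character(), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    set <- Biostrings::BStringSet(stats::setNames(out$sequence, out$header))
    Biostrings::writeXStringSet(set, path, width = 70L)
  }
  out
}
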