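#' Read a FASTA file
#'
#' Reads a single- or multi-record FASTA file. The sequence identifier is
#' the first whitespace-delimited token of the header; sequences are
#' uppercased on ingest.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `seq_id`, `sequence`, `source_file`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) stop("not a FASTA file (no '>' header): ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("FASTA record with empty identifier in ", path)
  data.frame(seq_id = ids, sequence = toupper(as.character(set)),
             source_file = path, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read every FASTA file in a folder
#'
#' Reads all files with extension `.fa`, `.fasta` or `.fna` in a folder, in
#' lexicographic file order.
#'
#' @param folder directory path.
#' @return named list (file name -> record data.frame as in [read_fasta()]).
#' @export
read_fasta_batch <- function(folder) {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- sort(list.files(folder, pattern = "\\.(fa|fasta|fna)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    warning("no FASTA files (.fa/.fasta/.fna) in ", folder)
    return(list())
  }
  stats::setNames(lapply(files, read_fasta), basename(files))
}

parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  joined <- grepl("join|order", loc)
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (length(nums) == 0L) return(NULL)
  list(start = as.integer(min(nums)), end = as.integer(max(nums)),
       strand = strand, joined = joined)
}

#' Read a GenBank flat file
#'
#' Minimal parser for GenBank flat files: extracts the versioned accession,
#' the ORIGIN sequence, and every CDS feature with its gene, locus_tag,
#' product and strand. Joined (multi-interval) locations are reduced to
#' their envelope `[min, max]` and flagged in the `joined` column — adequate
#' for the prokaryotic genomes this tool targets.
#'
#' @param path path to a GenBank flat file.
#' @return list with `record` (data.frame: `seq_id`, `sequence`,
#'   `source_file`) and `features` (data.frame: `gene`, `locus_tag`,
#'   `product`, `strand`, `start`, `end`, `seq_id`, `joined`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ver <- grep("^VERSION", lines, value = TRUE)
  seq_id <- if (length(ver)) strsplit(trimws(sub("^VERSION", "", ver[1L])),
                                      "\\s+")[[1L]][1L] else NA_character_
  if (is.na(seq_id) || !nzchar(seq_id)) {
    loc <- grep("^LOCUS", lines, value = TRUE)
    if (!length(loc)) stop("no LOCUS/VERSION line in ", path)
    seq_id <- strsplit(trimws(sub("^LOCUS", "", loc[1L])), "\\s+")[[1L]][1L]
  }
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("no ORIGIN section in ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("empty ORIGIN sequence in ", path)

  # feature table: entries start with a key at column 6; qualifier lines
  # are continuations at column 22
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    key_idx <- grep("^ {5}\\S", block)
    for (ki in seq_along(key_idx)) {
      from <- key_idx[ki]
      to <- if (ki < length(key_idx)) key_idx[ki + 1L] - 1L else length(block)
      key <- sub("^ {5}(\\S+).*$", "\\1", block[from])
      if (key != "CDS") next
      body <- trimws(block[from:to])
      body[1L] <- trimws(sub("^\\S+", "", body[1L]))
      # location may continue until the first qualifier line
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
      loc <- parse_gb_location(paste(body[seq_len(loc_end)], collapse = ""))
      if (is.null(loc)) next
      # fold wrapped qualifier values onto their /qualifier line
      quals <- character(0)
      cur <- ""
      for (ln in body[-seq_len(loc_end)]) {
        if (startsWith(ln, "/")) {
          if (nzchar(cur)) quals <- c(quals, cur)
          cur <- ln
        } else cur <- paste(cur, ln)
      }
      if (nzchar(cur)) quals <- c(quals, cur)
      getq <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return("")
        gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1L]))
      }
      feats[[length(feats) + 1L]] <- data.frame(
        gene = getq("gene"), locus_tag = getq("locus_tag"),
        product = getq("product"), strand = loc$strand,
        start = loc$start, end = loc$end, seq_id = seq_id,
        joined = loc$joined, stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(gene = character(), locus_tag = character(),
               product = character(), strand = character(),
               start = integer(), end = integer(), seq_id = character(),
               joined = logical(), stringsAsFactors = FALSE)
  list(record = data.frame(seq_id = seq_id, sequence = sequence,
                           source_file = path, stringsAsFactors = FALSE),
       features = features)
}

#' Read a mining parameters file
#'
#' Parses the parameters dialect: one `m:minExponent` pair per line (e.g.
#' `2:5` requires at least 5 copies of any 2-bp motif), an optional
#' `int:<gap>` line setting the compound-merge gap threshold (default 10),
#' `#` comments and blank lines ignored.
#'
#' @param path path to the parameters file.
#' @return a `mining_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  thresholds <- integer(0)
  interval <- 10L
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed parameters line: '", ln, "'")
    key <- trimws(parts[1L]); val <- suppressWarnings(as.integer(trimws(parts[2L])))
    if (is.na(val)) stop("malformed parameters line: '", ln, "'")
    if (tolower(key) == "int") {
      interval <- val
    } else {
      m <- suppressWarnings(as.integer(key))
      if (is.na(m)) stop("malformed parameters line: '", ln, "'")
      if (as.character(m) %in% names(thresholds))
        stop("duplicate motif length ", m, " in ", path)
      thresholds[as.character(m)] <- val
    }
  }
  mining_params(thresholds, interval)
}

ssr_table_columns <- c("ID", "SSR nr.", "SSR type", "SSR", "size", "start", "end")

tracts_to_table <- function(tracts) {
  if (length(tracts) == 0L)
    return(stats::setNames(
      data.frame(character(), integer(), character(), character(), integer(),
                 integer(), integer(), stringsAsFactors = FALSE),
      ssr_table_columns))
  rows <- lapply(tracts, function(t)
    data.frame(ID = t$seq_id, type = t$type, SSR = render_ssr_string(t),
               size = t$end - t$start + 1L, start = t$start, end = t$end,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  nr <- stats::ave(seq_len(nrow(out)), out$ID, FUN = seq_along)
  out <- data.frame(out$ID, as.integer(nr), out$type, out$SSR, out$size,
                    out$start, out$end, stringsAsFactors = FALSE)
  stats::setNames(out, ssr_table_columns)
}

#' Write the SSR result table
#'
#' Writes one row per tract in a MISA-style layout: sequence ID, per-
#' sequence SSR number, SSR type (`p1`..`pN` for perfect tracts by motif
#' length, `c` for compound), the SSR string, tract size and 1-based
#' start/end.
#'
#' @param tracts an `ssr_tracts` object (tracts from several sequences may
#'   be concatenated).
#' @param path output TSV path.
#' @return the written data.frame, invisibly.
#' @export
write_ssr_table <- function(tracts, path) {
  tab <- tracts_to_table(tracts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read back an SSR result table
#'
#' @param path TSV written by [write_ssr_table()].
#' @return data.frame with the table's columns.
#' @export
read_ssr_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write GenBank sidecar files
#'
#' For a parsed GenBank record, writes the genome sequence as FASTA and the
#' CDS features as a protein table TSV (gene, locus_tag, product, strand,
#' start, end).
#'
#' @param record,features as returned by [read_genbank()].
#' @param outdir output directory (created if needed).
#' @return character vector of the two paths written, invisibly.
#' @export
write_genbank_sidecars <- function(record, features, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(outdir, paste0(record$seq_id, ".fasta"))
  set <- Biostrings::BStringSet(stats::setNames(record$sequence, record$seq_id))
  Biostrings::writeXStringSet(set, fasta, width = 70L)
  prot <- file.path(outdir, paste0(record$seq_id, "_protein_table.tsv"))
  utils::write.table(
    features[, c("gene", "locus_tag", "product", "strand", "start", "end")],
    prot, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, protein_table = prot))
}

#' Read a genome-to-group mapping file
#'
#' Two-column TSV (no header requirement: a header line `genome<TAB>group`
#' is tolerated) mapping genome identifier to group label.
#'
#' @param path TSV path.
#' @return named character vector: genome id -> group label.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group file must have two tab-separated columns")
  if (tolower(tab[1L, 1L]) %in% c("genome", "genome_id", "id") ||
      tolower(tab[1L, 2L]) == "group")
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}
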