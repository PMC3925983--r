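#' Read sample sequences from FASTA or GenBank flat files
#'
#' FASTA parsing is delegated to Biostrings; GenBank flat files (LOCUS /
#' ACCESSION / ORIGIN) are read by a minimal built-in reader. Sequences
#' are normalised (uppercased, whitespace stripped) and any non-ACGT
#' character is rejected with its position. Sample source (blood or
#' germline) is inferred from the record id when it contains "blood" or
#' "germline".
#'
#' @param path Path to a FASTA (possibly multi-record) or GenBank flat
#'   file.
#' @return Data frame of class `sample_records` with columns `id`,
#'   `source`, `accession`, `sequence`.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- ""
  lines_peek <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- lines_peek[nzchar(trimws(lines_peek))]
  if (length(nonblank) == 0L) stop("empty file: ", path, call. = FALSE)
  first <- nonblank[1L]
  if (startsWith(first, "LOCUS")) return(read_genbank(path))
  if (!startsWith(first, ">")) {
    lineno <- which(nzchar(trimws(lines_peek)))[1L]
    stop("parse error in ", path, " at line ", lineno,
         ": expected FASTA header '>' or GenBank LOCUS", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path, call. = FALSE)
  seqs <- vapply(seq_along(set), function(i)
    normalize_sequence(as.character(set[[i]]), what = ids[i]), character(1))
  make_sample_records(ids, seqs)
}

make_sample_records <- function(ids, seqs, accession = NA_character_) {
  src <- rep(NA_character_, length(ids))
  src[grepl("germline", ids, ignore.case = TRUE)] <- "germline"
  src[grepl("blood", ids, ignore.case = TRUE)] <- "blood"
  out <- data.frame(id = ids, source = src,
                    accession = rep(accession, length.out = length(ids)),
                    sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("sample_records", "data.frame")
  out
}

# Minimal GenBank flat-file reader: one or more LOCUS..// entries; only
# LOCUS name, ACCESSION and the ORIGIN sequence block are used.
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "LOCUS"))
  if (length(starts) == 0L)
    stop("parse error in ", path, " at line 1: no LOCUS record", call. = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) < length(starts))
    stop("parse error in ", path, ": unterminated GenBank record (missing //)",
         call. = FALSE)
  ids <- character(0); accs <- character(0); seqs <- character(0)
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- ends[ends > from][1L]
    block <- lines[from:to]
    id <- strsplit(trimws(block[1L]), "[[:space:]]+")[[1L]][2L]
    acc_line <- grep("^ACCESSION", block, value = TRUE)
    acc <- if (length(acc_line))
      strsplit(trimws(acc_line[1L]), "[[:space:]]+")[[1L]][2L] else NA_character_
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0L)
      stop("parse error in ", path, " at line ", from,
           ": record has no ORIGIN block", call. = FALSE)
    seq_lines <- block[(ori[1L] + 1L):(length(block) - 1L)]
    seq_raw <- gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = ""))
    ids <- c(ids, id)
    accs <- c(accs, acc)
    seqs <- c(seqs, normalize_sequence(seq_raw, what = id))
  }
  make_sample_records(ids, seqs, accession = accs)
}

#' Write sequences to FASTA
#'
#' @param records A `sample_records` data frame (or a named character
#'   vector of sequences).
#' @param path Output path; lines wrapped at 70 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    stopifnot(!is.null(names(records)))
    seqs <- records
  } else {
    seqs <- setNames(records$sequence, records$id)
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Fetch a GenBank accession, with an offline cache
#'
#' Network access is strictly opt-in. With `allow_network = FALSE` (the
#' default) only the cache is consulted; a cache miss is an explicit
#' error telling the user where to place the flat file by hand.
#'
#' @param id Accession (e.g. `"KF941192"`; 1-2 letters then 5-8 digits,
#'   optionally `.version`).
#' @param cache_dir Directory holding `<id>.gb` flat files.
#' @param allow_network If `TRUE`, download and cache on a miss.
#' @return A one-row `sample_records` data frame.
#' @export
fetch_accession <- function(id, cache_dir = file.path(tempdir(), "dyz1kit-cache"),
                            allow_network = FALSE) {
  if (!grepl("^[A-Za-z]{1,2}[0-9]{5,8}(\\.[0-9]+)?$", id))
    stop("not a valid nucleotide accession: '", id, "'", call. = FALSE)
  id <- toupper(id)
  cache_file <- file.path(cache_dir, paste0(id, ".gb"))
  if (!file.exists(cache_file)) {
    if (!allow_network)
      stop("offline and no cached record for ", id,
           "; place a GenBank flat file at ", cache_file,
           " or call with allow_network = TRUE", call. = FALSE)
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                  "?db=nuccore&rettype=gb&retmode=text&id=", id)
    download.file(url, cache_file, quiet = TRUE, mode = "wb")
  }
  rec <- read_genbank(cache_file)
  if (nrow(rec) != 1L)
    stop("cached file for ", id, " does not contain exactly one record",
         call. = FALSE)
  rec
}

profile_table_frame <- function(profiles) {
  base <- data.frame(row = profile_row_labels(), stringsAsFactors = FALSE)
  for (s in names(profiles)) base[[s]] <- profile_row_values(profiles[[s]])
  base
}

#' Render deterministic report files for a run
#'
#' Writes TSV tables (profile table in the canonical row order, site
#' frequency table, variant blocks) and a JSON report carrying
#' copy-number results, the run configuration and the package version.
#' Output is byte-identical across runs on the same inputs; no
#' timestamps are embedded. Missing result sections yield header-only
#' tables.
#'
#' @param results Named list; recognised elements: `profiles` (named
#'   list of `dyz1_profile`), `site_frequency` (a
#'   [frequency_table()] result), `comparisons` (named list of
#'   `comparison_report`), `standard_curve`, `quantifications` (named
#'   list of `quant_result`).
#' @param out_dir Output directory (created if needed).
#' @param config Arbitrary run configuration, embedded verbatim in the
#'   JSON report for provenance.
#' @return Character vector of the files written, invisibly.
#' @export
render_reports <- function(results, out_dir, config = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  written <- character(0)
  tsv <- function(df, name) {
    f <- file.path(out_dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
  }

  profs <- results$profiles
  tsv(if (length(profs)) profile_table_frame(profs)
      else data.frame(row = character(0)), "profiles.tsv")

  freq <- results$site_frequency
  tsv(if (!is.null(freq)) as.data.frame(freq)
      else data.frame(name = character(0), recognition = character(0),
                      overhang = character(0)), "site_frequency.tsv")

  comps <- results$comparisons
  if (length(comps)) {
    blocks <- do.call(rbind, lapply(names(comps), function(nm) {
      bl <- comps[[nm]]$blocks
      if (nrow(bl) == 0L) return(NULL)
      cbind(comparison = nm, bl)
    }))
    if (is.null(blocks))
      blocks <- data.frame(comparison = character(0), kind = character(0),
                           ref_start = integer(0), ref_end = integer(0),
                           length = integer(0), alt_sequence = character(0))
  } else {
    blocks <- data.frame(comparison = character(0), kind = character(0),
                         ref_start = integer(0), ref_end = integer(0),
                         length = integer(0), alt_sequence = character(0))
  }
  tsv(blocks, "variant_blocks.tsv")

  report <- list(
    tool = list(package = "dyz1kit",
                version = as.character(packageVersion("dyz1kit"))),
    config = config,
    comparisons = lapply(comps, function(cp)
      list(net_length_difference = cp$net_length_difference,
           substitution_count = cp$substitution_count)),
    standard_curve = if (!is.null(results$standard_curve)) {
      sc <- results$standard_curve
      list(slope = sc$slope, intercept = sc$intercept,
           r_squared = sc$r_squared, efficiency = sc$efficiency)
    },
    quantifications = lapply(results$quantifications, function(q)
      list(estimated_copies = q$estimated_copies,
           replicate_spread = q$replicate_spread))
  )
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, f)
  invisible(written)
}
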