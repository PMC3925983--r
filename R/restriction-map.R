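IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Does a base satisfy an IUPAC degeneracy code?
#'
#' @param code Single IUPAC DNA code (A, C, G, T, N, R, Y, W, S, K, M,
#'   B, D, H, V); vectorised.
#' @param base Single base A/C/G/T; vectorised (recycled against `code`).
#' @return Logical: `TRUE` iff the base is in the code's degeneracy set.
#' @examples
#' iupac_match("R", "G")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' @export
iupac_match <- function(code, base) {
  code <- toupper(code); base <- toupper(base)
  if (any(!code %in% names(IUPAC_SETS)))
    stop("unknown IUPAC code: ",
         paste(unique(code[!code %in% names(IUPAC_SETS)]), collapse = ","),
         call. = FALSE)
  if (any(!base %in% c("A", "C", "G", "T")))
    stop("base must be one of A, C, G, T", call. = FALSE)
  mapply(function(cd, b) b %in% IUPAC_SETS[[cd]], code, base,
         USE.NAMES = FALSE)
}

#' Construct a restriction enzyme record
#'
#' @param name Enzyme name (unique within a panel).
#' @param recognition Recognition motif over the IUPAC DNA alphabet.
#' @param overhang Cut-end chemistry: `"5'"`, `"3'"` or `"blunt"`
#'   (metadata only; the package does not model cut offsets).
#' @return One-row data frame of class `enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, overhang = "blunt") {
  recognition <- toupper(recognition)
  if (nchar(recognition) == 0L ||
      any(!strsplit(recognition, "")[[1]] %in% names(IUPAC_SETS)))
    stop("recognition must be a non-empty IUPAC DNA string", call. = FALSE)
  if (!overhang %in% c("5'", "3'", "blunt"))
    stop("overhang must be \"5'\", \"3'\" or \"blunt\"", call. = FALSE)
  structure(data.frame(name = name, recognition = recognition,
                       overhang = overhang, stringsAsFactors = FALSE),
            class = c("enzyme", "data.frame"))
}

#' Built-in DYZ1 restriction-enzyme panel
#'
#' The panel of enzymes whose sites occur in sequenced 3.56 kb DYZ1
#' array units, shipped as a TSV (name, recognition, overhang). It is
#' the union of the two published per-sample site-frequency tables for
#' the twin blood and blood/germline comparisons (66 distinct enzymes).
#'
#' @param path Optional path to an alternative panel TSV.
#' @return Data frame of class `enzyme_panel` with columns `name`,
#'   `recognition`, `overhang`, in panel order.
#' @export
enzyme_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzyme_panel.tsv",
                        package = "dyz1kit", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "overhang") %in% names(tab)))
  if (anyDuplicated(tab$name))
    stop("enzyme panel names must be unique", call. = FALSE)
  for (i in seq_len(nrow(tab)))
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$overhang[i])
  class(tab) <- c("enzyme_panel", "data.frame")
  tab
}

as_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L)
    return(restriction_enzyme(enzyme, enzyme))
  if (is.data.frame(enzyme) && nrow(enzyme) == 1L &&
      all(c("name", "recognition") %in% names(enzyme)))
    return(enzyme)
  stop("enzyme must be a recognition string or a one-row enzyme record",
       call. = FALSE)
}

#' Scan a sequence for (degenerate) recognition-site matches
#'
#' Every start position whose window satisfies the IUPAC motif at all
#' offsets is reported. Overlapping matches are kept by default, since
#' site counts are motif statistics rather than cut simulations; with
#' `allow_overlaps = FALSE` a leftmost-greedy non-overlapping subset is
#' returned. In `"both"` mode the reverse-complement motif is also
#' scanned (reported on strand `-`); for self-reverse-complementary
#' motifs the reverse scan is redundant and skipped, and reverse hits
#' on self-reverse-complementary windows are deduplicated.
#'
#' @param sequence DNA string (ACGT).
#' @param enzyme A recognition string or an enzyme record
#'   ([restriction_enzyme()] / one row of [enzyme_panel()]).
#' @param strand_mode `"forward"` (default) or `"both"`.
#' @param allow_overlaps Keep overlapping hits (default `TRUE`).
#' @return Data frame of class `site_hits` with columns `start`
#'   (1-based), `strand` and `matched` (the matched window, forward
#'   strand of the subject).
#' @export
scan_sites <- function(sequence, enzyme,
                       strand_mode = c("forward", "both"),
                       allow_overlaps = TRUE) {
  strand_mode <- match.arg(strand_mode)
  sequence <- normalize_sequence(sequence)
  enzyme <- as_enzyme(enzyme)
  recog <- toupper(enzyme$recognition)
  subject <- Biostrings::DNAString(sequence)

  scan_one <- function(pat) {
    if (nchar(pat) > nchar(sequence))
      return(data.frame(start = integer(0), matched = character(0)))
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = "subject")
    data.frame(start = Biostrings::start(m),
               matched = as.character(m),
               stringsAsFactors = FALSE)
  }

  fwd <- scan_one(recog)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (strand_mode == "both") {
    rc <- reverse_complement(recog)
    if (rc != recog) {
      rev <- scan_one(rc)
      rev$strand <- rep("-", nrow(rev))
      if (nrow(rev) > 0L) {
        dup <- rev$start %in% fwd$start &
          vapply(rev$matched, function(w) reverse_complement(w) == w,
                 logical(1))
        rev <- rev[!dup, , drop = FALSE]
      }
      hits <- rbind(hits, rev)
    }
  }
  hits <- hits[order(hits$start, hits$strand), c("start", "strand", "matched")]
  rownames(hits) <- NULL
  if (!allow_overlaps && nrow(hits) > 1L) {
    keep <- logical(nrow(hits))
    last_end <- 0L
    w <- nchar(recog)
    for (i in seq_len(nrow(hits))) {
      if (hits$start[i] > last_end) {
        keep[i] <- TRUE
        last_end <- hits$start[i] + w - 1L
      }
    }
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
  }
  class(hits) <- c("site_hits", "data.frame")
  hits
}

#' Site-frequency table over a panel of enzymes
#'
#' @param samples Named character vector (or named list) of ACGT
#'   sequences, one per sample.
#' @param panel An [enzyme_panel()] (default: the built-in DYZ1 panel).
#' @param strand_mode Passed to [scan_sites()]; default `"forward"`.
#' @return Data frame of class `site_frequency_table`: panel columns
#'   `name`, `recognition`, `overhang` followed by one count column per
#'   sample, rows in panel order.
#' @export
frequency_table <- function(samples, panel = enzyme_panel(),
                            strand_mode = "forward") {
  samples <- unlist(samples)
  if (length(samples) < 1L || is.null(names(samples)) ||
      any(names(samples) == ""))
    stop("samples must be a named vector of at least one sequence",
         call. = FALSE)
  out <- panel
  for (s in names(samples)) {
    seq_s <- normalize_sequence(samples[[s]], what = s)
    out[[s]] <- vapply(seq_len(nrow(panel)), function(i) {
      nrow(scan_sites(seq_s, panel[i, ], strand_mode = strand_mode))
    }, integer(1))
  }
  class(out) <- c("site_frequency_table", "data.frame")
  out
}

#' Extract one sample's count column from a site-frequency table
#'
#' @param table A [frequency_table()] result.
#' @param sample Sample (column) name.
#' @return Named integer vector of counts (names = enzyme names).
#' @export
frequency_column <- function(table, sample) {
  stopifnot(inherits(table, "site_frequency_table"))
  if (!sample %in% names(table))
    stop("no sample column '", sample, "' in table", call. = FALSE)
  setNames(table[[sample]], table$name)
}

#' Loss/gain report between two site-count columns
#'
#' @param a,b Named count vectors over the same enzyme panel (see
#'   [frequency_column()]).
#' @return Data frame of class `loss_gain_report` containing exactly the
#'   enzymes with unequal counts: columns `enzyme`, `a`, `b`,
#'   `difference` (b - a; negative = sites lost in b relative to a).
#' @export
diff_frequency <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)) || !identical(names(a), names(b)))
    stop("panel mismatch: a and b must share the same enzyme names in the same order",
         call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("counts must be >= 0", call. = FALSE)
  changed <- which(a != b)
  out <- data.frame(enzyme = names(a)[changed],
                    a = unname(a[changed]),
                    b = unname(b[changed]),
                    difference = unname(b[changed] - a[changed]),
                    stringsAsFactors = FALSE)
  class(out) <- c("loss_gain_report", "data.frame")
  out
}

#' In-silico restriction digestion
#'
#' Cuts the sequence at the start coordinate of each non-overlapping
#' recognition-site hit (leftmost-greedy). The published panel gives
#' overhang type but not cut offsets, so cutting at site starts is an
#' approximation adequate for fragment counting; fragment lengths always
#' sum to the input length.
#'
#' @param sequence DNA string (ACGT).
#' @param enzyme Recognition string or enzyme record.
#' @return Integer vector of fragment lengths in bp, left to right; a
#'   site-free sequence gives one full-length fragment.
#' @export
digest_fragments <- function(sequence, enzyme) {
  sequence <- normalize_sequence(sequence)
  hits <- scan_sites(sequence, enzyme, strand_mode = "forward",
                     allow_overlaps = FALSE)
  n <- nchar(sequence)
  cuts <- hits$start[hits$start > 1L] - 1L
  as.integer(diff(c(0L, sort(unique(cuts)), n)))
}

#' Locate a primer on a sequence
#'
#' Exact-match search of the primer and of its reverse complement.
#' Multiplicity is data, not failure: zero, one or several hits are all
#' returned.
#'
#' @param sequence DNA string (ACGT).
#' @param primer Primer sequence (ACGT, length >= 10).
#' @return Data frame of class `primer_hits` with columns `start`,
#'   `end` (1-based inclusive, on the input sequence) and `orientation`
#'   (`"forward"` or `"reverse"`).
#' @export
locate_primer <- function(sequence, primer) {
  sequence <- normalize_sequence(sequence)
  primer <- normalize_sequence(primer, what = "primer")
  if (nchar(primer) < 10L)
    stop("primer must be at least 10 bp", call. = FALSE)
  find <- function(pat, orientation) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(sequence))
    data.frame(start = Biostrings::start(m),
               end = Biostrings::end(m),
               orientation = rep(orientation, length(m)),
               stringsAsFactors = FALSE)
  }
  hits <- rbind(find(primer, "forward"),
                find(reverse_complement(primer), "reverse"))
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("primer_hits", "data.frame")
  hits
}

#' PCR primer table for full-length DYZ1 array amplification
#'
#' The published panel of eight primers (DYZ1 A-H) used to amplify the
#' 3.56 kb HaeIII unit in overlapping fragments, shipped as a TSV.
#'
#' @param path Optional path to an alternative primer TSV.
#' @return Data frame with columns `primer_id`, `sequence`, `length`,
#'   `location`, `orientation`.
#' @export
primer_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "primer_table.tsv",
                        package = "dyz1kit", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
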