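#' Substitution class of a pentamer relative to TTCCA
#'
#' @param unit A DNA string of length 5 over ACGT (vectorised).
#' @param consensus Reference pentamer (default TTCCA).
#' @return Integer 0-5: the Hamming distance to the consensus.
#' @examples
#' hamming_class("TTCCA")  # 0
#' hamming_class("TTCGA")  # 1
#' @export
hamming_class <- function(unit, consensus = DYZ1_CONSENSUS) {
  stopifnot(nchar(consensus) == 5L)
  unit <- toupper(unit)
  if (any(nchar(unit) != 5L))
    stop("unit must have length 5, got length ",
         paste(unique(nchar(unit)[nchar(unit) != 5L]), collapse = ","),
         call. = FALSE)
  if (any(grepl("[^ACGT]", unit)))
    stop("unit contains non-ACGT characters", call. = FALSE)
  cb <- strsplit(consensus, "")[[1]]
  vapply(strsplit(unit, ""), function(u) sum(u != cb), integer(1))
}

#' Parameters for TTCCA-frame decomposition
#'
#' The adjusted TTCCA reading frame is formalised as the tiling of the
#' sequence into consecutive segments of length `min_len`..`max_len`
#' that minimises total cost, where a segment's cost is its Levenshtein
#' edit distance to the consensus plus `length_penalty` per bp of
#' deviation from 5. Ties are broken deterministically: a length-5 last
#' segment is preferred, then shorter segments.
#'
#' @param consensus Consensus pentamer (default TTCCA; must be length 5).
#' @param min_len,max_len Allowed segment lengths in bp (defaults 3 and 7,
#'   enough to absorb 1-2 bp slips without letting one segment swallow a
#'   whole indel block).
#' @param length_penalty Extra cost per bp of deviation from length 5
#'   (default 0: cost is edit distance alone).
#' @return Object of class `decomposition_params`.
#' @export
decomposition_params <- function(consensus = DYZ1_CONSENSUS,
                                 min_len = 3L, max_len = 7L,
                                 length_penalty = 0) {
  if (nchar(consensus) != 5L) stop("consensus must have length 5", call. = FALSE)
  if (min_len < 1L || max_len < min_len)
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  structure(list(consensus = toupper(consensus),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 length_penalty = length_penalty),
            class = "decomposition_params")
}

#' Decompose an array into TTCCA-anchored repeat units
#'
#' Dynamic programming over prefix ends: `best[i]` is the minimum total
#' cost of tiling the first `i` bases with segments of the allowed
#' lengths; candidate last-segment lengths are examined in the tie-break
#' order (5 first, then increasing) and only a strictly better cost
#' displaces the incumbent, so the reported tiling is deterministic.
#'
#' @param sequence DNA string (ACGT; lowercase is uppercased).
#' @param params A [decomposition_params()].
#' @return Data frame of class `repeat_units` with columns `start`
#'   (1-based bp), `length`, `sequence`, `edit_class` (Hamming distance
#'   to the consensus for length-5 units, `NA` otherwise) and
#'   `is_frameshift` (`TRUE` when length != 5). Units tile the input
#'   with no gaps or overlaps.
#' @export
decompose_array <- function(sequence, params = decomposition_params()) {
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  lens <- params$min_len:params$max_len
  if (n < params$min_len)
    stop("sequence shorter than min_len (", params$min_len, ")", call. = FALSE)
  # tie-break order: length 5 first (if allowed), then shorter before longer
  ord <- lens[order(lens != 5L, lens)]
  # segment costs, one vector per length: cost_l[[as.character(L)]][i] is
  # the cost of the segment ending at i (i.e. substring(i-L+1, i))
  cost_l <- list()
  for (L in lens) {
    if (L > n) { cost_l[[as.character(L)]] <- numeric(0); next }
    starts <- seq_len(n - L + 1L)
    segs <- substring(sequence, starts, starts + L - 1L)
    d <- as.numeric(adist(segs, params$consensus))
    cost_l[[as.character(L)]] <- d + params$length_penalty * abs(L - 5L)
  }
  INF <- Inf
  best <- rep(INF, n + 1L)
  best[1L] <- 0
  choice <- integer(n + 1L)
  for (i in seq_len(n)) {
    b <- INF; ch <- 0L
    for (L in ord) {
      if (i >= L) {
        c0 <- best[i - L + 1L]
        if (is.finite(c0)) {
          cand <- c0 + cost_l[[as.character(L)]][i - L + 1L]
          if (cand < b) { b <- cand; ch <- L }
        }
      }
    }
    best[i + 1L] <- b
    choice[i + 1L] <- ch
  }
  if (!is.finite(best[n + 1L]))
    stop("sequence of length ", n,
         " cannot be tiled with segment lengths ", params$min_len, "-",
         params$max_len, call. = FALSE)
  # traceback
  ends <- integer(0)
  i <- n
  while (i > 0L) {
    ends <- c(i, ends)
    i <- i - choice[i + 1L]
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  segs <- substring(sequence, starts, ends)
  lens_out <- ends - starts + 1L
  units <- data.frame(start = starts,
                      length = lens_out,
                      sequence = segs,
                      edit_class = NA_integer_,
                      is_frameshift = lens_out != 5L,
                      stringsAsFactors = FALSE)
  is5 <- lens_out == 5L
  if (any(is5))
    units$edit_class[is5] <- hamming_class(segs[is5], params$consensus)
  attr(units, "total_cost") <- best[n + 1L]
  attr(units, "sequence_length") <- n
  class(units) <- c("repeat_units", "data.frame")
  units
}

#' Build a derivative-count profile from repeat units
#'
#' Counts intact TTCCA units, each of the 15 single-bp derivatives
#' individually, aggregate 2/3/4/5-bp derivative classes, and frameshift
#' units (length != 5, which absorb small indels and are not folded into
#' the substitution classes).
#'
#' @param units A `repeat_units` data frame from [decompose_array()].
#' @param sequence_length Length of the profiled sequence in bp; units
#'   must tile it exactly.
#' @return Object of class `dyz1_profile`.
#' @export
build_profile <- function(units, sequence_length = attr(units, "sequence_length")) {
  units <- as.data.frame(units)
  if (is.null(sequence_length))
    stop("sequence_length is required", call. = FALSE)
  if (nrow(units) == 0L)
    stop("no units supplied", call. = FALSE)
  ends <- units$start + units$length - 1L
  if (units$start[1L] != 1L ||
      (nrow(units) > 1L && any(units$start[-1L] != head(ends, -1L) + 1L)) ||
      ends[nrow(units)] != sequence_length)
    stop("units do not tile the sequence (gaps, overlaps, or wrong total length)",
         call. = FALSE)
  is5 <- units$length == 5L
  cls <- rep(NA_integer_, nrow(units))
  cls[is5] <- hamming_class(units$sequence[is5])
  singles <- units$sequence[is5][cls[is5] == 1L]
  single_bp <- setNames(integer(15L), SINGLE_BP_DERIVATIVES)
  tab <- table(factor(singles, levels = SINGLE_BP_DERIVATIVES))
  single_bp[names(tab)] <- as.integer(tab)
  profile_from_counts(ttcca = sum(cls == 0L, na.rm = TRUE),
                      single_bp = single_bp,
                      class2 = sum(cls == 2L, na.rm = TRUE),
                      class3 = sum(cls == 3L, na.rm = TRUE),
                      class4 = sum(cls == 4L, na.rm = TRUE),
                      class5 = sum(cls == 5L, na.rm = TRUE),
                      frameshift = sum(!is5),
                      sequence_length = sequence_length)
}

#' Assemble a profile from explicit counts
#'
#' The class-1 aggregate is always computed by summing the 15 single-bp
#' derivative counts, so hand-entered published count columns go through
#' the same aggregation path as profiles computed from sequence.
#'
#' @param ttcca Count of intact TTCCA units.
#' @param single_bp Named integer vector over the 15 single-bp
#'   derivatives (any order; names must match [single_bp_derivatives()]).
#' @param class2,class3,class4,class5 Aggregate counts of 2-5 bp
#'   derivative pentamers.
#' @param frameshift Count of units of length != 5 (default 0).
#' @param sequence_length Profiled sequence length in bp (`NA` when the
#'   profile comes from a published table rather than a sequence).
#' @return Object of class `dyz1_profile`: a list with fields
#'   `sequence_length`, `ttcca_count`, `single_bp`, `class1` (the
#'   computed aggregate), `class2`..`class5`, `frameshift_units`,
#'   `total_units`.
#' @export
profile_from_counts <- function(ttcca, single_bp, class2, class3, class4,
                                class5, frameshift = 0L,
                                sequence_length = NA_integer_) {
  if (is.null(names(single_bp)))
    names(single_bp) <- SINGLE_BP_DERIVATIVES
  if (!setequal(names(single_bp), SINGLE_BP_DERIVATIVES))
    stop("single_bp names must be exactly the 15 Hamming-1 neighbours of TTCCA",
         call. = FALSE)
  single_bp <- as.integer(single_bp[SINGLE_BP_DERIVATIVES])
  names(single_bp) <- SINGLE_BP_DERIVATIVES
  class1 <- sum(single_bp)
  p <- structure(list(sequence_length = sequence_length,
                      ttcca_count = as.integer(ttcca),
                      single_bp = single_bp,
                      class1 = as.integer(class1),
                      class2 = as.integer(class2),
                      class3 = as.integer(class3),
                      class4 = as.integer(class4),
                      class5 = as.integer(class5),
                      frameshift_units = as.integer(frameshift),
                      total_units = as.integer(ttcca + class1 + class2 +
                                                 class3 + class4 + class5 +
                                                 frameshift)),
                 class = "dyz1_profile")
  p
}

profile_row_labels <- function() {
  c("TTCCA", "1 bp derivatives", SINGLE_BP_DERIVATIVES,
    "2 bp derivatives", "3 bp derivatives", "4 bp derivatives",
    "5 bp derivatives", "frameshift units", "total units")
}

profile_row_values <- function(p) {
  c(p$ttcca_count, p$class1, unname(p$single_bp),
    p$class2, p$class3, p$class4, p$class5,
    p$frameshift_units, p$total_units)
}

#' @export
print.dyz1_profile <- function(x, ...) {
  cat("DYZ1 repeat-unit profile",
      if (!is.na(x$sequence_length)) sprintf("(%d bp)", x$sequence_length),
      "\n")
  df <- data.frame(row = profile_row_labels(), count = profile_row_values(x))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Row-by-row comparison of two profiles
#'
#' @param a,b `dyz1_profile` objects.
#' @return Data frame of class `profile_comparison` with one row per
#'   profile-table row: columns `row`, `a`, `b`, `difference` (a - b)
#'   and `changed`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "dyz1_profile"), inherits(b, "dyz1_profile"))
  va <- profile_row_values(a)
  vb <- profile_row_values(b)
  out <- data.frame(row = profile_row_labels(),
                    a = va, b = vb,
                    difference = va - vb,
                    changed = va != vb,
                    stringsAsFactors = FALSE)
  class(out) <- c("profile_comparison", "data.frame")
  out
}

#' Published repeat-unit count profiles shipped with the package
#'
#' Loads the transcribed per-sample TTCCA/derivative count table for the
#' six sequenced twin blood samples (MZT1a, MZT1b, MZT2a, MZT2b, MZT3a,
#' MZT3b) and returns them as `dyz1_profile` objects built through the
#' same aggregation path as computed profiles.
#'
#' @param path Optional path to an alternative count table (TSV with a
#'   `row` column naming TTCCA, the 15 derivatives, and the 2-5 bp
#'   aggregates, plus one column per sample).
#' @return Named list of `dyz1_profile` objects.
#' @export
reported_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "repeat_unit_counts.tsv",
                        package = "dyz1kit", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  samples <- setdiff(names(tab), "row")
  rows <- tab$row
  lapply(setNames(samples, samples), function(s) {
    v <- setNames(tab[[s]], rows)
    profile_from_counts(ttcca = v[["TTCCA"]],
                        single_bp = v[SINGLE_BP_DERIVATIVES],
                        class2 = v[["2 bp derivatives"]],
                        class3 = v[["3 bp derivatives"]],
                        class4 = v[["4 bp derivatives"]],
                        class5 = v[["5 bp derivatives"]],
                        sequence_length = 3564L)
  })
}
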