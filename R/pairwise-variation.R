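#' Affine-gap alignment scoring parameters
#'
#' Defaults: match +2, mismatch -1, gap open -4 (cost of the first gap
#' base), gap extend -1 per further base. These weights favour one long
#' indel block over several short ones, which is how post-twinning
#' deletions present in satellite arrays.
#'
#' @param match Match score (> mismatch).
#' @param mismatch Mismatch score.
#' @param gap_open Score of the first base of a gap (<= gap_extend <= 0).
#' @param gap_extend Score of each subsequent gap base.
#' @return Object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -1,
                             gap_open = -4, gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("need gap_open <= gap_extend <= 0", call. = FALSE)
  if (!(match > mismatch)) stop("need match > mismatch", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

OP_LABELS <- c("match", "mismatch", "gap_b", "gap_a")

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment of two sequences. The
#' traceback is deterministic among equal-score alignments: diagonal is
#' preferred, then gap-in-b (a column consuming sequence `a`), then
#' gap-in-a.
#'
#' @param a,b Non-empty ACGT strings.
#' @param params An [alignment_params()].
#' @return Object of class `pairwise_alignment`: list with `score`,
#'   `ops` (character vector over `match`, `mismatch`, `gap_b`,
#'   `gap_a`, one entry per alignment column), `a`, `b`, `params`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  a <- normalize_sequence(a, "a")
  b <- normalize_sequence(b, "b")
  stopifnot(inherits(params, "alignment_params"))
  res <- .gotoh_align(a, b, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(list(score = res$score,
                 ops = OP_LABELS[res$ops + 1L],
                 a = a, b = b, params = params),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: %d vs %d bp, score %.1f\n",
              nchar(x$a), nchar(x$b), x$score))
  tab <- table(factor(x$ops, levels = OP_LABELS))
  cat(sprintf("  columns: %d match, %d mismatch, %d gap-in-b, %d gap-in-a\n",
              tab[["match"]], tab[["mismatch"]], tab[["gap_b"]],
              tab[["gap_a"]]))
  invisible(x)
}

#' Call variant blocks from a pairwise alignment
#'
#' Maximal runs of gap-in-b columns become deletion blocks (sequence
#' present in `a`, absent from `b`), runs of gap-in-a columns become
#' insertion blocks (anchored between two `a` positions), and runs of
#' mismatch columns become substitution blocks. All coordinates are
#' 1-based inclusive on the first sequence.
#'
#' @param alignment A [global_align()] result.
#' @return Object of class `comparison_report`: list with `blocks`
#'   (data frame: `kind`, `ref_start`, `ref_end`, `length`,
#'   `alt_sequence`), `net_length_difference` (`nchar(a) - nchar(b)`,
#'   always equal to total deletion length minus total insertion
#'   length), and `substitution_count`.
#' @export
call_variants <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ops <- alignment$ops
  a <- alignment$a; b <- alignment$b
  na <- sum(ops %in% c("match", "mismatch", "gap_b"))
  nb <- sum(ops %in% c("match", "mismatch", "gap_a"))
  if (na != nchar(a) || nb != nchar(b))
    stop("inconsistent alignment: ops do not consume both sequences",
         call. = FALSE)
  r <- rle(ops)
  blocks <- data.frame(kind = character(0), ref_start = integer(0),
                       ref_end = integer(0), length = integer(0),
                       alt_sequence = character(0),
                       stringsAsFactors = FALSE)
  i <- 0L; j <- 0L
  for (k in seq_along(r$values)) {
    v <- r$values[k]; L <- r$lengths[k]
    if (v == "match") {
      i <- i + L; j <- j + L
    } else if (v == "mismatch") {
      blocks <- rbind(blocks, data.frame(
        kind = "substitution", ref_start = i + 1L, ref_end = i + L,
        length = L, alt_sequence = substr(b, j + 1L, j + L),
        stringsAsFactors = FALSE))
      i <- i + L; j <- j + L
    } else if (v == "gap_b") {
      blocks <- rbind(blocks, data.frame(
        kind = "deletion", ref_start = i + 1L, ref_end = i + L,
        length = L, alt_sequence = NA_character_,
        stringsAsFactors = FALSE))
      i <- i + L
    } else {  # gap_a: insertion in b, anchored between a positions i, i+1
      blocks <- rbind(blocks, data.frame(
        kind = "insertion", ref_start = i, ref_end = i,
        length = L, alt_sequence = substr(b, j + 1L, j + L),
        stringsAsFactors = FALSE))
      j <- j + L
    }
  }
  net <- nchar(a) - nchar(b)
  dl <- sum(blocks$length[blocks$kind == "deletion"])
  il <- sum(blocks$length[blocks$kind == "insertion"])
  stopifnot(dl - il == net)
  structure(list(blocks = blocks,
                 net_length_difference = net,
                 substitution_count = sum(
                   blocks$length[blocks$kind == "substitution"])),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Pairwise comparison: net length difference %+d bp, %d substituted bp\n",
              x$net_length_difference, x$substitution_count))
  indels <- x$blocks[x$blocks$kind != "substitution", , drop = FALSE]
  if (nrow(indels) == 0L) cat("  no indel blocks\n") else {
    for (r in seq_len(nrow(indels)))
      cat(sprintf("  %s of %d bp at %d-%d\n", indels$kind[r],
                  indels$length[r], indels$ref_start[r], indels$ref_end[r]))
  }
  invisible(x)
}

#' Compare two array sequences end to end
#'
#' Convenience wrapper: aligns and calls variants in one step.
#'
#' @param a,b ACGT strings.
#' @param params An [alignment_params()].
#' @return A `comparison_report` (see [call_variants()]).
#' @export
compare_sequences <- function(a, b, params = alignment_params()) {
  call_variants(global_align(a, b, params))
}

#' Net length difference between two sequences
#'
#' @param a,b ACGT strings.
#' @return `nchar(a) - nchar(b)` in bp; by construction this always
#'   equals the alignment-derived net (deletions minus insertions).
#' @export
net_length_difference <- function(a, b) {
  nchar(normalize_sequence(a, "a")) - nchar(normalize_sequence(b, "b"))
}
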