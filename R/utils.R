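#' Normalise and validate a DNA sequence
#'
#' Uppercases the input, strips whitespace, and rejects any character
#' outside the unambiguous DNA alphabet ACGT, reporting the first
#' offending position. All analysis entry points in the package accept
#' only unambiguous sequence; the deposited DYZ1 array units contain no
#' ambiguity codes.
#'
#' @param x A single character string.
#' @param what Label used in error messages.
#' @return The normalised sequence string.
#' @export
normalize_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  x <- toupper(gsub("[[:space:]]+", "", x))
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0L)
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(x, bad, bad), bad), call. = FALSE)
  if (nchar(x) == 0L) stop(what, " is empty", call. = FALSE)
  x
}

#' Reverse complement of a DNA or IUPAC string
#'
#' @param x A single character string over the IUPAC DNA alphabet.
#' @return The reverse complement, preserving degeneracy codes.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. All stochastic generators in
# the package draw through this so a spec's seed fully determines output.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  code
}

# shared consensus for DYZ1 work
DYZ1_CONSENSUS <- "TTCCA"

# The 15 possible single-substitution derivatives of TTCCA, in the row
# order used by the package's profile tables (position 1 substitutions
# first would be one convention; the order here is the one the field's
# published profile tables use).
SINGLE_BP_DERIVATIVES <- c(
  "ATCCA", "TACCA", "TTACA", "TTCAA", "TTTCA", "TTCTA", "TTCCT",
  "GTCCA", "TGCCA", "TTGCA", "TTCGA", "TTCCG", "CTCCA", "TCCCA", "TTCCC"
)
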