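#' Specification of a synthetic DYZ1-like array
#'
#' Describes a tandem array of TTCCA-derived pentamer units. Each unit is
#' drawn independently from `class_spectrum`, the distribution over
#' substitution classes 0-5 (class k = pentamer differing from TTCCA at
#' exactly k positions). The default spectrum reproduces the class
#' proportions observed in a sequenced 3564 bp HaeIII unit of a DYZ1
#' array (235 intact TTCCA, 290 single-bp, 142 double-bp, 33 triple-bp,
#' 9 four-bp and 1 five-bp derivative out of 710 pentamers), so default
#' arrays are ~3550 bp and realistically diverged.
#'
#' @param unit_count Number of pentamer units (default 710).
#' @param class_spectrum Numeric vector of 6 probabilities (classes 0-5),
#'   summing to 1 within 1e-9.
#' @param derivative_weights Optional weights over the 15 single-bp
#'   derivatives (named by pentamer or in the order of
#'   [single_bp_derivatives()]); `NULL` means uniform within class 1.
#' @param indel_blocks Optional data frame with columns `position`
#'   (1-based bp on the concatenated array), `length` (bp), `kind`
#'   (`"insertion"` or `"deletion"`) and optionally `sequence` for
#'   insertions; blocks are applied after unit concatenation.
#' @param point_indel_rate Per-unit probability of a 1-bp slip
#'   (insertion or deletion inside the unit), default 0.
#' @param seed Integer seed; the same spec always generates the same
#'   array byte for byte.
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(unit_count = 710,
                       class_spectrum = c(235, 290, 142, 33, 9, 1) / 710,
                       derivative_weights = NULL,
                       indel_blocks = NULL,
                       point_indel_rate = 0,
                       seed = 1L) {
  if (!is.numeric(unit_count) || length(unit_count) != 1L ||
      is.na(unit_count) || unit_count < 1 || unit_count != round(unit_count))
    stop("invalid spec: unit_count must be a positive integer", call. = FALSE)
  if (!is.numeric(class_spectrum) || length(class_spectrum) != 6L ||
      anyNA(class_spectrum) || any(class_spectrum < 0))
    stop("invalid spec: class_spectrum must be 6 non-negative probabilities (classes 0-5)",
         call. = FALSE)
  if (abs(sum(class_spectrum) - 1) > 1e-9)
    stop("invalid spec: class_spectrum must sum to 1 (within 1e-9), got ",
         format(sum(class_spectrum), digits = 12), call. = FALSE)
  if (!is.null(derivative_weights)) {
    if (length(derivative_weights) != 15L || anyNA(derivative_weights) ||
        any(derivative_weights < 0) || sum(derivative_weights) <= 0)
      stop("invalid spec: derivative_weights must be 15 non-negative weights",
           call. = FALSE)
    if (!is.null(names(derivative_weights))) {
      if (!setequal(names(derivative_weights), SINGLE_BP_DERIVATIVES))
        stop("invalid spec: derivative_weights names must be the 15 single-bp derivatives",
             call. = FALSE)
      derivative_weights <- derivative_weights[SINGLE_BP_DERIVATIVES]
    } else names(derivative_weights) <- SINGLE_BP_DERIVATIVES
  }
  if (!is.null(indel_blocks)) indel_blocks <- validate_indel_blocks(indel_blocks)
  if (!is.numeric(point_indel_rate) || point_indel_rate < 0 || point_indel_rate > 1)
    stop("invalid spec: point_indel_rate must be in [0, 1]", call. = FALSE)
  structure(list(unit_count = as.integer(unit_count),
                 class_spectrum = setNames(class_spectrum, as.character(0:5)),
                 derivative_weights = derivative_weights,
                 indel_blocks = indel_blocks,
                 point_indel_rate = point_indel_rate,
                 seed = as.integer(seed)),
            class = "array_spec")
}

validate_indel_blocks <- function(blocks) {
  blocks <- as.data.frame(blocks)
  need <- c("position", "length", "kind")
  if (!all(need %in% names(blocks)))
    stop("invalid spec: indel_blocks needs columns position, length, kind",
         call. = FALSE)
  if (!all(blocks$kind %in% c("insertion", "deletion")))
    stop("invalid spec: indel_blocks kind must be 'insertion' or 'deletion'",
         call. = FALSE)
  if (any(blocks$position < 1) || any(blocks$length < 1))
    stop("invalid spec: indel_blocks positions and lengths must be >= 1",
         call. = FALSE)
  if (is.null(blocks$sequence)) blocks$sequence <- NA_character_
  blocks
}

#' The 15 single-substitution derivatives of TTCCA
#'
#' @return Character vector of the 15 pentamers at Hamming distance 1
#'   from TTCCA, in the package's canonical profile-table order.
#' @export
single_bp_derivatives <- function() SINGLE_BP_DERIVATIVES

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw one pentamer of substitution class k from TTCCA. Positions are
# chosen uniformly without replacement and each substituted base is
# uniform over the three non-reference bases, unless class-1 weights are
# supplied.
mutate_unit <- function(k, weights = NULL) {
  if (k == 0L) return(DYZ1_CONSENSUS)
  if (k == 1L && !is.null(weights))
    return(sample(SINGLE_BP_DERIVATIVES, 1L, prob = weights))
  bases <- strsplit(DYZ1_CONSENSUS, "")[[1]]
  pos <- sample.int(5L, k)
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  paste(bases, collapse = "")
}

# Apply indel blocks to a sequence in descending position order so that
# the stated 1-based coordinates all refer to the original sequence.
# Deletions remove `length` bp starting at `position`; insertions add
# `sequence` (or random bases) after `position`.
apply_indel_blocks <- function(sequence, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L)
    return(list(sequence = sequence, blocks = blocks))
  n <- nchar(sequence)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    end <- if (b$kind == "deletion") b$position + b$length - 1 else b$position
    if (end > n)
      stop("indel block at position ", b$position,
           " extends beyond sequence length ", n, call. = FALSE)
  }
  blocks <- blocks[order(-blocks$position), , drop = FALSE]
  for (i in seq_len(nrow(blocks))) {
    p <- blocks$position[i]
    L <- blocks$length[i]
    if (blocks$kind[i] == "deletion") {
      sequence <- paste0(substr(sequence, 1L, p - 1L),
                         substring(sequence, p + L))
    } else {
      ins <- blocks$sequence[i]
      if (is.na(ins)) ins <- random_dna(L)
      blocks$sequence[i] <- ins
      sequence <- paste0(substr(sequence, 1L, p),
                         ins,
                         substring(sequence, p + 1L))
    }
  }
  list(sequence = sequence, blocks = blocks[order(blocks$position), , drop = FALSE])
}

#' Generate a synthetic DYZ1-like array with ground truth
#'
#' Concatenates `unit_count` pentamer units drawn from the spec's class
#' spectrum, optionally applies per-unit 1-bp slips and the spec's indel
#' blocks, and records everything done.
#'
#' @param spec An [array_spec()].
#' @return A list of class `dyz1_array` with elements `sequence` (DNA
#'   string) and `truth`, a list holding `classes` (per-unit substitution
#'   class, in array order), `units` (the unit strings as generated,
#'   before slips), `slips` (data frame of 1-bp slips applied inside
#'   units), and `indel_blocks` (the blocks applied, with realised
#'   insertion sequences).
#' @export
generate_array <- function(spec) {
  if (!inherits(spec, "array_spec")) spec <- do.call(array_spec, as.list(spec))
  with_rng(spec$seed, {
    classes <- sample(0:5, spec$unit_count, replace = TRUE,
                      prob = spec$class_spectrum)
    units <- vapply(classes, mutate_unit, character(1),
                    weights = spec$derivative_weights)
    slips <- data.frame(unit = integer(0), kind = character(0),
                        offset = integer(0), base = character(0))
    if (spec$point_indel_rate > 0) {
      hit <- which(runif(spec$unit_count) < spec$point_indel_rate)
      for (u in hit) {
        if (runif(1) < 0.5) {   # 1-bp deletion inside the unit
          off <- sample.int(nchar(units[u]), 1L)
          base <- substr(units[u], off, off)
          units[u] <- paste0(substr(units[u], 1L, off - 1L),
                             substring(units[u], off + 1L))
          slips <- rbind(slips, data.frame(unit = u, kind = "deletion",
                                           offset = off, base = base))
        } else {                # 1-bp insertion inside the unit
          off <- sample.int(nchar(units[u]) + 1L, 1L) - 1L
          base <- sample(c("A", "C", "G", "T"), 1L)
          units[u] <- paste0(substr(units[u], 1L, off),
                             base, substring(units[u], off + 1L))
          slips <- rbind(slips, data.frame(unit = u, kind = "insertion",
                                           offset = off, base = base))
        }
      }
    }
    seq0 <- paste(units, collapse = "")
    res <- apply_indel_blocks(seq0, spec$indel_blocks)
    structure(list(sequence = res$sequence,
                   truth = list(classes = classes,
                                units = units,
                                slips = slips,
                                indel_blocks = res$blocks)),
              class = "dyz1_array")
  })
}

#' Specification of post-twinning edits between two array sequences
#'
#' Models the edits that differentiate one monozygotic twin's array from
#' the other's: a few deletion/insertion blocks (tens of bp) and an
#' optional per-bp substitution rate.
#'
#' @param deletions Data frame with columns `position` (1-based bp on
#'   the parent sequence) and `length` (bp), or `NULL`.
#' @param insertions Data frame with columns `position` (insertion lands
#'   after this 1-based parent position), `length` and optionally
#'   `sequence`, or `NULL`.
#' @param substitution_rate Per-bp probability of a point substitution in
#'   the child (default 0).
#' @param seed Integer seed for random insertion sequences and
#'   substitutions.
#' @return Object of class `twin_edit_spec`.
#' @export
twin_edit_spec <- function(deletions = NULL, insertions = NULL,
                           substitution_rate = 0, seed = 1L) {
  mk <- function(df, kind) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df <- as.data.frame(df)
    df$kind <- kind
    if (is.null(df$sequence)) df$sequence <- NA_character_
    df[, c("position", "length", "kind", "sequence")]
  }
  blocks <- rbind(mk(deletions, "deletion"), mk(insertions, "insertion"))
  if (!is.null(blocks)) {
    blocks <- validate_indel_blocks(blocks)
    # non-overlap: deletion spans must not touch each other or any
    # insertion anchor; duplicate insertion anchors are also rejected
    span <- function(i) {
      if (blocks$kind[i] == "deletion")
        c(blocks$position[i], blocks$position[i] + blocks$length[i] - 1)
      else c(blocks$position[i] + 0.5, blocks$position[i] + 0.5)
    }
    sp <- t(vapply(seq_len(nrow(blocks)), span, numeric(2)))
    ord <- order(sp[, 1])
    sp <- sp[ord, , drop = FALSE]
    if (nrow(sp) > 1 && any(sp[-1, 1] <= sp[-nrow(sp), 2]))
      stop("overlapping edits in twin_edit_spec", call. = FALSE)
  }
  if (!is.numeric(substitution_rate) || substitution_rate < 0 ||
      substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]", call. = FALSE)
  structure(list(blocks = blocks, substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "twin_edit_spec")
}

#' Apply post-twinning edits to a parent array sequence
#'
#' @param sequence Parent DNA string (ACGT).
#' @param edits A [twin_edit_spec()].
#' @return List of class `twin_pair` with `sequence` (the child),
#'   `truth$edits` (the indel blocks applied, with realised insertion
#'   sequences), `truth$substitutions` (data frame of point changes on
#'   child coordinates) and `truth$net_length_change`
#'   (child length minus parent length).
#' @export
apply_twin_edits <- function(sequence, edits) {
  sequence <- normalize_sequence(sequence)
  stopifnot(inherits(edits, "twin_edit_spec"))
  with_rng(edits$seed, {
    res <- apply_indel_blocks(sequence, edits$blocks)
    child <- res$sequence
    subs <- data.frame(position = integer(0), from = character(0),
                       to = character(0))
    if (edits$substitution_rate > 0) {
      hit <- which(runif(nchar(child)) < edits$substitution_rate)
      for (p in hit) {
        from <- substr(child, p, p)
        to <- sample(setdiff(c("A", "C", "G", "T"), from), 1L)
        substr(child, p, p) <- to
        subs <- rbind(subs, data.frame(position = p, from = from, to = to))
      }
    }
    structure(list(sequence = child,
                   truth = list(edits = res$blocks,
                                substitutions = subs,
                                net_length_change = nchar(child) - nchar(sequence))),
              class = "twin_pair")
  })
}

#' Specification of a qPCR standard dilution series
#'
#' The Ct model is `Ct = intercept_c0 - log(copies) / log(1 + efficiency)`
#' plus Gaussian replicate noise: with perfect efficiency (1.0, template
#' doubling every cycle) a 10-fold dilution raises Ct by log2(10) = 3.32.
#' `intercept_c0` is the Ct a single template copy would give.
#'
#' @param start_copies Copies in the first (most concentrated) point,
#'   default 2e8.
#' @param fold Dilution factor between points (> 1, default 10).
#' @param n_points Number of dilution points (>= 5 recommended; default 6).
#' @param intercept_c0 Ct at 1 copy (default 38, typical for SYBR
#'   assays of short amplicons).
#' @param efficiency Amplification efficiency in (0, 1], default 1.0.
#' @param noise_sd Replicate Ct standard deviation (default 0.15).
#' @param replicates Technical replicates per point (default 3).
#' @param seed Integer seed.
#' @return Object of class `dilution_series_spec`.
#' @export
dilution_series_spec <- function(start_copies = 2e8, fold = 10,
                                 n_points = 6, intercept_c0 = 38,
                                 efficiency = 1.0, noise_sd = 0.15,
                                 replicates = 3, seed = 1L) {
  if (start_copies <= 0) stop("start_copies must be > 0", call. = FALSE)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (efficiency <= 0 || efficiency > 1)
    stop("efficiency must be in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(start_copies = start_copies, fold = fold,
                 n_points = as.integer(n_points),
                 intercept_c0 = intercept_c0, efficiency = efficiency,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "dilution_series_spec")
}

#' Expected Ct for a template amount under the package's Ct model
#'
#' @param copies Template copies (> 0).
#' @param intercept_c0 Ct at one copy.
#' @param efficiency Amplification efficiency in (0, 1].
#' @return Numeric Ct value(s).
#' @export
expected_ct <- function(copies, intercept_c0 = 38, efficiency = 1.0) {
  stopifnot(all(copies > 0), efficiency > 0, efficiency <= 1)
  intercept_c0 - log(copies) / log(1 + efficiency)
}

#' Reported post-twinning edit blocks between sequenced DYZ1 arrays
#'
#' The deletion/insertion blocks reported between the sequenced twin
#' array units (and between blood and germline arrays of twin pair 1),
#' with 1-based positions on the parent sequence, shipped as a TSV.
#' These blocks are the inputs for reconstructing each comparison on a
#' synthetic parent array with [twin_edit_spec()] and
#' [apply_twin_edits()].
#'
#' @param path Optional path to an alternative TSV.
#' @return Data frame with columns `comparison`, `parent`, `child`,
#'   `kind`, `position`, `length`.
#' @export
reported_twin_edits <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "twin_edit_blocks.tsv",
                        package = "dyz1kit", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate a qPCR dilution series
#'
#' @param spec A [dilution_series_spec()].
#' @return Data frame of class `dilution_series` with columns `point`,
#'   `known_copies`, `replicate`, `ct`; deterministic for a fixed seed.
#' @export
simulate_dilution_series <- function(spec) {
  stopifnot(inherits(spec, "dilution_series_spec"))
  copies <- spec$start_copies / spec$fold^(seq_len(spec$n_points) - 1)
  with_rng(spec$seed, {
    out <- do.call(rbind, lapply(seq_along(copies), function(i) {
      ct0 <- expected_ct(copies[i], spec$intercept_c0, spec$efficiency)
      data.frame(point = i,
                 known_copies = copies[i],
                 replicate = seq_len(spec$replicates),
                 ct = ct0 + rnorm(spec$replicates, 0, spec$noise_sd))
    }))
    class(out) <- c("dilution_series", "data.frame")
    out
  })
}
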