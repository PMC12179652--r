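#' Scoring weights for tandem-repeat detection
#'
#' The detector scores a candidate array by aligning it against its cyclically
#' tiled consensus: `match` rewards every matched position, `mismatch` and
#' `indel` penalise every mismatched or inserted/deleted position, and only
#' arrays reaching `min_score` are reported.  The two settings of interest
#' are 2-7-7 (the TRF default, used for the primary full-sequence scan) and
#' the more sensitive 2-3-5 used for the second pass over the ITS2 insertion.
#'
#' @param match positive integer reward per matched position.
#' @param mismatch positive integer penalty per mismatched position.
#' @param indel positive integer penalty per inserted/deleted position.
#' @param min_score minimum reported array score (default 50, the usual
#'   reporting cutoff for characterised insertions).
#' @param max_period largest repeat period (bp) searched for.
#' @return an object of class `scoring_weights`.
#' @examples
#' scoring_weights()           # 2-7-7
#' scoring_weights(2, 3, 5)    # second-pass setting
#' @export
scoring_weights <- function(match = 2L, mismatch = 7L, indel = 7L,
                            min_score = 50L, max_period = 200L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  indel <- as.integer(indel); min_score <- as.integer(min_score)
  max_period <- as.integer(max_period)
  if (any(is.na(c(match, mismatch, indel, min_score, max_period))))
    stop("scoring weights must be integers")
  if (match <= 0L || mismatch <= 0L || indel <= 0L)
    stop("match, mismatch and indel weights must be positive")
  if (min_score < 0L) stop("min_score must be >= 0")
  if (max_period < 1L) stop("max_period must be >= 1")
  structure(list(match = match, mismatch = mismatch, indel = indel,
                 min_score = min_score, max_period = max_period),
            class = "scoring_weights")
}

#' @export
format.scoring_weights <- function(x, ...) {
  sprintf("%d-%d-%d", x$match, x$mismatch, x$indel)
}

#' @export
print.scoring_weights <- function(x, ...) {
  cat(sprintf("scoring weights %s (min score %d, max period %d)\n",
              format(x), x$min_score, x$max_period))
  invisible(x)
}

as_scoring_weights <- function(x) {
  if (inherits(x, "scoring_weights")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(scoring_weights(x[1], x[2], x[3]))
  stop("expected a scoring_weights object or a numeric triple")
}

#' A sequence record with optional ITS annotation
#'
#' Wraps one nucleotide sequence together with its identifier, optional
#' ITS1/5.8S/ITS2 annotation and the recomputed fraction of non-ACGT bases
#' used by the quality screen (records with more than 5% non-ATGC bases in
#' the target regions are excluded from repeat detection).
#'
#' @param seq_id sequence identifier (unique within a set).
#' @param sequence nucleotide string over A,C,G,T,N and IUPAC codes; case is
#'   folded to upper.
#' @param annotation optional data frame with columns `start`, `end`
#'   (0-based half-open) and `region` (one of `"ITS1"`, `"5.8S"`, `"ITS2"`).
#' @return an object of class `marker_record`.
#' @export
marker_record <- function(seq_id, sequence, annotation = NULL) {
  stopifnot(is.character(seq_id), length(seq_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTURYSWKMBDHVN-]", sequence))
    stop("sequence contains characters outside the IUPAC nucleotide alphabet")
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    need <- c("start", "end", "region")
    if (!all(need %in% names(annotation)))
      stop("annotation needs columns start, end, region")
    if (!all(annotation$region %in% c("ITS1", "5.8S", "ITS2")))
      stop("annotation regions must be ITS1, 5.8S or ITS2")
    if (any(annotation$start < 0 | annotation$end > nchar(sequence) |
            annotation$start >= annotation$end))
      stop("annotation intervals must be ordered and lie within the sequence")
  }
  n <- nchar(sequence)
  frac <- if (n == 0L) 0 else
    1 - nchar(gsub("[^ACGT]", "", sequence)) / n
  structure(list(seq_id = seq_id, sequence = sequence,
                 annotation = annotation, non_atgc_fraction = frac),
            class = "marker_record")
}

#' @export
print.marker_record <- function(x, ...) {
  cat(sprintf("marker record %s: %d bp, %.1f%% non-ACGT%s\n", x$seq_id,
              nchar(x$sequence), 100 * x$non_atgc_fraction,
              if (is.null(x$annotation)) "" else ", annotated"))
  invisible(x)
}

as_marker_record <- function(x, seq_id = "seq1") {
  if (inherits(x, "marker_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(marker_record(seq_id, x))
  stop("expected a marker_record or a single sequence string")
}

region_interval <- function(record, region) {
  ann <- record$annotation
  if (is.null(ann)) return(NULL)
  row <- ann[ann$region == region, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  c(row$start[1], row$end[1])
}

round_half_up <- function(x) floor(x + 0.5)

empty_hits <- function(seq_id = character(0)) {
  structure(data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0), period = integer(0),
                       copy_number = numeric(0), consensus = character(0),
                       percent_matches = integer(0), percent_indels = integer(0),
                       score = integer(0), stringsAsFactors = FALSE),
            class = c("repeat_hits", "data.frame"))
}

#' Detect tandem-repeat arrays in a sequence
#'
#' Finds tandem arrays whose alignment against the cyclically tiled consensus
#' pattern reaches the minimum score.  Candidate periods are seeded from exact
#' k-mer recurrences and refined by wraparound dynamic programming with
#' iterated majority-consensus updates; among overlapping candidate arrays
#' only the best-scoring one is kept (ties go to the smaller period, then the
#' leftmost start).  The consensus of a reported hit is the column majority
#' over its aligned copies (ties broken A<C<G<T) and the copy number is the
#' array length divided by the period, reported to one decimal.
#'
#' Records with more than 5% non-ACGT bases are refused unless
#' `override_quality = TRUE`, mirroring the sequence-quality screen applied
#' before the repeat search.
#'
#' @param record a [marker_record()] or a plain sequence string.
#' @param weights a [scoring_weights()] object (default 2-7-7, min score 50).
#' @param min_copies smallest array span, in units of the period, for a hit to
#'   be reported (default 1.8: an array must contain close to two copies;
#'   without this floor any sufficiently long substring would trivially match
#'   a single copy of itself).
#' @param override_quality report hits even when the record fails the 5%
#'   non-ACGT screen.
#' @param exhaustive consider every distinct substring of period <= 10 as a
#'   candidate pattern instead of only tandem-recurrent ones (used by the
#'   small-scale equivalence checks; slower on long sequences).
#' @return a `repeat_hits` data frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open), `period`, `copy_number`, `consensus`,
#'   `percent_matches`, `percent_indels`, `score`, sorted by `start`.
#' @examples
#' detect_tandem_repeats(strrep("AC", 13))          # a 26-bp microsatellite
#' detect_tandem_repeats("ACGT")                    # no array reaches score 50
#' @export
detect_tandem_repeats <- function(record, weights = scoring_weights(),
                                  min_copies = 1.8, override_quality = FALSE,
                                  exhaustive = FALSE) {
  record <- as_marker_record(record)
  weights <- as_scoring_weights(weights)
  if (nchar(record$sequence) == 0L) return(empty_hits())
  if (record$non_atgc_fraction > 0.05 && !override_quality)
    stop(sprintf("record %s has %.1f%% non-ATGC bases (> 5%% quality screen); ",
                 record$seq_id, 100 * record$non_atgc_fraction),
         "set override_quality = TRUE to scan anyway")
  raw <- scan_arrays_cpp(record$sequence, weights$match, weights$mismatch,
                         weights$indel, weights$min_score, weights$max_period,
                         exhaustive)
  if (nrow(raw) == 0L) return(empty_hits())
  span <- raw$end - raw$start
  raw <- raw[raw$score >= weights$min_score & span >= min_copies * raw$period, ,
             drop = FALSE]
  if (nrow(raw) == 0L) return(empty_hits())
  # overlap resolution: score desc, then smaller period, then leftmost
  ord <- order(-raw$score, raw$period, raw$start, raw$end, raw$consensus)
  raw <- raw[ord, , drop = FALSE]
  kept <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ok <- TRUE
    if (any(kept)) {
      k <- which(kept)
      ok <- all(raw$end[i] <= raw$start[k] | raw$start[i] >= raw$end[k])
    }
    kept[i] <- ok
  }
  raw <- raw[kept, , drop = FALSE]
  raw <- raw[order(raw$start, raw$end), , drop = FALSE]
  cols <- raw$n_match + raw$n_mismatch + raw$n_indel
  out <- data.frame(
    seq_id = record$seq_id,
    start = raw$start, end = raw$end, period = raw$period,
    copy_number = round((raw$end - raw$start) / raw$period, 1),
    consensus = raw$consensus,
    percent_matches = as.integer(round_half_up(100 * raw$n_match / cols)),
    percent_indels = as.integer(round_half_up(100 * raw$n_indel / cols)),
    score = raw$score, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("repeat_hits", "data.frame"))
}

#' @export
print.repeat_hits <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("repeat hits: none\n")
    return(invisible(x))
  }
  cat(sprintf("repeat hits: %d array(s) (coordinates 1-based inclusive)\n",
              nrow(x)))
  shown <- data.frame(seq_id = x$seq_id, start = x$start + 1L, end = x$end,
                      period = x$period, copies = x$copy_number,
                      match_pct = x$percent_matches,
                      indel_pct = x$percent_indels, score = x$score,
                      consensus = ifelse(nchar(x$consensus) > 32,
                                         paste0(substr(x$consensus, 1, 29), "..."),
                                         x$consensus))
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Best tandem-array score of a sequence
#'
#' Maximum array-vs-tiled-consensus alignment score over every candidate
#' pattern (all distinct substrings up to `max_period`, plus their
#' majority-consensus refinements), without the reporting filters of
#' [detect_tandem_repeats()].  This is the quantity checked against the
#' brute-force oracle [oracle_best_score()].
#'
#' @inheritParams detect_tandem_repeats
#' @param max_period largest candidate period.
#' @return integer score (0 when no positive-scoring array exists).
#' @export
best_array_score <- function(record, weights = scoring_weights(),
                             max_period = 10L) {
  record <- as_marker_record(record)
  weights <- as_scoring_weights(weights)
  wdp_best_score_cpp(record$sequence, weights$match, weights$mismatch,
                     weights$indel, as.integer(max_period))
}

#' Brute-force best array score (oracle)
#'
#' Independent maximisation of the same array score by plain Smith-Waterman
#' alignment of the sequence against explicitly tiled copies of every distinct
#' substring pattern.  Exponential-free but quadratic in everything; intended
#' for short sequences as a cross-check of [best_array_score()].
#'
#' @inheritParams best_array_score
#' @return integer score.
#' @export
oracle_best_score <- function(record, weights = scoring_weights(),
                              max_period = 10L) {
  record <- as_marker_record(record)
  weights <- as_scoring_weights(weights)
  oracle_best_score_cpp(record$sequence, weights$match, weights$mismatch,
                        weights$indel, as.integer(max_period))
}

#' Two-pass tandem-repeat scan of an ITS sequence
#'
#' Reproduces the two-stage protocol used to characterise the ITS2
#' minisatellite insertions: a primary scan of the full sequence at the
#' default 2-7-7 weights, then a second scan restricted to the ITS2 window at
#' the more sensitive 2-3-5 weights.  Second-pass coordinates are lifted back
#' to full-sequence space.  Both passes use minimum score 50.
#'
#' @param record a [marker_record()]; its ITS2 annotation supplies the window
#'   unless `its2_window` is given.
#' @param pass1,pass2 [scoring_weights()] for the two passes.
#' @param its2_window integer vector `c(start, end)` (0-based half-open) used
#'   when the record carries no ITS2 annotation.
#' @param ... passed on to [detect_tandem_repeats()].
#' @return a list with elements `pass1` and `pass2`, each a `repeat_hits`
#'   data frame in full-sequence coordinates.
#' @export
two_pass_its_scan <- function(record, pass1 = scoring_weights(2, 7, 7),
                              pass2 = scoring_weights(2, 3, 5),
                              its2_window = NULL, ...) {
  record <- as_marker_record(record)
  win <- if (!is.null(its2_window)) as.integer(its2_window) else
    region_interval(record, "ITS2")
  if (is.null(win))
    stop("no ITS2 annotation on the record and no its2_window supplied")
  if (length(win) != 2L || win[1] < 0L || win[2] > nchar(record$sequence) ||
      win[1] >= win[2])
    stop("ITS2 window lies outside the sequence")
  h1 <- detect_tandem_repeats(record, pass1, ...)
  sub <- marker_record(record$seq_id,
                       substr(record$sequence, win[1] + 1L, win[2]))
  h2 <- detect_tandem_repeats(sub, pass2, ...)
  if (nrow(h2) > 0L) {
    h2$start <- h2$start + win[1]
    h2$end <- h2$end + win[1]
  }
  list(pass1 = h1, pass2 = h2, its2_window = win)
}
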