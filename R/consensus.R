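#' Percent identity between two repeat consensus motifs
#'
#' Global alignment identity under unit costs (match +1, mismatch -1, gap -1):
#' the number of matched columns divided by the total alignment length, as a
#' percentage.  With `cyclic = TRUE` the maximum over all rotations of `b` is
#' returned, since a tandem-repeat consensus is only defined up to rotation.
#'
#' @param a,b non-empty DNA strings.
#' @param cyclic compare `a` against every rotation of `b`.
#' @return percent identity in \[0, 100\].
#' @examples
#' compare_consensus("ACGTACGT", "ACGTACGT")           # 100
#' compare_consensus("ACGTACGT", "GTACGTAC", cyclic = TRUE)  # 100
#' @export
compare_consensus <- function(a, b, cyclic = FALSE) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("consensus strings must be non-empty")
  ident <- function(x, y) {
    r <- nw_align_cpp(x, y)
    100 * r[["matches"]] / r[["alen"]]
  }
  if (!cyclic) return(ident(a, b))
  p <- nchar(b)
  bb <- paste0(b, b)
  max(vapply(seq_len(p) - 1L,
             function(k) ident(a, substr(bb, k + 1L, k + p)), numeric(1)))
}

#' Locate an insertion from a multiple alignment
#'
#' Given aligned sequences, the insertion carried by a target sequence is the
#' maximal contiguous column block that is a gap in every insertion-free
#' reference sequence and a non-gap in the target.  The block is returned in
#' ungapped target coordinates (0-based half-open).  When several disjoint
#' blocks exist the longest is returned (leftmost on ties) and the others are
#' listed; when no such block exists the interval is empty, signalling "no
#' insertion".
#'
#' @param aligned_block named character vector of equal-length gapped rows
#'   (gap character `-`).
#' @param with_insertion_ids names of the target rows carrying the insertion.
#' @param without_insertion_ids names of the insertion-free reference rows
#'   (at least one required).
#' @return a data frame with one row per target: `seq_id`, `start`, `end`
#'   (ungapped target coordinates), `n_blocks`, and `other_blocks` (a
#'   semicolon-separated list of alternative intervals, empty when unique).
#' @export
infer_insertion_boundaries <- function(aligned_block, with_insertion_ids,
                                       without_insertion_ids) {
  stopifnot(is.character(aligned_block), !is.null(names(aligned_block)))
  if (length(unique(nchar(aligned_block))) != 1L)
    stop("aligned rows must have equal length")
  if (length(without_insertion_ids) < 1L)
    stop("at least one insertion-free reference sequence is required")
  missing <- setdiff(c(with_insertion_ids, without_insertion_ids),
                     names(aligned_block))
  if (length(missing) > 0L)
    stop("ids not in alignment: ", paste(missing, collapse = ", "))
  ncol <- nchar(aligned_block[[1]])
  refmat <- do.call(rbind, strsplit(aligned_block[without_insertion_ids], ""))
  ref_gap <- apply(refmat == "-", 2, all)

  out <- lapply(with_insertion_ids, function(id) {
    tchars <- strsplit(aligned_block[[id]], "")[[1]]
    usable <- ref_gap & tchars != "-"
    # maximal runs of usable columns
    r <- rle(usable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts, ends)[r$values, , drop = FALSE]
    cum_ungapped <- cumsum(tchars != "-")
    to_target <- function(cs, ce) {
      s <- if (cs == 1L) 0L else cum_ungapped[cs - 1L]
      c(s, cum_ungapped[ce])
    }
    if (nrow(runs) == 0L)
      return(data.frame(seq_id = id, start = 0L, end = 0L, n_blocks = 0L,
                        other_blocks = "", stringsAsFactors = FALSE))
    lens <- runs[, 2] - runs[, 1] + 1L
    best <- which.max(lens)  # leftmost on ties
    iv <- to_target(runs[best, 1], runs[best, 2])
    others <- setdiff(seq_len(nrow(runs)), best)
    other_txt <- paste(vapply(others, function(k) {
      o <- to_target(runs[k, 1], runs[k, 2])
      sprintf("[%d,%d)", o[1], o[2])
    }, character(1)), collapse = ";")
    data.frame(seq_id = id, start = iv[1], end = iv[2],
               n_blocks = nrow(runs), other_blocks = other_txt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-species insertion profiles (Table-1 style)
#'
#' Aggregates detected tandem-repeat hits into one row per species, region and
#' weight setting: number of sequences examined, total sequence-length range,
#' insertion-size range, copy-number range, match/indel percentage ranges, the
#' distinct consensus patterns (collapsed when 100% identical up to rotation)
#' and the range of pairwise consensus similarities within the species.
#' Species/region/weight combinations without any hit are reported as "ND"
#' (not detected) rows.
#'
#' @param hits a named list of `repeat_hits` data frames, one per weight
#'   setting (names like `"2-7-7"`), or a single `repeat_hits` data frame
#'   (label taken from `weights_label`).
#' @param records list of [marker_record()] objects covering all hits.
#' @param species named character vector mapping `seq_id` to a species label.
#' @param weights_label label used when `hits` is a single data frame.
#' @return a `species_profiles` data frame.
#' @export
summarize_species_profiles <- function(hits, records, species,
                                       weights_label = "2-7-7") {
  if (is.data.frame(hits)) {
    hits <- stats::setNames(list(hits), weights_label)
  }
  stopifnot(is.list(hits), !is.null(names(hits)))
  recs <- stats::setNames(records, vapply(records, `[[`, "", "seq_id"))
  all_hit_ids <- unique(unlist(lapply(hits, function(h) h$seq_id)))
  unmapped <- setdiff(all_hit_ids, names(species))
  if (length(unmapped) > 0L)
    stop("hits with seq_id not mapped to a species: ",
         paste(unmapped, collapse = ", "))

  hit_region <- function(h, rec) {
    if (is.null(rec$annotation)) return(NA_character_)
    mid <- (h$start + h$end) / 2
    ann <- rec$annotation
    k <- which(ann$start <= mid & mid < ann$end)
    if (length(k) == 0L) NA_character_ else ann$region[k[1]]
  }

  rng <- function(x) c(min(x), max(x))
  rows <- list()
  sp_levels <- sort(unique(species[names(species) %in% names(recs)]))
  for (sp in sp_levels) {
    ids <- names(species)[species == sp]
    ids <- intersect(ids, names(recs))
    if (length(ids) == 0L) next
    lens <- vapply(recs[ids], function(r) nchar(r$sequence), numeric(1))
    for (wl in names(hits)) {
      h <- hits[[wl]]
      h <- h[h$seq_id %in% ids, , drop = FALSE]
      regions <- if (nrow(h) > 0L)
        vapply(seq_len(nrow(h)),
               function(i) hit_region(h[i, ], recs[[h$seq_id[i]]]),
               character(1)) else character(0)
      for (reg in c("ITS1", "ITS2")) {
        hr <- h[!is.na(regions) & regions == reg, , drop = FALSE]
        if (nrow(hr) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, region = reg, weights = wl,
            n_sequences = length(ids),
            its_len_min = rng(lens)[1], its_len_max = rng(lens)[2],
            insertion_min = NA_real_, insertion_max = NA_real_,
            copy_min = NA_real_, copy_max = NA_real_,
            match_min = NA_real_, match_max = NA_real_,
            indel_min = NA_real_, indel_max = NA_real_,
            n_patterns = 0L, consensus_patterns = "ND",
            similarity_min = NA_real_, similarity_max = NA_real_,
            detected = FALSE, stringsAsFactors = FALSE)
          next
        }
        sizes <- hr$end - hr$start
        cons <- unique(hr$consensus)
        # collapse motifs identical up to rotation
        keep <- character(0)
        for (cc in cons) {
          dup <- any(vapply(keep, function(k)
            nchar(k) == nchar(cc) &&
              compare_consensus(k, cc, cyclic = TRUE) == 100, logical(1)))
          if (!dup) keep <- c(keep, cc)
        }
        sims <- if (length(keep) < 2L) 100 else {
          prs <- utils::combn(keep, 2)
          vapply(seq_len(ncol(prs)), function(k)
            compare_consensus(prs[1, k], prs[2, k], cyclic = TRUE), numeric(1))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, region = reg, weights = wl,
          n_sequences = length(ids),
          its_len_min = rng(lens)[1], its_len_max = rng(lens)[2],
          insertion_min = rng(sizes)[1], insertion_max = rng(sizes)[2],
          copy_min = rng(hr$copy_number)[1], copy_max = rng(hr$copy_number)[2],
          match_min = rng(hr$percent_matches)[1],
          match_max = rng(hr$percent_matches)[2],
          indel_min = rng(hr$percent_indels)[1],
          indel_max = rng(hr$percent_indels)[2],
          n_patterns = length(keep),
          consensus_patterns = paste(sprintf("%s (%d)", keep, nchar(keep)),
                                     collapse = "; "),
          similarity_min = round(rng(sims)[1], 1),
          similarity_max = round(rng(sims)[2], 1),
          detected = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("species_profiles", "data.frame"))
}

#' @export
print.species_profiles <- function(x, ...) {
  fr <- function(a, b, digits = 0) {
    if (is.na(a)) return("ND")
    if (a == b) format(round(a, digits)) else
      paste0(format(round(a, digits)), "\u2013", format(round(b, digits)))
  }
  cat("Tandem-repeat insertion profiles\n")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    cat(sprintf("%s (%s) n=%d, %s: len %s, ins %s, copies %s, match%% %s, indel%% %s, %s\n",
                r$species, r$region, r$n_sequences, r$weights,
                fr(r$its_len_min, r$its_len_max),
                fr(r$insertion_min, r$insertion_max),
                fr(r$copy_min, r$copy_max, 1),
                fr(r$match_min, r$match_max),
                fr(r$indel_min, r$indel_max),
                r$consensus_patterns))
  }
  invisible(x)
}
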