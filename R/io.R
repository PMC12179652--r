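#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and wrapped as [marker_record()] objects with the
#' non-ACGT fraction recomputed on load; duplicate identifiers and empty files
#' are errors.  Identifiers are the first whitespace-delimited token of each
#' header.
#'
#' @param path FASTA file.
#' @return list of [marker_record()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  mapply(marker_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write marker records to FASTA (80-column wrap)
#'
#' @param records list of [marker_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a BED-like region annotation and attach it to records
#'
#' The annotation is 4-column tab-separated text without header: sequence id,
#' start (0-based), end (half-open), region (ITS1, 5.8S or ITS2).
#'
#' @param path annotation file.
#' @return data frame with columns `seq_id`, `start`, `end`, `region`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 4L) stop("annotation needs 4 columns: seqid start end region")
  ann <- ann[, 1:4]
  names(ann) <- c("seq_id", "start", "end", "region")
  if (!all(ann$region %in% c("ITS1", "5.8S", "ITS2")))
    stop("annotation regions must be ITS1, 5.8S or ITS2")
  ann
}

#' @rdname read_annotation
#' @param records list of [marker_record()].
#' @param annotation data frame as returned by `read_annotation()`.
#' @return `annotate_records()`: the records with annotations attached.
#' @export
annotate_records <- function(records, annotation) {
  lapply(records, function(r) {
    rows <- annotation[annotation$seq_id == r$seq_id, , drop = FALSE]
    if (nrow(rows) == 0L) return(r)
    marker_record(r$seq_id, r$sequence,
                  rows[, c("start", "end", "region")])
  })
}

#' @rdname read_annotation
#' @export
write_annotation <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    if (is.null(r$annotation)) return(NULL)
    cbind(seq_id = r$seq_id, r$annotation[, c("start", "end", "region")])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a morphometric measurement CSV
#'
#' Expected header: `collection,basidiome,structure,length_um,width_um`.
#'
#' @param path CSV file.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  measurement_set(df)
}

#' @rdname read_measurements
#' @param ms a [measurement_set()].
#' @export
write_measurements <- function(ms, path) {
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a locus manifest and its genealogies
#'
#' The manifest is tab-separated with header
#' `locus linkage_group tree_path support_convention`; tree paths are
#' resolved relative to the manifest's directory.
#'
#' @param path manifest file.
#' @param outgroup outgroup taxon passed to [parse_annotated_tree()].
#' @return list of `genealogy` objects.
#' @export
read_locus_manifest <- function(path, outgroup = NULL) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "linkage_group", "tree_path", "support_convention")
  if (!all(need %in% names(man)))
    stop("manifest needs columns ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(man)), function(i) {
    tp <- man$tree_path[i]
    if (!file.exists(tp)) tp <- file.path(base, tp)
    parse_annotated_tree(tp, support_convention = man$support_convention[i],
                         locus = man$locus[i],
                         linkage_group = man$linkage_group[i],
                         outgroup = outgroup)
  })
}

# small deterministic polynomial hash for config fingerprints
config_hash <- function(txt) {
  h <- 17
  for (b in utf8ToInt(enc2utf8(txt))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

report_header <- function(seed = NA, config = list()) {
  cfg <- paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  c(sprintf("# boletax %s",
            as.character(utils::packageVersion("boletax"))),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s", config_hash(cfg)))
}

tsv_lines <- function(df) {
  body <- if (nrow(df) == 0L) character(0) else
    do.call(paste, c(lapply(df, as.character), sep = "\t"))
  c(paste(names(df), collapse = "\t"), body)
}

write_tsv_report <- function(df, path, seed = NA, config = list(),
                             extra = character(0)) {
  writeLines(c(report_header(seed, config), tsv_lines(df), extra), path)
  invisible(path)
}

hits_report_df <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(seq_id = "ND", start = "ND", end = "ND", period = "ND",
                      copy_number = "ND", consensus_size = "ND",
                      percent_matches = "ND", percent_indels = "ND",
                      score = "ND", consensus = "ND",
                      stringsAsFactors = FALSE))
  data.frame(seq_id = hits$seq_id, start = hits$start + 1L, end = hits$end,
             period = hits$period, copy_number = hits$copy_number,
             consensus_size = nchar(hits$consensus),
             percent_matches = hits$percent_matches,
             percent_indels = hits$percent_indels, score = hits$score,
             consensus = hits$consensus, stringsAsFactors = FALSE)
}

delimitation_report_df <- function(delim) {
  if (length(delim$lineages) == 0L)
    return(data.frame(lineage = character(0), status = character(0),
                      taxa = character(0), supporting_loci = character(0),
                      flags = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(delim$lineages), function(i) {
    l <- delim$lineages[[i]]
    data.frame(lineage = sprintf("L%02d", i), status = l$status,
               taxa = paste(l$taxa, collapse = ","),
               supporting_loci = paste(l$supporting_loci, collapse = ","),
               flags = paste(l$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Render tab-separated reports for pipeline results
#'
#' Writes one file per recognised result type into `out_dir`: repeat hits
#' (TRF-dat-style table, coordinates 1-based inclusive), species insertion
#' profiles, a delimitation report with a dedicated putative-species section,
#' morphometric summaries and ellipse parameters.  Every file begins with a
#' header recording the package version, a configuration hash and the seed,
#' and output is byte-deterministic given fixed inputs.
#'
#' @param results named list; recognised elements: `hits` (`repeat_hits`),
#'   `profiles` (`species_profiles`), `delimitation` (`delimitation`),
#'   `summary` (`structure_summary`), `ellipse` (`iso_ellipse`).
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the headers.
#' @param config named list recorded (hashed) in the headers.
#' @return character vector of the files written.
#' @export
render_reports <- function(results, out_dir, seed = NA, config = list()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable")
  files <- character(0)
  if (!is.null(results$hits)) {
    f <- file.path(out_dir, "repeat_hits.tsv")
    write_tsv_report(hits_report_df(results$hits), f, seed, config)
    files <- c(files, f)
  }
  if (!is.null(results$profiles)) {
    f <- file.path(out_dir, "species_profiles.tsv")
    write_tsv_report(as.data.frame(results$profiles), f, seed, config)
    files <- c(files, f)
  }
  if (!is.null(results$delimitation)) {
    f <- file.path(out_dir, "delimitation.tsv")
    df <- delimitation_report_df(results$delimitation)
    put <- df[df$status == "putative_species", , drop = FALSE]
    extra <- c(
      "# putative species (evidence from a single linkage group; review manually)",
      if (nrow(put) == 0L) "# none" else
        sprintf("# %s\t%s", put$lineage, put$taxa),
      if (length(results$delimitation$unassigned))
        sprintf("# unassigned: %s",
                paste(results$delimitation$unassigned, collapse = ",")))
    write_tsv_report(df, f, seed, config, extra = extra)
    files <- c(files, f)
  }
  if (!is.null(results$summary)) {
    f <- file.path(out_dir, "morphometrics.tsv")
    s <- results$summary
    df <- data.frame(structure = s$structure, n = s$n, m = s$m, p = s$p,
                     description = format(s), stringsAsFactors = FALSE)
    write_tsv_report(df, f, seed, config)
    files <- c(files, f)
  }
  if (!is.null(results$ellipse)) {
    f <- file.path(out_dir, "ellipse.tsv")
    e <- results$ellipse
    df <- data.frame(center_length = e$center[1], center_width = e$center[2],
                     semi_major = e$semi_axes[1], semi_minor = e$semi_axes[2],
                     angle_rad = e$angle, level = e$level,
                     stringsAsFactors = FALSE)
    write_tsv_report(df, f, seed, config)
    files <- c(files, f)
  }
  files
}
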