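#' Parameters for simulating a multi-locus genealogy set
#'
#' Describes a study design of several independently inherited loci (by
#' default ITS, LSU, tef1 and rpb2, with ITS and LSU sharing one linkage
#' group) over a known species partition.  Each locus tree renders each true
#' species monophyletic with probability `concordance_prob`; deliberately
#' concordant species clades receive supports from the `support_true` ranges,
#' all other internal nodes from `support_other`.  Specimens can be masked
#' from individual loci to emulate missing sequences.
#'
#' @param true_partition named character vector: specimen id -> species id.
#' @param loci data frame with columns `locus` and `linkage_group`.
#' @param concordance_prob probability in \[0, 1\] that a locus renders a true
#'   species monophyletic (drawn independently per species per locus).
#' @param support_true,support_other lists with elements `bs = c(lo, hi)`
#'   (bootstrap range, within \[0, 100\]) and `pp = c(lo, hi)` (posterior
#'   range, within \[0, 1\]).
#' @param masking named list: locus -> character vector of specimens absent
#'   from that locus.
#' @param outgroup outgroup taxon appended to every tree.
#' @param seed integer seed.
#' @return an object of class `genealogy_sim_params`.
#' @export
genealogy_sim_params <- function(true_partition,
                                 loci = NULL,
                                 concordance_prob = 1,
                                 support_true = list(bs = c(95, 100),
                                                     pp = c(0.99, 1)),
                                 support_other = list(bs = c(20, 69),
                                                      pp = c(0.30, 0.94)),
                                 masking = list(),
                                 outgroup = "Imleria_badia",
                                 seed = 1L) {
  if (length(true_partition) == 0L || is.null(names(true_partition)))
    stop("true_partition must be a non-empty named vector (specimen -> species)")
  if (anyDuplicated(names(true_partition)))
    stop("every specimen must belong to exactly one species")
  if (length(unique(true_partition)) < 2L) stop("need at least 2 species")
  if (length(true_partition) < 3L) stop("need at least 3 specimens")
  if (!is.finite(concordance_prob) || concordance_prob < 0 ||
      concordance_prob > 1)
    stop("concordance_prob must lie in [0, 1]")
  if (is.null(loci))
    loci <- data.frame(locus = c("ITS", "LSU", "tef1", "rpb2"),
                       linkage_group = c("ITS-LSU", "ITS-LSU", "tef1", "rpb2"),
                       stringsAsFactors = FALSE)
  chk_rng <- function(r, lo, hi, what) {
    if (length(r) != 2L || any(r < lo) || any(r > hi) || r[1] > r[2])
      stop(what, " range must be ordered and within [", lo, ", ", hi, "]")
  }
  chk_rng(support_true$bs, 0, 100, "true BS")
  chk_rng(support_other$bs, 0, 100, "other BS")
  chk_rng(support_true$pp, 0, 1, "true PP")
  chk_rng(support_other$pp, 0, 1, "other PP")
  if (length(masking) > 0L) {
    if (!all(names(masking) %in% loci$locus))
      stop("masking names must be locus names")
    bad <- setdiff(unlist(masking), names(true_partition))
    if (length(bad) > 0L)
      stop("masked specimens not in partition: ", paste(bad, collapse = ", "))
    for (sp in unique(true_partition)) {
      mem <- names(true_partition)[true_partition == sp]
      present_somewhere <- any(vapply(loci$locus, function(lc)
        length(setdiff(mem, masking[[lc]])) > 0L, logical(1)))
      if (!present_somewhere)
        stop("masking removes every member of species '", sp,
             "' from every locus")
    }
  }
  if (outgroup %in% names(true_partition))
    stop("outgroup id collides with a specimen id")
  structure(list(true_partition = true_partition, loci = loci,
                 concordance_prob = concordance_prob,
                 support_true = support_true, support_other = support_other,
                 masking = masking, outgroup = outgroup,
                 seed = as.integer(seed)),
            class = "genealogy_sim_params")
}

node_newick <- function(node) {
  if (!is.null(node$tip)) return(node$tip)
  lab <- if (is.null(node$support)) "" else
    sprintf("%d/%.2f", node$support[1], node$support[2])
  paste0("(", paste(vapply(node$children, node_newick, character(1)),
                    collapse = ","), ")", lab)
}

#' Simulate a set of single-locus genealogies with a known species partition
#'
#' Topologies are random bifurcating coalescent-style joins: each species
#' drawn as concordant contributes a random subtree over its members (its root
#' labelled with "true" supports), discordant species scatter their members as
#' independent tips, and the resulting units are joined at random (labels from
#' the "other" support ranges).  The outgroup is attached at the root.  Output
#' is byte-deterministic for a fixed seed.
#'
#' @param params a [genealogy_sim_params()].
#' @return a list with `genealogies` (list of [parse_annotated_tree()]
#'   objects, one per locus), `newick` (named character vector of the exact
#'   emitted trees) and `true_partition`.
#' @export
simulate_genealogy_set <- function(params) {
  stopifnot(inherits(params, "genealogy_sim_params"))
  set.seed(params$seed)
  tp <- params$true_partition
  draw <- function(rng) {
    c(round(stats::runif(1, rng$bs[1], rng$bs[2])),
      round(stats::runif(1, rng$pp[1], rng$pp[2]), 2))
  }
  coalesce <- function(units) {
    while (length(units) > 1L) {
      k <- sample.int(length(units), 2L)
      merged <- list(children = units[k], support = draw(params$support_other))
      units <- c(units[-k], list(merged))
    }
    units[[1L]]
  }
  newicks <- character(0)
  genealogies <- vector("list", nrow(params$loci))
  for (li in seq_len(nrow(params$loci))) {
    locus <- params$loci$locus[li]
    present <- setdiff(names(tp), params$masking[[locus]])
    units <- list()
    for (sp in sort(unique(tp))) {
      mem <- sort(intersect(names(tp)[tp == sp], present))
      if (length(mem) == 0L) next
      concordant <- stats::runif(1) < params$concordance_prob
      if (length(mem) == 1L) {
        units <- c(units, list(list(tip = mem)))
      } else if (concordant) {
        sub <- coalesce(lapply(mem, function(m) list(tip = m)))
        sub$support <- draw(params$support_true)
        units <- c(units, list(sub))
      } else {
        units <- c(units, lapply(mem, function(m) list(tip = m)))
      }
    }
    ingroup <- coalesce(units)
    nwk <- paste0("(", node_newick(ingroup), ",", params$outgroup, ");")
    newicks[locus] <- nwk
    genealogies[[li]] <- parse_annotated_tree(
      nwk, support_convention = "bs/pp", locus = locus,
      linkage_group = params$loci$linkage_group[li],
      outgroup = params$outgroup)
  }
  list(genealogies = genealogies, newick = newicks, true_partition = tp)
}

#' Parameters for simulating ITS sequences with planted repeat insertions
#'
#' Each simulated record is an ITS-like backbone carrying a planted
#' dinucleotide microsatellite inside ITS1 and a planted minisatellite array
#' inside ITS2: `floor(copies)` full copies of the consensus plus a prefix of
#' length `floor(frac * period)`, then mutated at the stated substitution and
#' indel rates.  Defaults emulate the long ITS2 insertion of H. bubalinus
#' (82-bp consensus, 2.8 copies) and a 26-bp AC run in ITS1.
#'
#' @param backbone_length backbone (insert-free) ITS length in bp.
#' @param its_annotation data frame (`start`, `end`, `region`) of the
#'   ITS1/5.8S/ITS2 intervals on the backbone, 0-based half-open; a default
#'   partition is derived from `backbone_length` when `NULL`.
#' @param minis_consensus minisatellite consensus (A/C/G/T only).
#' @param minis_copies planted copy number (>= 1; fractional allowed).
#' @param minis_sub_rate,minis_indel_rate per-base mutation probabilities in
#'   \[0, 1\] applied to the planted minisatellite.
#' @param micro_unit microsatellite unit (default `"AC"`).
#' @param micro_length planted microsatellite length in bp (even, >= 0).
#' @param n_sequences number of records.
#' @param seed integer seed.
#' @return an object of class `marker_sim_params`.
#' @export
marker_sim_params <- function(backbone_length = 680L,
                              its_annotation = NULL,
                              minis_consensus = paste0(
                                "GGGACTCGAGCGAAGGGTCGGCTTAGCTATTAGTTGGTCGTG",
                                "AGGCCAGCGAACGCGGTCGGGCTGTGGGTCTCGAGCTTCA"),
                              minis_copies = 2.8,
                              minis_sub_rate = 0.02,
                              minis_indel_rate = 0.005,
                              micro_unit = "AC",
                              micro_length = 26L,
                              n_sequences = 5L,
                              seed = 1L) {
  backbone_length <- as.integer(backbone_length)
  micro_length <- as.integer(micro_length)
  minis_consensus <- toupper(minis_consensus)
  micro_unit <- toupper(micro_unit)
  if (nchar(minis_consensus) == 0L || grepl("[^ACGT]", minis_consensus))
    stop("minis_consensus must be a non-empty string over A, C, G, T")
  if (grepl("[^ACGT]", micro_unit) || nchar(micro_unit) == 0L)
    stop("micro_unit must be over A, C, G, T")
  if (micro_length < 0L || micro_length %% 2L != 0L)
    stop("micro_length must be even and >= 0")
  if (minis_copies < 1) stop("minis_copies must be >= 1")
  for (r in c(minis_sub_rate, minis_indel_rate))
    if (!is.finite(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (is.null(its_annotation)) {
    its1_end <- round(0.35 * backbone_length)
    s58_end <- its1_end + 155L
    if (s58_end >= backbone_length)
      stop("backbone too short for the default ITS partition")
    its_annotation <- data.frame(
      start = c(0L, its1_end, s58_end),
      end = c(its1_end, s58_end, backbone_length),
      region = c("ITS1", "5.8S", "ITS2"), stringsAsFactors = FALSE)
  }
  ann <- as.data.frame(its_annotation)
  if (!all(c("start", "end", "region") %in% names(ann)) ||
      !setequal(ann$region, c("ITS1", "5.8S", "ITS2")))
    stop("its_annotation needs ITS1, 5.8S and ITS2 rows")
  ann <- ann[order(ann$start), ]
  if (any(ann$start >= ann$end) || any(ann$end[-3] > ann$start[-1]) ||
      ann$start[1] < 0L || ann$end[3] > backbone_length)
    stop("annotation intervals must be ordered, non-overlapping and within the backbone")
  structure(list(backbone_length = backbone_length, its_annotation = ann,
                 minis_consensus = minis_consensus,
                 minis_copies = minis_copies,
                 minis_sub_rate = minis_sub_rate,
                 minis_indel_rate = minis_indel_rate,
                 micro_unit = micro_unit, micro_length = micro_length,
                 n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed)),
            class = "marker_sim_params")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(x, sub_rate, indel_rate) {
  ch <- strsplit(x, "")[[1]]
  bases <- c("A", "C", "G", "T")
  if (sub_rate > 0) {
    hit <- stats::runif(length(ch)) < sub_rate
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (b in ch) {
      if (stats::runif(1) < indel_rate) {
        if (stats::runif(1) < 0.5) next           # deletion
        out <- c(out, sample(bases, 1L), b)       # insertion before the base
      } else out <- c(out, b)
    }
    ch <- out
  }
  paste(ch, collapse = "")
}

tile_to_length <- function(unit, len) {
  substr(strrep(unit, ceiling(len / nchar(unit))), 1L, len)
}

#' Simulate ITS records with planted tandem-repeat insertions
#'
#' One backbone is drawn per call (the "species" sequence); every record
#' receives the planted microsatellite (exact) and an independently mutated
#' copy of the planted minisatellite, so records emulate conspecific
#' sequences with intraspecific insertion variability.  The truth table gives
#' the exact planted coordinates (0-based half-open, in final-sequence space)
#' together with the planted consensus, copy number and the pre-mutation
#' planted string.
#'
#' @param params a [marker_sim_params()].
#' @return list with `records` (list of [marker_record()]) and `truth`
#'   (data frame: `seq_id`, `region`, `start`, `end`, `consensus`, `copies`,
#'   `planted`).
#' @export
simulate_marker_sequences <- function(params) {
  stopifnot(inherits(params, "marker_sim_params"))
  set.seed(params$seed)
  ann <- params$its_annotation
  iv <- function(region) unlist(ann[ann$region == region, c("start", "end")])
  backbone <- random_dna(params$backbone_length)
  micro <- tile_to_length(params$micro_unit, params$micro_length)
  p <- nchar(params$minis_consensus)
  full <- floor(params$minis_copies)
  # guard against binary representation of fractional copy numbers:
  # total planted length is floor(copies * period)
  partial <- floor(params$minis_copies * p + 1e-9) - full * p
  minis <- paste0(strrep(params$minis_consensus, full),
                  substr(params$minis_consensus, 1L, partial))

  its1 <- iv("ITS1"); its2 <- iv("ITS2")
  pos_micro <- floor((its1[1] + its1[2]) / 2)
  pos_minis <- floor((its2[1] + its2[2]) / 2)

  records <- vector("list", params$n_sequences)
  truth <- vector("list", params$n_sequences)
  for (i in seq_len(params$n_sequences)) {
    minis_mut <- mutate_dna(minis, params$minis_sub_rate,
                            params$minis_indel_rate)
    lm <- nchar(micro); lmm <- nchar(minis_mut)
    seqstr <- paste0(substr(backbone, 1, pos_micro), micro,
                     substr(backbone, pos_micro + 1, pos_minis), minis_mut,
                     substr(backbone, pos_minis + 1, params$backbone_length))
    id <- sprintf("seq%02d", i)
    new_ann <- data.frame(
      start = c(0L, iv("5.8S")[1] + lm, its2[1] + lm),
      end = c(its1[2] + lm, iv("5.8S")[2] + lm,
              its2[2] + lm + lmm),
      region = c("ITS1", "5.8S", "ITS2"), stringsAsFactors = FALSE)
    records[[i]] <- marker_record(id, seqstr, new_ann)
    truth[[i]] <- data.frame(
      seq_id = id,
      region = c("ITS1", "ITS2"),
      start = c(pos_micro, pos_minis + lm),
      end = c(pos_micro + lm, pos_minis + lm + lmm),
      consensus = c(params$micro_unit, params$minis_consensus),
      copies = c(params$micro_length / nchar(params$micro_unit),
                 params$minis_copies),
      planted = c(micro, minis), stringsAsFactors = FALSE)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Parameters for simulating grouped spore measurements
#'
#' Bivariate-Gaussian (length, width) observations grouped into collections:
#' each collection's mean is the global mean jittered by
#' `between_collection_sd`, and its observations are drawn around it with the
#' within-collection covariance `cov`.  Defaults reflect typical bolete
#' basidiospores (11.6 x 5.0 um) measured as at least 31 spores from one
#' basidiome in each of 19 collections.
#'
#' @param mean_length,mean_width true mean spore dimensions (um), > 0.
#' @param cov 2x2 symmetric positive semi-definite within-collection
#'   covariance (um^2).
#' @param between_collection_sd jitter sd of collection means (um); length 1
#'   or 2 (length, width).
#' @param n_per_collection,m_basidiomes,p_collections counts (>= 1):
#'   measurements per collection, basidiomes per collection, collections.
#' @param seed integer seed.
#' @return an object of class `spore_sim_params`.
#' @export
spore_sim_params <- function(mean_length = 11.6, mean_width = 5.0,
                             cov = diag(c(0.81, 0.09)),
                             between_collection_sd = c(0.6, 0.2),
                             n_per_collection = 31L, m_basidiomes = 1L,
                             p_collections = 19L, seed = 1L) {
  if (mean_length <= 0 || mean_width <= 0) stop("means must be positive")
  cov <- as.matrix(cov)
  if (!all(dim(cov) == 2L) || max(abs(cov - t(cov))) > 1e-8)
    stop("cov must be a symmetric 2x2 matrix")
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("cov must be positive semi-definite")
  counts <- c(n_per_collection, m_basidiomes, p_collections)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (length(between_collection_sd) == 1L)
    between_collection_sd <- rep(between_collection_sd, 2L)
  if (any(between_collection_sd < 0)) stop("jitter sd must be >= 0")
  structure(list(mean = c(mean_length, mean_width), cov = cov,
                 between_collection_sd = between_collection_sd,
                 n_per_collection = as.integer(n_per_collection),
                 m_basidiomes = as.integer(m_basidiomes),
                 p_collections = as.integer(p_collections),
                 seed = as.integer(seed)),
            class = "spore_sim_params")
}

#' Simulate grouped bivariate spore measurements
#'
#' Draws with non-positive length or width are redrawn (truncation by
#' rejection, preserving the Gaussian shape in the bulk).  Deterministic for
#' a fixed seed.
#'
#' @param params a [spore_sim_params()].
#' @return a [measurement_set()] data frame.
#' @export
simulate_spore_measurements <- function(params) {
  stopifnot(inherits(params, "spore_sim_params"))
  set.seed(params$seed)
  ev <- eigen(params$cov, symmetric = TRUE)
  S <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  rows <- vector("list", params$p_collections)
  for (ci in seq_len(params$p_collections)) {
    cid <- sprintf("coll%02d", ci)
    cmean <- params$mean + stats::rnorm(2) * params$between_collection_sd
    n <- params$n_per_collection
    pts <- matrix(stats::rnorm(2 * n), n, 2) %*% S +
      matrix(cmean, n, 2, byrow = TRUE)
    for (tries in 1:1000) {
      bad <- which(pts[, 1] <= 0 | pts[, 2] <= 0)
      if (length(bad) == 0L) break
      pts[bad, ] <- matrix(stats::rnorm(2 * length(bad)), length(bad), 2) %*%
        S + matrix(cmean, length(bad), 2, byrow = TRUE)
    }
    if (any(pts <= 0))
      stop("could not draw positive measurements; check means and covariance")
    rows[[ci]] <- data.frame(
      collection = cid,
      basidiome = sprintf("%s-b%d", cid,
                          1L + (seq_len(n) - 1L) %% params$m_basidiomes),
      structure = "basidiospores",
      length_um = pts[, 1], width_um = pts[, 2], stringsAsFactors = FALSE)
  }
  measurement_set(do.call(rbind, rows))
}
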