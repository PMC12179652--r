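#' Parse a support-annotated Newick genealogy
#'
#' Reads one locus's rooted tree whose internal node labels carry clade
#' supports: maximum-likelihood bootstrap (BS, percent) and/or Bayesian
#' posterior probability (PP), in one of three dialects: `"bs/pp"` (slash-
#' separated, the usual RAxML+MrBayes merge), `"bs"` (bare bootstrap) or
#' `"pp"` (bare posterior).  Labels may be absent: supports below the usual
#' reporting floor (BS <= 50, PP <= 0.8) are commonly collapsed, and an
#' absent value is treated as unknown rather than as conflict.
#'
#' @param newick a Newick string or the path of a file containing one tree.
#' @param support_convention one of `"bs/pp"`, `"bs"`, `"pp"`.
#' @param locus locus name.
#' @param linkage_group linkage-group identifier; loci inherited together
#'   (ITS and LSU) share one group.  Defaults to the locus name.
#' @param outgroup outgroup taxon; the tree is (re-)rooted on it when needed
#'   and the outgroup is excluded from candidate clades.
#' @return an object of class `genealogy`: the `ape` tree plus one record per
#'   internal clade (member taxa, BS, PP).
#' @examples
#' g <- parse_annotated_tree("((A:1,B:1)95/0.99:1,(C:1,OUT:1):1);",
#'                           outgroup = "OUT")
#' @export
parse_annotated_tree <- function(newick, support_convention = "bs/pp",
                                 locus = "locus1", linkage_group = locus,
                                 outgroup = NULL) {
  support_convention <- match.arg(support_convention, c("bs/pp", "bs", "pp"))
  tree <- if (grepl("\\(", newick)) ape::read.tree(text = newick)
          else ape::read.tree(file = newick)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate taxa in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label)
      stop("outgroup '", outgroup, "' not present in tree")
    n_tip <- length(tree$tip.label)
    og_parent <- tree$edge[tree$edge[, 2] == match(outgroup, tree$tip.label), 1]
    if (!ape::is.rooted(tree) || og_parent != n_tip + 1L)
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                        edgelabel = TRUE)
  }
  n_tip <- length(tree$tip.label)
  tree2 <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree2$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree2$tip.label[i]
  for (k in seq_len(nrow(tree2$edge))) {
    pa <- tree2$edge[k, 1]; ch <- tree2$edge[k, 2]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }

  parse_num <- function(txt, lo, hi, what, node) {
    if (is.na(txt) || txt %in% c("", "-", "NA", "ND", "Root")) return(NA_real_)
    v <- suppressWarnings(as.numeric(txt))
    if (is.na(v)) stop(sprintf("unparseable %s label '%s' at node %d",
                               what, txt, node))
    if (v < lo || v > hi)
      stop(sprintf("%s value %s at node %d outside [%s, %s]",
                   what, txt, node, lo, hi))
    v
  }
  labels <- tree2$node.label
  clades <- list()
  for (nd in (n_tip + 1L):(n_tip + tree2$Nnode)) {
    lab <- if (is.null(labels)) NA_character_ else labels[nd - n_tip]
    bs <- NA_real_; pp <- NA_real_
    if (!is.na(lab) && nzchar(lab)) {
      if (support_convention == "bs/pp") {
        parts <- strsplit(lab, "/", fixed = TRUE)[[1]]
        if (length(parts) > 2L)
          stop(sprintf("unparseable support label '%s' at node %d", lab, nd))
        bs <- parse_num(parts[1], 0, 100, "BS", nd)
        if (length(parts) == 2L) pp <- parse_num(parts[2], 0, 1, "PP", nd)
      } else if (support_convention == "bs") {
        bs <- parse_num(lab, 0, 100, "BS", nd)
      } else {
        pp <- parse_num(lab, 0, 1, "PP", nd)
      }
    }
    taxa <- sort(sets[[nd]])
    if (!is.null(outgroup) && outgroup %in% taxa) next  # complements of root path
    clades[[length(clades) + 1L]] <- list(taxa = taxa, bs = bs, pp = pp,
                                          node = nd)
  }
  ingroup <- sort(setdiff(tree$tip.label, outgroup))
  structure(list(locus = locus, linkage_group = linkage_group,
                 outgroup = outgroup, taxa = ingroup, tree = tree,
                 clades = clades),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("genealogy '%s' (linkage group %s): %d ingroup taxa, %d clades%s\n",
              x$locus, x$linkage_group, length(x$taxa), length(x$clades),
              if (is.null(x$outgroup)) "" else
                sprintf(", outgroup %s", x$outgroup)))
  invisible(x)
}

bs_band <- function(bs) {
  if (is.na(bs)) return(NA_character_)
  if (bs >= 90) "strong" else if (bs >= 70) "medium"
  else if (bs >= 50) "weak" else "unsupported"
}

pp_band <- function(pp) {
  if (is.na(pp)) return(NA_character_)
  if (pp >= 0.99) "strong" else if (pp >= 0.95) "medium"
  else if (pp >= 0.80) "weak" else "unsupported"
}

support_rank <- c(unsupported = 0L, weak = 1L, medium = 2L, strong = 3L)

#' Classify clade support from bootstrap and posterior probability
#'
#' A clade is strongly supported at BS >= 90 and PP >= 0.99, medium at
#' BS 70-89 and PP 0.95-0.98, weak at BS 50-69 and PP 0.80-0.94, otherwise
#' unsupported.  When both metrics are present the class is the weaker of the
#' two band assignments (the bands are conjunctions, so the weaker metric is
#' binding); a clade is well supported when it is strong or medium, i.e.
#' BS >= 70 and PP >= 0.95.  When only one metric is present the class comes
#' from that metric alone and the result carries a `single_metric` flag.
#'
#' @param bs bootstrap support in \[0, 100\] or `NA`.
#' @param pp posterior probability in \[0, 1\] or `NA`.
#' @return an object of class `support_class` with fields `class` (one of
#'   `"strong"`, `"medium"`, `"weak"`, `"unsupported"`), `well_supported`,
#'   and `single_metric`.
#' @examples
#' classify_support(90, 0.99)   # strong
#' classify_support(70, 0.95)   # medium, well supported
#' classify_support(95, 0.96)   # medium: the weaker metric is binding
#' @export
classify_support <- function(bs = NA, pp = NA) {
  if (!is.na(bs) && (bs < 0 || bs > 100)) stop("BS outside [0, 100]")
  if (!is.na(pp) && (pp < 0 || pp > 1)) stop("PP outside [0, 1]")
  bands <- c(bs_band(bs), pp_band(pp))
  present <- bands[!is.na(bands)]
  cls <- if (length(present) == 0L) "unsupported"
         else names(support_rank)[min(support_rank[present]) + 1L]
  structure(list(class = cls,
                 well_supported = cls %in% c("strong", "medium"),
                 single_metric = length(present) < 2L,
                 bs = bs, pp = pp),
            class = "support_class")
}

#' @export
print.support_class <- function(x, ...) {
  cat(sprintf("%s%s%s (BS = %s, PP = %s)\n", x$class,
              if (x$well_supported) ", well supported" else "",
              if (x$single_metric) ", single metric" else "",
              ifelse(is.na(x$bs), "-", x$bs), ifelse(is.na(x$pp), "-", x$pp)))
  invisible(x)
}

clade_is_well_supported <- function(clade) {
  classify_support(clade$bs, clade$pp)$well_supported
}

#' Test a candidate clade against one genealogy
#'
#' The candidate taxon set is first restricted to the genealogy's own taxa.
#' The verdict is `"uninformative"` when fewer than two taxa remain or when
#' every taxon of the genealogy remains (nothing left outside to contrast
#' with); `"supported"` when the restriction is a clade of the genealogy;
#' `"contradicted"` when some well-supported clade of the genealogy overlaps
#' the restriction without either containing the other (unsupported conflicts
#' do not count: a poorly resolved tree contradicts nothing); otherwise
#' `"compatible"`.
#'
#' @param clade_taxa character vector of taxa.
#' @param genealogy a [parse_annotated_tree()] result.
#' @return one of `"supported"`, `"compatible"`, `"contradicted"`,
#'   `"uninformative"`.
#' @export
assess_clade_against_genealogy <- function(clade_taxa, genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  rest <- intersect(clade_taxa, genealogy$taxa)
  if (length(rest) < 2L) return("uninformative")
  if (length(rest) == length(genealogy$taxa)) return("uninformative")
  rest <- sort(rest)
  for (cl in genealogy$clades)
    if (identical(cl$taxa, rest)) return("supported")
  for (cl in genealogy$clades) {
    if (!clade_is_well_supported(cl)) next
    ov <- length(intersect(cl$taxa, rest))
    if (ov > 0L && ov < length(cl$taxa) && ov < length(rest))
      return("contradicted")
  }
  "compatible"
}

taxa_key <- function(taxa) paste(sort(taxa), collapse = "\x1f")

#' Delimit species by genealogical concordance (GCPSR)
#'
#' Applies the genealogical concordance criterion to a set of single-locus
#' genealogies: a clade is recognised as an independent evolutionary lineage
#' when it is well supported (BS >= 70 and PP >= 0.95) in at least one
#' single-locus genealogy and not contradicted by any other.  Lineages are
#' reported at the maximal accepted clade; mutually incompatible accepted
#' clades are resolved by the number of independently inherited supporting
#' linkage groups, then the minimum support class, then the smaller clade.
#' A lineage whose supporting evidence all comes from a single linkage group
#' (one locus, or loci inherited together such as ITS and LSU) is classed as
#' a putative phylogenetic species rather than a phylogenetic species.  Taxa
#' belonging to no accepted lineage are listed as unassigned.  When a
#' concatenated multilocus tree is supplied, lineages it contradicts are
#' flagged in the report but not removed.
#'
#' @param genealogies list of [parse_annotated_tree()] results.
#' @param multilocus_tree optional `genealogy` built from the concatenated
#'   multilocus analysis.
#' @return an object of class `delimitation` with elements `lineages` (each
#'   with `taxa`, `status`, `supporting`, `flags`, `substructure`),
#'   `unassigned`, and a `candidates` table recording every evaluated clade.
#' @export
delimit_species <- function(genealogies, multilocus_tree = NULL) {
  if (inherits(genealogies, "genealogy")) genealogies <- list(genealogies)
  stopifnot(length(genealogies) >= 1L,
            all(vapply(genealogies, inherits, TRUE, "genealogy")))
  locs <- vapply(genealogies, `[[`, "", "locus")
  genealogies <- genealogies[order(locs)]
  if (length(genealogies) > 1L) {
    shared <- utils::combn(length(genealogies), 2, function(ij)
      length(intersect(genealogies[[ij[1]]]$taxa, genealogies[[ij[2]]]$taxa)))
    if (all(shared == 0L))
      stop("no basis for concordance: the genealogies share no taxa")
  }
  U <- sort(unique(unlist(lapply(genealogies, `[[`, "taxa"))))

  # candidate clades: well-supported, at least two taxa, not the whole ingroup
  cand <- new.env(parent = emptyenv())
  for (g in genealogies) {
    for (cl in g$clades) {
      if (length(cl$taxa) < 2L || length(cl$taxa) >= length(U)) next
      if (!clade_is_well_supported(cl)) next
      key <- taxa_key(cl$taxa)
      if (is.null(cand[[key]])) cand[[key]] <- list(taxa = cl$taxa)
    }
  }
  keys <- sort(ls(cand))
  if (length(keys) == 0L) {
    return(structure(list(lineages = list(), unassigned = U,
                          candidates = data.frame(),
                          loci = vapply(genealogies, `[[`, "", "locus")),
                     class = "delimitation"))
  }

  evaluate <- function(taxa) {
    supporting <- list()
    contradicting <- character(0)
    for (g in genealogies) {
      verdict <- assess_clade_against_genealogy(taxa, g)
      if (verdict == "contradicted") {
        contradicting <- c(contradicting, g$locus)
      } else if (verdict == "supported") {
        rest <- sort(intersect(taxa, g$taxa))
        for (cl in g$clades) {
          if (identical(cl$taxa, rest) && clade_is_well_supported(cl)) {
            sc <- classify_support(cl$bs, cl$pp)
            supporting[[length(supporting) + 1L]] <-
              list(locus = g$locus, linkage_group = g$linkage_group,
                   bs = cl$bs, pp = cl$pp, class = sc$class,
                   rank = support_rank[[sc$class]],
                   single_metric = sc$single_metric)
            break
          }
        }
      }
    }
    list(supporting = supporting, contradicting = contradicting)
  }

  info <- lapply(keys, function(k) {
    taxa <- cand[[k]]$taxa
    ev <- evaluate(taxa)
    groups <- unique(vapply(ev$supporting, `[[`, "", "linkage_group"))
    list(key = k, taxa = taxa, supporting = ev$supporting,
         contradicting = ev$contradicting,
         n_groups = length(groups),
         min_rank = if (length(ev$supporting) == 0L) 0L
                    else min(vapply(ev$supporting, `[[`, 0L, "rank")),
         accepted = length(ev$contradicting) == 0L &&
                    length(ev$supporting) >= 1L)
  })

  acc <- Filter(function(x) x$accepted, info)
  # conflict resolution order: more independent groups, stronger minimum
  # support, smaller clade, then lexicographic for full determinism
  ord <- order(-vapply(acc, `[[`, 0L, "n_groups"),
               -vapply(acc, `[[`, 0L, "min_rank"),
               vapply(acc, function(x) length(x$taxa), 0L),
               vapply(acc, `[[`, "", "key"))
  acc <- acc[ord]
  kept <- list()
  for (x in acc) {
    compatible <- all(vapply(kept, function(k) {
      ov <- length(intersect(k$taxa, x$taxa))
      ov == 0L || ov == length(k$taxa) || ov == length(x$taxa)
    }, logical(1)))
    if (compatible) kept[[length(kept) + 1L]] <- x
  }
  is_maximal <- vapply(kept, function(x) !any(vapply(kept, function(k)
    length(k$taxa) > length(x$taxa) && all(x$taxa %in% k$taxa),
    logical(1))), logical(1))
  maximal <- kept[is_maximal]
  nested <- kept[!is_maximal]

  lineages <- lapply(maximal, function(x) {
    flags <- character(0)
    if (any(vapply(x$supporting, `[[`, TRUE, "single_metric")))
      flags <- c(flags, "single_metric_support")
    if (!is.null(multilocus_tree) &&
        assess_clade_against_genealogy(x$taxa, multilocus_tree) ==
          "contradicted")
      flags <- c(flags, "conflicts_with_multilocus_tree")
    sub <- Filter(function(k) all(k$taxa %in% x$taxa) &&
                    length(k$taxa) < length(x$taxa), nested)
    list(taxa = x$taxa,
         status = if (x$n_groups > 1L) "phylogenetic_species"
                  else "putative_species",
         supporting = x$supporting,
         supporting_loci = vapply(x$supporting, `[[`, "", "locus"),
         linkage_groups = unique(vapply(x$supporting, `[[`, "",
                                        "linkage_group")),
         flags = flags,
         substructure = lapply(sub, `[[`, "taxa"))
  })
  lineages <- lineages[order(-vapply(lineages, function(l) length(l$taxa), 0L),
                             vapply(lineages, function(l) taxa_key(l$taxa),
                                    ""))]
  unassigned <- sort(setdiff(U, unlist(lapply(lineages, `[[`, "taxa"))))

  cand_df <- data.frame(
    taxa = vapply(info, function(x) paste(x$taxa, collapse = ","), ""),
    size = vapply(info, function(x) length(x$taxa), 0L),
    supporting_loci = vapply(info, function(x)
      paste(vapply(x$supporting, `[[`, "", "locus"), collapse = ","), ""),
    linkage_groups = vapply(info, `[[`, 0L, "n_groups"),
    contradicted_by = vapply(info, function(x)
      paste(x$contradicting, collapse = ","), ""),
    accepted = vapply(info, `[[`, TRUE, "accepted"),
    stringsAsFactors = FALSE)

  structure(list(lineages = lineages, unassigned = unassigned,
                 candidates = cand_df,
                 loci = sort(vapply(genealogies, `[[`, "", "locus"))),
            class = "delimitation")
}

#' @export
summary.delimitation <- function(object, ...) {
  st <- vapply(object$lineages, `[[`, "", "status")
  out <- list(n_lineages = length(object$lineages),
              n_phylogenetic = sum(st == "phylogenetic_species"),
              n_putative = sum(st == "putative_species"),
              n_unassigned = length(object$unassigned))
  class(out) <- "summary.delimitation"
  out
}

#' @export
print.summary.delimitation <- function(x, ...) {
  cat(sprintf("GCPSR delimitation: %d lineage(s) \u2014 %d phylogenetic, %d putative; %d unassigned taxa\n",
              x$n_lineages, x$n_phylogenetic, x$n_putative, x$n_unassigned))
  invisible(x)
}

#' @export
print.delimitation <- function(x, ...) {
  print(summary(x))
  for (i in seq_along(x$lineages)) {
    l <- x$lineages[[i]]
    cat(sprintf("  L%02d %-22s [%s] %s%s\n", i, l$status,
                paste(l$supporting_loci, collapse = ","),
                paste(l$taxa, collapse = " "),
                if (length(l$flags)) paste0("  <", paste(l$flags,
                                                         collapse = ";"), ">")
                else ""))
  }
  if (length(x$unassigned))
    cat("  unassigned:", paste(x$unassigned, collapse = " "), "\n")
  invisible(x)
}

#' Count parsimony-informative sites in an alignment
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' nucleotide states (A, C, G, T) each occur in at least two sequences; gaps
#' and ambiguity codes are treated as missing data.
#'
#' @param alignment character vector of equal-length aligned sequences, or a
#'   character matrix of single characters (rows = sequences).
#' @return a list with `count`, `n_columns` and `fraction`
#'   (`count / n_columns`).
#' @examples
#' count_parsimony_informative(c("AATT", "AATT", "TTAA", "TTAA"))
#' @export
count_parsimony_informative <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    stopifnot(is.character(alignment))
    if (length(unique(nchar(alignment))) != 1L)
      stop("ragged alignment: sequences differ in length")
    m <- toupper(do.call(rbind, strsplit(alignment, "")))
  }
  if (ncol(m) == 0L) return(list(count = 0L, n_columns = 0L, fraction = NaN))
  informative <- apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 4L) return(FALSE)
    sum(table(col) >= 2L) >= 2L
  })
  count <- sum(informative)
  list(count = as.integer(count), n_columns = ncol(m),
       fraction = count / ncol(m))
}
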