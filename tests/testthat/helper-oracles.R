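# shared fixtures and small independent oracles

table1_motifs <- function() {
  utils::read.delim(system.file("extdata", "table1_motifs.tsv",
                                package = "boletax"),
                    stringsAsFactors = FALSE)
}

motif_of <- function(species, weights = "2-7-7", region = "ITS2") {
  m <- table1_motifs()
  m$consensus[m$species == species & m$weights == weights &
                m$region == region][1]
}

# random flank that contains no reportable array of its own and whose
# junction bases (G) cannot extend an adjacent A/C-phase array
nonrepetitive_flank <- function(n, seed) {
  for (sub in 0:99) {
    set.seed(seed + 101L * sub)
    x <- sample(c("A", "C", "G", "T"), n, TRUE)
    x[c(1L, n)] <- "G"
    fl <- paste(x, collapse = "")
    if (nrow(detect_tandem_repeats(fl)) == 0L) return(fl)
  }
  stop("could not construct a non-repetitive flank")
}

# exhaustive enumeration: probability that `target` ends up as an exact unit
# under uniform random sequential pair-joining of the given starting units
mono_prob_enum <- function(units, target) {
  target <- sort(target)
  if (any(vapply(units, function(u) identical(sort(u), target), logical(1))))
    return(1)
  m <- length(units)
  if (m == 1L) return(0)
  prs <- utils::combn(m, 2)
  mean(vapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    merged <- c(units[-c(i, j)], list(c(units[[i]], units[[j]])))
    mono_prob_enum(merged, target)
  }, numeric(1)))
}

# naive per-column parsimony-informative rule, written independently
pi_oracle <- function(rows) {
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  sum(apply(m, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    counts <- table(col)
    sum(counts >= 2L) >= 2L
  }))
}

# edit distance between motifs, minimised over rotations of b
rotational_edit_dist <- function(a, b) {
  p <- nchar(b)
  bb <- paste0(b, b)
  min(vapply(seq_len(p) - 1L, function(k)
    utils::adist(a, substr(bb, k + 1L, k + p))[1, 1], numeric(1)))
}

# is `taxa` monophyletic in a genealogy?
is_clade_in <- function(taxa, genealogy) {
  taxa <- sort(taxa)
  any(vapply(genealogy$clades, function(cl) identical(cl$taxa, taxa),
             logical(1)))
}

make_partition <- function(n_species, n_per) {
  sp <- sprintf("sp%d", seq_len(n_species))
  stats::setNames(rep(sp, each = n_per),
                  paste0(rep(sp, each = n_per), "_", seq_len(n_per)))
}
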