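test_that("annotated Newick parsing extracts clades and BS/PP labels", {
  g <- parse_annotated_tree("((A:1,B:1)95/0.99:1,(C:1,OUT:1):1);",
                            outgroup = "OUT")
  ab <- Filter(function(cl) identical(cl$taxa, c("A", "B")), g$clades)
  expect_equal(length(ab), 1L)
  expect_equal(ab[[1]]$bs, 95)
  expect_equal(ab[[1]]$pp, 0.99)
  expect_equal(g$taxa, c("A", "B", "C"))
  # unlabeled internal node: clade enumerated, supports absent
  g2 <- parse_annotated_tree("(((A,B),C)90/0.99,OUT);", outgroup = "OUT")
  abc <- Filter(function(cl) identical(cl$taxa, c("A", "B")), g2$clades)
  expect_true(is.na(abc[[1]]$bs) && is.na(abc[[1]]$pp))
  expect_error(parse_annotated_tree("((A,A),B);"), "duplicate")
  expect_error(parse_annotated_tree("((A,B)xx/0.5,(C,OUT));", outgroup = "OUT"),
               "unparseable")
  expect_error(parse_annotated_tree("((A,B)95/1.2,(C,OUT));", outgroup = "OUT"),
               "outside")
  # bare conventions
  gb <- parse_annotated_tree("((A,B)88,(C,OUT));", "bs", outgroup = "OUT")
  expect_equal(Filter(function(cl) identical(cl$taxa, c("A", "B")),
                      gb$clades)[[1]]$bs, 88)
})

test_that("support bands and the weaker-of-two rule classify as specified", {
  expect_equal(classify_support(90, 0.99)$class, "strong")
  m <- classify_support(70, 0.95)
  expect_equal(m$class, "medium")
  expect_true(m$well_supported)
  expect_equal(classify_support(95, 0.96)$class, "medium")  # weaker metric binds
  expect_equal(classify_support(69, 0.99)$class, "weak")
  expect_equal(classify_support(50, 0.80)$class, "weak")
  expect_equal(classify_support(49, 0.99)$class, "unsupported")
  expect_false(classify_support(89, 0.94)$well_supported)
  s <- classify_support(95, NA)
  expect_equal(s$class, "strong")
  expect_true(s$single_metric)
  expect_false(classify_support(NA, NA)$well_supported)
  expect_error(classify_support(120, 0.5), "outside")
  expect_error(classify_support(80, 1.5), "outside")
})

test_that("clade assessment distinguishes supported, contradicted, compatible, uninformative", {
  g1 <- parse_annotated_tree("((A,B)100/1.00,(C,OUT));", outgroup = "OUT")
  expect_equal(assess_clade_against_genealogy(c("A", "B"), g1), "supported")
  g2 <- parse_annotated_tree("(((A,C)99/1.00,B),OUT);", outgroup = "OUT")
  expect_equal(assess_clade_against_genealogy(c("A", "B"), g2), "contradicted")
  # unsupported conflicting topology counts as compatible
  g3 <- parse_annotated_tree("(((A,C),B),OUT);", outgroup = "OUT")
  expect_equal(assess_clade_against_genealogy(c("A", "B"), g3), "compatible")
  # fewer than two shared taxa, or nothing outside, is uninformative
  g4 <- parse_annotated_tree("((A,D)90/0.99,OUT);", outgroup = "OUT")
  expect_equal(assess_clade_against_genealogy(c("A", "B"), g4), "uninformative")
  expect_equal(assess_clade_against_genealogy(c("A", "B", "C"), g1),
               "uninformative")
})

test_that("three concordant loci recover three species; candidates enumerate cleanly", {
  part <- make_partition(3, 4)
  sim <- simulate_genealogy_set(genealogy_sim_params(part, seed = 101))
  d <- delimit_species(sim$genealogies)
  s <- summary(d)
  expect_equal(s$n_lineages, 3L)
  expect_equal(s$n_phylogenetic, 3L)
  expect_equal(s$n_putative, 0L)
  expect_equal(s$n_unassigned, 0L)
  got <- lapply(d$lineages, `[[`, "taxa")
  want <- unname(split(names(part), part))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, function(x) paste(sort(x), collapse = ","), ""))
  # every accepted candidate must be one of the true species clades or nested in one
  acc <- d$candidates[d$candidates$accepted, ]
  for (tx in strsplit(acc$taxa, ",")) {
    expect_true(any(vapply(want, function(w) all(tx %in% w), logical(1))))
  }
})

test_that("a species confined to the linked ITS-LSU pair is putative, others unchanged", {
  part <- make_partition(4, 3)
  d_members <- names(part)[part == "sp4"]
  masking <- list(tef1 = d_members, rpb2 = d_members)
  sim <- simulate_genealogy_set(genealogy_sim_params(part, masking = masking,
                                                     seed = 77))
  d <- delimit_species(sim$genealogies)
  st <- stats::setNames(vapply(d$lineages, `[[`, "", "status"),
                        vapply(d$lineages, function(l)
                          paste(sort(l$taxa), collapse = ","), ""))
  key4 <- paste(sort(d_members), collapse = ",")
  expect_equal(unname(st[key4]), "putative_species")
  expect_equal(sum(st == "phylogenetic_species"), 3L)
  expect_equal(length(d$unassigned), 0L)
  lg <- d$lineages[[which(names(st) == key4)]]$linkage_groups
  expect_equal(lg, "ITS-LSU")
})

test_that("a single unsupported genealogy delimits nothing", {
  g <- parse_annotated_tree("(((A,B),(C,D)),OUT);", outgroup = "OUT")
  d <- delimit_species(list(g))
  expect_equal(length(d$lineages), 0L)
  expect_setequal(d$unassigned, c("A", "B", "C", "D"))
})

test_that("delimitation is invariant to genealogy order and taxon order in Newick", {
  nwk_a <- c("((A,B)95/0.99,((C,D)97/1.00,OUT));",
             "(((D,C)90/0.99,(B,A)99/1.00),OUT);")
  nwk_b <- rev(c("((B,A)95/0.99,((D,C)97/1.00,OUT));",
                 "(((C,D)90/0.99,(A,B)99/1.00),OUT);"))
  mk <- function(nwks) {
    list(parse_annotated_tree(nwks[1], locus = "ITS",
                              linkage_group = "ITS-LSU", outgroup = "OUT"),
         parse_annotated_tree(nwks[2], locus = "tef1", outgroup = "OUT"))
  }
  d1 <- delimit_species(mk(nwk_a))
  d2 <- delimit_species(mk(nwk_b))
  lin <- function(d) lapply(d$lineages, function(l)
    list(taxa = l$taxa, status = l$status))
  expect_identical(lin(d1), lin(d2))
  expect_equal(summary(d1)$n_phylogenetic, 2L)
})

test_that("disjoint genealogies give no basis for concordance", {
  g1 <- parse_annotated_tree("((A,B)99/1.00,OUT);", locus = "l1",
                             outgroup = "OUT")
  g2 <- parse_annotated_tree("((X,Y)99/1.00,OUT);", locus = "l2",
                             outgroup = "OUT")
  expect_error(delimit_species(list(g1, g2)), "no basis for concordance")
})

test_that("a multilocus tree flags, but does not remove, conflicting lineages", {
  gens <- list(
    parse_annotated_tree("(((A,B)99/1.00,(C,D)),OUT);", locus = "ITS",
                         linkage_group = "ITS-LSU", outgroup = "OUT"))
  ml <- parse_annotated_tree("(((A,C)99/1.00,(B,D)),OUT);",
                             locus = "multilocus", outgroup = "OUT")
  d <- delimit_species(gens, multilocus_tree = ml)
  expect_equal(length(d$lineages), 1L)
  expect_true("conflicts_with_multilocus_tree" %in% d$lineages[[1]]$flags)
})

test_that("parsimony-informative counting follows the two-states-twice rule", {
  toy <- c("AAAAGC",
           "AAATGC",
           "TATAGA",
           "TA-TGA")
  # hand count: col1 A,A,T,T informative; col2 all A not; col3 A,A,T,- not;
  # col4 A,T,A,T informative; col5 all G not; col6 C,C,A,A informative
  r <- count_parsimony_informative(toy)
  expect_equal(r$count, 3L)
  expect_equal(r$n_columns, 6L)
  expect_equal(r$count, pi_oracle(toy))
  same <- rep("ACGTACGT", 4)
  expect_equal(count_parsimony_informative(same)$count, 0L)
  expect_equal(count_parsimony_informative(same)$fraction, 0)
  expect_error(count_parsimony_informative(c("ACGT", "ACG")), "ragged")
})

test_that("gaps and ambiguity codes are missing data for informativeness", {
  expect_equal(count_parsimony_informative(c("A", "-", "T", "T"))$count, 0L)
  expect_equal(count_parsimony_informative(c("A", "A", "T", "T"))$count, 1L)
  expect_equal(count_parsimony_informative(c("A", "N", "T", "T"))$count, 0L)
  # R treated as a state would make this informative; as missing it is not
  expect_equal(count_parsimony_informative(c("R", "R", "A", "T", "T"))$count, 0L)
})

test_that("chance monophyly under full discordance matches the enumeration oracle", {
  # 2 species x 2 specimens scatter to 4 singleton units; the enumeration
  # oracle gives the exact probability that a species pair coalesces directly
  part <- make_partition(2, 2)
  units <- lapply(names(part), function(x) x)
  target <- names(part)[part == "sp1"]
  p_exp <- mono_prob_enum(units, target)
  expect_equal(p_exp, 2 / 9)
  n_hit <- 0L; n_tot <- 0L
  for (seed in 1:200) {
    sim <- simulate_genealogy_set(genealogy_sim_params(
      part, concordance_prob = 0, seed = seed))
    for (g in sim$genealogies) {
      n_tot <- n_tot + 1L
      if (is_clade_in(target, g)) n_hit <- n_hit + 1L
    }
  }
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(n_hit / n_tot - p_exp), 3 * se + 1e-9)
})
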