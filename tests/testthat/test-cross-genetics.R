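test_that("gamete enumeration follows Mendelian expectations", {
  # XO male carrying an X-linked null: half the gametes carry the null X,
  # half carry no X
  male <- set_null(wt_genotype("pacificus", "male"), "eud-1")
  g <- gametes(male)
  x_bearing <- vapply(g, `[[`, logical(1), "x_bearing")
  probs <- vapply(g, `[[`, numeric(1), "prob")
  expect_equal(sum(probs), 1)
  expect_equal(sum(probs[x_bearing]), 0.5)
  carried <- unique(vapply(g[x_bearing], function(x) x$alleles[["eud-1"]],
                           character(1)))
  expect_identical(carried, "null")

  # fully homozygous XX parent: a single gamete class
  expect_length(gametes(wt_genotype("pacificus")), 1L)

  # XX heterozygote at one autosomal locus: two classes at 1/2 each
  het <- set_null(wt_genotype("pacificus"), "seud-1", copies = 1)
  gh <- gametes(het)
  expect_length(gh, 2L)
  expect_equal(sort(vapply(gh, `[[`, numeric(1), "prob")), c(0.5, 0.5))
})

test_that("within-species wild-type cross yields 2:2 females and 1:2 males", {
  off <- cross(wt_genotype("pacificus"), wt_genotype("pacificus", "male"))
  tab <- offspring_dosages(off)
  expect_equal(sum(tab$prob), 1)
  expect_identical(tab$ratio[tab$sex == "hermaphrodite"], "2:2")
  expect_identical(tab$ratio[tab$sex == "male"], "1:2")
  expect_equal(tab$prob, c(0.5, 0.5))
})

test_that("a mutant seud-1 father transmits the null to all F1, males take the maternal X", {
  father <- set_null(wt_genotype("pacificus", "male"), "seud-1")
  off <- cross(wt_genotype("pacificus"), father)
  for (o in off) {
    expect_identical(sum(o$genotype$alleles[["seud-1"]] == "null"), 1L)
    if (o$genotype$sex == "male")
      expect_identical(o$genotype$alleles[["eud-1"]], "functional")
  }
  expect_equal(sum(vapply(off, `[[`, numeric(1), "prob")), 1)
})

test_that("functional dosage sums paralogs and respects hemizygosity", {
  expect_identical(dosage_ratio(wt_genotype("pacificus"))$ratio, "2:2")
  expect_identical(dosage_ratio(wt_genotype("exspectatus"))$ratio, "2:4")
  expect_identical(dosage_ratio(wt_genotype("pacificus", "male"))$ratio, "1:2")
  # interspecies F1 female: Ppa mother x Pex father
  off <- cross(wt_genotype("pacificus"), wt_genotype("exspectatus", "male"))
  females <- Filter(function(o) o$genotype$sex == "hermaphrodite", off)
  expect_identical(unique(vapply(females, function(o)
    dosage_ratio(o$genotype)$ratio, character(1))), "2:3")
})

test_that("the hybrid panel reproduces the four printed F1-female dosage classes", {
  pan <- enumerate_panel(hybrid_panel_designs(), females_only = TRUE)
  expect_setequal(pan$ratio, c("2:3", "1:3", "2:2", "1:2"))
  expect_identical(pan$ratio[pan$design == "wt_hybrid"], "2:3")
  expect_identical(pan$ratio[pan$design == "double_mutant_hybrid"], "1:2")
  expect_equal(as.numeric(tapply(pan$prob, pan$design, sum)), rep(0.5, 4))
  expect_identical(nrow(enumerate_panel(list())), 0L)
})

test_that("the S=1, E=2 intraspecific class is flagged almost all-Eu", {
  # eud-1 wild type, seud-1 heterozygous null mother selfed
  het <- set_null(wt_genotype("pacificus"), "seud-1", copies = 1)
  tab <- offspring_dosages(cross(het, het))
  cls <- tab[tab$E == 2 & tab$S == 1, ]
  expect_identical(nrow(cls), 1L)
  expect_identical(cls$regime, "almost all-Eu")
  # and seud-1 homozygous nulls are all-Eu, eud-1 nulls all-St
  expect_identical(tab$regime[tab$S == 0], "all-Eu")
  eud_null <- set_null(wt_genotype("pacificus"), "eud-1")
  tab2 <- offspring_dosages(cross(eud_null, eud_null))
  expect_identical(unique(tab2$regime[tab2$E == 0]), "all-St")
})

test_that("reciprocal crosses share autosomal dosages and differ in X transmission", {
  ppa_h <- set_null(wt_genotype("pacificus"), "seud-1", copies = 1)
  pex_m <- wt_genotype("exspectatus", "male")
  pex_h <- wt_genotype("exspectatus")
  ppa_m <- set_null(wt_genotype("pacificus", "male"), "seud-1", copies = 1)
  ab <- offspring_dosages(cross(ppa_h, pex_m))
  ba <- offspring_dosages(cross(pex_h, ppa_m))
  s_dist <- function(tab) {
    agg <- stats::aggregate(prob ~ S, data = tab, FUN = sum)
    agg[order(agg$S), ]
  }
  expect_equal(s_dist(ab), s_dist(ba))
})

test_that("offspring dosage is additive over parental gamete contributions", {
  mother <- set_null(wt_genotype("pacificus"), "seud-1", copies = 1)
  father <- wt_genotype("exspectatus", "male")
  mg <- gametes(mother); fg <- gametes(father)
  count_fun <- function(alleles) sum(alleles == "functional", na.rm = TRUE)
  off <- cross(mother, father)
  # every offspring class must decompose as one maternal + one paternal gamete
  for (o in off) {
    total <- sum(unlist(o$genotype$alleles) == "functional")
    decomposable <- any(vapply(mg, function(m) any(vapply(fg, function(f) {
      if (o$genotype$sex == "male" && f$x_bearing) return(FALSE)
      if (o$genotype$sex == "hermaphrodite" && !f$x_bearing) return(FALSE)
      count_fun(unlist(m$alleles)) + count_fun(unlist(f$alleles)) == total
    }, logical(1))), logical(1)))
    expect_true(decomposable)
  }
})

test_that("Monte-Carlo sampling converges to the enumerated distribution", {
  mother <- set_null(wt_genotype("pacificus"), "seud-1", copies = 1)
  father <- set_null(wt_genotype("pacificus", "male"), "eud-1")
  tab <- offspring_dosages(cross(mother, father))
  set.seed(99)
  draws <- sample_cross(mother, father, 10000)
  key <- paste(draws$sex, draws$ratio)
  expected_key <- paste(tab$sex, tab$ratio)
  counts <- table(factor(key, levels = expected_key))
  gof <- stats::chisq.test(counts, p = tab$prob)
  expect_gt(gof$p.value, 0.001)
})

test_that("linked paralogs co-transmit while unlinked ones assort freely", {
  # Pex parent heterozygous at both seud-1 duplicates in repulsion
  g <- wt_genotype("exspectatus")
  g$alleles[["seud-1"]] <- c("null", "functional")
  g$alleles[["seud-1.2"]] <- c("functional", "null")
  free <- gametes(g)
  expect_length(free, 4L)
  linked <- gametes(g, linked = list(c("seud-1", "seud-1.2")))
  expect_length(linked, 2L)
  combos <- vapply(linked, function(x)
    paste(x$alleles[["seud-1"]], x$alleles[["seud-1.2"]]), character(1))
  expect_setequal(combos, c("null functional", "functional null"))
})

test_that("complementation partitioning recovers planted groups", {
  m <- gen_complementation_matrix(c(2L, 2L, 3L))
  groups <- complementation_groups(m)
  expect_length(groups, 3L)
  expect_identical(sort(unname(lengths(groups))), c(2L, 2L, 3L))
  # the designated two-allele pair stays together
  expect_true(all(c("mutant_1", "mutant_2") %in%
                    groups[[attr(m, "truth")[["mutant_1"]]]]))
  # all-complementing mutants are singletons
  singletons <- complementation_matrix(
    diag(TRUE, 7) |> (\(x) {dimnames(x) <- list(paste0("m", 1:7),
                                                paste0("m", 1:7)); x})())
  expect_length(complementation_groups(singletons), 7L)
})

test_that("intransitive complementation data raise an informative error", {
  fails <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"),
                                               c("A", "B", "C")))
  diag(fails) <- TRUE
  fails["A", "B"] <- fails["B", "A"] <- TRUE
  fails["B", "C"] <- fails["C", "B"] <- TRUE  # A ~ B, B ~ C, A complements C
  expect_error(complementation_groups(complementation_matrix(fails)),
               "intransitive.*A ~ B ~ C")
})

test_that("complementation matrices round-trip through TSV", {
  m <- gen_complementation_matrix(c(2L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_complementation_tsv(m, path)
  back <- read_complementation_tsv(path)
  expect_identical(unclass(back)[, ], unclass(m)[, ])
})

test_that("invalid genotypes and matrices are rejected", {
  expect_error(genotype("male", list(`eud-1` = c("functional", "functional"),
                                     `seud-1` = rep("functional", 2),
                                     `seud-1.2` = rep("absent", 2))),
               "1 allele slot")
  bad <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(complementation_matrix(bad), "symmetric")
})
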