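ALLELE_STATES <- c("functional", "null", "absent")

#' Default locus set of the polyphenism switch
#'
#' Three loci: X-linked *eud-1*; autosomal *seud-1* (present in both
#' species); and the autosomal duplicate *seud-1.2*, present only on
#' *P. exspectatus* haplotypes (its slots are `absent` on *P. pacificus*
#' haplotypes). The duplicate is grouped with *seud-1* in the `seud-1`
#' family for dosage summation, and both duplicates are treated as fully
#' functional.
#'
#' @return Named list of locus definitions (`linkage`, `family`).
#' @export
switch_loci <- function() {
  list(
    `eud-1`   = list(linkage = "X", family = "eud-1"),
    `seud-1`  = list(linkage = "autosomal", family = "seud-1"),
    `seud-1.2` = list(linkage = "autosomal", family = "seud-1")
  )
}

#' Construct a genotype
#'
#' Allele states are `functional`, `null` or `absent` (species lacking a
#' paralog). Under XX/XO sex determination, X-linked loci have two allele
#' slots in hermaphrodites/females and one in males; autosomal loci always
#' have two (each paralog counted as its own locus).
#'
#' @param sex `"hermaphrodite"` (XX; females are equivalent) or `"male"` (XO).
#' @param alleles Named list: locus -> character vector of allele states.
#' @param loci Locus definitions, as from [switch_loci()].
#' @return A `genotype` object.
#' @export
genotype <- function(sex = c("hermaphrodite", "male"), alleles,
                     loci = switch_loci()) {
  sex <- match.arg(sex)
  if (!setequal(names(alleles), names(loci)))
    stop("alleles must name exactly the loci: ",
         paste(names(loci), collapse = ", "))
  for (nm in names(loci)) {
    a <- alleles[[nm]]
    if (!all(a %in% ALLELE_STATES))
      stop("invalid allele state(s) at ", nm)
    want <- if (loci[[nm]]$linkage == "X" && sex == "male") 1L else 2L
    if (length(a) != want)
      stop(nm, " needs ", want, " allele slot(s) for a ", sex)
  }
  structure(list(sex = sex, alleles = alleles[names(loci)], loci = loci),
            class = "genotype")
}

#' Wild-type genotypes of the two species
#'
#' @param species `"pacificus"` (single *seud-1* copy per haplotype) or
#'   `"exspectatus"` (both *seud-1* duplicates).
#' @param sex Passed to [genotype()].
#' @return A `genotype`.
#' @export
wt_genotype <- function(species = c("pacificus", "exspectatus"),
                        sex = "hermaphrodite") {
  species <- match.arg(species)
  nx <- if (sex == "male") 1L else 2L
  dup <- if (species == "exspectatus") "functional" else "absent"
  genotype(sex, list(
    `eud-1` = rep("functional", nx),
    `seud-1` = rep("functional", 2L),
    `seud-1.2` = rep(dup, 2L)
  ))
}

#' Set null alleles at a locus
#'
#' Replaces the first `copies` non-absent allele slots with `null`
#' (homozygous/hemizygous mutants by default).
#'
#' @param g A `genotype`.
#' @param locus Locus name.
#' @param copies Number of slots to null, default all present slots.
#' @return The modified `genotype`.
#' @export
set_null <- function(g, locus, copies = Inf) {
  a <- g$alleles[[locus]]
  if (is.null(a)) stop("unknown locus ", locus)
  present <- which(a != "absent")
  take <- utils::head(present, copies)
  a[take] <- "null"
  g$alleles[[locus]] <- a
  g
}

#' Enumerate the gamete distribution of a parent
#'
#' Autosomal loci segregate one allele per slot pair and assort
#' independently unless grouped in `linked`; all X-linked loci travel on the
#' chosen X haplotype. XX parents make only X-bearing gametes; XO parents
#' make X-bearing and nullo-X gametes in equal proportion.
#'
#' @param g A `genotype`.
#' @param linked Optional list of character vectors; autosomal loci within
#'   one vector are co-transmitted (same haplotype index), e.g.
#'   `list(c("seud-1", "seud-1.2"))` for physically linked paralogs.
#' @return A `gamete_distribution`: list of gametes, each with `alleles`
#'   (one state per locus; X loci `NA` in nullo-X gametes), `x_bearing`, and
#'   `prob`. Probabilities sum to 1.
#' @export
gametes <- function(g, linked = NULL) {
  loci <- g$loci
  aut <- names(loci)[vapply(loci, function(l) l$linkage == "autosomal", logical(1))]
  xl <- setdiff(names(loci), aut)
  # factor groups: each linked group (or solitary autosomal locus) is one
  # independently assorting unit
  groups <- list()
  used <- character(0)
  for (grp in linked %||% list()) {
    grp <- intersect(grp, aut)
    if (length(grp)) { groups[[length(groups) + 1L]] <- grp; used <- c(used, grp) }
  }
  for (l in setdiff(aut, used)) groups[[length(groups) + 1L]] <- l
  factors <- rep(list(1:2), length(groups))
  names(factors) <- paste0("g", seq_along(groups))
  x_levels <- if (g$sex == "male") c("X", "0") else c("1", "2")
  factors$X <- x_levels
  combos <- expand.grid(factors, stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    alle <- stats::setNames(rep(NA_character_, length(loci)), names(loci))
    for (k in seq_along(groups)) {
      idx <- combos[r, k]
      for (l in groups[[k]]) alle[l] <- g$alleles[[l]][idx]
    }
    xv <- combos$X[r]
    x_bearing <- xv != "0"
    if (x_bearing) {
      xi <- if (g$sex == "male") 1L else as.integer(xv)
      for (l in xl) alle[l] <- g$alleles[[l]][xi]
    }
    out[[r]] <- list(alleles = alle, x_bearing = x_bearing,
                     prob = (0.5)^(length(groups) + 1L) * 2^0)
  }
  # each factor (including X) has two equiprobable levels
  for (r in seq_along(out)) out[[r]]$prob <- 0.5^(length(groups) + 1L)
  aggregate_gametes(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

aggregate_gametes <- function(gams) {
  keys <- vapply(gams, function(g)
    paste(g$x_bearing, paste(g$alleles, collapse = "|")), character(1))
  agg <- lapply(split(seq_along(gams), keys), function(idx) {
    g <- gams[[idx[1]]]
    g$prob <- sum(vapply(gams[idx], `[[`, numeric(1), "prob"))
    g
  })
  structure(unname(agg), class = "gamete_distribution")
}

#' Cross two parents
#'
#' Offspring distribution is the product of the parental gamete
#' distributions. A paternal X-bearing gamete gives an XX
#' hermaphrodite/female; a nullo-X gamete gives an XO male. Hermaphrodite
#' selfing is `cross(g, g)`: self sperm are modelled as all X-bearing, so
#' selfing yields XX offspring only (rare nullo-X self sperm are ignored).
#'
#' @param mother An XX `genotype`.
#' @param father A `genotype` (male or, for selfing, the same hermaphrodite).
#' @param linked Passed to [gametes()] for both parents.
#' @return An `offspring_distribution`: list of (`genotype`, `prob`),
#'   probabilities summing to 1.
#' @export
cross <- function(mother, father, linked = NULL) {
  if (mother$sex != "hermaphrodite")
    stop("mother must be XX (hermaphrodite/female)")
  mg <- gametes(mother, linked)
  fg <- gametes(father, linked)
  loci <- mother$loci
  xl <- names(loci)[vapply(loci, function(l) l$linkage == "X", logical(1))]
  aut <- setdiff(names(loci), xl)
  out <- list()
  for (m in mg) for (f in fg) {
    alle <- list()
    for (l in aut) alle[[l]] <- c(m$alleles[[l]], f$alleles[[l]])
    if (f$x_bearing) {
      sex <- "hermaphrodite"
      for (l in xl) alle[[l]] <- c(m$alleles[[l]], f$alleles[[l]])
    } else {
      sex <- "male"
      for (l in xl) alle[[l]] <- m$alleles[[l]]
    }
    out[[length(out) + 1L]] <- list(
      genotype = genotype(sex, alle, loci),
      prob = m$prob * f$prob
    )
  }
  aggregate_offspring(out)
}

aggregate_offspring <- function(offs) {
  keys <- vapply(offs, function(o)
    paste(o$genotype$sex,
          paste(unlist(o$genotype$alleles), collapse = "|")), character(1))
  agg <- lapply(split(seq_along(offs), keys), function(idx) {
    o <- offs[[idx[1]]]
    o$prob <- sum(vapply(offs[idx], `[[`, numeric(1), "prob"))
    o
  })
  structure(unname(agg), class = "offspring_distribution")
}

#' Count functional copies at a locus or gene family
#'
#' @param g A `genotype`.
#' @param what A locus name or a family name (e.g. `"seud-1"` sums the
#'   duplicates).
#' @return Integer count of `functional` alleles.
#' @export
functional_dosage <- function(g, what) {
  fams <- vapply(g$loci, `[[`, character(1), "family")
  loci <- if (what %in% names(g$loci) && !(what %in% fams[names(fams) != what]))
    what else names(g$loci)[fams == what]
  if (!length(loci)) loci <- intersect(what, names(g$loci))
  if (!length(loci)) stop("unknown locus or family: ", what)
  sum(vapply(loci, function(l) sum(g$alleles[[l]] == "functional"), integer(1)))
}

#' Functional dosage ratio E:S of a genotype
#'
#' @param g A `genotype`.
#' @return List with `E` (functional *eud-1* copies), `S` (functional
#'   *seud-1* copies summed over paralogs) and `ratio` (the "E:S" label).
#' @export
dosage_ratio <- function(g) {
  E <- functional_dosage(g, "eud-1")
  S <- functional_dosage(g, "seud-1")
  list(E = E, S = S, ratio = paste0(E, ":", S))
}

#' Tabulate an offspring distribution by dosage class
#'
#' @param offspring An `offspring_distribution` from [cross()].
#' @param params [morph_params()] used to annotate each class with its
#'   expected Eu probability and regime label.
#' @return Data frame: `sex`, `E`, `S`, `ratio`, `prob`, `p_eu`, `regime`,
#'   aggregated over genotypes with equal (sex, E, S).
#' @export
offspring_dosages <- function(offspring, params = morph_params()) {
  rows <- lapply(offspring, function(o) {
    d <- dosage_ratio(o$genotype)
    data.frame(sex = o$genotype$sex, E = d$E, S = d$S, ratio = d$ratio,
               prob = o$prob, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- stats::aggregate(prob ~ sex + E + S + ratio, data = df, FUN = sum)
  df <- df[order(df$sex, -df$prob), ]
  df$p_eu <- mapply(morph_probability, df$E, df$S,
                    MoreArgs = list(params = params))
  df$regime <- vapply(seq_len(nrow(df)), function(i) {
    if (df$S[i] == 0 && df$E[i] + df$S[i] > 0) "all-Eu"
    else if (df$E[i] == 0 && df$S[i] > 0) "all-St"
    else if (df$E[i] == 0 && df$S[i] == 0) "undefined"
    else if (df$p_eu[i] > 0.95) "almost all-Eu"
    else if (df$p_eu[i] < 0.05) "almost all-St"
    else "graded"
  }, character(1))
  rownames(df) <- NULL
  df
}

#' Expected Eu probability for a dosage class
#'
#' Hard boundaries: S = 0 (with any functional *eud-1*) is all-Eu and E = 0
#' (with functional *seud-1*) is all-St; otherwise
#' `plogis(intercept + slope * log2(E/S))`.
#'
#' @param E,S Functional copy counts.
#' @param params A [morph_params()].
#' @return Probability an individual develops the Eu morph.
#' @export
morph_probability <- function(E, S, params = morph_params()) {
  if (E == 0 && S == 0) stop("undefined genotype: no functional copies of either gene")
  if (S == 0) return(1)
  if (E == 0) return(0)
  stats::plogis(params$intercept + params$slope * log2(E / S))
}

#' Enumerate offspring dosage classes for a panel of cross designs
#'
#' @param designs Named list; each element has `mother` and `father`
#'   genotypes and optionally `linked`.
#' @param females_only Keep only XX offspring (hybrid phenotyping scores
#'   females only).
#' @param params [morph_params()] for class annotation.
#' @return Data frame of `design` x dosage classes (empty for an empty
#'   design list).
#' @export
enumerate_panel <- function(designs, females_only = FALSE,
                            params = morph_params()) {
  if (!length(designs))
    return(data.frame(design = character(0), sex = character(0),
                      E = integer(0), S = integer(0), ratio = character(0),
                      prob = numeric(0), p_eu = numeric(0),
                      regime = character(0)))
  rows <- lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    off <- cross(d$mother, d$father, linked = d$linked %||% NULL)
    tab <- offspring_dosages(off, params)
    cbind(design = nm, tab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (females_only) out <- out[out$sex == "hermaphrodite", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The four interspecies hybrid cross designs
#'
#' *P. pacificus* mothers (wild type, *eud-1* null, *seud-1* null, or the
#' double mutant) crossed to wild-type *P. exspectatus* males. F1 females
#' from these designs carry the dosage classes 2:3, 1:3, 2:2 and 1:2.
#'
#' @return Named list of designs for [enumerate_panel()].
#' @export
hybrid_panel_designs <- function() {
  pex_m <- wt_genotype("exspectatus", "male")
  ppa <- wt_genotype("pacificus")
  list(
    wt_hybrid = list(mother = ppa, father = pex_m),
    eud1_mutant_hybrid = list(mother = set_null(ppa, "eud-1"), father = pex_m),
    seud1_mutant_hybrid = list(mother = set_null(ppa, "seud-1"), father = pex_m),
    double_mutant_hybrid = list(
      mother = set_null(set_null(ppa, "eud-1"), "seud-1"), father = pex_m)
  )
}

#' Sample offspring classes from a cross
#'
#' Monte-Carlo companion to the exact enumeration, for goodness-of-fit
#' checks and downstream phenotype simulation.
#'
#' @param mother,father,linked As in [cross()].
#' @param n Number of offspring to draw.
#' @return Data frame of sampled offspring with `sex`, `E`, `S`, `ratio`.
#' @export
sample_cross <- function(mother, father, n, linked = NULL) {
  off <- cross(mother, father, linked)
  tab <- offspring_dosages(off)
  idx <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$prob)
  out <- tab[idx, c("sex", "E", "S", "ratio")]
  rownames(out) <- NULL
  out
}
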