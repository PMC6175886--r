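test_that("VCF loading round-trips records and skips non-SNV lines", {
  tab <- variant_table(
    contig = c("chr1", "chr1", "chr2"), pos = c(100L, 250L, 31L),
    ref = c("G", "C", "A"), alt = c("A", "T", "C"),
    qual = c(45.5, 31, 60), depth = c(18L, 25L, 9L), strain = "toy"
  )
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants_vcf(tab, vcf)
  back <- load_variants(vcf, strain = "toy")
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  expect_identical(attr(back, "skipped"), 0L)

  # header-only file -> empty table
  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(readLines(vcf)[1:4], empty)
  expect_identical(nrow(load_variants(empty)), 0L)

  # one multi-allelic line is skipped and counted
  lines <- readLines(vcf)
  lines <- c(lines, "chr2\t40\t.\tA\tC,G\t50\t.\tDP=12")
  multi <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, multi)
  got <- suppressMessages(load_variants(multi, strain = "toy"))
  expect_identical(nrow(got), 3L)
  expect_identical(attr(got, "skipped"), 1L)

  # TSV dialect round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variants_tsv(tab, tsv)
  expect_equal(as.data.frame(load_variants(tsv)), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("malformed variant input is rejected with a location", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt\tqual\tdepth\tstrain",
               "chr1\t10\tA\tG\t50\t10\ts",
               "chr1\t-3\tA\tG\t50\t10\ts"), tsv)
  expect_error(load_variants(tsv), "line 3")
  writeLines(c("contig\tpos", "chr1\t10"), tsv)
  expect_error(load_variants(tsv), "missing column")
})

test_that("quality filter retains exactly the records above both thresholds", {
  tab <- variant_table(contig = "c", pos = 1:4, ref = "A", alt = "G",
                       qual = c(10, 30, 30, 50), depth = c(20L, 2L, 8L, 9L),
                       strain = "s")
  expect_identical(nrow(quality_filter(tab, 0, 0)), 4L)
  expect_identical(nrow(quality_filter(tab, 100, 100)), 0L)
  kept <- quality_filter(tab, 20, 5)
  expect_identical(kept$pos, c(3L, 4L))
  # idempotent
  expect_identical(quality_filter(kept, 20, 5), kept)
  expect_error(quality_filter(tab, -1, 0), ">= 0")
})

test_that("background subtraction removes exactly the shared keys", {
  tab <- variant_table(contig = "c", pos = 1:3, ref = "A", alt = "G",
                       qual = 50, depth = 10L, strain = "mut")
  bg <- variant_table(contig = "c", pos = 2L, ref = "A", alt = "G",
                      qual = 12, depth = 3L, strain = "parent")
  expect_identical(subtract_shared(tab, list()), tab)
  expect_identical(nrow(subtract_shared(tab, list(tab))), 0L)
  got <- subtract_shared(tab, list(bg))
  expect_identical(got$pos, c(1L, 3L))
  # strain and quality fields are ignored for matching; order of backgrounds
  # does not matter and the operation is idempotent
  bg2 <- variant_table(contig = "c", pos = 3L, ref = "A", alt = "G",
                       qual = 50, depth = 10L, strain = "other")
  ab <- subtract_shared(tab, list(bg, bg2))
  ba <- subtract_shared(tab, list(bg2, bg))
  expect_identical(ab, ba)
  expect_identical(subtract_shared(ab, list(bg, bg2)), ab)
  # candidate pool shrinks monotonically as backgrounds accumulate
  expect_lte(nrow(ab), nrow(got))
})

test_that("impact classification matches hand-derived toy cases", {
  # plus-strand single-exon gene: ATG AAA GAA TAA at positions 11..22
  seq <- paste0(strrep("T", 10), "ATGAAAGAATAA", strrep("T", 10))
  genome <- toy_genome(seq)
  ann <- toy_annotation(data.frame(start = 11L, end = 22L))
  classify1 <- function(pos, ref, alt) {
    tab <- variant_table(contig = "chr1", pos = pos, ref = ref, alt = alt,
                         qual = 50, depth = 10L, strain = "s")
    classify_impact(tab, ann, genome)
  }
  # A->T at first base of codon 2: AAA -> TAA
  expect_identical(classify1(14L, "A", "T")$impact, "nonsense")
  # A->G at third base of codon 3: GAA -> GAG
  expect_identical(classify1(19L, "A", "G")$impact, "synonymous")
  expect_identical(classify1(19L, "A", "G")$aa_ref, "E")
  # A->C at second base of codon 2: AAA -> ACA (Lys -> Thr)
  expect_identical(classify1(15L, "A", "C")$impact, "missense")
  # far from any gene
  expect_identical(classify1(3L, "T", "G")$impact, "noncoding")
  expect_true(is.na(classify1(3L, "T", "G")$gene))
  # reference mismatch is a consistency error
  expect_error(classify1(14L, "G", "T"), "mismatch")
})

test_that("impact classification handles splice windows and minus strands", {
  # two-exon plus-strand gene with a 20 bp intron (positions 21..40)
  exon1 <- "ATGAAAGAAT"        # 10 bp, positions 11..20
  intron <- paste0("GT", strrep("C", 16), "AG")
  exon2 <- "CAGGGTTTTAA"       # positions 41..51
  seq <- paste0(strrep("T", 10), exon1, intron, exon2, strrep("T", 10))
  genome <- toy_genome(seq)
  ann <- toy_annotation(data.frame(start = c(11L, 41L), end = c(20L, 51L)))
  tab <- variant_table(contig = "chr1", pos = c(22L, 39L, 30L),
                       ref = c("T", "A", "C"), alt = c("A", "T", "A"),
                       qual = 50, depth = 10L, strain = "s")
  got <- classify_impact(tab, ann, genome)
  expect_identical(got$impact, c("splice_site", "splice_site", "noncoding"))

  # minus-strand gene: genomic segment is the reverse complement of
  # ATG AAA GAA TAA; transcript exon 1 is the rightmost interval
  cds <- "ATGAAAGAATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  seq2 <- paste0(strrep("G", 10), rc, strrep("G", 10))
  genome2 <- toy_genome(seq2)
  ann2 <- toy_annotation(data.frame(start = 11L, end = 22L), strand = "-")
  # codon 2 first base (transcript) sits at genomic position 19 on the
  # complement; A->T on the coding strand is T->A on the genome
  tab2 <- variant_table(contig = "chr1", pos = 19L, ref = "T", alt = "A",
                        qual = 50, depth = 10L, strain = "s")
  got2 <- classify_impact(tab2, ann2, genome2)
  expect_identical(got2$impact, "nonsense")
  expect_identical(got2$codon_index, 2L)
})

test_that("impact calls agree with the full-CDS translation oracle", {
  fx <- default_screen(21L)
  p2 <- fx$params; p2$n_background_variants <- 30; p2$seed <- 22L
  scr <- gen_screen_dataset(fx$ref, p2)
  tab <- rbind(as.data.frame(scr$tables$mutant_a),
               as.data.frame(scr$tables$mutant_b))
  tab <- polyswitch:::validate_variant_table(tab)
  got <- classify_impact(tab, fx$ref$annotation, fx$ref$genome)
  for (i in seq_len(nrow(got))) {
    expected <- oracle_impact(got$contig[i], got$pos[i], got$alt[i],
                              fx$ref$annotation, fx$ref$genome)
    expect_identical(got$impact[i], expected)
  }
})

test_that("harmful subset keeps nonsense, missense and splice-site calls only", {
  calls <- data.frame(
    contig = "c", pos = 1:5, ref = "A", alt = "G", qual = 50, depth = 10,
    strain = "s", gene = c("g1", "g1", NA, "g2", "g3"),
    impact = c("synonymous", "nonsense", "noncoding", "missense",
               "splice_site"),
    codon_index = NA, aa_ref = NA, aa_alt = NA
  )
  got <- harmful_subset(calls)
  expect_identical(sort(got$impact), c("missense", "nonsense", "splice_site"))
  # order-invariant
  shuffled <- harmful_subset(calls[c(4, 2, 5, 1, 3), ])
  expect_identical(sort(polyswitch:::variant_key(shuffled)),
                   sort(polyswitch:::variant_key(got)))
  all_syn <- calls[calls$impact == "synonymous", ]
  expect_identical(nrow(harmful_subset(all_syn)), 0L)
})

test_that("candidate intersection requires non-identical harmful calls in both alleles", {
  mk_call <- function(pos, gene, impact = "missense") data.frame(
    contig = "c", pos = pos, ref = "A", alt = "G", qual = 50, depth = 10,
    strain = "s", gene = gene, impact = impact, codon_index = 1,
    aa_ref = "K", aa_alt = "R")
  empty <- mk_call(1L, "g0")[0, ]
  expect_identical(sum(intersect_candidates(empty, empty)$qualifying), 0L)
  # same single variant in both alleles: not qualifying
  same <- intersect_candidates(mk_call(5L, "g1"), mk_call(5L, "g1"))
  expect_false(same$qualifying)
  # distinct variants in the same gene: qualifying
  diff <- intersect_candidates(mk_call(5L, "g1"), mk_call(9L, "g1"))
  expect_true(diff$qualifying)
  # harmful in only one allele: not qualifying
  onesided <- intersect_candidates(mk_call(5L, "g1"), mk_call(9L, "g2"))
  expect_identical(sum(onesided$qualifying), 0L)
})

test_that("the mapping cascade recovers the planted causal gene", {
  for (seed in c(31L, 32L, 33L)) {
    fx <- default_screen(seed)
    report <- run_default_mapping(fx)
    hits <- report$gene[report$qualifying]
    expect_identical(hits, fx$scr$truth$causal_gene)
    # reported lesion positions equal the planted ones
    calls <- attr(report, "calls")
    pos_a <- calls$a$pos[calls$a$gene == hits]
    pos_b <- calls$b$pos[calls$b$gene == hits]
    expect_true(fx$scr$truth$lesions$pos[1] %in% pos_a)
    expect_true(fx$scr$truth$lesions$pos[2] %in% pos_b)
    # provenance log: counts shrink through the cascade
    log <- attr(report, "log")
    expect_true(all(log$quality_filtered <= log$loaded))
    expect_true(all(log$background_subtracted <= log$quality_filtered))
    expect_true(all(log$harmful <= log$background_subtracted))
  }
})

test_that("mapping accepts file paths and writes its report", {
  fx <- default_screen(41L)
  dir <- withr::local_tempdir()
  paths <- list()
  for (nm in names(fx$scr$tables))
    paths[[nm]] <- write_variants_vcf(fx$scr$tables[[nm]],
                                      file.path(dir, paste0(nm, ".vcf")))
  fa <- write_genome_fasta(fx$ref$genome, file.path(dir, "ref.fa"))
  gff <- write_annotation_gff3(fx$ref$annotation, file.path(dir, "genes.gff3"))
  report <- run_mapping(paths$mutant_a, paths$mutant_b,
                        backgrounds = list(paths$parental, paths$marker),
                        annotation = gff, genome = fa)
  expect_identical(report$gene[report$qualifying], fx$scr$truth$causal_gene)
  out_tsv <- file.path(dir, "report.tsv")
  out_json <- file.path(dir, "report.json")
  write_candidate_report(report, tsv = out_tsv, json = out_json)
  expect_true(file.exists(out_tsv) && file.exists(out_json))
  round <- utils::read.delim(out_tsv)
  expect_identical(round$gene[round$qualifying], fx$scr$truth$causal_gene)
})
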