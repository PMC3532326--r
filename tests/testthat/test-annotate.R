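# Small helper: run the annotation stage directly on prepared components.
annotate_fx <- function(fx, variants = fx$variants) {
  comp <- decompose_variants(variants)
  assigned <- assign_variants(comp, fx$exons)
  annotate_variants(assigned, fx$exons, fx$genome)
}

test_that("Grantham scores and classes follow the published matrix", {
  g <- grantham_classify("L", "S")
  expect_equal(g$score, 145)
  expect_equal(g$class, "MODERATELY_RADICAL")
  expect_equal(g$so_category, "non_conservative_missense_codon")
  g <- grantham_classify("I", "V")
  expect_equal(g$score, 29)
  expect_equal(g$class, "CONSERVATIVE")
  expect_equal(g$so_category, "conservative_missense_codon")
  expect_error(grantham_classify("L", "L"), "differing")
  expect_error(grantham_classify("L", "*"), "stop")
})

test_that("Grantham classification is symmetric over all 190 pairs", {
  aa <- rownames(read_grantham_matrix())
  pairs <- t(combn(aa, 2))
  a <- grantham_classify(pairs[, 1], pairs[, 2])
  b <- grantham_classify(pairs[, 2], pairs[, 1])
  expect_equal(nrow(pairs), 190)
  expect_equal(a$score, b$score)
  expect_equal(a$class, b$class)
})

test_that("co-occurring same-codon SNVs are applied jointly to the codon", {
  # plus-strand transcript whose codon 1 (0-based) is CTG
  genome <- c(c1 = "ATGCTGGGGTAA")
  ex <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                       start = 1L, end = 12L, strand = "+")
  both <- tibble::tibble(pos = c(4L, 5L), ref_seq = c("C", "T"),
                         alt_seq = c("T", "C"))
  vc <- variant_codon(ex, "t1", genome, 1L, both)
  expect_equal(vc, list(ref_codon = "CTG", var_codon = "TCG"))
  one <- both[1, ]
  expect_equal(variant_codon(ex, "t1", genome, 1L, one)$var_codon, "TTG")
  none <- both[0, ]
  expect_equal(variant_codon(ex, "t1", genome, 1L, none)$var_codon, "CTG")
})

test_that("SNV consequences cover synonymous, joint missense, splice and stops", {
  fx <- generate_fixture("missense_joint_codon", 7)
  ann <- annotate_fx(fx)
  expect_equal(ann$category,
               rep("non_conservative_missense_codon", 2))
  expect_equal(unique(ann$ref_codon), "CTG")
  expect_equal(unique(ann$var_codon), "TCG")
  expect_equal(unique(ann$var_aa), "S")
  expect_equal(unique(ann$grantham_score), 145L)
  # the first SNV alone is synonymous (CTG -> TTG, both leucine)
  solo <- annotate_fx(fx, fx$variants[1, ])
  expect_equal(solo$category, "synonymous_codon")
  expect_equal(solo$var_codon, "TTG")

  syn <- generate_fixture("synonymous", 7)
  expect_equal(annotate_fx(syn)$category, "synonymous_codon")

  sp <- generate_fixture("splice_hit", 7)
  expect_equal(annotate_fx(sp)$category, "splice_donor_variant")

  # stop lost: TAA -> TAT at the terminal codon (third base A->T)
  genome <- c(c1 = "ATGCCCTAAGG")
  ex <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                       start = 1L, end = 9L, strand = "+")
  vars <- tibble::tibble(chrom = "c1", pos = 9L, ref = "A", alt = "T")
  ann <- annotate_fx(list(genome = genome, exons = ex), vars)
  expect_equal(ann$category, "stop_lost")
  expect_equal(ann$ref_codon, "TAA")
  expect_equal(ann$var_codon, "TAT")

  # stop gained: TAC -> TAA
  genome <- c(c1 = "ATGTACCCCTAA")
  ex <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                       start = 1L, end = 12L, strand = "+")
  vars <- tibble::tibble(chrom = "c1", pos = 6L, ref = "C", alt = "A")
  ann <- annotate_fx(list(genome = genome, exons = ex), vars)
  expect_equal(ann$category, "stop_gained")
})

test_that("reference-mismatching variants are skipped with a warning", {
  genome <- c(c1 = "ATGCTGGGGTAA")
  ex <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                       start = 1L, end = 12L, strand = "+")
  comp <- tibble::tibble(record = 1L, chrom = "c1", kind = "SNV", pos = 4L,
                         ref_seq = "G", alt_seq = "A")  # genome has C
  assigned <- assign_variants(comp, ex)
  expect_warning(ann <- annotate_variants(assigned, ex, genome),
                 "reference")
  expect_equal(nrow(ann), 0)
})

test_that("indel consequences follow the net coding-length change", {
  fx <- generate_fixture("frame_restore", 11)
  ann <- annotate_fx(fx)
  expect_setequal(ann$category, "frameshift_variant")
  expect_setequal(ann$coding_length_delta, c(-1L, 1L))

  # 18-bp insertion inside the CDS is inframe
  genome <- c(c1 = paste0("ATG", strrep("GCC", 10), "TAA"))
  ex <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                       start = 1L, end = 36L, strand = "+")
  vars <- tibble::tibble(chrom = "c1", pos = 9L, ref = "C",
                         alt = paste0("C", strrep("AGT", 6)))
  ann <- annotate_fx(list(genome = genome, exons = ex), vars)
  expect_equal(ann$category, "inframe_variant")
  expect_equal(ann$coding_length_delta, 18L)

  # intronic deletion away from the splice dinucleotides is silent
  fx2 <- generate_fixture("boundary_insertion", 11)
  ann2 <- annotate_fx(fx2)
  expect_equal(ann2$category, rep("silent_mutation", 2))

  intron_mid <- fx2$exons$end[1] + 10L
  g <- fx2$genome[["chrI"]]
  vars <- tibble::tibble(
    chrom = "chrI", pos = intron_mid - 1L,
    ref = substr(g, intron_mid - 1L, intron_mid + 2L),
    alt = substr(g, intron_mid - 1L, intron_mid - 1L)
  )
  ann3 <- annotate_fx(fx2, vars)
  expect_equal(ann3$category, "silent_mutation")

  # a deletion reaching into the donor dinucleotide is a splice variant
  e1_end <- fx2$exons$end[1]
  vars <- tibble::tibble(
    chrom = "chrI", pos = e1_end - 1L,
    ref = substr(g, e1_end - 1L, e1_end + 2L),
    alt = substr(g, e1_end - 1L, e1_end - 1L)
  )
  ann4 <- annotate_fx(fx2, vars)
  expect_equal(ann4$category, "splice_donor_variant")
})

test_that("an indel whose |delta| is a positive multiple of 3 is never frameshift", {
  for (seed in 1:20) {
    set.seed(seed)
    n_cod <- sample(10:20, 1)
    genome <- c(c1 = paste0("ATG", strrep("GCC", n_cod), "TAA"))
    ex <- tibble::tibble(transcript_id = "t1", chrom = "c1", start = 1L,
                         end = nchar(genome[[1]]), strand = "+")
    k <- 3L * sample(1:3, 1)
    p <- sample(5:(nchar(genome[[1]]) - 15L), 1)
    if (sample(c(TRUE, FALSE), 1)) {
      vars <- tibble::tibble(chrom = "c1", pos = p,
                             ref = substr(genome[[1]], p, p),
                             alt = paste0(substr(genome[[1]], p, p),
                                          strrep("A", k)))
    } else {
      vars <- tibble::tibble(chrom = "c1", pos = p,
                             ref = substr(genome[[1]], p, p + k),
                             alt = substr(genome[[1]], p, p))
    }
    ann <- annotate_fx(list(genome = genome, exons = ex), vars)
    expect_false(any(ann$category == "frameshift_variant"))
  }
})

test_that("single-SNV classification matches an independent oracle", {
  n_checked <- 0
  for (seed in 1:40) {
    fx <- random_fixture(seed)
    snvs <- fx$variants[fx$variants$kind == "SNV", ]
    if (nrow(snvs) == 0) next
    snv <- snvs[1, ]
    vars <- tibble::tibble(chrom = snv$chrom, pos = snv$pos,
                           ref = snv$ref_seq, alt = snv$alt_seq)
    ann <- annotate_fx(fx, vars)
    if (nrow(ann) == 0) next  # outside the annotation window
    want <- oracle_classify_single_snv(fx$genome, fx$exons, "t1",
                                       snv$pos, snv$ref_seq, snv$alt_seq)
    expect_equal(ann$category, want, info = paste("seed", seed))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("coding SNV annotations are internally consistent", {
  for (seed in c(3, 7, 13)) {
    fx <- generate_fixture("missense_joint_codon", seed)
    ann <- annotate_fx(fx)
    coding <- ann[!is.na(ann$ref_codon), ]
    expect_gt(nrow(coding), 0)
    expect_equal(vapply(coding$ref_codon, translate_cds, ""),
                 setNames(coding$ref_aa, coding$ref_codon))
    expect_equal(vapply(coding$var_codon, translate_cds, ""),
                 setNames(coding$var_aa, coding$var_codon))
    expect_false(any(coding$kind != "SNV"))
  }
})

test_that("SNVs hitting transcripts differently are listed as multi-category", {
  # two overlapping transcripts in different frames on one strand
  genome <- c(c1 = "AAATGCTGGGGTAACCATGGCTGGGGTGATAACC")
  ex <- tibble::tibble(
    transcript_id = c("t1", "t2"), chrom = "c1",
    start = c(3L, 4L), end = c(14L, 15L), strand = "+"
  )
  # one SNV inside both transcripts: frames differ so categories can too
  vars <- tibble::tibble(chrom = "c1", pos = 8L, ref = "G", alt = "A")
  comp <- decompose_variants(vars)
  assigned <- assign_variants(comp, ex)
  ann <- annotate_variants(assigned, ex, genome)
  expect_equal(nrow(ann), 2)
  mc <- multi_category_variants(ann)
  if (dplyr::n_distinct(ann$category) >= 2) {
    expect_equal(nrow(mc), 2)
  } else {
    expect_equal(nrow(mc), 0)
  }
  # identical consequences are not listed
  same <- ann
  same$category <- "synonymous_codon"
  expect_equal(nrow(multi_category_variants(same)), 0)
  # single-transcript SNVs are never listed
  expect_equal(nrow(multi_category_variants(ann[1, ])), 0)
})
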