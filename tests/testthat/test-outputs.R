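run_fx <- function(scenario, seed) {
  fx <- generate_fixture(scenario, seed)
  jv_annotate(fx$variants, fx$genome, fx$exons)
}

test_that("GVF output round-trips coordinates, types and alleles", {
  run <- run_fx("compound_decomposition", 3)
  f <- withr::local_tempfile(fileext = ".gvf")
  write_gvf(run$annotations, run$components, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gvf-version 1.05")
  back <- read_gvf(f)
  expect_equal(nrow(back),
               nrow(dplyr::distinct(run$components, chrom, kind, pos,
                                    ref_seq, alt_seq)))
  comp <- dplyr::arrange(run$components, chrom, pos, kind)
  expect_equal(back$kind, comp$kind)
  expect_equal(back$ref_seq, comp$ref_seq)
  expect_equal(back$alt_seq, comp$alt_seq)
  # spans: SNV/insertion single-base anchored, deletion covers its bases
  is_del <- back$kind == "deletion"
  expect_equal(back$start, comp$pos)
  expect_equal(back$end[!is_del], back$start[!is_del])
  expect_equal(back$end[is_del],
               comp$pos[is_del] + nchar(comp$ref_seq[is_del]) - 1L)
  expect_true(all(back$type %in% SO_CATEGORIES))
})

test_that("GVF carries per-transcript effects and codon/Grantham detail", {
  run <- run_fx("missense_joint_codon", 3)
  f <- withr::local_tempfile(fileext = ".gvf")
  write_gvf(run$annotations, run$components, f)
  back <- read_gvf(f)
  expect_equal(nrow(back), 2)
  expect_true(all(grepl("impacted_transcripts=t1", back$attributes)))
  expect_true(all(grepl("effects=t1\\|non_conservative_missense_codon",
                        back$attributes)))
  expect_true(all(grepl("codon_change=CTG>TCG", back$attributes)))
  expect_true(all(grepl("aa_change=L>S", back$attributes)))
  expect_true(all(grepl("grantham_score=145", back$attributes)))

  # unassigned variants are still reported, typed silent_mutation
  fx <- generate_fixture("intact", 3)
  far <- tibble::tibble(chrom = "chrI", pos = 1L,
                        ref = substr(fx$genome[["chrI"]], 1, 1), alt = "A")
  far$alt <- ifelse(far$ref == "A", "C", "A")
  run2 <- jv_annotate(far, fx$genome, fx$exons)
  f2 <- withr::local_tempfile(fileext = ".gvf")
  write_gvf(run2$annotations, run2$components, f2)
  back2 <- read_gvf(f2)
  expect_equal(back2$type, "silent_mutation")
  expect_false(grepl("impacted_transcripts", back2$attributes))

  # no variants: header-only file
  f3 <- withr::local_tempfile(fileext = ".gvf")
  write_gvf(run2$annotations[0, ], run2$components[0, ], f3)
  expect_equal(nrow(read_gvf(f3)), 0)
})

test_that("transcript GFF3 reports ORF status, CDS children and variants", {
  run <- run_fx("frameshift_stop", 3)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_transcript_gff(run$exons, run$transcripts, run$annotations, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  tx_line <- grep("\ttranscript\t", lines, value = TRUE)
  expect_length(tx_line, 1)
  expect_true(grepl("orf_status=ORF_DISRUPTED", tx_line))
  expect_true(grepl("first_internal_stop_pct=", tx_line))
  expect_equal(sum(grepl("\tCDS\t", lines)), nrow(run$exons))
  expect_equal(sum(grepl("\tframeshift_variant\t", lines)),
               sum(run$annotations$category == "frameshift_variant"))
})

test_that("run statistics add up and record codon bias", {
  run <- run_fx("missense_joint_codon", 3)
  s <- run$stats
  expect_equal(sum(s$orf_status_counts$n_transcripts),
               nrow(run$transcripts))
  expect_setequal(s$orf_status_counts$orf_status, ORF_STATUSES)
  expect_equal(s$affected_by_kind$kinds, "SNV")
  expect_equal(s$affected_by_kind$n_transcripts, 1)
  # both same-codon SNVs are non-synonymous against ref codon CTG
  expect_equal(s$codon_bias$codon, "CTG")
  expect_equal(s$codon_bias$synonymous, 0)
  expect_equal(s$codon_bias$non_synonymous, 2)
  expect_equal(nrow(s$indel_lengths_genome), 0)

  # an intronic (CDS-silent) indel appears only in the genome histogram
  fx <- generate_fixture("boundary_insertion", 3)
  g <- fx$genome[["chrI"]]
  mid <- fx$exons$end[1] + 10L
  intronic <- tibble::tibble(chrom = "chrI", pos = mid,
                             ref = substr(g, mid, mid),
                             alt = paste0(substr(g, mid, mid), "AC"))
  run2 <- jv_annotate(intronic, fx$genome, fx$exons)
  expect_equal(run2$stats$indel_lengths_genome$length, 2)
  expect_equal(run2$stats$indel_lengths_genome$n_variants, 1)
  expect_equal(nrow(run2$stats$indel_lengths_cds), 0)

  st <- run_fx("frameshift_stop", 3)$stats
  expect_equal(sum(st$internal_stop_distribution$n_transcripts), 1)
  expect_equal(st$indel_lengths_cds$length, -1)

  f <- tempfile()
  write_run_stats(s, f)
  expect_true(all(file.exists(file.path(
    f, c("variant.stat", "codon_bias.stat", "indel_lengths_genome.stat",
         "indel_lengths_cds.stat")))))
})

test_that("circos tracks tile each chromosome and conserve counts", {
  run <- run_fx("compound_decomposition", 3)
  d <- tempfile()
  paths <- write_circos_tracks(run$components, run$exons,
                               run$chrom_lengths, d, bin_size = 50)
  expect_true(all(file.exists(paths)))
  read_track <- function(p) {
    x <- read.table(p, col.names = c("chrom", "start", "end", "count"))
    tibble::as_tibble(x)
  }
  snv <- read_track(file.path(d, "snvs.circos.txt"))
  chrom_len <- unname(run$chrom_lengths["chrI"])
  expect_equal(snv$start[1], 1)
  expect_equal(max(snv$end), chrom_len)
  expect_true(all(snv$end - snv$start + 1 <= 50))
  expect_equal(sum(snv$count), sum(run$components$kind == "SNV"))
  ins <- read_track(file.path(d, "insertions.circos.txt"))
  del <- read_track(file.path(d, "deletions.circos.txt"))
  expect_equal(sum(ins$count), sum(run$components$kind == "insertion"))
  expect_equal(sum(del$count), sum(run$components$kind == "deletion"))
  cds <- read_track(file.path(d, "coding_exons.circos.txt"))
  expect_equal(sum(cds$count), nrow(run$exons))

  # single-bin case: bin at least as long as the chromosome
  d2 <- tempfile()
  write_circos_tracks(run$components, run$exons, run$chrom_lengths, d2,
                      bin_size = 1e6)
  one <- read_track(file.path(d2, "snvs.circos.txt"))
  expect_equal(nrow(one), 1)
  expect_equal(one$count, sum(run$components$kind == "SNV"))
})

test_that("variant sequence files agree with the reconstruction", {
  run <- run_fx("frame_restore", 3)
  d <- tempfile()
  write_variant_sequences(run$transcripts, d)
  vt <- read_genome(file.path(d, "variant_transcripts.fasta"))
  expect_equal(unname(vt["t1"]), run$transcripts$var_cds)
  vp <- readLines(file.path(d, "variant_proteins.fasta"))
  expect_equal(paste(vp[-1], collapse = ""), run$transcripts$var_protein)
  ref_ex <- read_genome(file.path(d, "reference_exons.fasta"))
  expect_equal(unname(ref_ex["t1.exon1"]), run$transcripts$ref_cds)
  aln <- readLines(file.path(d, "exon_alignments.txt"))
  expect_equal(aln[1], ">t1.exon1")
  expect_true(any(grepl("-", aln)))  # the deletion leaves a gap
})

test_that("tidy, glance, print and autoplot expose the run", {
  run <- run_fx("missense_joint_codon", 3)
  expect_identical(tidy(run), run$annotations)
  g <- glance(run)
  expect_equal(g$n_records, 2)
  expect_equal(g$n_components, 2)
  expect_equal(g$n_transcripts, 1)
  expect_equal(g$orf_preserved, 1)
  expect_equal(g$orf_intact + g$orf_disrupted + g$fully_deleted, 0)
  expect_output(print(run), "jointvar annotation run")
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
})

test_that("empty variant input leaves every transcript intact", {
  fx <- generate_fixture("intact", 3)
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character())
  run <- jv_annotate(empty, fx$genome, fx$exons)
  expect_equal(run$transcripts$orf_status, "ORF_INTACT")
  expect_equal(nrow(run$annotations), 0)
  expect_equal(nrow(run$components), 0)
  d <- tempfile()
  write_run_outputs(run, d)
  expect_true(file.exists(file.path(d, "variants.gvf")))
  expect_equal(nrow(read_gvf(file.path(d, "variants.gvf"))), 0)
})
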