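#' Jointly annotate variants against protein-coding transcripts
#'
#' The in-memory pipeline: decompose raw records into atomic component
#' variants, assign them to overlapping transcript annotation windows,
#' classify every variant x transcript pair (joint codon effects, Grantham
#' classes, splice hits), reconstruct each transcript's variant CDS and
#' protein, call ORF status, and compute run statistics.
#'
#' @param variants Tibble of raw variant records (`chrom`, `pos`, `ref`,
#'   `alt`), e.g. from [read_vcf()] or [read_variant_tab()].
#' @param genome Reference genome from [read_genome()].
#' @param exons Coding-exon tibble from [read_coding_exons()].
#' @param flank Annotation-window flank in bp (default 2).
#' @param codon_table Codon table.
#' @param grantham Grantham matrix.
#' @return A `jv_run` object (list) with elements `variants` (input),
#'   `components`, `annotations`, `transcripts`, `multi_category`, `stats`,
#'   `exons`, `chrom_lengths`.
#' @export
#' @examples
#' genome <- c(chr1 = "ATGCTGGGTTAA")
#' exons <- tibble::tibble(transcript_id = "t1", chrom = "chr1",
#'                         start = 1L, end = 12L, strand = "+")
#' vars <- tibble::tibble(chrom = "chr1", pos = 6L, ref = "G", alt = "A")
#' run <- jv_annotate(vars, genome, exons)
#' run$annotations$category
jv_annotate <- function(variants, genome, exons, flank = 2L,
                        codon_table = default_codon_table(),
                        grantham = default_grantham_matrix()) {
  missing_chrom <- setdiff(unique(c(variants$chrom, exons$chrom)),
                           names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) referenced but absent from the reference ",
                 "genome: ", paste(missing_chrom, collapse = ", ")))
  }
  components <- decompose_variants(variants)
  assigned <- assign_variants(components, exons, flank)
  annotations <- annotate_variants(assigned, exons, genome, codon_table,
                                   grantham)
  transcripts <- reconstruct_transcripts(assigned, exons, genome,
                                         annotations, codon_table)
  structure(list(
    variants = variants,
    components = components,
    annotations = annotations,
    transcripts = transcripts,
    multi_category = multi_category_variants(annotations),
    stats = compute_run_stats(annotations, transcripts, components),
    exons = exons,
    chrom_lengths = setNames(nchar(genome), names(genome))
  ), class = "jv_run")
}

#' Write all output files of an annotation run
#'
#' @param run A `jv_run` object from [jv_annotate()].
#' @param outdir Output directory (created if needed).
#' @param circos Also write Circos-compatible density tracks?
#' @param bin_size Circos bin width in bp.
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(run, outdir, circos = FALSE, bin_size = 1e5) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_gvf(run$annotations, run$components,
            file.path(outdir, "variants.gvf"))
  write_transcript_gff(run$exons, run$transcripts, run$annotations,
                       file.path(outdir, "transcripts.gff3"))
  write_run_stats(run$stats, outdir)
  write_variant_sequences(run$transcripts, outdir)
  mc <- run$multi_category
  mc_lines <- c(
    paste(c("chrom", "pos", "ref", "alt", "transcript_id", "category"),
          collapse = "\t"),
    if (nrow(mc) > 0) paste(mc$chrom, mc$pos, mc$ref_seq, mc$alt_seq,
                            mc$transcript_id, mc$category, sep = "\t")
  )
  writeLines(mc_lines, file.path(outdir, "multi_category_snvs.txt"))
  if (circos) {
    write_circos_tracks(run$components, run$exons, run$chrom_lengths,
                        file.path(outdir, "circos"), bin_size)
  }
  invisible(outdir)
}

#' Run the full annotation pipeline on files
#'
#' File-level driver used by the command-line interface: reads the inputs,
#' runs [jv_annotate()], writes every output file plus a run summary
#' (`run_summary.txt`) that records warning/skip counts.
#'
#' @param variant_path Path to a VCF (`format = "vcf"`) or 4-column
#'   tab-delimited (`format = "tab"`) variant file.
#' @param fasta_path Reference genome FASTA.
#' @param exon_path Protein-coding exon GFF3/GTF.
#' @param outdir Output directory.
#' @param format `"vcf"` or `"tab"`.
#' @param circos Write Circos tracks?
#' @param bin_size Circos bin width.
#' @param codon_table_path Optional codon-table file.
#' @param grantham_path Optional Grantham-matrix file.
#' @param flank Annotation-window flank.
#' @return The `jv_run` object, invisibly.
#' @export
run_annotate <- function(variant_path, fasta_path, exon_path, outdir,
                         format = c("vcf", "tab"), circos = FALSE,
                         bin_size = 1e5, codon_table_path = NULL,
                         grantham_path = NULL, flank = 2L) {
  format <- match.arg(format)
  msgs <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  genome <- read_genome(fasta_path)
  exons <- collect(read_coding_exons(exon_path))
  variants <- collect(
    if (format == "vcf") read_vcf(variant_path) else
      read_variant_tab(variant_path)
  )
  codon_table <- if (is.null(codon_table_path)) default_codon_table() else
    read_codon_table(codon_table_path)
  grantham <- if (is.null(grantham_path)) default_grantham_matrix() else
    read_grantham_matrix(grantham_path)
  run <- collect(jv_annotate(variants, genome, exons, flank = flank,
                             codon_table = codon_table, grantham = grantham))
  write_run_outputs(run, outdir, circos = circos, bin_size = bin_size)
  g <- glance(run)
  writeLines(c(
    "jointvar run summary",
    paste0("input variant records: ", nrow(variants)),
    paste0("component variants: ", nrow(run$components)),
    paste0("transcripts: ", nrow(run$transcripts)),
    paste0("ORF_INTACT: ", g$orf_intact),
    paste0("ORF_PRESERVED: ", g$orf_preserved),
    paste0("ORF_DISRUPTED: ", g$orf_disrupted),
    paste0("FULLY_DELETED: ", g$fully_deleted),
    paste0("multi-category SNVs: ", g$n_multi_category),
    "",
    "warnings:",
    if (length(msgs) > 0) paste0("  ", msgs) else "  none"
  ), file.path(outdir, "run_summary.txt"))
  invisible(run)
}

#' @export
print.jv_run <- function(x, ...) {
  g <- glance(x)
  cat("<jointvar annotation run>\n")
  cat("  input records:     ", g$n_records, "\n")
  cat("  component variants:", g$n_components, "\n")
  cat("  transcripts:       ", g$n_transcripts, "\n")
  cat("  ORF status:         INTACT ", g$orf_intact,
      " | PRESERVED ", g$orf_preserved,
      " | DISRUPTED ", g$orf_disrupted,
      " | FULLY_DELETED ", g$fully_deleted, "\n", sep = "")
  invisible(x)
}

#' Tidy the per-variant annotations of a run
#'
#' @param x A `jv_run` object.
#' @param ... Unused.
#' @return The annotation tibble (one row per variant x transcript).
#' @export
tidy.jv_run <- function(x, ...) {
  x$annotations
}

#' One-row summary of an annotation run
#'
#' @param x A `jv_run` object.
#' @param ... Unused.
#' @return One-row tibble with record/component/transcript counts and
#'   ORF-status totals.
#' @export
glance.jv_run <- function(x, ...) {
  s <- setNames(x$stats$orf_status_counts$n_transcripts,
                x$stats$orf_status_counts$orf_status)
  tibble(
    n_records = nrow(x$variants),
    n_components = nrow(x$components),
    n_transcripts = nrow(x$transcripts),
    orf_intact = unname(s["ORF_INTACT"]),
    orf_preserved = unname(s["ORF_PRESERVED"]),
    orf_disrupted = unname(s["ORF_DISRUPTED"]),
    fully_deleted = unname(s["FULLY_DELETED"]),
    n_multi_category = nrow(distinct(x$multi_category, .data$chrom,
                                     .data$pos, .data$ref_seq,
                                     .data$alt_seq))
  )
}

#' Plot the consequence spectrum of a run
#'
#' Bar chart of Sequence Ontology consequence counts across all variant x
#' transcript annotations.
#'
#' @param object A `jv_run` object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.jv_run <- function(object, ...) {
  d <- count(object$annotations,
             category = factor(.data$category, levels = SO_CATEGORIES),
             .drop = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "variant x transcript annotations") +
    ggplot2::theme_minimal()
}

#' Plot variant density along the genome
#'
#' Binned counts of SNVs, insertions and deletions per chromosome, the same
#' quantities emitted by [write_circos_tracks()].
#'
#' @param run A `jv_run` object.
#' @param bin_size Bin width in bp.
#' @return A `ggplot` object.
#' @export
plot_variant_density <- function(run, bin_size = 1e5) {
  comp <- run$components
  d <- comp |>
    mutate(bin = (floor((.data$pos - 1) / bin_size)) * bin_size + 1) |>
    count(.data$chrom, .data$kind, .data$bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$n,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "genomic position", y = "variants per bin",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
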