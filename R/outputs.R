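gvf_span <- function(kind, pos, ref_seq) {
  start <- pos
  end <- ifelse(kind == "deletion", pos + nchar(ref_seq) - 1L, pos)
  list(start = as.integer(start), end = as.integer(end))
}

#' Write variant annotations as GVF
#'
#' One record per component variant (GVF 1.05 pragma), typed with the
#' Sequence Ontology category of its first impacted transcript (or
#' `silent_mutation` for variants outside every annotation window); effects
#' on all impacted transcripts are carried in the attributes. Records are
#' ordered deterministically by chromosome, start and kind. Insertions are
#' written with `start == end ==` anchor base.
#'
#' @param annotations Annotation tibble from [annotate_variants()].
#' @param components Full component tibble from [decompose_variants()]
#'   (so unassigned variants are reported too).
#' @param path Output path.
#' @param source Value for the GVF source column.
#' @return The path, invisibly.
#' @export
write_gvf <- function(annotations, components, path, source = "jointvar") {
  key <- function(d) paste(d$chrom, d$pos, d$kind, d$ref_seq, d$alt_seq,
                           sep = "\r")
  comp <- distinct(components, .data$chrom, .data$kind, .data$pos,
                   .data$ref_seq, .data$alt_seq)
  comp <- arrange(comp, .data$chrom, .data$pos, .data$kind)
  ann_key <- key(annotations)
  lines <- c("##gvf-version 1.05", "##gff-version 3")
  for (i in seq_len(nrow(comp))) {
    v <- comp[i, ]
    eff <- annotations[ann_key == key(v), , drop = FALSE]
    eff <- arrange(eff, .data$transcript_id)
    type <- if (nrow(eff) > 0) eff$category[1] else "silent_mutation"
    sp <- gvf_span(v$kind, v$pos, v$ref_seq)
    attrs <- c(
      paste0("ID=GV", sprintf("%06d", i)),
      paste0("Variant_seq=", if (nzchar(v$alt_seq)) v$alt_seq else "-"),
      paste0("Reference_seq=", if (nzchar(v$ref_seq)) v$ref_seq else "-"),
      paste0("variant_kind=", v$kind)
    )
    if (nrow(eff) > 0) {
      attrs <- c(attrs,
        paste0("impacted_transcripts=",
               paste(eff$transcript_id, collapse = ",")),
        paste0("effects=", paste(eff$transcript_id, eff$category,
                                 sep = "|", collapse = ","))
      )
      cod <- eff[!is.na(eff$ref_codon), , drop = FALSE]
      if (nrow(cod) > 0) {
        attrs <- c(attrs,
          paste0("codon_change=", cod$ref_codon[1], ">", cod$var_codon[1]),
          paste0("aa_change=", cod$ref_aa[1], ">", cod$var_aa[1])
        )
      }
      gr <- eff[!is.na(eff$grantham_class), , drop = FALSE]
      if (nrow(gr) > 0) {
        attrs <- c(attrs,
          paste0("grantham_class=", gr$grantham_class[1]),
          paste0("grantham_score=", gr$grantham_score[1])
        )
      }
    }
    lines <- c(lines, paste(
      v$chrom, source, type, sp$start, sp$end, ".", "+", ".",
      paste(attrs, collapse = ";"),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GVF file written by [write_gvf()]
#'
#' @param path Path to a GVF file.
#' @return Tibble with columns `chrom`, `source`, `type`, `start`, `end`,
#'   `strand`, `attributes`, plus parsed `kind`, `ref_seq`, `alt_seq`, and
#'   the raw `line`.
#' @export
read_gvf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(data, "\t", fixed = TRUE)
  attr_field <- map_chr(fields, 9)
  get_attr <- function(attrs, key) {
    vapply(attrs, function(a) {
      m <- regmatches(a, regexpr(paste0("(^|;)", key, "=[^;]*"), a))
      if (length(m) == 0) NA_character_ else
        sub(paste0("^;?", key, "="), "", m)
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(
    chrom = map_chr(fields, 1),
    source = map_chr(fields, 2),
    type = map_chr(fields, 3),
    start = as.integer(map_chr(fields, 4)),
    end = as.integer(map_chr(fields, 5)),
    strand = map_chr(fields, 7),
    attributes = attr_field,
    kind = get_attr(attr_field, "variant_kind"),
    ref_seq = sub("^-$", "", get_attr(attr_field, "Reference_seq")),
    alt_seq = sub("^-$", "", get_attr(attr_field, "Variant_seq")),
    line = data
  )
}

#' Write transcript models, their variants, and ORF predictions as GFF3
#'
#' Each transcript gets a `transcript` feature carrying its ORF status (and
#' first-internal-stop percentage when disrupted by a stop), its `CDS`
#' children, and one child feature per impacting variant typed with its
#' Sequence Ontology category.
#'
#' @param exons Coding-exon tibble.
#' @param transcripts Reconstruction tibble from
#'   [reconstruct_transcripts()].
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_transcript_gff <- function(exons, transcripts, annotations, path) {
  lines <- "##gff-version 3"
  transcripts <- arrange(transcripts, .data$transcript_id)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    ex <- exons[exons$transcript_id == t$transcript_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    attrs <- paste0("ID=", t$transcript_id, ";orf_status=", t$orf_status)
    if (!is.na(t$first_internal_stop_pct)) {
      attrs <- paste0(attrs, ";first_internal_stop_pct=",
                      format(round(t$first_internal_stop_pct, 2)))
    }
    lines <- c(lines, paste(
      t$chrom, "jointvar", "transcript", min(ex$start), max(ex$end), ".",
      t$strand, ".", attrs, sep = "\t"
    ))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        ex$chrom[j], "jointvar", "CDS", ex$start[j], ex$end[j], ".",
        ex$strand[j], "0", paste0("Parent=", t$transcript_id), sep = "\t"
      ))
    }
    eff <- annotations[annotations$transcript_id == t$transcript_id, ,
                       drop = FALSE]
    eff <- arrange(eff, .data$pos, .data$kind)
    for (j in seq_len(nrow(eff))) {
      v <- eff[j, ]
      sp <- gvf_span(v$kind, v$pos, v$ref_seq)
      lines <- c(lines, paste(
        v$chrom, "jointvar", v$category, sp$start, sp$end, ".", t$strand,
        ".",
        paste0("Parent=", t$transcript_id, ";variant_kind=", v$kind,
               ";Reference_seq=", if (nzchar(v$ref_seq)) v$ref_seq else "-",
               ";Variant_seq=", if (nzchar(v$alt_seq)) v$alt_seq else "-"),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Summary statistics of an annotation run
#'
#' @param annotations Annotation tibble.
#' @param transcripts Reconstruction tibble.
#' @param components Component tibble (all variants, genome-wide).
#' @return List of tibbles: `orf_status_counts`, `affected_by_kind`
#'   (transcripts per combination of impacting variant kinds),
#'   `internal_stop_distribution` (decile bins of the first-internal-stop
#'   percentage), `codon_bias` (per reference codon, synonymous vs
#'   non-synonymous SNV counts), `indel_lengths_genome` and
#'   `indel_lengths_cds` (signed-length histograms).
#' @export
compute_run_stats <- function(annotations, transcripts, components) {
  status <- transcripts |>
    count(orf_status = factor(.data$orf_status, levels = ORF_STATUSES),
          .drop = FALSE, name = "n_transcripts") |>
    mutate(orf_status = as.character(.data$orf_status))
  affected <- annotations |>
    distinct(.data$transcript_id, .data$kind) |>
    group_by(.data$transcript_id) |>
    summarise(kinds = paste(sort(unique(.data$kind)), collapse = "+"),
              .groups = "drop") |>
    count(.data$kinds, name = "n_transcripts")
  stop_bins <- transcripts |>
    filter(!is.na(.data$first_internal_stop_pct)) |>
    mutate(bin = pmin(floor(.data$first_internal_stop_pct / 10) * 10, 90)) |>
    count(.data$bin, name = "n_transcripts") |>
    mutate(bin = paste0(.data$bin, "-", .data$bin + 10, "%"))
  codon_bias <- annotations |>
    filter(.data$kind == "SNV", !is.na(.data$ref_codon),
           .data$category %in% c("synonymous_codon",
                                 "conservative_missense_codon",
                                 "non_conservative_missense_codon",
                                 "stop_gained", "stop_lost")) |>
    group_by(codon = .data$ref_codon) |>
    summarise(
      synonymous = sum(.data$category == "synonymous_codon"),
      non_synonymous = sum(.data$category != "synonymous_codon"),
      .groups = "drop"
    )
  signed_len <- function(d) {
    ifelse(d$kind == "insertion", nchar(d$alt_seq), -nchar(d$ref_seq))
  }
  genome_indels <- filter(components, .data$kind != "SNV")
  lens_genome <- if (nrow(genome_indels) > 0) {
    tibble(length = signed_len(genome_indels)) |>
      count(.data$length, name = "n_variants")
  } else {
    tibble(length = integer(), n_variants = integer())
  }
  cds_indels <- annotations |>
    filter(.data$kind != "SNV",
           (!is.na(.data$coding_length_delta) &
              .data$coding_length_delta != 0) |
             .data$category %in% c("splice_donor_variant",
                                   "splice_acceptor_variant")) |>
    distinct(.data$chrom, .data$pos, .data$kind, .data$ref_seq,
             .data$alt_seq)
  lens_cds <- if (nrow(cds_indels) > 0) {
    tibble(length = signed_len(cds_indels)) |>
      count(.data$length, name = "n_variants")
  } else {
    tibble(length = integer(), n_variants = integer())
  }
  list(
    orf_status_counts = status,
    affected_by_kind = affected,
    internal_stop_distribution = stop_bins,
    codon_bias = codon_bias,
    indel_lengths_genome = lens_genome,
    indel_lengths_cds = lens_cds
  )
}

#' Write run statistics to tab-separated text files
#'
#' Emits `variant.stat` (ORF-status counts, transcripts affected per variant
#' kind combination, internal-stop location distribution), `codon_bias.stat`
#' and two indel-length histograms into `dir`.
#'
#' @param stats List from [compute_run_stats()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run_stats <- function(stats, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d) {
    c(paste(names(d), collapse = "\t"),
      if (nrow(d) > 0) do.call(paste, c(unname(as.list(d)), sep = "\t")))
  }
  writeLines(c(
    "# transcripts per ORF status", tsv(stats$orf_status_counts), "",
    "# transcripts affected per variant-kind combination",
    tsv(stats$affected_by_kind), "",
    "# first internal stop location (percent of reference ORF)",
    tsv(stats$internal_stop_distribution)
  ), file.path(dir, "variant.stat"))
  writeLines(tsv(stats$codon_bias), file.path(dir, "codon_bias.stat"))
  writeLines(tsv(stats$indel_lengths_genome),
             file.path(dir, "indel_lengths_genome.stat"))
  writeLines(tsv(stats$indel_lengths_cds),
             file.path(dir, "indel_lengths_cds.stat"))
  invisible(dir)
}

#' Write Circos-compatible density tracks
#'
#' Bins each chromosome into fixed-width windows and writes four track files
#' (`snvs`, `insertions`, `deletions`, `coding_exons`) with lines
#' `chrom start end count`, where count is the number of features whose
#' start position falls in the bin.
#'
#' @param components Component tibble.
#' @param exons Coding-exon tibble.
#' @param genome Reference genome (for chromosome lengths), or a named
#'   integer vector of chromosome lengths.
#' @param dir Output directory.
#' @param bin_size Bin width in bp (default 100 kb).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_circos_tracks <- function(components, exons, genome, dir,
                                bin_size = 1e5) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lens <- if (is.character(genome)) nchar(genome) else as.integer(genome)
  lens <- setNames(as.integer(lens), names(genome))
  track <- function(chroms, starts) {
    out <- character(0)
    for (ch in names(lens)) {
      bins_start <- seq(1L, lens[[ch]], by = as.integer(bin_size))
      bins_end <- pmin(bins_start + as.integer(bin_size) - 1L, lens[[ch]])
      p <- starts[chroms == ch]
      counts <- if (length(p) > 0) {
        tabulate(findInterval(p, bins_start), nbins = length(bins_start))
      } else {
        rep(0L, length(bins_start))
      }
      out <- c(out, paste(ch, bins_start, bins_end, counts))
    }
    out
  }
  files <- c(snvs = "snvs.circos.txt", insertions = "insertions.circos.txt",
             deletions = "deletions.circos.txt",
             coding_exons = "coding_exons.circos.txt")
  for (k in c("SNV", "insertion", "deletion")) {
    d <- components[components$kind == k, , drop = FALSE]
    key <- c(SNV = "snvs", insertion = "insertions", deletion = "deletions")[k]
    writeLines(track(d$chrom, d$pos), file.path(dir, files[[key]]))
  }
  writeLines(track(exons$chrom, exons$start),
             file.path(dir, files[["coding_exons"]]))
  invisible(file.path(dir, unname(files)))
}

# 60-column FASTA writer for plain character vectors.
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    if (nchar(s) == 0) {
      writeLines("", con)
    } else {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
                 con)
    }
  }
  invisible(path)
}

#' Write variant transcript/protein FASTA files and exon alignments
#'
#' Produces full-length variant CDS and protein FASTA files, per-exon
#' reference and variant FASTA files, and a text alignment file in which
#' unchanged bases are lowercase, variant bases UPPERCASE, and `-` marks
#' gaps.
#'
#' @param transcripts Reconstruction tibble from
#'   [reconstruct_transcripts()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_variant_sequences <- function(transcripts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  transcripts <- arrange(transcripts, .data$transcript_id)
  write_fasta(setNames(transcripts$var_cds, transcripts$transcript_id),
              file.path(dir, "variant_transcripts.fasta"))
  write_fasta(setNames(transcripts$var_protein, transcripts$transcript_id),
              file.path(dir, "variant_proteins.fasta"))
  ref_ex <- character(0)
  var_ex <- character(0)
  aln_lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    aln <- t$exon_alignments[[1]]
    for (j in seq_len(nrow(aln))) {
      id <- paste0(t$transcript_id, ".exon", aln$exon[j])
      ref_ex[[id]] <- toupper(gsub("-", "", aln$ref_row[j], fixed = TRUE))
      var_ex[[id]] <- toupper(gsub("-", "", aln$var_row[j], fixed = TRUE))
      aln_lines <- c(aln_lines, paste0(">", id),
                     paste0("ref ", aln$ref_row[j]),
                     paste0("var ", aln$var_row[j]))
    }
  }
  write_fasta(ref_ex, file.path(dir, "reference_exons.fasta"))
  write_fasta(var_ex, file.path(dir, "variant_exons.fasta"))
  writeLines(aln_lines, file.path(dir, "exon_alignments.txt"))
  invisible(dir)
}
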