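#' Read a reference genome from FASTA
#'
#' Loads a (multi-record, possibly line-wrapped) FASTA file and returns the
#' sequences as an uppercase named character vector, one element per
#' chromosome. The chromosome identifier is the header token before the first
#' whitespace; any description after it is dropped.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase nucleotide sequences
#'   (alphabet `ACGTN`).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "acgtACGT"), fa)
#' read_genome(fa)
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate chromosome id(s) in FASTA: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  setNames(toupper(as.character(seqs)), ids)
}

#' Read protein-coding exon models from GFF3 or GTF
#'
#' Consumes only `CDS`-typed features. The dialect is auto-detected from the
#' attribute syntax (`ID=`/`Parent=` for GFF3 versus space-and-quotes GTF
#' `transcript_id`). Exons are grouped by transcript, sorted by genomic start,
#' and validated: transcripts with exons on mixed chromosomes/strands, with
#' overlapping exons, or with a total coding length below one codon are
#' rejected with a warning.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A tibble of coding exons with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (coordinates 1-based inclusive), sorted by
#'   transcript and start.
#' @export
read_coding_exons <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  fmt <- detect_gff_dialect(path)
  gr <- rtracklayer::import(path, format = fmt)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0) abort(paste0("no CDS features found in ", path))
  if (fmt == "gtf") {
    tid <- as.character(gr$transcript_id)
  } else {
    par <- gr$Parent
    tid <- vapply(as.list(par), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    # CDS rows without Parent fall back to their own ID
    if (anyNA(tid) && !is.null(gr$ID)) tid[is.na(tid)] <- gr$ID[is.na(tid)]
  }
  exons <- tibble(
    transcript_id = tid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  exons <- filter(exons, !is.na(.data$transcript_id))
  validate_coding_exons(exons)
}

detect_gff_dialect <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(data) == 0) return("gff3")
  attrs <- vapply(strsplit(data, "\t", fixed = TRUE), function(f) {
    if (length(f) >= 9) f[9] else ""
  }, character(1))
  if (any(grepl("transcript_id\\s+\"", attrs))) "gtf" else "gff3"
}

validate_coding_exons <- function(exons) {
  exons <- arrange(exons, .data$transcript_id, .data$start)
  bad <- exons |>
    group_by(.data$transcript_id) |>
    summarise(
      mixed = n_distinct(.data$strand) > 1 | n_distinct(.data$chrom) > 1,
      overlapping = n() > 1 && any(.data$start[-1] <= .data$end[-n()]),
      too_short = sum(.data$end - .data$start + 1) < 3,
      bad_strand = any(!.data$strand %in% c("+", "-")),
      .groups = "drop"
    ) |>
    filter(.data$mixed | .data$overlapping | .data$too_short | .data$bad_strand)
  if (nrow(bad) > 0) {
    warn(paste0(
      "rejected ", nrow(bad), " transcript model(s) failing validation: ",
      paste(head(bad$transcript_id, 5), collapse = ", "),
      if (nrow(bad) > 5) ", ..." else ""
    ))
    exons <- filter(exons, !.data$transcript_id %in% bad$transcript_id)
  }
  exons
}

# Internal per-transcript model used by the annotation engine: a plain list
# with exon bounds in genomic order plus cached CDS geometry.
transcript_model <- function(exons, id) {
  ex <- exons[exons$transcript_id == id, , drop = FALSE]
  if (nrow(ex) == 0) abort(paste0("unknown transcript: ", id))
  ex <- ex[order(ex$start), , drop = FALSE]
  lens <- ex$end - ex$start + 1L
  list(
    id = id,
    chrom = ex$chrom[1],
    strand = ex$strand[1],
    starts = ex$start,
    ends = ex$end,
    lens = lens,
    cum_before = cumsum(c(0L, lens))[seq_along(lens)],
    cds_len = sum(lens),
    tx_start = min(ex$start),
    tx_end = max(ex$end)
  )
}

transcript_models <- function(exons) {
  ids <- unique(exons$transcript_id)
  setNames(lapply(ids, function(id) transcript_model(exons, id)), ids)
}

#' Spliced coding sequence of a transcript
#'
#' Concatenates the exon sequences in genomic order and, for minus-strand
#' transcripts, reverse-complements the concatenation so the result always
#' reads 5'->3' in coding orientation.
#'
#' @param exons Coding-exon tibble (see [read_coding_exons()]).
#' @param transcript_id Transcript to splice.
#' @param genome Named character vector from [read_genome()].
#' @return Nucleotide string (the CDS, coding orientation).
#' @export
spliced_cds <- function(exons, transcript_id, genome) {
  model <- transcript_model(exons, transcript_id)
  model_spliced_cds(model, genome)
}

model_spliced_cds <- function(model, genome) {
  chrom_seq <- genome_chrom(genome, model$chrom)
  if (any(model$ends > nchar(chrom_seq))) {
    abort(paste0(
      "transcript ", model$id, " exceeds bounds of chromosome ", model$chrom
    ))
  }
  pieces <- substring(chrom_seq, model$starts, model$ends)
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds) else cds
}

genome_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome not present in reference genome: ", chrom))
  }
  genome[[chrom]]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

#' Default codon table (standard genetic code)
#'
#' @return Named character vector mapping each of the 64 codons to an
#'   amino-acid letter, with `*` for stop codons.
#' @export
default_codon_table <- function() {
  tab <- Biostrings::GENETIC_CODE
  setNames(as.character(tab), names(tab))
}

#' Read a codon table from a two-column file
#'
#' Expects tab-separated lines `codon<TAB>amino-acid` (one-letter, `*` for
#' stop); lines starting with `#` are ignored. Exactly 64 codons required.
#'
#' @param path Path to the codon-table file.
#' @return Named character vector as [default_codon_table()].
#' @export
read_codon_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  codons <- toupper(vapply(parts, `[`, character(1), 1))
  aas <- toupper(vapply(parts, `[`, character(1), 2))
  if (length(codons) != 64 || anyDuplicated(codons)) {
    abort("codon table must define exactly 64 distinct codons")
  }
  setNames(aas, codons)
}

#' Translate a coding sequence
#'
#' Full-peptide translation: does not halt at internal stop codons (rendered
#' `*`), so their positions can be located. A trailing partial codon (1-2 nt)
#' is ignored; codons containing characters outside `ACGT` translate to `X`.
#'
#' @param cds Nucleotide string.
#' @param codon_table Codon table (see [default_codon_table()]).
#' @return Amino-acid string of length `floor(nchar(cds) / 3)`.
#' @export
#' @examples
#' translate_cds("ATGTAA")
translate_cds <- function(cds, codon_table = default_codon_table()) {
  n <- nchar(cds) %/% 3L
  if (n == 0) return("")
  starts <- 3L * seq_len(n) - 2L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Map a genomic position to its 0-based CDS offset
#'
#' Strand-aware: offset 0 is the first coding base in coding orientation.
#' Positions not inside any coding exon map to `NA`.
#'
#' @param exons Coding-exon tibble.
#' @param transcript_id Transcript id.
#' @param genomic_pos Integer vector of 1-based genomic positions.
#' @return Integer vector of 0-based CDS offsets (`NA` outside exons).
#' @export
genomic_to_cds_offset <- function(exons, transcript_id, genomic_pos) {
  model <- transcript_model(exons, transcript_id)
  model_cds_offset(model, genomic_pos)
}

model_cds_offset <- function(model, genomic_pos) {
  vapply(genomic_pos, function(p) {
    i <- which(model$starts <= p & model$ends >= p)
    if (length(i) == 0) return(NA_integer_)
    off_plus <- model$cum_before[i] + (p - model$starts[i])
    if (model$strand == "+") off_plus else model$cds_len - 1L - off_plus
  }, integer(1))
}

# Inverse of model_cds_offset: 0-based CDS offset -> genomic position.
model_offset_to_genomic <- function(model, offset) {
  vapply(offset, function(o) {
    if (is.na(o) || o < 0 || o >= model$cds_len) return(NA_integer_)
    op <- if (model$strand == "+") o else model$cds_len - 1L - o
    i <- max(which(model$cum_before <= op))
    as.integer(model$starts[i] + (op - model$cum_before[i]))
  }, integer(1))
}

#' Splice-site dinucleotide windows of a transcript
#'
#' For every intron, returns the two intronic bases adjacent to the upstream
#' exon (coding orientation) tagged `donor` and the two adjacent to the
#' downstream exon tagged `acceptor`. Strand-aware; a single-exon transcript
#' yields an empty tibble. Windows are clipped to the intron for introns
#' shorter than 2 bp.
#'
#' @param exons Coding-exon tibble.
#' @param transcript_id Transcript id.
#' @return Tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `site` (`donor`/`acceptor`), `intron` (index in genomic order).
#' @export
splice_site_windows <- function(exons, transcript_id) {
  model <- transcript_model(exons, transcript_id)
  model_splice_windows(model)
}

model_splice_windows <- function(model) {
  k <- length(model$starts)
  if (k < 2) {
    return(tibble(
      transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), site = character(),
      intron = integer()
    ))
  }
  istart <- model$ends[-k] + 1L
  iend <- model$starts[-1] - 1L
  keep <- istart <= iend
  istart <- istart[keep]
  iend <- iend[keep]
  if (length(istart) == 0) {
    return(model_splice_windows(list(starts = 1L)))  # empty tibble
  }
  left <- tibble(start = istart, end = pmin(istart + 1L, iend))
  right <- tibble(start = pmax(iend - 1L, istart), end = iend)
  if (model$strand == "+") {
    left$site <- "donor"
    right$site <- "acceptor"
  } else {
    left$site <- "acceptor"
    right$site <- "donor"
  }
  out <- bind_rows(
    mutate(left, intron = seq_along(istart)),
    mutate(right, intron = seq_along(istart))
  )
  mutate(out,
    transcript_id = model$id, chrom = model$chrom,
    .before = 1
  )
}
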