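#' Apply all variants of a transcript and rebuild its CDS and protein
#'
#' Substitutions, insertions and deletions are applied jointly to the exon
#' sequences (in descending coordinate order, so genomic positions stay
#' valid), spliced, orientation-corrected, and translated. Insertions whose
#' anchor gap lies outside the coding exons and intronic parts of straddling
#' deletions do not alter the CDS. A deletion covering the whole transcript
#' span yields an empty variant CDS (`FULLY_DELETED`).
#'
#' @param exons Coding-exon tibble.
#' @param transcript_id Transcript id.
#' @param genome Reference genome.
#' @param variants Component-variant tibble for this transcript (columns
#'   `kind`, `pos`, `ref_seq`, `alt_seq`).
#' @param codon_table Codon table.
#' @return List with `transcript_id`, `ref_cds`, `var_cds`, `ref_protein`,
#'   `var_protein`, `fully_deleted`, and `exon_alignments` (tibble with
#'   `exon`, `ref_row`, `var_row`: unchanged bases lowercase, variant bases
#'   UPPERCASE, `-` marking gaps).
#' @export
apply_transcript_variants <- function(exons, transcript_id, genome, variants,
                                      codon_table = default_codon_table()) {
  model <- transcript_model(exons, transcript_id)
  ref_cds <- model_spliced_cds(model, genome)
  fully_deleted <- nrow(variants) > 0 && any(
    variants$kind == "deletion" &
      variants$pos <= model$tx_start &
      variants$pos + nchar(variants$ref_seq) - 1L >= model$tx_end
  )
  aln <- render_exon_alignments(model, genome, variants)
  if (fully_deleted) {
    var_cds <- ""
  } else {
    pieces <- map_chr(aln$var_row, function(row) {
      toupper(gsub("-", "", row, fixed = TRUE))
    })
    var_cds <- paste(pieces, collapse = "")
    if (model$strand == "-" && nchar(var_cds) > 0) var_cds <- revcomp(var_cds)
  }
  list(
    transcript_id = transcript_id,
    ref_cds = ref_cds,
    var_cds = var_cds,
    ref_protein = translate_cds(ref_cds, codon_table),
    var_protein = translate_cds(var_cds, codon_table),
    fully_deleted = fully_deleted,
    exon_alignments = aln
  )
}

#' Exon-based alignment of reference and variant sequences
#'
#' Per-exon gapped rendering on the plus (genomic) strand: SNVs appear as
#' UPPERCASE bases in both rows, insertions as a `-` run in the reference
#' row with UPPERCASE inserted bases in the variant row, deletions as
#' UPPERCASE in the reference row and `-` in the variant row; unchanged
#' bases are lowercase.
#'
#' @inheritParams apply_transcript_variants
#' @return Tibble with `exon` (index in genomic order), `ref_row`,
#'   `var_row`.
#' @export
exon_alignment <- function(exons, transcript_id, genome, variants) {
  model <- transcript_model(exons, transcript_id)
  render_exon_alignments(model, genome, variants)
}

render_exon_alignments <- function(model, genome, variants) {
  chrom_seq <- genome_chrom(genome, model$chrom)
  rows <- map(seq_along(model$starts), function(i) {
    s <- model$starts[i]
    e <- model$ends[i]
    r <- strsplit(tolower(substr(chrom_seq, s, e)), "")[[1]]
    v <- r
    ev <- exon_events(variants, s, e)
    for (j in seq_len(nrow(ev))) {
      x <- ev[j, ]
      if (x$kind == "SNV") {
        li <- x$pos - s + 1L
        r[li] <- toupper(x$ref_seq)
        v[li] <- toupper(x$alt_seq)
      } else if (x$kind == "deletion") {
        li1 <- max(x$pos, s) - s + 1L
        li2 <- min(x$pos + nchar(x$ref_seq) - 1L, e) - s + 1L
        r[li1:li2] <- toupper(r[li1:li2])
        v[li1:li2] <- "-"
      } else {
        li <- x$pos - s + 1L
        ins <- strsplit(toupper(x$alt_seq), "")[[1]]
        r <- append(r, rep("-", length(ins)), after = li)
        v <- append(v, ins, after = li)
      }
    }
    tibble(exon = i, ref_row = paste(r, collapse = ""),
           var_row = paste(v, collapse = ""))
  })
  bind_rows(rows)
}

# Events touching exon [s, e], ordered for descending-coordinate application.
exon_events <- function(variants, s, e) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(tibble(kind = character(), pos = integer(),
                  ref_seq = character(), alt_seq = character()))
  }
  keep <- (variants$kind == "SNV" & variants$pos >= s & variants$pos <= e) |
    (variants$kind == "deletion" &
       variants$pos <= e & variants$pos + nchar(variants$ref_seq) - 1L >= s) |
    (variants$kind == "insertion" & variants$pos >= s & variants$pos < e)
  ev <- variants[keep, c("kind", "pos", "ref_seq", "alt_seq"), drop = FALSE]
  ev[order(-ev$pos, ev$kind != "insertion"), , drop = FALSE]
}

#' Percentage location of the first internal stop codon
#'
#' An internal stop is a `*` before the final residue of the (full-length)
#' translation. The location is reported relative to the REFERENCE protein
#' length: `100 * index / nchar(ref_protein)`.
#'
#' @param ref_protein,var_protein Amino-acid strings.
#' @return Percentage (numeric), or `NA` when the variant protein has no
#'   internal stop.
#' @export
first_internal_stop_percentage <- function(ref_protein, var_protein) {
  idx <- first_internal_stop(var_protein)
  if (is.na(idx) || nchar(ref_protein) == 0) return(NA_real_)
  100 * idx / nchar(ref_protein)
}

# 1-based index of the first internal '*' (NA if none).
first_internal_stop <- function(protein) {
  n <- nchar(protein)
  if (n < 2) return(NA_integer_)
  stops <- which(strsplit(protein, "")[[1]] == "*")
  stops <- stops[stops < n]
  if (length(stops) == 0) NA_integer_ else stops[1]
}

has_internal_stop <- function(protein) !is.na(first_internal_stop(protein))

#' ORF status of a variant transcript
#'
#' `FULLY_DELETED` when the whole transcript span is deleted;
#' `ORF_DISRUPTED` when any splice-dinucleotide variant is present or the
#' variant protein gains a NEW internal stop (the stop criterion is disabled
#' for transcripts whose reference protein already contains an internal
#' stop); `ORF_PRESERVED` when variants are present but neither applies;
#' `ORF_INTACT` when no variant touches the transcript.
#'
#' @param ref_protein,var_protein Amino-acid strings.
#' @param annotations Annotation tibble rows for this transcript (their
#'   presence marks the transcript as impacted; splice categories trigger
#'   disruption).
#' @param fully_deleted Logical flag.
#' @return One of `ORF_INTACT`, `ORF_PRESERVED`, `ORF_DISRUPTED`,
#'   `FULLY_DELETED`.
#' @export
orf_status <- function(ref_protein, var_protein, annotations,
                       fully_deleted = FALSE) {
  if (isTRUE(fully_deleted)) return("FULLY_DELETED")
  touched <- !is.null(annotations) && nrow(annotations) > 0
  if (!touched) return("ORF_INTACT")
  splice_hit <- any(annotations$category %in%
                      c("splice_donor_variant", "splice_acceptor_variant"))
  if (splice_hit) return("ORF_DISRUPTED")
  if (!has_internal_stop(ref_protein) && has_internal_stop(var_protein)) {
    return("ORF_DISRUPTED")
  }
  "ORF_PRESERVED"
}

#' Reconstruct all transcripts under their assigned variants
#'
#' Runs [apply_transcript_variants()] for every transcript in `exons`
#' (including untouched ones, which come back `ORF_INTACT`), derives ORF
#' status and the first-internal-stop percentage.
#'
#' @param assigned Variant x transcript tibble from [assign_variants()]
#'   (after annotation-stage reference checks, pass the annotation tibble's
#'   variant columns to stay consistent).
#' @param exons Coding-exon tibble.
#' @param genome Reference genome.
#' @param annotations Annotation tibble from [annotate_variants()].
#' @param codon_table Codon table.
#' @return Tibble, one row per transcript: `transcript_id`, `chrom`,
#'   `strand`, `n_variants`, `orf_status`, `first_internal_stop_pct`,
#'   `ref_cds`, `var_cds`, `ref_protein`, `var_protein`, `exon_alignments`
#'   (list-column).
#' @export
reconstruct_transcripts <- function(assigned, exons, genome, annotations,
                                    codon_table = default_codon_table()) {
  ids <- unique(exons$transcript_id)
  rows <- map(ids, function(id) {
    vars <- annotations[annotations$transcript_id == id, , drop = FALSE]
    rec <- apply_transcript_variants(exons, id, genome, vars, codon_table)
    status <- orf_status(rec$ref_protein, rec$var_protein, vars,
                         rec$fully_deleted)
    pct <- if (status == "ORF_DISRUPTED" &&
               !has_internal_stop(rec$ref_protein)) {
      first_internal_stop_percentage(rec$ref_protein, rec$var_protein)
    } else {
      NA_real_
    }
    model <- transcript_model(exons, id)
    tibble(
      transcript_id = id, chrom = model$chrom, strand = model$strand,
      n_variants = nrow(vars), orf_status = status,
      first_internal_stop_pct = pct,
      ref_cds = rec$ref_cds, var_cds = rec$var_cds,
      ref_protein = rec$ref_protein, var_protein = rec$var_protein,
      exon_alignments = list(rec$exon_alignments)
    )
  })
  bind_rows(rows)
}
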