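#' Reference and variant codon under co-occurring SNVs
#'
#' Computes the reference codon at `codon_index` (0-based, coding
#' orientation) of a transcript and the variant codon obtained by applying
#' ALL supplied SNVs that fall in that codon simultaneously. This is the
#' joint-effect primitive: a substitution that looks synonymous on its own
#' can be missense once a neighbouring same-codon substitution is taken into
#' account.
#'
#' @param exons Coding-exon tibble.
#' @param transcript_id Transcript id.
#' @param genome Reference genome (named character vector).
#' @param codon_index 0-based codon index in the CDS.
#' @param snvs Tibble of SNV components (`pos`, `ref_seq`, `alt_seq`) that
#'   co-occur on this transcript; SNVs outside the codon are ignored.
#' @param codon_table Codon table.
#' @return List with `ref_codon` and `var_codon` (3-mers, coding
#'   orientation).
#' @export
variant_codon <- function(exons, transcript_id, genome, codon_index, snvs,
                          codon_table = default_codon_table()) {
  model <- transcript_model(exons, transcript_id)
  cds <- model_spliced_cds(model, genome)
  joint_codon(model, cds, codon_index, snvs)
}

joint_codon <- function(model, cds, codon_index, snvs) {
  ref_codon <- substr(cds, 3L * codon_index + 1L, 3L * codon_index + 3L)
  var <- strsplit(ref_codon, "")[[1]]
  if (!is.null(snvs) && nrow(snvs) > 0) {
    off <- model_cds_offset(model, snvs$pos)
    in_codon <- !is.na(off) & off %/% 3L == codon_index
    for (i in which(in_codon)) {
      base <- if (model$strand == "+") snvs$alt_seq[i] else
        comp_base(snvs$alt_seq[i])
      var[off[i] %% 3L + 1L] <- base
    }
  }
  list(ref_codon = ref_codon, var_codon = paste(var, collapse = ""))
}

#' Annotate component variants with Sequence Ontology consequences
#'
#' Classifies every variant x transcript pair. SNVs inside the coding
#' sequence are evaluated under the joint effect of all co-occurring SNVs in
#' the same codon (categories `synonymous_codon`,
#' `conservative_missense_codon`, `non_conservative_missense_codon`,
#' `stop_gained`, `stop_lost`); SNVs in a splice dinucleotide window become
#' `splice_donor_variant`/`splice_acceptor_variant`; anything else inside the
#' annotation window is `silent_mutation`. Indels are `frameshift_variant`
#' or `inframe_variant` by their net coding-length change (splice overlap
#' takes precedence; boundary insertions whose anchor gap lies outside the
#' CDS contribute nothing). Variants whose reference allele disagrees with
#' the genome are skipped with a warning.
#'
#' @param assigned Variant x transcript tibble from [assign_variants()].
#' @param exons Coding-exon tibble.
#' @param genome Reference genome.
#' @param codon_table Codon table.
#' @param grantham Grantham matrix.
#' @return Tibble: the assigned columns plus `category`, `ref_codon`,
#'   `var_codon`, `ref_aa`, `var_aa`, `grantham_score`, `grantham_class`,
#'   `coding_length_delta`.
#' @export
annotate_variants <- function(assigned, exons, genome,
                              codon_table = default_codon_table(),
                              grantham = default_grantham_matrix()) {
  empty <- tibble(
    record = integer(), chrom = character(), kind = character(),
    pos = integer(), ref_seq = character(), alt_seq = character(),
    transcript_id = character(), category = character(),
    ref_codon = character(), var_codon = character(),
    ref_aa = character(), var_aa = character(),
    grantham_score = integer(), grantham_class = character(),
    coding_length_delta = integer()
  )
  if (nrow(assigned) == 0) return(empty)
  assigned <- drop_reference_mismatches(assigned, genome)
  if (nrow(assigned) == 0) return(empty)
  models <- transcript_models(
    exons[exons$transcript_id %in% unique(assigned$transcript_id), ,
          drop = FALSE]
  )
  out <- map_dfr(models, function(model) {
    vars <- assigned[assigned$transcript_id == model$id, , drop = FALSE]
    annotate_transcript_variants(vars, model, genome, codon_table, grantham)
  })
  bind_rows(empty, out)
}

drop_reference_mismatches <- function(components, genome) {
  n <- nrow(components)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (components$kind[i] == "insertion") next
    len <- nchar(components$ref_seq[i])
    chrom_seq <- genome_chrom(genome, components$chrom[i])
    obs <- substr(chrom_seq, components$pos[i], components$pos[i] + len - 1L)
    ok[i] <- identical(obs, components$ref_seq[i])
  }
  if (any(!ok)) {
    warn(paste0("skipped ", sum(!ok), " variant(s) whose reference allele ",
                "disagrees with the genome"))
  }
  components[ok, , drop = FALSE]
}

annotate_transcript_variants <- function(vars, model, genome, codon_table,
                                         grantham) {
  cds <- model_spliced_cds(model, genome)
  windows <- model_splice_windows(model)
  snvs <- vars[vars$kind == "SNV", , drop = FALSE]
  vars$category <- NA_character_
  vars$ref_codon <- NA_character_
  vars$var_codon <- NA_character_
  vars$ref_aa <- NA_character_
  vars$var_aa <- NA_character_
  vars$grantham_score <- NA_integer_
  vars$grantham_class <- NA_character_
  vars$coding_length_delta <- NA_integer_

  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$kind == "SNV") {
      site <- snv_splice_site(v$pos, windows)
      if (!is.na(site)) {
        vars$category[i] <- paste0("splice_", site, "_variant")
        next
      }
      off <- model_cds_offset(model, v$pos)
      if (is.na(off)) {
        vars$category[i] <- "silent_mutation"
        next
      }
      ci <- off %/% 3L
      cod <- joint_codon(model, cds, ci, snvs)
      ref_aa <- translate_cds(cod$ref_codon, codon_table)
      var_aa <- translate_cds(cod$var_codon, codon_table)
      vars$ref_codon[i] <- cod$ref_codon
      vars$var_codon[i] <- cod$var_codon
      vars$ref_aa[i] <- ref_aa
      vars$var_aa[i] <- var_aa
      if (ref_aa == var_aa) {
        vars$category[i] <- "synonymous_codon"
      } else if (var_aa == "*") {
        vars$category[i] <- "stop_gained"
      } else if (ref_aa == "*") {
        vars$category[i] <- "stop_lost"
      } else if (ref_aa == "X" || var_aa == "X") {
        # ambiguous reference context; treat conservatively as silent
        vars$category[i] <- "silent_mutation"
      } else {
        g <- grantham_classify(ref_aa, var_aa, grantham)
        vars$category[i] <- g$so_category
        vars$grantham_score[i] <- g$score
        vars$grantham_class[i] <- g$class
      }
    } else {
      site <- indel_splice_site(v, windows)
      if (!is.na(site)) {
        vars$category[i] <- paste0("splice_", site, "_variant")
        next
      }
      delta <- coding_length_delta(v, model)
      vars$coding_length_delta[i] <- delta
      vars$category[i] <- if (delta %% 3L != 0L) "frameshift_variant"
        else if (delta != 0L) "inframe_variant"
        else "silent_mutation"
    }
  }
  vars
}

snv_splice_site <- function(pos, windows) {
  if (nrow(windows) == 0) return(NA_character_)
  hit <- which(windows$start <= pos & windows$end >= pos)
  if (length(hit) == 0) NA_character_ else windows$site[hit[1]]
}

indel_splice_site <- function(v, windows) {
  if (nrow(windows) == 0) return(NA_character_)
  if (v$kind == "insertion") {
    # anchor gap strictly inside the window: both flanking bases within it
    hit <- which(windows$start <= v$pos & windows$end >= v$pos + 1L)
  } else {
    e <- v$pos + nchar(v$ref_seq) - 1L
    hit <- which(windows$start <= e & windows$end >= v$pos)
  }
  if (length(hit) == 0) NA_character_ else windows$site[hit[1]]
}

# Net change in coding length caused by one indel: inserted bases count only
# when the anchor gap is strictly inside a coding exon; deleted bases count
# only where they overlap coding exons.
coding_length_delta <- function(v, model) {
  if (v$kind == "insertion") {
    inside <- any(model$starts <= v$pos & model$ends > v$pos)
    if (inside) nchar(v$alt_seq) else 0L
  } else {
    e <- v$pos + nchar(v$ref_seq) - 1L
    ov <- pmin(model$ends, e) - pmax(model$starts, v$pos) + 1L
    -sum(pmax(ov, 0L))
  }
}

#' Variants with divergent consequences across transcripts
#'
#' Lists SNVs annotated with two or more distinct Sequence Ontology
#' categories across the transcripts they impact (e.g. synonymous in one
#' transcript, missense in another).
#'
#' @param annotations Annotation tibble from [annotate_variants()].
#' @return Tibble of the multi-category SNVs, one row per variant x
#'   transcript, with an `n_categories` column.
#' @export
multi_category_variants <- function(annotations) {
  snv <- filter(annotations, .data$kind == "SNV")
  snv |>
    group_by(.data$chrom, .data$pos, .data$ref_seq, .data$alt_seq) |>
    mutate(n_categories = n_distinct(.data$category)) |>
    ungroup() |>
    filter(.data$n_categories >= 2) |>
    arrange(.data$chrom, .data$pos, .data$transcript_id)
}
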