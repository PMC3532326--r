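#' Read variants from a VCF file
#'
#' Minimal VCF 4.x ingestion tailored to joint-consequence annotation: only
#' `CHROM`, `POS`, `REF` and the FIRST comma-separated `ALT` allele are
#' retained (multi-allelic sites are truncated to their first alternative
#' allele). Symbolic ALT alleles (`<...>`) and breakends are skipped with a
#' warning, as are malformed data lines; skip counts are attached as the
#' `skipped` attribute.
#'
#' @param path Path to a VCF file.
#' @return Tibble of raw variant records with columns `chrom`, `pos`
#'   (1-based position of the first REF base), `ref`, `alt` (uppercase).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parse_variant_lines(data, min_fields = 8L, ref_col = 4L, alt_col = 5L)
}

#' Read variants from a simple tab-delimited file
#'
#' Four columns: `chrom`, `pos`, `ref`, `alt`; lines starting with `#` are
#' ignored; lines with the wrong column count are skipped with a warning.
#'
#' @inheritParams read_vcf
#' @return As [read_vcf()].
#' @export
read_variant_tab <- function(path) {
  if (!file.exists(path)) abort(paste0("variant file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parse_variant_lines(data, min_fields = 4L, ref_col = 3L, alt_col = 4L,
                      exact_fields = 4L)
}

parse_variant_lines <- function(data, min_fields, ref_col, alt_col,
                                exact_fields = NULL) {
  fields <- strsplit(data, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok_shape <- if (is.null(exact_fields)) nf >= min_fields else nf == exact_fields
  n_malformed <- sum(!ok_shape)
  fields <- fields[ok_shape]
  rec <- tibble(
    chrom = map_chr(fields, 1),
    pos = suppressWarnings(as.integer(map_chr(fields, 2))),
    ref = toupper(map_chr(fields, ref_col)),
    alt = toupper(map_chr(fields, alt_col))
  )
  # first-ALT-only policy for multi-allelic records
  rec$alt <- sub(",.*$", "", rec$alt)
  symbolic <- grepl("[][<>]", rec$alt) | rec$alt == "*"
  bad <- is.na(rec$pos) | rec$pos < 1 |
    !grepl("^[ACGTN]+$", rec$ref) | (!grepl("^[ACGTN]+$", rec$alt) & !symbolic)
  n_symbolic <- sum(symbolic & !bad)
  n_malformed <- n_malformed + sum(bad)
  if (n_symbolic > 0) {
    warn(paste0("skipped ", n_symbolic, " symbolic/breakend ALT record(s)"))
  }
  if (n_malformed > 0) {
    warn(paste0("skipped ", n_malformed, " malformed variant line(s)"))
  }
  rec <- rec[!bad & !symbolic, , drop = FALSE]
  structure(rec, skipped = c(malformed = n_malformed, symbolic = n_symbolic))
}

#' Decompose compound variant records into atomic component variants
#'
#' A VCF record whose REF and ALT alleles differ at several positions and/or
#' in length encodes several atomic variants. Decomposition compares the
#' first `min(|ref|, |alt|)` bases position by position, emitting one SNV per
#' mismatch; an unmatched REF tail becomes a single deletion (first deleted
#' base at `pos + |alt|`) and an unmatched ALT tail a single insertion
#' anchored after `pos + |ref| - 1`. Re-applying the components to the REF
#' allele reconstructs the ALT allele exactly.
#'
#' @param records Tibble of raw records (from [read_vcf()] /
#'   [read_variant_tab()]) or any tibble with `chrom`, `pos`, `ref`, `alt`.
#' @return Tibble of component variants: `record` (input row index), `chrom`,
#'   `kind` (`SNV`/`insertion`/`deletion`), `pos` (SNV: substituted base;
#'   deletion: first deleted base; insertion: base AFTER which the sequence
#'   is inserted), `ref_seq`, `alt_seq`.
#' @export
#' @examples
#' decompose_variants(tibble::tibble(
#'   chrom = "chr1", pos = 100L, ref = "ATG", alt = "AC"
#' ))
decompose_variants <- function(records) {
  comp <- pmap(
    list(seq_len(nrow(records)), records$chrom, records$pos,
         records$ref, records$alt),
    function(i, chrom, pos, ref, alt) {
      d <- decompose_one(pos, ref, alt)
      if (nrow(d) > 0) mutate(d, record = i, chrom = chrom, .before = 1) else d
    }
  )
  out <- bind_rows(comp)
  if (nrow(out) == 0) {
    out <- tibble(record = integer(), chrom = character(), kind = character(),
                  pos = integer(), ref_seq = character(),
                  alt_seq = character())
  }
  out
}

decompose_one <- function(pos, ref, alt) {
  if (identical(ref, alt)) {
    return(tibble(kind = character(), pos = integer(),
                  ref_seq = character(), alt_seq = character()))
  }
  nr <- nchar(ref)
  na <- nchar(alt)
  m <- min(nr, na)
  rb <- substring(ref, 1:m, 1:m)
  ab <- substring(alt, 1:m, 1:m)
  mis <- which(rb != ab)
  snvs <- tibble(
    kind = rep("SNV", length(mis)),
    pos = pos + mis - 1L,
    ref_seq = rb[mis],
    alt_seq = ab[mis]
  )
  indel <- NULL
  if (nr > na) {
    indel <- tibble(kind = "deletion", pos = pos + na,
                    ref_seq = substr(ref, na + 1L, nr), alt_seq = "")
  } else if (na > nr) {
    indel <- tibble(kind = "insertion", pos = pos + nr - 1L,
                    ref_seq = "", alt_seq = substr(alt, nr + 1L, na))
  }
  bind_rows(snvs, indel)
}

#' Build an interval index over transcript annotation windows
#'
#' The annotation window of a transcript spans its outermost coding exons
#' extended by a flank (default 2 bp, enough to capture the splice
#' dinucleotides). Returns a `GRanges` usable with [assign_variants()].
#'
#' @param exons Coding-exon tibble.
#' @param flank Flank in bp added on both sides (default 2).
#' @return `GRanges` of annotation windows, one per transcript
#'   (`transcript_id` metadata column).
#' @export
build_transcript_index <- function(exons, flank = 2L) {
  tx <- exons |>
    group_by(.data$transcript_id) |>
    summarise(chrom = .data$chrom[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1L, tx$start - as.integer(flank)),
      end = tx$end + as.integer(flank)
    ),
    transcript_id = tx$transcript_id
  )
}

# Genomic footprint of a component variant used for window overlap:
# SNV pos..pos, deletion pos..pos+len-1, insertion anchor gap pos..pos+1.
component_span <- function(components) {
  len <- nchar(components$ref_seq)
  start <- components$pos
  end <- ifelse(components$kind == "deletion", components$pos + len - 1L,
         ifelse(components$kind == "insertion", components$pos + 1L,
                components$pos))
  tibble(start = as.integer(start), end = as.integer(end))
}

#' Assign component variants to overlapping transcripts
#'
#' Each component variant is attached to every transcript whose annotation
#' window it overlaps (a variant can appear under several transcripts).
#' Overlapping-deletion conflicts within one transcript are resolved in
#' coordinate order: a variant whose reference span (or, for insertions,
#' anchor gap) falls inside an earlier deletion's span is dropped with a
#' warning.
#'
#' @param components Component-variant tibble from [decompose_variants()].
#' @param exons Coding-exon tibble, or a prebuilt index from
#'   [build_transcript_index()].
#' @param flank Annotation-window flank (ignored if an index is supplied).
#' @return Tibble: component columns plus `transcript_id`, sorted by
#'   transcript then position.
#' @export
assign_variants <- function(components, exons, flank = 2L) {
  index <- if (inherits(exons, "GRanges")) exons else
    build_transcript_index(exons, flank)
  if (nrow(components) == 0) {
    return(mutate(components, transcript_id = character(0)))
  }
  span <- component_span(components)
  q <- GenomicRanges::GRanges(
    seqnames = components$chrom,
    ranges = IRanges::IRanges(start = span$start, end = span$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, index))
  assigned <- components[S4Vectors::queryHits(hits), , drop = FALSE]
  assigned$transcript_id <-
    index$transcript_id[S4Vectors::subjectHits(hits)]
  assigned <- arrange(as_tibble(assigned), .data$transcript_id, .data$pos,
                      .data$kind)
  resolve_deletion_conflicts(assigned)
}

# Drop variants whose footprint was already removed by an earlier deletion on
# the same transcript. Deterministic: variants visited in coordinate order.
resolve_deletion_conflicts <- function(assigned) {
  if (nrow(assigned) == 0) return(assigned)
  keep <- rep(TRUE, nrow(assigned))
  for (tid in unique(assigned$transcript_id)) {
    idx <- which(assigned$transcript_id == tid)
    del_start <- integer(0)
    del_end <- integer(0)
    for (i in idx) {
      v <- assigned[i, ]
      if (v$kind == "insertion") {
        # anchor gap destroyed if both flanking bases are inside one deletion
        clash <- any(del_start <= v$pos & del_end >= v$pos + 1L)
      } else {
        s <- v$pos
        e <- v$pos + max(nchar(v$ref_seq), 1L) - 1L
        clash <- any(del_start <= e & del_end >= s)
      }
      if (clash) {
        keep[i] <- FALSE
      } else if (v$kind == "deletion") {
        del_start <- c(del_start, v$pos)
        del_end <- c(del_end, v$pos + nchar(v$ref_seq) - 1L)
      }
    }
  }
  if (any(!keep)) {
    warn(paste0("dropped ", sum(!keep), " variant assignment(s) whose span ",
                "was removed by an earlier overlapping deletion"))
  }
  assigned[keep, , drop = FALSE]
}
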