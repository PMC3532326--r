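#' Map protein (domain) coordinates to genomic intervals
#'
#' An amino-acid range `aa_start..aa_end` (1-based inclusive) of a
#' transcript's protein corresponds to CDS nucleotides
#' `3*(aa_start-1)+1 .. 3*aa_end`; these are mapped through the exon
#' structure, yielding one genomic interval per exon crossed. Strand-aware:
#' interval lengths always sum to `3 * (aa_end - aa_start + 1)`.
#'
#' @param regions Tibble with columns `transcript_id`, `aa_start`, `aa_end`,
#'   `label`.
#' @param exons Coding-exon tibble.
#' @return Tibble of genomic intervals: `label`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (sorted by genomic position within a region).
#' @export
protein_to_genome <- function(regions, exons) {
  rows <- map(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    model <- transcript_model(exons, r$transcript_id)
    if (3L * r$aa_end > model$cds_len) {
      abort(paste0("region '", r$label, "' exceeds the CDS of transcript ",
                   r$transcript_id))
    }
    o1 <- 3L * (r$aa_start - 1L)       # 0-based inclusive CDS offsets
    o2 <- 3L * r$aa_end - 1L
    iv <- cds_range_to_genomic(model, o1, o2)
    mutate(iv, label = r$label, transcript_id = r$transcript_id,
           chrom = model$chrom, strand = model$strand, .before = 1)
  })
  bind_rows(rows)
}

# Map a 0-based inclusive CDS-offset range to genomic intervals, one per
# exon crossed.
cds_range_to_genomic <- function(model, o1, o2) {
  # convert coding-orientation offsets to plus-strand CDS offsets
  if (model$strand == "-") {
    tmp <- model$cds_len - 1L - c(o2, o1)
    o1 <- tmp[1]
    o2 <- tmp[2]
  }
  out <- list()
  for (i in seq_along(model$starts)) {
    c0 <- model$cum_before[i]
    c1 <- c0 + model$lens[i] - 1L
    lo <- max(o1, c0)
    hi <- min(o2, c1)
    if (lo > hi) next
    out[[length(out) + 1L]] <- tibble(
      start = model$starts[i] + (lo - c0),
      end = model$starts[i] + (hi - c0)
    )
  }
  bind_rows(out)
}

#' Read genomic regions from a GFF3 file
#'
#' Accepts any feature type; the region label is taken from the `Name`
#' attribute, falling back to `ID`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `label`.
#' @export
read_region_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  label <- if (!is.null(gr$Name)) as.character(gr$Name) else
    rep(NA_character_, length(gr))
  if (!is.null(gr$ID)) {
    label <- ifelse(is.na(label) | !nzchar(label), as.character(gr$ID), label)
  }
  label[is.na(label)] <- paste0("region", seq_len(length(gr)))[is.na(label)]
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    label = label
  )
}

#' Annotate a GVF file with overlapping regions
#'
#' Each GVF record overlapping one or more regions (inclusive-coordinate
#' intersection of at least 1 bp; insertions overlap a region only when
#' their anchor gap lies strictly inside it) gains an
#' `overlapping_regions=` attribute listing the region labels; all other
#' records pass through unchanged.
#'
#' @param gvf_path Input GVF (as written by [write_gvf()]).
#' @param regions Region tibble (from [read_region_gff()]) or a path to a
#'   region GFF3 file.
#' @param out_path Output GVF path.
#' @return Tibble of the annotated records (also written to `out_path`).
#' @export
annotate_regions <- function(gvf_path, regions, out_path) {
  if (is.character(regions) && length(regions) == 1) {
    regions <- read_region_gff(regions)
  }
  gvf <- read_gvf(gvf_path)
  header <- readLines(gvf_path, warn = FALSE)
  header <- header[startsWith(header, "#")]
  labels <- overlapping_region_labels(gvf, regions)
  out_lines <- gvf$line
  has <- lengths(labels) > 0
  out_lines[has] <- paste0(
    out_lines[has], ";overlapping_regions=",
    vapply(labels[has], paste, character(1), collapse = ",")
  )
  writeLines(c(header, out_lines), out_path)
  mutate(gvf, overlapping_regions = vapply(
    labels, function(x) if (length(x)) paste(x, collapse = ",") else
      NA_character_, character(1)
  ), line = out_lines)
}

overlapping_region_labels <- function(gvf, regions) {
  if (nrow(gvf) == 0) return(list())
  if (nrow(regions) == 0) return(rep(list(character(0)), nrow(gvf)))
  subj <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
  is_ins <- !is.na(gvf$kind) & gvf$kind == "insertion"
  # insertions (anchor at start==end) must have both gap-flanking bases
  # inside the region; other records use plain intersection
  qstart <- ifelse(is_ins, gvf$start, gvf$start)
  qend <- ifelse(is_ins, gvf$start + 1L, gvf$end)
  q <- GenomicRanges::GRanges(
    seqnames = gvf$chrom,
    ranges = IRanges::IRanges(start = qstart, end = qend)
  )
  type <- ifelse(is_ins, "within", "any")
  labels <- rep(list(character(0)), nrow(gvf))
  for (tp in unique(type)) {
    idx <- which(type == tp)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q[idx], subj, type = tp)
    )
    for (h in seq_along(hits)) {
      qi <- idx[S4Vectors::queryHits(hits)[h]]
      labels[[qi]] <- c(labels[[qi]],
                        regions$label[S4Vectors::subjectHits(hits)[h]])
    }
  }
  lapply(labels, function(x) sort(unique(x)))
}
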