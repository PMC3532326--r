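# Independent brute-force oracles and small random fixtures used by the
# property-style tests. These deliberately avoid the package's own code
# paths (hand-rolled reverse complement, per-base chromosome editing,
# all-pairs overlap scans).

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

oracle_translate <- function(cds) {
  code <- setNames(as.character(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE))
  n <- nchar(cds) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(cds, 3 * i - 2, 3 * i)
    out[i] <- if (cod %in% names(code)) code[[cod]] else "X"
  }
  paste(out, collapse = "")
}

# Whole-chromosome-edit oracle: annotate every base of the chromosome with
# its replacement (SNV), removal (deletion) or trailing insertion, then
# re-splice the exons.
oracle_apply_variants <- function(genome, exons, transcript_id, variants) {
  ex <- exons[exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$start), ]
  chrom <- genome[[ex$chrom[1]]]
  n <- nchar(chrom)
  base <- substring(chrom, seq_len(n), seq_len(n))
  ins_after <- rep("", n)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "SNV") {
      base[v$pos] <- v$alt_seq
    } else if (v$kind == "deletion") {
      base[v$pos:(v$pos + nchar(v$ref_seq) - 1)] <- ""
    } else {
      ins_after[v$pos] <- paste0(ins_after[v$pos], v$alt_seq)
    }
  }
  pieces <- character(0)
  for (j in seq_len(nrow(ex))) {
    s <- ex$start[j]
    e <- ex$end[j]
    piece <- ""
    for (p in s:e) {
      piece <- paste0(piece, base[p], if (p < e) ins_after[p] else "")
    }
    pieces <- c(pieces, piece)
  }
  out <- paste(pieces, collapse = "")
  if (ex$strand[1] == "-") oracle_revcomp(out) else out
}

# All-pairs overlap scan: which transcripts does each component variant hit?
oracle_assign <- function(components, exons, flank = 2L) {
  tx <- unique(exons$transcript_id)
  hits <- list()
  for (tid in tx) {
    ex <- exons[exons$transcript_id == tid, ]
    ws <- min(ex$start) - flank
    we <- max(ex$end) + flank
    for (i in seq_len(nrow(components))) {
      v <- components[i, ]
      if (v$chrom != ex$chrom[1]) next
      s <- v$pos
      e <- if (v$kind == "deletion") v$pos + nchar(v$ref_seq) - 1 else
        if (v$kind == "insertion") v$pos + 1 else v$pos
    if (s <= we && e >= ws) {
        hits[[length(hits) + 1]] <- data.frame(i = i, transcript_id = tid)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(i = integer(), transcript_id = character()))
  }
  do.call(rbind, hits)
}

# Re-apply decomposition components to the reference allele (round-trip).
oracle_reapply <- function(pos, ref, components) {
  n <- nchar(ref)
  base <- substring(ref, seq_len(n), seq_len(n))
  ins_after <- rep("", n)  # ins_after[i]: sequence inserted after base i
  for (i in seq_len(nrow(components))) {
    v <- components[i, ]
    local <- v$pos - pos + 1
    if (v$kind == "SNV") {
      base[local] <- v$alt_seq
    } else if (v$kind == "deletion") {
      base[local:(local + nchar(v$ref_seq) - 1)] <- ""
    } else {
      ins_after[local] <- paste0(ins_after[local], v$alt_seq)
    }
  }
  paste(rbind(base, ins_after), collapse = "")
}

random_allele <- function(max_len = 12) {
  n <- sample(1:max_len, 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random 1-3 exon transcript on a random chromosome, with optional
# well-separated variants (spacing >= 8 bp, so no conflicts arise).
random_fixture <- function(seed, n_exons = NULL, with_variants = TRUE) {
  set.seed(seed)
  chrom_len <- 160
  chrom <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                 collapse = "")
  if (is.null(n_exons)) n_exons <- sample(1:3, 1)
  repeat {
    cuts <- sort(sample(15:(chrom_len - 15), 2 * n_exons))
    starts <- cuts[seq(1, 2 * n_exons, 2)]
    ends <- cuts[seq(2, 2 * n_exons, 2)]
    if (all(ends - starts >= 2) &&
        (n_exons == 1 || all(starts[-1] - ends[-n_exons] >= 5)) &&
        sum(ends - starts + 1) >= 3) break
  }
  strand <- sample(c("+", "-"), 1)
  exons <- tibble::tibble(transcript_id = "t1", chrom = "chrI",
                          start = starts, end = ends, strand = strand)
  variants <- NULL
  if (with_variants) {
    k <- sample(0:4, 1)
    anchors <- as.integer(sort(sample(seq(5L, chrom_len - 10L, by = 8L), k)))
    rows <- list()
    for (p in anchors) {
      kind <- sample(c("SNV", "insertion", "deletion"), 1)
      refb <- substr(chrom, p, p)
      if (kind == "SNV") {
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          kind = "SNV", chrom = "chrI", pos = p, ref_seq = refb,
          alt_seq = alt)
      } else if (kind == "insertion") {
        rows[[length(rows) + 1]] <- tibble::tibble(
          kind = "insertion", chrom = "chrI", pos = p, ref_seq = "",
          alt_seq = random_allele(4))
      } else {
        len <- sample(1:4, 1)
        del_ref <- substr(chrom, p, p + len - 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          kind = "deletion", chrom = "chrI", pos = p,
          ref_seq = del_ref, alt_seq = "")
      }
    }
    variants <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(kind = character(), chrom = character(),
                     pos = integer(), ref_seq = character(),
                     alt_seq = character())
  }
  list(genome = c(chrI = chrom), exons = exons, variants = variants)
}

# Independent single-SNV consequence oracle (no co-occurrence): enumerates
# coding positions directly, derives splice windows by hand, and decides
# the category from first principles.
oracle_classify_single_snv <- function(genome, exons, transcript_id, pos,
                                       ref, alt) {
  ex <- exons[exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$start), ]
  strand <- ex$strand[1]
  chrom <- genome[[ex$chrom[1]]]
  # splice windows
  if (nrow(ex) > 1) {
    for (j in seq_len(nrow(ex) - 1)) {
      a <- ex$end[j] + 1
      b <- ex$start[j + 1] - 1
      if (a > b) next
      left <- c(a, min(a + 1, b))
      right <- c(max(b - 1, a), b)
      left_site <- if (strand == "+") "donor" else "acceptor"
      right_site <- if (strand == "+") "acceptor" else "donor"
      if (pos >= left[1] && pos <= left[2]) {
        return(paste0("splice_", left_site, "_variant"))
      }
      if (pos >= right[1] && pos <= right[2]) {
        return(paste0("splice_", right_site, "_variant"))
      }
    }
  }
  coding_pos <- unlist(lapply(seq_len(nrow(ex)),
                              function(j) ex$start[j]:ex$end[j]))
  if (strand == "-") coding_pos <- rev(coding_pos)
  off <- match(pos, coding_pos)   # 1-based coding index
  if (is.na(off)) return("silent_mutation")
  cds <- paste(vapply(coding_pos, function(p) substr(chrom, p, p),
                      character(1)), collapse = "")
  if (strand == "-") cds <- chartr("ACGTN", "TGCAN", cds)
  ci <- (off - 1) %/% 3
  ref_codon <- substr(cds, 3 * ci + 1, 3 * ci + 3)
  var_codon <- ref_codon
  coding_alt <- if (strand == "+") alt else chartr("ACGTN", "TGCAN", alt)
  substr(var_codon, (off - 1) %% 3 + 1, (off - 1) %% 3 + 1) <- coding_alt
  ref_aa <- oracle_translate(ref_codon)
  var_aa <- oracle_translate(var_codon)
  if (ref_aa == var_aa) return("synonymous_codon")
  if (var_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  g <- grantham_classify(ref_aa, var_aa)
  g$so_category
}
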