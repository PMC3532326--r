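#' Names of the built-in synthetic test scenarios
#'
#' Valid `scenario` values for [generate_fixture()].
#' @export
FIXTURE_SCENARIOS <- c(
  "intact", "synonymous", "missense_joint_codon", "frame_restore",
  "frameshift_stop", "boundary_insertion", "splice_hit", "full_deletion",
  "compound_decomposition"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
NON_STOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_codons <- function(n) {
  paste(sample(NON_STOP_CODONS, n, replace = TRUE), collapse = "")
}

#' Generate a deterministic synthetic test fixture
#'
#' Builds a small reference genome, transcript model(s) and variant set for
#' one of nine scenarios that exercise the joint-annotation phenomena
#' (frame restoration by paired indels, same-codon co-occurring SNVs,
#' boundary insertions, splice hits, compound-allele decomposition, ...),
#' together with the expected ("truth") annotations. Regenerating with the
#' same seed reproduces identical files and truth.
#'
#' @param scenario One of `intact`, `synonymous`, `missense_joint_codon`,
#'   `frame_restore`, `frameshift_stop`, `boundary_insertion`, `splice_hit`,
#'   `full_deletion`, `compound_decomposition`.
#' @param seed Integer RNG seed.
#' @param dir Directory to write `genome.fasta`, `exons.gff3` and
#'   `variants.vcf` into (created if needed); `NULL` keeps the fixture
#'   in memory only.
#' @return List with `scenario`, `seed`, `genome`, `exons`, `variants`,
#'   `paths` (if written), and `truth`: `expected_orf` (tibble
#'   `transcript_id`, `orf_status`), `expected_categories` (tibble `pos`,
#'   `kind`, `transcript_id`, `category`), `expected_components` (tibble
#'   `record`, `n_snv`, `n_insertion`, `n_deletion`; decomposition scenarios
#'   only), and scenario extras (e.g. `expected_stop_pct`).
#' @export
generate_fixture <- function(scenario, seed, dir = NULL) {
  if (!scenario %in% FIXTURE_SCENARIOS) {
    abort(paste0("unknown fixture scenario: ", scenario))
  }
  fx <- with_fixture_seed(seed, switch(
    scenario,
    intact = fixture_point_snv(scenario, plant = "none"),
    synonymous = fixture_point_snv(scenario, plant = "synonymous"),
    missense_joint_codon = fixture_point_snv(scenario, plant = "joint"),
    frame_restore = fixture_frame_restore(),
    frameshift_stop = fixture_frameshift_stop(),
    boundary_insertion = fixture_two_exon(scenario, plant = "boundary"),
    splice_hit = fixture_two_exon(scenario, plant = "splice"),
    full_deletion = fixture_full_deletion(),
    compound_decomposition = fixture_compound()
  ))
  fx$scenario <- scenario
  fx$seed <- seed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "genome.fasta"),
      gff = file.path(dir, "exons.gff3"),
      vcf = file.path(dir, "variants.vcf")
    )
    write_fasta(fx$genome, paths$fasta)
    write_fixture_gff(fx$exons, paths$gff)
    write_fixture_vcf(fx$variants, paths$vcf)
    fx$paths <- paths
  }
  fx
}

write_fixture_gff <- function(exons, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    lines <- c(lines, paste(
      e$chrom, "fixture", "CDS", e$start, e$end, ".", e$strand, "0",
      paste0("ID=cds:", e$transcript_id, ".", i, ";Parent=",
             e$transcript_id),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
}

write_fixture_vcf <- function(variants, path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  if (nrow(variants) > 0) {
    lines <- c(lines, paste(variants$chrom, variants$pos, ".", variants$ref,
                            variants$alt, ".", ".", ".", sep = "\t"))
  }
  writeLines(lines, path)
}

# Single-exon plus-strand transcript with an optional planted codon and a
# genomic coordinate map for CDS offsets.
base_single_exon <- function(n_codons, planted_codon = NULL,
                             planted_index = NULL) {
  body <- strsplit(random_codons(n_codons - 2L), "")[[1]]
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  if (!is.null(planted_codon)) {
    o <- 3L * planted_index
    substr(cds, o + 1L, o + 3L) <- planted_codon
  }
  f1 <- 30L
  chrom <- paste0(random_bases(f1), cds, random_bases(30L))
  exons <- tibble(transcript_id = "t1", chrom = "chrI",
                  start = f1 + 1L, end = f1 + nchar(cds), strand = "+")
  list(genome = c(chrI = chrom), exons = exons, cds = cds,
       n_codons = n_codons,
       pos_of_offset = function(off) f1 + 1L + off)
}

fixture_point_snv <- function(scenario, plant) {
  n_codons <- sample(35:45, 1)
  i <- sample(8:20, 1)   # 0-based codon index of the planted codon
  fx <- base_single_exon(n_codons, planted_codon = "CTG", planted_index = i)
  p1 <- fx$pos_of_offset(3L * i)       # codon base 1
  variants <- switch(plant,
    none = tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character()),
    synonymous = tibble(chrom = "chrI", pos = p1 + 2L, ref = "G", alt = "A"),
    joint = tibble(chrom = "chrI", pos = c(p1, p1 + 1L),
                   ref = c("C", "T"), alt = c("T", "C"))
  )
  truth <- switch(plant,
    none = list(
      expected_orf = tibble(transcript_id = "t1", orf_status = "ORF_INTACT"),
      expected_categories = tibble(pos = integer(), kind = character(),
                                   transcript_id = character(),
                                   category = character())
    ),
    synonymous = list(
      expected_orf = tibble(transcript_id = "t1",
                            orf_status = "ORF_PRESERVED"),
      expected_categories = tibble(pos = p1 + 2L, kind = "SNV",
                                   transcript_id = "t1",
                                   category = "synonymous_codon")
    ),
    joint = list(
      expected_orf = tibble(transcript_id = "t1",
                            orf_status = "ORF_PRESERVED"),
      # CTG -> TCG jointly: leucine to serine, Grantham 145
      expected_categories = tibble(
        pos = c(p1, p1 + 1L), kind = "SNV", transcript_id = "t1",
        category = "non_conservative_missense_codon"
      ),
      expected_codon = c(ref = "CTG", var = "TCG")
    )
  )
  list(genome = fx$genome, exons = fx$exons, variants = variants,
       truth = truth)
}

fixture_frame_restore <- function() {
  n_codons <- sample(38:46, 1)
  i <- sample(8:14, 1)          # 0-based index of first GCC codon
  run_len <- sample(4:7, 1)     # GCC codons; shifted frames are stop-free
  fx <- base_single_exon(n_codons)
  cds <- fx$cds
  for (k in seq_len(run_len)) {
    o <- 3L * (i + k - 1L)
    substr(cds, o + 1L, o + 3L) <- "GCC"
  }
  genome <- fx$genome
  substr(genome[["chrI"]], fx$pos_of_offset(0L),
         fx$pos_of_offset(nchar(cds) - 1L)) <- cds
  # 1-bp deletion inside the run, 1-bp insertion a few bases downstream:
  # deltas cancel and the shifted stretch is all G/C, so no stop can arise
  del_pos <- fx$pos_of_offset(3L * (i + 1L))          # a G of the run
  ins_pos <- fx$pos_of_offset(3L * (i + run_len - 1L))
  anchor <- function(p) substr(genome[["chrI"]], p, p)
  variants <- tibble(
    chrom = "chrI",
    pos = c(del_pos - 1L, ins_pos),
    ref = c(paste0(anchor(del_pos - 1L), anchor(del_pos)), anchor(ins_pos)),
    alt = c(anchor(del_pos - 1L), paste0(anchor(ins_pos), "C"))
  )
  list(genome = genome, exons = fx$exons, variants = variants, truth = list(
    expected_orf = tibble(transcript_id = "t1",
                          orf_status = "ORF_PRESERVED"),
    expected_categories = tibble(
      pos = c(del_pos, ins_pos), kind = c("deletion", "insertion"),
      transcript_id = "t1", category = "frameshift_variant"
    )
  ))
}

fixture_frameshift_stop <- function() {
  n_codons <- sample(38:46, 1)
  i <- sample(8:14, 1)
  fx <- base_single_exon(n_codons)
  cds <- fx$cds
  # reference codons GCC ATA ACC; deleting the G shifts to CCA TAA ...,
  # creating an internal stop at codon i+1 (0-based)
  planted <- c("GCC", "ATA", "ACC")
  for (k in 0:2) {
    o <- 3L * (i + k)
    substr(cds, o + 1L, o + 3L) <- planted[k + 1L]
  }
  genome <- fx$genome
  substr(genome[["chrI"]], fx$pos_of_offset(0L),
         fx$pos_of_offset(nchar(cds) - 1L)) <- cds
  del_pos <- fx$pos_of_offset(3L * i)   # the G
  anchor <- substr(genome[["chrI"]], del_pos - 1L, del_pos - 1L)
  variants <- tibble(chrom = "chrI", pos = del_pos - 1L,
                     ref = paste0(anchor, "G"), alt = anchor)
  stop_pct <- 100 * (i + 2L) / n_codons
  list(genome = genome, exons = fx$exons, variants = variants, truth = list(
    expected_orf = tibble(transcript_id = "t1",
                          orf_status = "ORF_DISRUPTED"),
    expected_categories = tibble(pos = del_pos, kind = "deletion",
                                 transcript_id = "t1",
                                 category = "frameshift_variant"),
    expected_stop_pct = stop_pct
  ))
}

# Two-exon plus-strand transcript split at a codon boundary.
base_two_exon <- function(n_codons) {
  cds <- paste0("ATG", random_codons(n_codons - 2L), "TAA")
  split_at <- 3L * sample(6:12, 1)   # bases in exon 1
  intron <- paste0("GT", random_bases(36L), "AG")
  f1 <- 30L
  e1 <- substr(cds, 1L, split_at)
  e2 <- substr(cds, split_at + 1L, nchar(cds))
  chrom <- paste0(random_bases(f1), e1, intron, e2, random_bases(30L))
  exons <- tibble(
    transcript_id = "t1", chrom = "chrI",
    start = c(f1 + 1L, f1 + split_at + nchar(intron) + 1L),
    end = c(f1 + split_at, f1 + split_at + nchar(intron) + nchar(e2)),
    strand = "+"
  )
  list(genome = c(chrI = chrom), exons = exons, cds = cds)
}

fixture_two_exon <- function(scenario, plant) {
  fx <- base_two_exon(sample(38:46, 1))
  e1_end <- fx$exons$end[1]
  e2_start <- fx$exons$start[2]
  g <- fx$genome[["chrI"]]
  base_at <- function(p) substr(g, p, p)
  if (plant == "splice") {
    # hit the first donor base (the G of the intronic GT)
    p <- e1_end + 1L
    variants <- tibble(chrom = "chrI", pos = p, ref = base_at(p), alt = "A")
    truth <- list(
      expected_orf = tibble(transcript_id = "t1",
                            orf_status = "ORF_DISRUPTED"),
      expected_categories = tibble(pos = p, kind = "SNV",
                                   transcript_id = "t1",
                                   category = "splice_donor_variant")
    )
  } else {
    # 1-bp insertions anchored right after exon 1 and right before exon 2:
    # both anchor gaps lie outside the CDS, so no frameshift
    variants <- tibble(
      chrom = "chrI",
      pos = c(e1_end, e2_start - 1L),
      ref = c(base_at(e1_end), base_at(e2_start - 1L)),
      alt = c(paste0(base_at(e1_end), "C"),
              paste0(base_at(e2_start - 1L), "C"))
    )
    truth <- list(
      expected_orf = tibble(transcript_id = "t1",
                            orf_status = "ORF_PRESERVED"),
      expected_categories = tibble(
        pos = c(e1_end, e2_start - 1L), kind = "insertion",
        transcript_id = "t1", category = "silent_mutation"
      )
    )
  }
  list(genome = fx$genome, exons = fx$exons, variants = variants,
       truth = truth)
}

fixture_full_deletion <- function() {
  fx <- base_single_exon(sample(35:45, 1))
  tx_start <- fx$exons$start[1]
  tx_end <- fx$exons$end[1]
  g <- fx$genome[["chrI"]]
  p <- tx_start - 6L
  ref <- substr(g, p, tx_end + 5L)
  variants <- tibble(chrom = "chrI", pos = p, ref = ref,
                     alt = substr(ref, 1L, 1L))
  list(genome = fx$genome, exons = fx$exons, variants = variants,
       truth = list(
    expected_orf = tibble(transcript_id = "t1",
                          orf_status = "FULLY_DELETED"),
    # the whole CDS (a codon multiple) is removed, so the length delta is
    # 0 mod 3: an inframe deletion at the variant level, FULLY_DELETED at
    # the transcript level
    expected_categories = tibble(pos = p + 1L, kind = "deletion",
                                 transcript_id = "t1",
                                 category = "inframe_variant")
  ))
}

fixture_compound <- function() {
  pairs <- tibble(
    ref = c("ATG", "GGGTCAGGACGCG", "CCCAGT", "CGTAA", "TACCA", "GTG",
            "CT", "AGA", "TGCAGAGGAGC"),
    alt = c("AC", "GGGTCAGGACGCC", "CCCAGC", "TGTAA", "TACCG", "GTA",
            "CCGCTGCCGCCTCCAAAGCC", "TGC", "TGCGGAGGAGCCGCAGGCTGGGGCTGCAGGGC")
  )
  expected <- tibble(
    record = seq_len(nrow(pairs)),
    n_snv = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L),
    n_insertion = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 1L),
    n_deletion = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  )
  spacer <- function() random_bases(sample(10:20, 1))
  chrom <- spacer()
  pos <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pos[i] <- nchar(chrom) + 1L
    chrom <- paste0(chrom, pairs$ref[i], spacer())
  }
  # a harmless transcript on the far side of the chromosome
  cds <- paste0("ATG", random_codons(10L), "TAA")
  tx_start <- nchar(chrom) + 20L
  chrom <- paste0(chrom, random_bases(19L), cds, random_bases(20L))
  exons <- tibble(transcript_id = "t1", chrom = "chrI", start = tx_start,
                  end = tx_start + nchar(cds) - 1L, strand = "+")
  variants <- tibble(chrom = "chrI", pos = pos, ref = pairs$ref,
                     alt = pairs$alt)
  list(genome = c(chrI = chrom), exons = exons, variants = variants,
       truth = list(
    expected_orf = tibble(transcript_id = "t1", orf_status = "ORF_INTACT"),
    expected_categories = tibble(pos = integer(), kind = character(),
                                 transcript_id = character(),
                                 category = character()),
    expected_components = expected
  ))
}
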