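#' Load the Grantham amino-acid distance matrix
#'
#' Reads a tab-separated 20x20 symmetric matrix of Grantham (1974)
#' physico-chemical distances (first column/row: one-letter amino-acid
#' codes). The copy shipped with the package is the published matrix.
#'
#' @param path Path to a matrix file; defaults to the shipped copy.
#' @return Numeric 20x20 matrix with amino-acid letter dimnames.
#' @export
read_grantham_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "grantham_distance.tsv",
                        package = "jointvar", mustWork = TRUE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (!identical(sort(rownames(m)), sort(colnames(m))) || nrow(m) != 20) {
    abort("Grantham matrix must be 20x20 with matching row/column names")
  }
  m
}

grantham_cache <- new.env(parent = emptyenv())

default_grantham_matrix <- function() {
  if (is.null(grantham_cache$m)) grantham_cache$m <- read_grantham_matrix()
  grantham_cache$m
}

GRANTHAM_CLASSES <- c("CONSERVATIVE", "MODERATELY_CONSERVATIVE",
                      "MODERATELY_RADICAL", "RADICAL")

#' Classify an amino-acid substitution by Grantham distance
#'
#' Distances are binned into four classes: 0-50 `CONSERVATIVE`, 51-100
#' `MODERATELY_CONSERVATIVE`, 101-150 `MODERATELY_RADICAL`, >150 `RADICAL`.
#' The first two map to the Sequence Ontology term
#' `conservative_missense_codon`, the last two to
#' `non_conservative_missense_codon`.
#'
#' @param aa_ref,aa_alt One-letter amino-acid codes (vectors recycle);
#'   must differ and neither may be a stop (`*`).
#' @param matrix Grantham matrix (see [read_grantham_matrix()]).
#' @return Tibble with columns `score`, `class`, `so_category`.
#' @export
#' @examples
#' grantham_classify("L", "S")
grantham_classify <- function(aa_ref, aa_alt,
                              matrix = default_grantham_matrix()) {
  if (any(aa_ref == aa_alt)) {
    abort("grantham_classify() requires differing amino acids")
  }
  if (any(aa_ref == "*" | aa_alt == "*")) {
    abort("stop codons are not Grantham-classified")
  }
  bad <- !(aa_ref %in% rownames(matrix)) | !(aa_alt %in% rownames(matrix))
  if (any(bad)) {
    abort(paste0("unknown amino acid(s): ",
                 paste(unique(c(aa_ref[bad], aa_alt[bad])), collapse = ", ")))
  }
  score <- matrix[cbind(aa_ref, aa_alt)]
  cls <- ifelse(score <= 50, "CONSERVATIVE",
         ifelse(score <= 100, "MODERATELY_CONSERVATIVE",
         ifelse(score <= 150, "MODERATELY_RADICAL", "RADICAL")))
  tibble(
    score = as.integer(score),
    class = cls,
    so_category = ifelse(cls %in% c("CONSERVATIVE", "MODERATELY_CONSERVATIVE"),
                         "conservative_missense_codon",
                         "non_conservative_missense_codon")
  )
}
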