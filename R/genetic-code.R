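#' Genetic code tables
#'
#' Build the codon table used throughout the package. Two NCBI translation
#' tables are supported: 1 (standard) and 2 (vertebrate mitochondrial). Under
#' table 2 the stop set is \{TAA, TAG, AGA, AGG\}, ATA translates to Met and
#' TGA to Trp, leaving 60 sense codons; under table 1 the stops are
#' \{TAA, TAG, TGA\} and there are 61 sense codons.
#'
#' @param table_id Integer NCBI translation table id, 1 or 2. Default 2,
#'   the code mitochondrial protein-coding genes are read in.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codon_to_aa` (named character vector over all 64 codons),
#'   `stop_codons`, `start_codons`, `sense_codons`, `families` (list mapping
#'   amino acid to its synonymous codon set), `degeneracy` (named integer per
#'   sense codon), and `max_enc` (ENC under perfectly uniform usage).
#' @examples
#' code <- genetic_code(2)
#' code$stop_codons
#' code$degeneracy[["CTA"]] # Leu is 6-fold under table 2
#' @export
genetic_code <- function(table_id = 2) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 2L)) {
    abort("`table_id` must be 1 (standard) or 2 (vertebrate mitochondrial).")
  }
  key <- paste0("code_", table_id)
  if (!is.null(.mitocub_cache[[key]])) {
    return(.mitocub_cache[[key]])
  }
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codon_to_aa <- setNames(as.character(tab), names(tab))
  stopifnot(length(codon_to_aa) == 64L)
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  sense <- names(codon_to_aa)[codon_to_aa != "*"]
  starts <- union("ATG", attr(tab, "alt_init_codons"))
  fams <- split(sense, codon_to_aa[sense])
  degeneracy <- setNames(
    lengths(fams)[codon_to_aa[sense]],
    sense
  )
  # ENC under uniform usage: each k-fold family contributes k
  nk <- table(lengths(fams))
  max_enc <- sum(as.integer(names(nk)) * as.integer(nk))
  code <- structure(
    list(
      table_id = table_id,
      codon_to_aa = codon_to_aa,
      stop_codons = stops,
      start_codons = starts,
      sense_codons = sense,
      families = fams,
      degeneracy = degeneracy,
      max_enc = max_enc
    ),
    class = "genetic_code"
  )
  .mitocub_cache[[key]] <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(
    "<genetic_code> NCBI table", x$table_id, "-",
    length(x$sense_codons), "sense codons,",
    length(x$stop_codons), "stops (", paste(x$stop_codons, collapse = " "), ")\n"
  )
  invisible(x)
}

# all 64 codons in a fixed canonical order: grouped by amino acid
# (alphabetical), alphabetical within family, stops last
codon_order <- function(code = genetic_code(2)) {
  sense <- unlist(lapply(code$families[order(names(code$families))], sort),
    use.names = FALSE
  )
  c(sense, sort(code$stop_codons))
}

# split a nucleotide string into its in-frame codons, dropping any
# trailing partial codon
split_codons <- function(x) {
  stopifnot(length(x) == 1L)
  n <- nchar(x)
  n_full <- n %/% 3L
  if (n_full == 0L) {
    return(character(0))
  }
  substring(x, seq(1L, by = 3L, length.out = n_full), seq(3L, by = 3L, length.out = n_full))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
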