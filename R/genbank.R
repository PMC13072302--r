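# GenBank flat-file ingest. Mitogenome records are small and flat (no
# multi-record files, no join() locations in practice), so a compact parser
# covering LOCUS, the FEATURES table and ORIGIN is sufficient; anything it
# cannot represent (join/order locations, origin-spanning features) is
# rejected loudly rather than mis-handled.

# canonical short names used throughout the package
.gene_name_map <- c(
  "ND1" = "nad1", "ND2" = "nad2", "ND3" = "nad3", "ND4" = "nad4",
  "ND4L" = "nad4L", "ND5" = "nad5", "ND6" = "nad6",
  "NAD1" = "nad1", "NAD2" = "nad2", "NAD3" = "nad3", "NAD4" = "nad4",
  "NAD4L" = "nad4L", "NAD5" = "nad5", "NAD6" = "nad6",
  "COX1" = "cox1", "COX2" = "cox2", "COX3" = "cox3",
  "COI" = "cox1", "COII" = "cox2", "COIII" = "cox3",
  "CO1" = "cox1", "CO2" = "cox2", "CO3" = "cox3",
  "COB" = "cytb", "CYTB" = "cytb", "CYB" = "cytb",
  "ATP6" = "atp6", "ATP8" = "atp8", "ATPASE6" = "atp6", "ATPASE8" = "atp8",
  "12S" = "rrnS", "16S" = "rrnL", "S-RRNA" = "rrnS", "L-RRNA" = "rrnL",
  "RRNS" = "rrnS", "RRNL" = "rrnL", "12S RRNA" = "rrnS", "16S RRNA" = "rrnL",
  "12S RIBOSOMAL RNA" = "rrnS", "16S RIBOSOMAL RNA" = "rrnL",
  "D-LOOP" = "NCR", "CONTROL REGION" = "NCR"
)

.trna_letter <- c(
  "ALA" = "A", "ARG" = "R", "ASN" = "N", "ASP" = "D", "CYS" = "C",
  "GLN" = "Q", "GLU" = "E", "GLY" = "G", "HIS" = "H", "ILE" = "I",
  "LEU" = "L", "LYS" = "K", "MET" = "M", "PHE" = "F", "PRO" = "P",
  "SER" = "S", "THR" = "T", "TRP" = "W", "TYR" = "Y", "VAL" = "V"
)

#' Normalise a mitochondrial gene name
#'
#' Maps the many spellings found in GenBank annotations (ND6, COX1/COI,
#' CYTB/cob, 12S rRNA, tRNA-Phe, ...) onto the canonical short names used in
#' this package (nad6, cox1, cytb, rrnS, trnF, ...). Leu/Ser tRNAs are
#' disambiguated by anticodon when one is supplied (Leu: TAA = trnL2,
#' TAG = trnL1; Ser: GCT = trnS1, TGA = trnS2). Unknown names pass through
#' unchanged with a warning.
#'
#' @param name Gene or product name.
#' @param anticodon Optional anticodon (used only for tRNA-Leu/Ser).
#' @return Canonical gene name.
#' @export
normalize_gene_name <- function(name, anticodon = NA_character_) {
  raw <- name
  up <- toupper(trimws(name))
  if (grepl("^TRN[A-Z][0-9]?$", up)) {
    return(paste0("trn", substr(raw, 4, nchar(raw))))
  }
  if (grepl("^TRNA[-_ ]", up)) {
    aa <- toupper(sub("^TRNA[-_ ]", "", up))
    aa3 <- substr(aa, 1, 3)
    if (aa3 %in% names(.trna_letter)) {
      letter <- .trna_letter[[aa3]]
      if (letter == "L") {
        if (identical(toupper(anticodon), "TAG")) letter <- "L1"
        if (identical(toupper(anticodon), "TAA")) letter <- "L2"
      }
      if (letter == "S") {
        if (identical(toupper(anticodon), "GCT")) letter <- "S1"
        if (identical(toupper(anticodon), "TGA")) letter <- "S2"
      }
      return(paste0("trn", letter))
    }
  }
  if (up %in% names(.gene_name_map)) {
    return(unname(.gene_name_map[[up]]))
  }
  if (up %in% c("OL", "NCR")) {
    return(up)
  }
  known <- c(
    paste0("nad", c(1:6, "4L")), paste0("cox", 1:3), "cytb", "atp6", "atp8",
    "rrnS", "rrnL"
  )
  if (name %in% known || grepl("^trn", name)) {
    return(name)
  }
  warn(paste0("unrecognised gene name '", raw, "' passed through unchanged"))
  raw
}

parse_gb_location <- function(loc, key) {
  loc <- gsub("[<>]", "", loc)
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\(", "", sub("\\)$", "", loc))
  }
  if (grepl("join|order|complement", loc)) {
    abort(paste0(
      "unsupported location '", loc, "' for ", key,
      " feature: join/order/origin-spanning locations are not handled"
    ))
  }
  parts <- strsplit(loc, "\\.\\.")[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    abort(paste0("malformed location '", loc, "' for ", key, " feature"))
  }
  list(start = as.integer(parts[1]), end = as.integer(parts[2]), strand = strand)
}

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS (genome length, circular flag), the FEATURES table (CDS,
#' tRNA, rRNA and D-loop entries; `complement()` locations become light
#' strand) and the ORIGIN sequence. Gene names are normalised with
#' [normalize_gene_name()]. `join()` and origin-spanning locations raise an
#' explicit unsupported-location error.
#'
#' @param path Path to a `.gb`/`.gbk` file.
#' @param require_sequence Error if the record has no ORIGIN sequence?
#'   Default `FALSE`.
#' @return A [mito_annotation()].
#' @export
read_genbank <- function(path, require_sequence = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(paste0("GenBank file '", path, "' is empty"))
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_length <- NULL
  circular <- TRUE
  if (length(locus) > 0) {
    m <- regmatches(locus[1], regexpr("[0-9]+(?= bp)", locus[1], perl = TRUE))
    if (length(m)) genome_length <- as.integer(m)
    circular <- grepl("circular", locus[1])
  }
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line)) trimws(sub("^ACCESSION", "", acc_line[1])) else NA_character_

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  feat_end <- if (length(origin_start)) origin_start[1] - 1L else length(lines)
  if (length(feat_start) == 0L) abort("no FEATURES block found")
  block <- lines[(feat_start[1] + 1L):feat_end]

  # fold qualifier continuation lines into single feature records
  is_key <- grepl("^ {5}\\S", block)
  idx <- cumsum(is_key)
  feats <- split(block[idx > 0], idx[idx > 0])

  rows <- purrr::map_dfr(feats, function(fl) {
    header <- fl[1]
    key <- trimws(substr(header, 1, 21))
    if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) {
      return(tibble())
    }
    loc <- parse_gb_location(trimws(substr(header, 22, nchar(header))), key)
    quals <- paste(trimws(fl[-1]), collapse = " ")
    get_qual <- function(q) {
      m <- regmatches(quals, regexpr(paste0("/", q, '="?[^"/]*'), quals))
      if (length(m) == 0) {
        return(NA_character_)
      }
      gsub(paste0("^/", q, '="?'), "", m)
    }
    gene <- get_qual("gene")
    product <- get_qual("product")
    anticodon_seq <- get_qual("anticodon")
    anticodon <- NA_character_
    if (!is.na(anticodon_seq)) {
      m <- regmatches(anticodon_seq, regexpr("seq:[acgtACGT]{3}", anticodon_seq))
      if (length(m)) anticodon <- toupper(sub("seq:", "", m))
    }
    raw_name <- if (!is.na(gene)) gene else if (!is.na(product)) product else key
    cls <- switch(key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "noncoding"
    )
    tibble(
      gene = normalize_gene_name(raw_name, anticodon),
      class = cls, start = loc$start, end = loc$end, strand = loc$strand,
      start_codon = NA_character_, stop_codon = NA_character_,
      anticodon = anticodon,
      transl_table = suppressWarnings(as.integer(get_qual("transl_table")))
    )
  })
  if (nrow(rows) == 0L) {
    abort(paste0("GenBank file '", path, "' contains no usable features"))
  }
  transl_table <- unique(rows$transl_table[!is.na(rows$transl_table)])
  rows$transl_table <- NULL

  sequence <- NULL
  if (length(origin_start)) {
    seq_lines <- lines[(origin_start[1] + 1L):length(lines)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0L) sequence <- NULL
  }
  if (require_sequence && is.null(sequence)) {
    abort(paste0("GenBank file '", path, "' has no ORIGIN sequence"))
  }
  ann <- mito_annotation(rows,
    genome_length = genome_length, accession = accession,
    circular = circular, sequence = sequence
  )
  if (length(transl_table)) attr(ann, "transl_table") <- transl_table[1]
  ann
}
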