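#' Mitogenome annotations
#'
#' A `mito_annotation` bundles an ordered feature table with the genome
#' length and (optionally) the genome sequence. Coordinates are 1-based and
#' inclusive on both ends (GenBank convention), so
#' `length = end - start + 1`. Features may not span the circular origin;
#' such locations are rejected with an explicit error.
#'
#' @param features A data frame with columns `gene`, `class` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"noncoding"`), `start`, `end`, `strand`
#'   (`"H"` heavy / `"L"` light) and optionally `start_codon`, `stop_codon`,
#'   `anticodon`.
#' @param genome_length Genome length in bp; defaults to `max(end)`.
#' @param accession Optional accession string.
#' @param circular Logical; mitogenomes are circular. Default `TRUE`.
#' @param sequence Optional genome sequence (single string over A/C/G/T/N);
#'   must have `nchar() == genome_length`.
#' @return A `mito_annotation` object.
#' @export
mito_annotation <- function(features, genome_length = NULL, accession = NA_character_,
                            circular = TRUE, sequence = NULL) {
  features <- as_tibble(features)
  required <- c("gene", "class", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("feature table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  if (nrow(features) == 0L) {
    abort("annotation has no features")
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  bad <- which(is.na(features$start) | is.na(features$end) | features$start < 1L |
    features$end < features$start)
  if (length(bad) > 0) {
    abort(paste0(
      "invalid coordinates for feature '", features$gene[bad[1]],
      "' (row ", bad[1], "): start=", features$start[bad[1]],
      ", end=", features$end[bad[1]]
    ))
  }
  bad_strand <- which(!features$strand %in% c("H", "L"))
  if (length(bad_strand) > 0) {
    abort(paste0(
      "unknown strand '", features$strand[bad_strand[1]], "' for feature '",
      features$gene[bad_strand[1]], "' (row ", bad_strand[1], ")"
    ))
  }
  bad_class <- which(!features$class %in% c("PCG", "tRNA", "rRNA", "noncoding"))
  if (length(bad_class) > 0) {
    abort(paste0(
      "unknown feature class '", features$class[bad_class[1]], "' for feature '",
      features$gene[bad_class[1]], "'"
    ))
  }
  features$start_codon[features$class != "PCG"] <- NA_character_
  features$stop_codon[features$class != "PCG"] <- NA_character_
  features <- arrange(features, .data$start, .data$end)
  if (is.null(genome_length)) genome_length <- max(features$end)
  genome_length <- as.integer(genome_length)
  if (max(features$end) > genome_length) {
    abort("feature coordinates exceed `genome_length`")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length) {
      abort(paste0(
        "sequence length (", nchar(sequence), ") does not match genome_length (",
        genome_length, ")"
      ))
    }
    if (grepl("[^ACGTN]", sequence)) {
      abort("sequence contains characters outside A/C/G/T/N")
    }
  }
  structure(
    list(
      accession = accession,
      genome_length = genome_length,
      circular = isTRUE(circular),
      features = select(
        features, "gene", "class", "start", "end", "strand",
        "start_codon", "stop_codon", "anticodon"
      ),
      sequence = sequence
    ),
    class = "mito_annotation"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(
    "<mito_annotation>", if (!is.na(x$accession)) x$accession else "",
    paste0(x$genome_length, " bp"), if (x$circular) "(circular)" else "(linear)",
    if (!is.null(x$sequence)) "with sequence" else "no sequence", "\n"
  )
  print(count(x$features, .data$class))
  invisible(x)
}

infer_feature_class <- function(gene) {
  dplyr::case_when(
    grepl("^trn", gene, ignore.case = TRUE) ~ "tRNA",
    grepl("^rrn", gene, ignore.case = TRUE) ~ "rRNA",
    toupper(gene) %in% c("OL", "NCR", "D-LOOP", "DLOOP", "CR") ~ "noncoding",
    TRUE ~ "PCG"
  )
}

parse_position <- function(x, gene, row) {
  x <- gsub(",", "", x) # tolerate thousands separators
  x <- gsub("–|—", "-", x) # en/em dash as range separator
  parts <- strsplit(x, "\\.\\.|-")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts)))) {
    abort(paste0("malformed coordinate '", x, "' for feature '", gene, "' (row ", row, ")"))
  }
  as.integer(parts)
}

#' Read a mitogenome feature table
#'
#' Reads a TSV feature table in the shape of a printed mitogenome summary
#' table: one row per feature with either a single `Position` column
#' (`"start-end"`, thousands separators and en-dashes tolerated) or separate
#' `start`/`end` columns. Column names are matched case-insensitively;
#' `Feature`/`gene`, `Initiation`/`start_codon`, `Stop`/`stop_codon`,
#' `Anticodon` and `Strand` are recognised. A `class` column is optional;
#' when absent the class is inferred from the gene name (`trn*` tRNA,
#' `rrn*` rRNA, `OL`/`NCR`/`D-loop` noncoding, otherwise PCG).
#'
#' @param path Path to the TSV file.
#' @param genome_length Optional genome length; defaults to `max(end)`.
#' @param accession Optional accession recorded on the annotation.
#' @return A [mito_annotation()].
#' @examples
#' tsv <- system.file("extdata", "abramis_brama_orientalis_mtgenome.tsv",
#'   package = "mitocub"
#' )
#' ann <- read_feature_table(tsv)
#' ann$genome_length
#' @export
read_feature_table <- function(path, genome_length = NULL, accession = NA_character_) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) {
    abort(paste0("feature table '", path, "' is empty"))
  }
  nm <- tolower(names(raw))
  take <- function(...) {
    idx <- which(nm %in% c(...))
    if (length(idx) == 0) {
      return(rep(NA_character_, nrow(raw)))
    }
    raw[[idx[1]]]
  }
  gene <- take("feature", "gene", "name")
  if (all(is.na(gene))) abort("feature table lacks a Feature/gene column")
  strand <- take("strand")
  pos <- take("position", "pos", "location")
  if (all(is.na(pos))) {
    start <- suppressWarnings(as.integer(gsub(",", "", take("start"))))
    end <- suppressWarnings(as.integer(gsub(",", "", take("end"))))
  } else {
    se <- purrr::imap(pos, ~ parse_position(.x, gene[.y], .y))
    start <- purrr::map_int(se, 1)
    end <- purrr::map_int(se, 2)
  }
  cls <- take("class", "feature_class", "type")
  if (all(is.na(cls))) cls <- infer_feature_class(gene)
  features <- tibble(
    gene = gene, class = cls, start = start, end = end, strand = strand,
    start_codon = take("initiation", "initiation codon", "start_codon"),
    stop_codon = take("stop", "stop codon", "stop_codon"),
    anticodon = take("anticodon")
  )
  mito_annotation(features,
    genome_length = genome_length, accession = accession
  )
}

#' Write a mitogenome feature table
#'
#' Inverse of [read_feature_table()]: writes the annotation's features as a
#' TSV with `Feature`, `Position`, `Strand`, codon and anticodon columns, so
#' that read-then-write round-trips.
#'
#' @param annotation A [mito_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "mito_annotation"))
  out <- annotation$features %>%
    mutate(Position = paste0(.data$start, "-", .data$end)) %>%
    select(
      Feature = "gene", "Position", Class = "class", Strand = "strand",
      Initiation = "start_codon", Stop = "stop_codon", Anticodon = "anticodon"
    )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Gene lengths and extreme protein-coding genes
#'
#' @param annotation A [mito_annotation()].
#' @return A tibble `(gene, class, length)` in genome order, with attributes
#'   `longest_pcg` and `shortest_pcg` (one-row tibbles).
#' @examples
#' tsv <- system.file("extdata", "abramis_brama_orientalis_mtgenome.tsv",
#'   package = "mitocub"
#' )
#' lengths <- gene_lengths(read_feature_table(tsv))
#' attr(lengths, "longest_pcg")
#' @export
gene_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  out <- annotation$features %>%
    mutate(length = .data$end - .data$start + 1L) %>%
    select("gene", "class", "length")
  pcgs <- filter(out, .data$class == "PCG")
  attr(out, "longest_pcg") <- if (nrow(pcgs)) slice(pcgs, which.max(.data$length)) else pcgs
  attr(out, "shortest_pcg") <- if (nrow(pcgs)) slice(pcgs, which.min(.data$length)) else pcgs
  out
}

#' Intergenic spacers and overlaps
#'
#' Computes, for each consecutive pair of features in genome order, the
#' signed spacer `downstream$start - upstream$end - 1`. Negative values are
#' gene overlaps. Following the linearised presentation of mitogenome
#' summary tables, no spacer is emitted between the last feature and the
#' first across the circular origin.
#'
#' @param annotation A [mito_annotation()].
#' @return A tibble `(upstream_gene, downstream_gene, spacer)` with
#'   attribute `n_overlaps`, the number of negative spacers.
#' @export
intergenic_spacers <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  f <- annotation$features
  if (nrow(f) < 2L) {
    out <- tibble(
      upstream_gene = character(), downstream_gene = character(),
      spacer = integer()
    )
    attr(out, "n_overlaps") <- 0L
    return(out)
  }
  out <- tibble(
    upstream_gene = f$gene[-nrow(f)],
    downstream_gene = f$gene[-1],
    spacer = f$start[-1] - f$end[-nrow(f)] - 1L
  )
  attr(out, "n_overlaps") <- sum(out$spacer < 0L)
  out
}

#' Extract a strand-correct coding sequence
#'
#' Returns the coding-sense nucleotide sequence of a protein-coding gene:
#' the genomic slice for heavy-strand genes, its reverse complement for
#' light-strand genes. When the feature length is not a multiple of 3 the
#' trailing 1-2 nt are an incomplete stop codon (completed to TAA by mRNA
#' polyadenylation in vertebrate mitochondria); they are flagged and, by
#' default, trimmed so downstream codon-level analyses see whole codons.
#'
#' @param annotation A [mito_annotation()] carrying a sequence.
#' @param gene Gene name of a PCG feature.
#' @param trim_incomplete Trim the trailing partial codon? Default `TRUE`.
#' @return A single string with attributes `incomplete_stop` (the trailing
#'   1-2 nt, or `NA`), `start_codon` and `stop_codon` as read from the
#'   extracted sequence.
#' @export
extract_cds <- function(annotation, gene, trim_incomplete = TRUE) {
  stopifnot(inherits(annotation, "mito_annotation"))
  if (is.null(annotation$sequence)) {
    abort("annotation carries no sequence; cannot extract CDS")
  }
  f <- filter(annotation$features, .data$gene == !!gene)
  if (nrow(f) == 0L) abort(paste0("gene '", gene, "' not found in annotation"))
  f <- slice(f, 1)
  if (f$class != "PCG") abort(paste0("gene '", gene, "' is not a protein-coding gene"))
  seq <- substr(annotation$sequence, f$start, f$end)
  if (f$strand == "L") seq <- reverse_complement(seq)
  rem <- nchar(seq) %% 3L
  incomplete <- NA_character_
  if (rem > 0L) {
    incomplete <- substr(seq, nchar(seq) - rem + 1L, nchar(seq))
    if (trim_incomplete) seq <- substr(seq, 1L, nchar(seq) - rem)
  }
  structure(seq,
    incomplete_stop = incomplete,
    start_codon = substr(seq, 1L, 3L),
    stop_codon = if (!is.na(incomplete)) incomplete else substr(seq, nchar(seq) - 2L, nchar(seq))
  )
}

#' Extract all protein-coding sequences
#'
#' @param annotation A [mito_annotation()] carrying a sequence.
#' @param trim_incomplete Trim trailing partial codons? Default `TRUE`.
#' @return A tibble `(gene, cds, n_codons, incomplete_stop)`.
#' @export
extract_all_cds <- function(annotation, trim_incomplete = TRUE) {
  stopifnot(inherits(annotation, "mito_annotation"))
  pcgs <- filter(annotation$features, .data$class == "PCG")$gene
  purrr::map_dfr(pcgs, function(g) {
    x <- extract_cds(annotation, g, trim_incomplete = trim_incomplete)
    inc <- attr(x, "incomplete_stop")
    tibble(
      gene = g,
      cds = as.character(x),
      n_codons = nchar(x) %/% 3L,
      incomplete_stop = inc
    )
  })
}

#' Start/stop codon census across protein-coding genes
#'
#' Tallies initiation and termination codon usage over the annotated PCGs,
#' as reported in mitogenome descriptions ("ATG in 12 of 13 PCGs" etc.).
#' Codons are taken from the annotation table when present, otherwise from
#' the extracted CDS if a sequence is available.
#'
#' @param annotation A [mito_annotation()].
#' @return A tibble `(kind, codon, n_genes, genes)` where `kind` is
#'   `"start"` or `"stop"` and `genes` is a comma-separated gene list.
#' @export
codon_census <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  pcgs <- filter(annotation$features, .data$class == "PCG")
  if (nrow(pcgs) == 0L) {
    return(tibble(
      kind = character(), codon = character(),
      n_genes = integer(), genes = character()
    ))
  }
  if (any(is.na(pcgs$start_codon)) && !is.null(annotation$sequence)) {
    cds <- extract_all_cds(annotation)
    pcgs <- pcgs %>%
      left_join(select(cds, "gene", "incomplete_stop"), by = "gene") %>%
      mutate(
        start_codon = dplyr::coalesce(
          .data$start_codon,
          purrr::map_chr(.data$gene, ~ attr(extract_cds(annotation, .x), "start_codon"))
        ),
        stop_codon = dplyr::coalesce(
          .data$stop_codon,
          purrr::map_chr(.data$gene, ~ attr(extract_cds(annotation, .x), "stop_codon"))
        )
      )
  }
  bind_rows(
    pcgs %>% filter(!is.na(.data$start_codon)) %>% group_by(codon = .data$start_codon) %>%
      summarise(
        kind = "start", n_genes = n(),
        genes = paste(.data$gene, collapse = ","), .groups = "drop"
      ),
    pcgs %>% filter(!is.na(.data$stop_codon)) %>% group_by(codon = .data$stop_codon) %>%
      summarise(
        kind = "stop", n_genes = n(),
        genes = paste(.data$gene, collapse = ","), .groups = "drop"
      )
  ) %>%
    select("kind", "codon", "n_genes", "genes") %>%
    arrange(.data$kind, dplyr::desc(.data$n_genes), .data$codon)
}

#' Feature-class census
#'
#' @param annotation A [mito_annotation()].
#' @return A tibble `(class, n)`.
#' @export
feature_census <- function(annotation) {
  stopifnot(inherits(annotation, "mito_annotation"))
  count(annotation$features, .data$class, name = "n")
}
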