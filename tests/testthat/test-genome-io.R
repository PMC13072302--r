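fixture <- system.file("extdata", "abramis_brama_orientalis_mtgenome.tsv",
  package = "mitocub"
)

test_that("the packaged mitogenome table parses with the printed arithmetic", {
  ann <- read_feature_table(fixture)
  expect_s3_class(ann$features, "tbl_df")
  expect_equal(ann$genome_length, 16607L)
  expect_equal(nrow(ann$features), 39L)

  gl <- gene_lengths(ann)
  expect_equal(gl$length[gl$gene == "nad5"], 1836L)
  expect_equal(gl$length[gl$gene == "trnF"], 69L)
  expect_equal(gl$length[gl$gene == "cytb"], 1141L)
  expect_equal(attr(gl, "longest_pcg")$gene, "nad5")
  expect_equal(attr(gl, "shortest_pcg")$gene, "atp8")
  expect_equal(attr(gl, "shortest_pcg")$length, 165L)
  expect_equal(sum(gl$length[gl$class == "PCG"]), 11497L)

  census <- feature_census(ann)
  expect_equal(census$n[census$class == "tRNA"], 22L)
  expect_equal(census$n[census$class == "PCG"], 13L)
  expect_equal(census$n[census$class == "rRNA"], 2L)
})

test_that("intergenic spacers reproduce the printed overlaps", {
  ann <- read_feature_table(fixture)
  sp <- intergenic_spacers(ann)
  get <- function(g) sp$spacer[sp$downstream_gene == g]
  expect_equal(get("atp6"), -7L)
  expect_equal(get("trnG"), -56L)
  expect_equal(get("trnK"), -14L)
  expect_equal(get("nad3"), 0L)
  expect_equal(get("NCR"), 26L)
  expect_equal(attr(sp, "n_overlaps"), 12L)
})

test_that("re-deriving the printed intergenic column matches except a known swapped pair", {
  # the printed values for trnW and trnA are swapped relative to what the
  # printed coordinates imply; every other non-empty cell reproduces exactly
  raw <- readr::read_tsv(fixture, show_col_types = FALSE)
  ann <- read_feature_table(fixture)
  sp <- intergenic_spacers(ann)
  printed <- raw$Intergenic[match(sp$downstream_gene, raw$Feature)]
  comparable <- !is.na(printed) & !sp$downstream_gene %in% c("trnW", "trnA")
  expect_true(all(sp$spacer[comparable] == printed[comparable]))
  expect_equal(sp$spacer[sp$downstream_gene == "trnW"], -2L)
  expect_equal(sp$spacer[sp$downstream_gene == "trnA"], 1L)
})

test_that("coordinates round-trip through the spacer identity and write/read", {
  ann <- read_feature_table(fixture)
  f <- ann$features
  sp <- intergenic_spacers(ann)
  # start_{i+1} = end_i + spacer_i + 1 reconstructs every coordinate
  expect_equal(f$start[-1], f$end[-nrow(f)] + sp$spacer + 1L)
  expect_equal(max(f$end), ann$genome_length)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, tmp)
  ann2 <- read_feature_table(tmp)
  expect_equal(ann2$features, ann$features)
  expect_equal(ann2$genome_length, ann$genome_length)
})

test_that("feature table validation errors name the offending row", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Feature\tPosition\tStrand", tmp)
  expect_error(read_feature_table(tmp), "empty")

  writeLines(c("Feature\tPosition\tStrand", "nad1\t10..x\tH"), tmp)
  expect_error(read_feature_table(tmp), "malformed coordinate.*nad1")

  writeLines(c("Feature\tPosition\tStrand", "nad1\t100-50\tH"), tmp)
  expect_error(read_feature_table(tmp), "invalid coordinates.*nad1")

  writeLines(c("Feature\tPosition\tStrand", "nad1\t50-100\tX"), tmp)
  expect_error(read_feature_table(tmp), "unknown strand 'X'")
})

test_that("thousands separators and en-dashes are tolerated", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Feature\tPosition\tStrand", "NCR\t15,703–16,607\tH"), tmp)
  ann <- read_feature_table(tmp)
  expect_equal(ann$features$start, 15703L)
  expect_equal(ann$features$end, 16607L)
})

test_that("codon census tallies the printed start/stop usage", {
  ann <- read_feature_table(fixture)
  cen <- codon_census(ann)
  expect_equal(cen$n_genes[cen$kind == "start" & cen$codon == "ATG"], 12L)
  expect_equal(cen$n_genes[cen$kind == "start" & cen$codon == "GTG"], 1L)
  expect_equal(cen$n_genes[cen$kind == "stop" & cen$codon == "TAA"], 8L)
  expect_equal(cen$n_genes[cen$kind == "stop" & cen$codon == "TAG"], 4L)
  expect_equal(cen$n_genes[cen$kind == "stop" & cen$codon == "T"], 1L)
  expect_true("cox1" %in% strsplit(cen$genes[cen$codon == "GTG"], ",")[[1]])

  no_pcg <- mito_annotation(
    dplyr::filter(ann$features, class == "tRNA")
  )
  expect_equal(nrow(codon_census(no_pcg)), 0L)
})

test_that("CDS extraction is strand-correct and trims incomplete stops", {
  feats <- tibble::tibble(
    gene = c("fwd", "rev", "part"),
    class = "PCG",
    start = c(1L, 13L, 22L),
    end = c(9L, 21L, 31L),
    strand = c("H", "L", "H"),
    start_codon = NA_character_, stop_codon = NA_character_,
    anticodon = NA_character_
  )
  #        fwd: ATGAAATAA  gap: CGA  rev slice: TTACATCAT  part: ATGCCCTAGT
  seq <- paste0("ATGAAATAA", "CGA", "TTACATCAT", "ATGCCCTAGT")
  ann <- mito_annotation(feats, genome_length = nchar(seq), sequence = seq)

  fwd <- extract_cds(ann, "fwd")
  expect_equal(as.character(fwd), "ATGAAATAA")
  expect_true(is.na(attr(fwd, "incomplete_stop")))

  rev <- extract_cds(ann, "rev")
  expect_equal(as.character(rev), oracle_revcomp("TTACATCAT"))
  expect_equal(substr(as.character(rev), 1, 3), "ATG")

  part <- extract_cds(ann, "part")
  expect_equal(as.character(part), "ATGCCCTAG")
  expect_equal(attr(part, "incomplete_stop"), "T")
  expect_equal(attr(part, "stop_codon"), "T")
  untrimmed <- extract_cds(ann, "part", trim_incomplete = FALSE)
  expect_equal(nchar(untrimmed), 10L)

  expect_error(extract_cds(ann, "nope"), "not found")
  no_seq <- mito_annotation(feats, genome_length = nchar(seq))
  expect_error(extract_cds(no_seq, "fwd"), "no sequence")
})

test_that("light-strand extraction equals the reverse-complement oracle on random slices", {
  set.seed(42)
  for (i in 1:20) {
    len <- 3L * sample(5:40, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len + 12, replace = TRUE), collapse = "")
    feats <- tibble::tibble(
      gene = "g", class = "PCG", start = 7L, end = 6L + len, strand = "L",
      start_codon = NA_character_, stop_codon = NA_character_, anticodon = NA_character_
    )
    ann <- mito_annotation(feats, genome_length = nchar(seq), sequence = seq)
    expect_equal(
      as.character(extract_cds(ann, "g")),
      oracle_revcomp(substr(seq, 7, 6 + len))
    )
  }
})

test_that("GenBank records parse with strand, class and name normalisation", {
  seq <- paste(rep("acgt", 40), collapse = "")
  gb <- make_gb_text(
    sequence = toupper(seq),
    features = c(
      "     CDS             complement(10..45)",
      "                     /gene=\"ND6\"",
      "                     /transl_table=2",
      "     tRNA            50..85",
      "                     /product=\"tRNA-Phe\"",
      "     rRNA            90..130",
      "                     /product=\"12S ribosomal RNA\"",
      "     D-loop          131..158"
    )
  )
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tmp)
  ann <- read_genbank(tmp)
  f <- ann$features
  expect_equal(f$gene[f$class == "PCG"], "nad6")
  expect_equal(f$strand[f$gene == "nad6"], "L")
  expect_equal(f$gene[f$class == "tRNA"], "trnF")
  expect_equal(f$gene[f$class == "rRNA"], "rrnS")
  expect_equal(f$class[4], "noncoding")
  expect_equal(attr(ann, "transl_table"), 2L)
  expect_equal(nchar(ann$sequence), 160L)
})

test_that("GenBank parsing rejects what it cannot represent", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_gb_text(features = character(0)), tmp)
  expect_error(read_genbank(tmp), "no usable features")

  writeLines(
    make_gb_text(features = c(
      "     CDS             join(10..45,90..120)",
      "                     /gene=\"ND1\""
    )),
    tmp
  )
  expect_error(read_genbank(tmp), "join/order")

  writeLines(
    make_gb_text(features = c(
      "     CDS             10..45",
      "                     /gene=\"ND1\""
    )),
    tmp
  )
  expect_error(read_genbank(tmp, require_sequence = TRUE), "no ORIGIN")
})

test_that("gene names normalise across annotation dialects", {
  expect_equal(normalize_gene_name("COX1"), "cox1")
  expect_equal(normalize_gene_name("COI"), "cox1")
  expect_equal(normalize_gene_name("cob"), "cytb")
  expect_equal(normalize_gene_name("12S"), "rrnS")
  expect_equal(normalize_gene_name("tRNA-Leu", anticodon = "TAA"), "trnL2")
  expect_equal(normalize_gene_name("tRNA-Leu", anticodon = "TAG"), "trnL1")
  expect_equal(normalize_gene_name("tRNA-Ser", anticodon = "GCT"), "trnS1")
  expect_warning(out <- normalize_gene_name("mystery9"), "unrecognised")
  expect_equal(out, "mystery9")
})
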