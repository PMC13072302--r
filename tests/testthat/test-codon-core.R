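mito <- genetic_code(2)
std <- genetic_code(1)

test_that("genetic code tables have the expected structure", {
  expect_setequal(mito$stop_codons, c("TAA", "TAG", "AGA", "AGG"))
  expect_equal(length(mito$sense_codons), 60L)
  expect_equal(mito$codon_to_aa[["ATA"]], "M")
  expect_equal(mito$codon_to_aa[["TGA"]], "W")
  expect_equal(mito$max_enc, 60L)

  expect_setequal(std$stop_codons, c("TAA", "TAG", "TGA"))
  expect_equal(length(std$sense_codons), 61L)
  expect_equal(std$max_enc, 61L)

  # every 3-mer appears exactly once
  expect_equal(sort(names(mito$codon_to_aa)), sort(names(std$codon_to_aa)))
  expect_equal(length(unique(names(mito$codon_to_aa))), 64L)
  # Leu and Ser are 6-fold under the mitochondrial code, Met and Trp 2-fold
  expect_equal(unname(mito$degeneracy[c("CTA", "TCA", "ATG", "TGG")]), c(6L, 6L, 2L, 2L))
})

test_that("codon counting reads frame 0, drops stops and flags ambiguity", {
  cc <- count_codons("ATGAAACCC", std)
  expect_equal(cc$count[cc$codon %in% c("ATG", "AAA", "CCC")], c(1L, 1L, 1L))
  expect_equal(attr(cc, "n_codons"), 3L)

  cc2 <- count_codons("ATGAAATAA", mito, drop_stops = TRUE)
  expect_equal(attr(cc2, "n_codons"), 2L)
  expect_false("TAA" %in% cc2$codon)

  cc3 <- count_codons("ATGAAAT", std)
  expect_equal(attr(cc3, "n_codons"), 2L)

  cc4 <- count_codons("ATGANAAAA", std)
  expect_equal(attr(cc4, "n_codons"), 2L)
  expect_equal(attr(cc4, "n_ambiguous"), 1L)

  expect_error(count_codons("AT", std), "shorter")

  # stops can never appear among sense counts under the mitochondrial code
  cc5 <- count_codons("AGAAGGTAATAG", mito, drop_stops = TRUE)
  expect_equal(attr(cc5, "n_codons"), 0L)
})

test_that("RSCU matches hand-computed values and the thresholds", {
  r1 <- rscu(count_codons("TTTTTCTTTTTC", std), std)
  expect_equal(r1$rscu[r1$codon %in% c("TTT", "TTC")], c(1, 1))

  r2 <- rscu(count_codons("TTTTTTTTTTTC", std), std) # Phe 3:1
  expect_equal(r2$rscu[r2$codon == "TTT"], 1.5)
  expect_equal(r2$rscu[r2$codon == "TTC"], 0.5)
  expect_equal(r2$class[r2$codon == "TTC"], "underrepresented")

  r3 <- rscu(count_codons("GGAGGAGGAGGA", std), std) # Gly only GGA
  expect_equal(r3$rscu[r3$codon == "GGA"], 4)
  expect_equal(r3$class[r3$codon == "GGA"], "overrepresented")
  expect_equal(r3$rscu[r3$codon == "GGC"], 0)
  expect_equal(r3$class[r3$codon == "GGC"], "underrepresented")
  # unused families are missing, not zero
  expect_true(all(is.na(r3$rscu[r3$aa == "K"])))
  expect_true(all(is.na(r3$class[r3$aa == "K"])))
})

test_that("RSCU classification respects the 1.6/0.6 boundaries exactly", {
  # Phe 4:1 -> RSCU 1.6 / 0.4; the boundary value 1.6 is not overrepresented
  counts <- count_codons(paste0(strrep("TTT", 4), "TTC"), std)
  r <- rscu(counts, std)
  expect_equal(r$rscu[r$codon == "TTT"], 1.6)
  expect_equal(r$class[r$codon == "TTT"], "neutral")
  # Leu (6-fold) 1:1:1:1:1:5 gives RSCU 0.6 for the singles: not under
  leu <- paste0(c("TTA", "TTG", "CTT", "CTC", "CTA", strrep("CTG", 5)), collapse = "")
  r2 <- rscu(count_codons(leu, std), std)
  expect_equal(r2$rscu[r2$codon == "TTA"], 0.6)
  expect_equal(r2$class[r2$codon == "TTA"], "neutral")
  expect_equal(r2$rscu[r2$codon == "CTG"], 3)
  expect_equal(r2$class[r2$codon == "CTG"], "overrepresented")
})

test_that("RSCU family sums equal family size and scale-invariance holds", {
  set.seed(7)
  for (code in list(std, mito)) {
    for (rep in 1:25) {
      counts <- random_counts(code, min_count = 0, max_count = 30)
      r <- rscu(counts, code)
      sums <- tapply(r$rscu, r$aa, sum)
      sizes <- tapply(r$rscu, r$aa, length)
      defined <- !is.na(sums)
      expect_equal(as.numeric(sums[defined]), as.numeric(sizes[defined]))

      scaled <- counts
      scaled$count <- scaled$count * 7L
      expect_equal(rscu(scaled, code)$rscu, r$rscu)
    }
  }
})

test_that("aggregation is element-wise and equals counting the concatenation", {
  a <- count_codons("AAAAAA", std) # AAA x2
  b <- count_codons("AAACCC", std)
  agg <- aggregate_counts(a, b)
  expect_equal(agg$count[agg$codon == "AAA"], 3L)
  expect_equal(attr(agg, "n_codons"), 4L)

  empty <- count_codons("TTT", std)
  empty$count <- 0L
  expect_equal(aggregate_counts(a, empty)$count, a$count)

  set.seed(11)
  genes <- replicate(13, {
    paste(sample(std$sense_codons, 40, replace = TRUE), collapse = "")
  })
  per_gene <- lapply(genes, count_codons, code = std)
  expect_equal(
    aggregate_counts(per_gene)$count,
    count_codons(paste(genes, collapse = ""), std)$count
  )

  mixed <- count_codons("TTT", mito)
  expect_error(aggregate_counts(a, mixed), "codon set")
})

test_that("positional composition matches forced-base examples", {
  c1 <- composition("GGGGCC")
  expect_equal(c1$gc1, 100)
  expect_equal(c1$gc2, 100)
  expect_equal(c1$gc3, 100)
  expect_equal(c1$gc12, 100)

  c2 <- composition("ATGATGATG")
  expect_equal(c2$gc3, 100) # all G at third positions
  expect_equal(c2$gc12, 0) # A and T only at positions 1-2
  expect_equal(c2$a3, 0L)
  expect_equal(c2$g3, 3L)

  # AT-only sequence: AT skew defined, GC skew missing (never 0)
  b <- base_composition("AATT")
  expect_equal(b$at_skew, 0)
  expect_true(is.na(b$gc_skew))

  c3 <- composition("AAATTT")
  expect_equal(c3$at_skew, 0)
  expect_true(is.na(c3$gc_skew))
})

test_that("GC3s excludes Met, Trp and stop codons under the stated definition", {
  # ATG (Met) and TGG (Trp) excluded; TTC contributes its C
  expect_equal(composition("ATGTGGTTC", mito)$gc3s, 100)
  expect_equal(composition("ATGTGGTTT", mito)$gc3s, 0)
  # ATA is Met under the mitochondrial code only
  expect_equal(composition("ATATTC", mito)$gc3s, 100)
  expect_equal(composition("ATATTC", std)$gc3s, 50)
  # all codons excluded -> missing
  expect_true(is.na(composition("ATGTGG", mito)$gc3s))
  # code-aware variant: under the mitochondrial code Met and Trp are
  # two-codon families, so only stops are excluded and all three third
  # positions (G, G, T) count
  expect_equal(
    composition("ATGTGGTTT", mito, gc3s_exclusions = "code_aware")$gc3s,
    200 / 3
  )
  # under the standard code ATG and TGG are single-codon families: excluded
  expect_equal(
    composition("ATGTGGTTT", std, gc3s_exclusions = "code_aware")$gc3s,
    0
  )
})

test_that("composition of a concatenation is the count-weighted merge", {
  set.seed(5)
  seqs <- replicate(6, paste(sample(mito$sense_codons, 50, replace = TRUE), collapse = ""))
  parts <- composition(seqs)
  whole <- composition(paste(seqs, collapse = ""))
  expect_equal(whole$n_codons, sum(parts$n_codons))
  expect_equal(whole$gc3, sum(parts$gc3 * parts$n_codons) / sum(parts$n_codons))
  expect_equal(whole$a3, sum(parts$a3))
  expect_equal(
    whole$gc12,
    sum(parts$gc12 * parts$n_codons) / sum(parts$n_codons)
  )
})
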