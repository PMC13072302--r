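#' Count in-frame codons of a coding sequence
#'
#' Reads the sequence in frame 0 from the first base. A trailing incomplete
#' codon is ignored; codons containing N (or any non-ACGT character) are
#' excluded from the counts and tallied separately in the `n_ambiguous`
#' attribute.
#'
#' @param cds Coding nucleotide string (length >= 3).
#' @param code A [genetic_code()]. Default vertebrate mitochondrial.
#' @param drop_stops Exclude codons in the code's stop set? Default `TRUE`,
#'   so downstream synonymous-usage statistics see sense codons only.
#' @param source Optional label recorded on the result.
#' @return A tibble `(codon, aa, count)` over the code's codons (sense
#'   codons only when `drop_stops`), in canonical order, with attributes
#'   `n_codons` (total counted), `n_ambiguous` and `source`.
#' @examples
#' count_codons("ATGAAACCC")
#' @export
count_codons <- function(cds, code = genetic_code(2), drop_stops = TRUE,
                         source = NA_character_) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) abort("`cds` is shorter than one codon")
  codons <- split_codons(cds)
  ambiguous <- grepl("[^ACGT]", codons)
  codons <- codons[!ambiguous]
  keep <- codon_order(code)
  if (drop_stops) keep <- setdiff(keep, code$stop_codons)
  tab <- table(factor(codons, levels = keep))
  out <- tibble(
    codon = names(tab),
    aa = unname(code$codon_to_aa[names(tab)]),
    count = as.integer(tab)
  )
  attr(out, "n_codons") <- sum(out$count)
  attr(out, "n_ambiguous") <- sum(ambiguous)
  attr(out, "source") <- source
  out
}

#' Sum codon counts element-wise
#'
#' Aggregates per-gene codon counts into a species-level count table (e.g.
#' the concatenation of the 13 mitochondrial PCGs). All inputs must be codon
#' count tibbles over the same codon set.
#'
#' @param ... Codon count tibbles from [count_codons()], or a single list of
#'   them.
#' @param source Optional label for the aggregate.
#' @return A codon count tibble.
#' @export
aggregate_counts <- function(..., source = NA_character_) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  stopifnot(length(dots) >= 1L)
  base <- dots[[1]]
  for (x in dots[-1]) {
    if (!identical(x$codon, base$codon)) {
      abort("codon count tables disagree on codon set/order; same genetic code required")
    }
  }
  out <- base
  out$count <- Reduce(`+`, purrr::map(dots, "count"))
  attr(out, "n_codons") <- sum(out$count)
  attr(out, "n_ambiguous") <- sum(purrr::map_int(dots, ~ attr(.x, "n_ambiguous") %||% 0L))
  attr(out, "source") <- source
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all members of its synonymous family were used equally:
#' `RSCU = count * family_size / family_total`. Within each family the RSCU
#' values sum to the family size. Codons with `RSCU > over` are classified
#' overrepresented and `RSCU < under` underrepresented; a codon in a family
#' with zero usage has no defined RSCU and is reported `NA`, never 0.
#'
#' @param counts A codon count tibble from [count_codons()] (sense codons).
#' @param code A [genetic_code()].
#' @param over,under Classification thresholds. Defaults 1.6 and 0.6.
#' @return A tibble `(codon, aa, count, rscu, class)` where `class` is one
#'   of `"overrepresented"`, `"neutral"`, `"underrepresented"` or `NA`.
#' @examples
#' rscu(count_codons("TTTTTTTTCATG"))
#' @export
rscu <- function(counts, code = genetic_code(2), over = 1.6, under = 0.6) {
  stopifnot(over > under, under > 0)
  out <- counts %>%
    filter(!.data$codon %in% code$stop_codons) %>%
    group_by(.data$aa) %>%
    mutate(
      family_size = n(),
      family_total = sum(.data$count),
      rscu = ifelse(.data$family_total > 0,
        .data$count * .data$family_size / .data$family_total, NA_real_
      )
    ) %>%
    ungroup() %>%
    mutate(class = case_when(
      is.na(.data$rscu) ~ NA_character_,
      .data$rscu > over ~ "overrepresented",
      .data$rscu < under ~ "underrepresented",
      TRUE ~ "neutral"
    )) %>%
    select("codon", "aa", "count", "rscu", "class")
  attr(out, "source") <- attr(counts, "source")
  out
}

base_counts <- function(chars) {
  tab <- table(factor(chars, levels = c("A", "C", "G", "T")))
  as.integer(tab)
}

pct_or_na <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
skew_or_na <- function(p, q) ifelse(p + q > 0, (p - q) / (p + q), NA_real_)

#' Positional nucleotide composition of coding sequences
#'
#' For each in-frame coding sequence, computes overall base percentages, AT
#' and GC skews (`(A-T)/(A+T)`, `(G-C)/(G+C)`; Perna-Kocher convention),
#' GC content at each codon position (GC1, GC2, GC3, and GC12 the mean of
#' GC1 and GC2), GC3s (GC at synonymous third positions), and third-position
#' base counts A3/T3/G3/C3. Percentages are on the 0-100 scale. Ratios with
#' a zero denominator are reported `NA`, never 0.
#'
#' GC3s follows the classical definition: third positions of codons other
#' than those encoding Met and Trp and the stop codons
#' (`gc3s_exclusions = "paper"`). Under the mitochondrial code Met and Trp
#' are two-codon families, so a code-aware variant
#' (`gc3s_exclusions = "code_aware"`) that excludes only single-codon
#' families and stops is also provided.
#'
#' @param seqs Character vector of in-frame coding sequences (names used as
#'   labels when present).
#' @param code A [genetic_code()].
#' @param gc3s_exclusions `"paper"` (default) or `"code_aware"`, see above.
#' @param labels Optional label column values.
#' @return A tibble with one row per sequence: `label`, `n_codons`,
#'   `a_pct`..`c_pct`, `gc_pct`, `at_skew`, `gc_skew`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, `gc3s`, and third-position counts `a3`, `t3`, `g3`, `c3`.
#' @examples
#' composition(c(nad1 = "ATGAAACGATGA"))
#' @export
composition <- function(seqs, code = genetic_code(2),
                        gc3s_exclusions = c("paper", "code_aware"),
                        labels = NULL) {
  gc3s_exclusions <- match.arg(gc3s_exclusions)
  if (length(seqs) == 0L) abort("no sequences supplied")
  if (is.null(labels)) {
    labels <- names(seqs) %||% paste0("seq", seq_along(seqs))
  }
  excluded <- if (gc3s_exclusions == "paper") {
    names(code$codon_to_aa)[code$codon_to_aa %in% c("M", "W", "*")]
  } else {
    union(code$stop_codons, names(code$degeneracy)[code$degeneracy == 1L])
  }
  # codon index arithmetic (A=0 C=1 G=2 T=3; idx = 16 b1 + 4 b2 + b3 + 1)
  bases <- c("A", "C", "G", "T")
  all64 <- sort(names(code$codon_to_aa)) # lexicographic = base-4 digit order
  excl_idx <- all64 %in% excluded
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(toupper(seqs[[i]]), "", fixed = TRUE)[[1]]
    n3 <- length(ch) %/% 3L
    if (n3 > 0L) ch <- ch[seq_len(3L * n3)]
    b <- match(ch, bases) # NA for ambiguous
    dim(b) <- c(3L, n3)
    ok <- !is.na(b[1L, ]) & !is.na(b[2L, ]) & !is.na(b[3L, ])
    b <- b[, ok, drop = FALSE]
    nc <- ncol(b)
    if (nc == 0L) abort("sequence contains no complete unambiguous codons")
    cnt_all <- tabulate(b, 4L)
    n_all <- 3L * nc
    b3 <- tabulate(b[3L, ], 4L)
    gc1 <- 100 * sum(b[1L, ] %in% c(2L, 3L)) / nc
    gc2 <- 100 * sum(b[2L, ] %in% c(2L, 3L)) / nc
    gc3 <- 100 * sum(b[3L, ] %in% c(2L, 3L)) / nc
    idx <- 16L * (b[1L, ] - 1L) + 4L * (b[2L, ] - 1L) + b[3L, ]
    syn <- !excl_idx[idx]
    gc3s <- if (any(syn)) 100 * sum(b[3L, syn] %in% c(2L, 3L)) / sum(syn) else NA_real_
    rows[[i]] <- list(
      label = labels[[i]],
      n_codons = nc,
      a_pct = pct_or_na(cnt_all[1], n_all),
      c_pct = pct_or_na(cnt_all[2], n_all),
      g_pct = pct_or_na(cnt_all[3], n_all),
      t_pct = pct_or_na(cnt_all[4], n_all),
      gc_pct = pct_or_na(cnt_all[2] + cnt_all[3], n_all),
      at_skew = skew_or_na(cnt_all[1], cnt_all[4]),
      gc_skew = skew_or_na(cnt_all[3], cnt_all[2]),
      gc1 = gc1, gc2 = gc2, gc3 = gc3,
      gc12 = (gc1 + gc2) / 2,
      gc3s = gc3s,
      a3 = b3[1], c3 = b3[2], g3 = b3[3], t3 = b3[4]
    )
  }
  dplyr::bind_rows(rows)
}

#' Base composition of arbitrary nucleotide sequences
#'
#' Non-positional counterpart of [composition()] for whole genomes, tRNAs
#' and rRNAs: base percentages and AT/GC skews only.
#'
#' @param seqs Character vector of nucleotide sequences.
#' @param labels Optional labels (default from names).
#' @return A tibble `(label, length, a_pct, c_pct, g_pct, t_pct, gc_pct,
#'   at_pct, at_skew, gc_skew)`.
#' @export
base_composition <- function(seqs, labels = NULL) {
  if (length(seqs) == 0L) abort("no sequences supplied")
  if (is.null(labels)) labels <- names(seqs) %||% paste0("seq", seq_along(seqs))
  purrr::map2_dfr(unname(seqs), labels, function(s, lab) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch <- ch[ch %in% c("A", "C", "G", "T")]
    b <- base_counts(ch)
    n <- sum(b)
    tibble(
      label = lab, length = nchar(s),
      a_pct = pct_or_na(b[1], n), c_pct = pct_or_na(b[2], n),
      g_pct = pct_or_na(b[3], n), t_pct = pct_or_na(b[4], n),
      gc_pct = pct_or_na(b[2] + b[3], n), at_pct = pct_or_na(b[1] + b[4], n),
      at_skew = skew_or_na(b[1], b[4]), gc_skew = skew_or_na(b[3], b[2])
    )
  })
}
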