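# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Site counting: each codon position contributes up to one site, split into
# a synonymous fraction (number of synonymous single-nucleotide changes at
# that position divided by 3) and a nonsynonymous fraction; changes to stop
# codons are excluded, so s + n = 3 minus one third of the stop-mutant
# count. Difference counting for codons differing at 2-3 positions averages
# synonymous/nonsynonymous steps over all minimal mutational pathways with
# equal weight, excluding pathways passing through a stop codon.

ng86_tables <- function(code) {
  key <- paste0("ng86_", code$table_id)
  if (!is.null(.mitocub_cache[[key]])) {
    return(.mitocub_cache[[key]])
  }
  bases <- c("A", "C", "G", "T")
  all_codons <- names(code$codon_to_aa)
  aa <- code$codon_to_aa
  is_stop <- aa == "*"

  mutants <- function(codon, pos) {
    cur <- substr(codon, pos, pos)
    vapply(setdiff(bases, cur), function(b) {
      out <- codon
      substr(out, pos, pos) <- b
      out
    }, character(1))
  }

  sites <- matrix(NA_real_, nrow = 64, ncol = 2, dimnames = list(all_codons, c("s", "n")))
  for (codon in all_codons[!is_stop]) {
    s <- 0
    n <- 0
    for (pos in 1:3) {
      for (m in mutants(codon, pos)) {
        if (is_stop[[m]]) next
        if (aa[[m]] == aa[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
    sites[codon, ] <- c(s, n)
  }

  # pathway-averaged pairwise difference counts
  syn_d <- matrix(NA_real_, 64, 64, dimnames = list(all_codons, all_codons))
  non_d <- matrix(NA_real_, 64, 64, dimnames = list(all_codons, all_codons))
  step_type <- function(c1, c2) as.integer(aa[[c1]] == aa[[c2]]) # 1 = synonymous
  for (c1 in all_codons[!is_stop]) {
    for (c2 in all_codons[!is_stop]) {
      pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      d <- length(pos_diff)
      if (d == 0L) {
        syn_d[c1, c2] <- 0
        non_d[c1, c2] <- 0
        next
      }
      perms <- if (d == 1L) {
        list(pos_diff)
      } else if (d == 2L) {
        list(pos_diff, rev(pos_diff))
      } else {
        lapply(
          list(
            c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
          ),
          function(o) pos_diff[o]
        )
      }
      path_counts <- purrr::map(perms, function(order) {
        cur <- c1
        s <- 0
        n <- 0
        for (pos in order) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (is_stop[[nxt]]) {
            return(NULL)
          }
          if (step_type(cur, nxt) == 1L) s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        c(s, n)
      })
      valid <- purrr::compact(path_counts)
      if (length(valid) == 0L) {
        # every pathway crosses a stop; fall back to averaging all pathways
        valid <- purrr::map(perms, function(order) {
          cur <- c1
          s <- 0
          n <- 0
          for (pos in order) {
            nxt <- cur
            substr(nxt, pos, pos) <- substr(c2, pos, pos)
            if (aa[[nxt]] != "*" && aa[[cur]] != "*" && aa[[cur]] == aa[[nxt]]) {
              s <- s + 1
            } else {
              n <- n + 1
            }
            cur <- nxt
          }
          c(s, n)
        })
      }
      m <- do.call(rbind, valid)
      syn_d[c1, c2] <- mean(m[, 1])
      non_d[c1, c2] <- mean(m[, 2])
    }
  }
  out <- list(sites = sites, syn_d = syn_d, non_d = non_d)
  .mitocub_cache[[key]] <- out
  out
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Nei-Gojobori site counting for a single sense codon: each position
#' contributes 1/3 of a site per possible single-nucleotide change, assigned
#' synonymous or nonsynonymous by whether the encoded amino acid changes;
#' changes producing a stop codon are excluded, so `s + n <= 3`.
#'
#' @param codon A sense codon (3-mer over ACGT).
#' @param code A [genetic_code()].
#' @return A named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' ng86_sites("TTT", genetic_code(1)) # s = 1/3, n = 8/3
#' @export
ng86_sites <- function(codon, code = genetic_code(2)) {
  codon <- toupper(codon)
  if (!codon %in% names(code$codon_to_aa)) abort(paste0("'", codon, "' is not a codon"))
  if (codon %in% code$stop_codons) abort(paste0("'", codon, "' is a stop codon"))
  tabs <- ng86_tables(code)
  c(s = unname(tabs$sites[codon, "s"]), n = unname(tabs$sites[codon, "n"]))
}

jc_correct <- function(p) {
  ifelse(is.na(p), NA_real_,
    ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  )
}

#' Pairwise Ka and Ks by the Nei-Gojobori method
#'
#' Compares two aligned, equal-length, in-frame coding sequences. Codon
#' pairs containing gaps, ambiguous bases or stop codons are removed
#' pairwise. Site totals are averaged over the two sequences; observed
#' synonymous/nonsynonymous differences are pathway-averaged (see
#' [ng86_sites()]); proportions are distance-corrected with Jukes-Cantor
#' `d = -3/4 log(1 - 4p/3)`. `Ka/Ks` is `NA` when `Ks` is 0 or undefined.
#'
#' @param cds_a,cds_b Coding sequences of equal length.
#' @param code A [genetic_code()].
#' @param pair Optional pair label(s) (length 2, e.g. two species names).
#' @param gene Optional gene label.
#' @return A one-row tibble `(gene, species_a, species_b, n_codons_compared,
#'   s_sites, n_sites, syn_diffs, nonsyn_diffs, ka, ks, kaks,
#'   selection_call)`. A proportion at or beyond the Jukes-Cantor saturation
#'   point (p >= 3/4) yields `NA` with a warning.
#' @examples
#' ng86_pair("ATGAAACCTTGGTTT", "ATGAAGCCTTGGTTT", code = genetic_code(1))
#' @export
ng86_pair <- function(cds_a, cds_b, code = genetic_code(2),
                      pair = c("a", "b"), gene = NA_character_) {
  cds_a <- toupper(cds_a)
  cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("sequences differ in length; ng86_pair needs an aligned in-frame pair")
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  ok_codon <- function(x) !grepl("[^ACGT]", x) & !x %in% code$stop_codons
  keep <- ok_codon(ca) & ok_codon(cb)
  ca <- ca[keep]
  cb <- cb[keep]
  if (length(ca) == 0L) abort("no comparable codon pairs after filtering")
  tabs <- ng86_tables(code)
  s_sites <- (sum(tabs$sites[ca, "s"]) + sum(tabs$sites[cb, "s"])) / 2
  n_sites <- (sum(tabs$sites[ca, "n"]) + sum(tabs$sites[cb, "n"])) / 2
  idx <- cbind(ca, cb)
  sd <- sum(tabs$syn_d[idx])
  nd <- sum(tabs$non_d[idx])
  ps <- if (s_sites > 0) sd / s_sites else NA_real_
  pn <- if (n_sites > 0) nd / n_sites else NA_real_
  if (!is.na(ps) && ps >= 0.75) {
    warn("synonymous proportion at Jukes-Cantor saturation (p >= 3/4); Ks undefined")
  }
  if (!is.na(pn) && pn >= 0.75) {
    warn("nonsynonymous proportion at Jukes-Cantor saturation (p >= 3/4); Ka undefined")
  }
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  kaks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  tibble(
    gene = gene, species_a = pair[1], species_b = pair[2],
    n_codons_compared = length(ca),
    s_sites = s_sites, n_sites = n_sites,
    syn_diffs = sd, nonsyn_diffs = nd,
    ka = ka, ks = ks, kaks = kaks,
    selection_call = case_when(
      is.na(kaks) ~ NA_character_,
      kaks < 1 ~ "purifying",
      kaks > 1 ~ "positive",
      TRUE ~ "neutral"
    )
  )
}

#' All pairwise Ka/Ks for one gene across species
#'
#' @param cds_set Named character vector of aligned equal-length CDS, one
#'   per species.
#' @param gene Gene label.
#' @param code A [genetic_code()].
#' @return A tibble of [ng86_pair()] rows for all species pairs.
#' @export
kaks_pairwise <- function(cds_set, gene = NA_character_, code = genetic_code(2)) {
  if (length(cds_set) < 2L) abort("need at least two sequences")
  if (is.null(names(cds_set))) names(cds_set) <- paste0("sp", seq_along(cds_set))
  pairs <- combn(names(cds_set), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    p <- pairs[, i]
    ng86_pair(cds_set[[p[1]]], cds_set[[p[2]]],
      code = code, pair = p, gene = gene
    )
  })
}

#' Per-gene average Ka, Ks and Ka/Ks
#'
#' Averages the pairwise results of one gene. The per-gene ratio is, by
#' default, the mean of the defined pairwise ratios (`"mean_of_ratios"`);
#' `"ratio_of_means"` divides mean Ka by mean Ks instead.
#'
#' @param pairwise A tibble from [kaks_pairwise()] (possibly several genes).
#' @param ratio_mode `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return A tibble with one row per gene: `(gene, n_pairs, mean_ka,
#'   mean_ks, mean_kaks, selection_call)`.
#' @export
kaks_average <- function(pairwise, ratio_mode = c("mean_of_ratios", "ratio_of_means")) {
  ratio_mode <- match.arg(ratio_mode)
  if (nrow(pairwise) == 0L) abort("no pairwise results to average")
  pairwise %>%
    group_by(.data$gene) %>%
    summarise(
      n_pairs = n(),
      mean_ka = mean(.data$ka, na.rm = TRUE),
      mean_ks = mean(.data$ks, na.rm = TRUE),
      mean_kaks = if (ratio_mode == "mean_of_ratios") {
        mean(.data$kaks, na.rm = TRUE)
      } else {
        mean(.data$ka, na.rm = TRUE) / mean(.data$ks, na.rm = TRUE)
      },
      .groups = "drop"
    ) %>%
    mutate(selection_call = case_when(
      is.na(.data$mean_kaks) ~ NA_character_,
      .data$mean_kaks < 1 ~ "purifying",
      .data$mean_kaks > 1 ~ "positive",
      TRUE ~ "neutral"
    ))
}

#' Contrast Ka/Ks between two gene groups
#'
#' Mann-Whitney U test on per-gene mean Ka/Ks between two gene families,
#' canonically the cytochrome oxidase genes (cox1-cox3) versus the NADH
#' dehydrogenase genes (nad1-nad6, nad4L).
#'
#' @param gene_summary A tibble from [kaks_average()].
#' @param group_a,group_b Character vectors of gene names.
#' @param ... Passed to [mann_whitney_u()].
#' @return A one-row tibble; see [mann_whitney_u()].
#' @export
kaks_group_contrast <- function(gene_summary,
                                group_a = paste0("cox", 1:3),
                                group_b = c(paste0("nad", 1:6), "nad4L"),
                                ...) {
  va <- filter(gene_summary, .data$gene %in% group_a)$mean_kaks
  vb <- filter(gene_summary, .data$gene %in% group_b)$mean_kaks
  if (length(va) == 0L || length(vb) == 0L) {
    abort("one of the gene groups is empty in `gene_summary`")
  }
  mann_whitney_u(va, vb, ...)
}
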