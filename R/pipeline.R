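#' Run the full codon-usage-bias analysis
#'
#' Orchestrates the end-to-end analysis over a set of annotated genomes
#' (with sequences): per-gene and per-species composition, RSCU with UPGMA
#' clustering of species profiles, ENC observed/expected with ENC-ratio
#' calls and the binomial test on selection dominance, PR2 coordinates,
#' the neutrality regression (per-gene and per-species units), and -- when
#' a per-gene multi-species CDS set is supplied -- Nei-Gojobori Ka/Ks with
#' the cox-versus-nad contrast. The run is a pure function of its inputs:
#' re-running with the same inputs writes byte-identical tables.
#'
#' Genes listed in `genes` but absent from a species are skipped with a
#' warning naming the species, and the remaining genes are analysed.
#'
#' @param annotations Named list of [mito_annotation()] objects carrying
#'   sequences (names are species labels).
#' @param out_dir Output directory for the TSV/Newick bundle; `NULL`
#'   (default) skips writing and only returns the tables.
#' @param cds_sets Optional tibble `(gene, species, cds)` of aligned
#'   equal-length CDS for Ka/Ks (e.g. from [sim_kaks_genes()]).
#' @param genes PCG inclusion list. Default: the 13 mitochondrial PCGs.
#' @param code A [genetic_code()].
#' @param rscu_over,rscu_under RSCU classification thresholds (1.6 / 0.6).
#' @param enc_band ENC-ratio mutation band half-width (0.05).
#' @param enc_strong ENC strong-bias cutoff (35).
#' @param alpha Significance level (0.05).
#' @param slope_upper Neutrality selection-call slope bound (0.5).
#' @return A list of tibbles: `composition`, `species_composition`, `rscu`,
#'   `rscu_matrix`, `tree` (upgma), `newick`, `heatmap`, `enc`,
#'   `enc_binomial`, `pr2`, `neutrality_gene`, `neutrality_species`, and
#'   (with `cds_sets`) `kaks_pairwise`, `kaks_gene`, `kaks_contrast`.
#' @export
run_pipeline <- function(annotations, out_dir = NULL, cds_sets = NULL,
                         genes = c(
                           paste0("nad", c(1:6, "4L")), paste0("cox", 1:3),
                           "atp6", "atp8", "cytb"
                         ),
                         code = genetic_code(2),
                         rscu_over = 1.6, rscu_under = 0.6,
                         enc_band = 0.05, enc_strong = 35,
                         alpha = 0.05, slope_upper = 0.5) {
  stopifnot(length(genes) >= 1, rscu_over > 0, enc_band > 0, alpha > 0)
  if (is.null(names(annotations))) {
    names(annotations) <- purrr::map_chr(
      annotations,
      ~ .x$accession %||% NA_character_
    )
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  cds_tbl <- stage("extract_cds", purrr::imap_dfr(annotations, function(ann, sp) {
    got <- extract_all_cds(ann) %>% filter(.data$gene %in% genes)
    missing <- setdiff(genes, got$gene)
    if (length(missing) > 0) {
      warn(paste0(
        "gene(s) ", paste(missing, collapse = ", "),
        " absent in species '", sp, "'; skipped"
      ))
    }
    mutate(got, species = sp)
  }))

  comp <- stage("composition", cds_tbl %>%
    select("species", "gene", "cds") %>%
    mutate(comp = purrr::map(.data$cds, ~ composition(.x, code = code))) %>%
    select(-"cds") %>%
    tidyr::unnest("comp") %>%
    select(-"label"))

  sp_comp <- stage("species_composition", cds_tbl %>%
    group_by(.data$species) %>%
    summarise(cds = paste(.data$cds, collapse = ""), .groups = "drop") %>%
    mutate(comp = purrr::map(.data$cds, ~ composition(.x, code = code))) %>%
    tidyr::unnest("comp") %>%
    select(-"label", -"cds"))

  counts_by_species <- stage("codon_counts", cds_tbl %>%
    group_by(.data$species) %>%
    summarise(cds = paste(.data$cds, collapse = ""), .groups = "drop") %>%
    (function(d) {
      setNames(
        purrr::map(d$cds, ~ count_codons(.x, code = code, drop_stops = TRUE)),
        d$species
      )
    }))

  rscu_tables <- stage("rscu", purrr::map(
    counts_by_species,
    ~ rscu(.x, code = code, over = rscu_over, under = rscu_under)
  ))
  rscu_long <- purrr::imap_dfr(rscu_tables, ~ mutate(.x, species = .y))
  rmat <- stage("rscu_matrix", rscu_matrix(rscu_tables, code = code))
  tree <- NULL
  newick <- NA_character_
  heat <- NULL
  if (nrow(rmat) >= 2) {
    tree <- stage("upgma", upgma(rscu_dist_matrix(rmat)))
    newick <- export_newick(tree)
    heat <- heatmap_table(rmat, tree)
  }

  enc_tbl <- stage("enc", cds_tbl %>%
    mutate(
      enc_obs = purrr::map_dbl(
        .data$cds,
        ~ as.numeric(enc_observed(count_codons(.x, code = code, drop_stops = TRUE), code = code))
      )
    ) %>%
    left_join(select(comp, "species", "gene", "gc3s"), by = c("species", "gene")) %>%
    mutate(enc_exp = enc_expected(.data$gc3s / 100)) %>%
    select("species", "gene", "gc3s", "enc_obs", "enc_exp") %>%
    dplyr::bind_cols(
      enc_ratio(.$enc_obs, .$enc_exp, band = enc_band, strong_cutoff = enc_strong) %>%
        select("enc_ratio", "driver_call", "bias_strength")
    ))

  n_sel <- sum(enc_tbl$driver_call == "selection", na.rm = TRUE)
  n_tot <- sum(!is.na(enc_tbl$driver_call))
  enc_binom <- stage(
    "enc_binomial",
    binomial_test(n_sel, n_tot, p0 = 0.5, alternative = "greater")
  )

  pr2_tbl <- stage("pr2", comp %>%
    mutate(label = paste(.data$species, .data$gene, sep = ":")) %>%
    (function(d) dplyr::bind_cols(select(d, "species", "gene"), pr2(d))))

  fit_gene <- stage(
    "neutrality_gene",
    neutrality_fit(comp,
      gc3 = gc3, gc12 = gc12, alpha = alpha,
      slope_upper = slope_upper
    )
  )
  fit_species <- if (nrow(sp_comp) >= 3) {
    stage(
      "neutrality_species",
      neutrality_fit(sp_comp,
        gc3 = gc3, gc12 = gc12, alpha = alpha,
        slope_upper = slope_upper
      )
    )
  } else {
    NULL
  }

  out <- list(
    composition = comp, species_composition = sp_comp,
    rscu = rscu_long, rscu_matrix = rmat, tree = tree, newick = newick,
    heatmap = heat, enc = enc_tbl, enc_binomial = enc_binom, pr2 = pr2_tbl,
    neutrality_gene = fit_gene, neutrality_species = fit_species
  )

  if (!is.null(cds_sets)) {
    pw <- stage("kaks", purrr::map_dfr(
      split(cds_sets, cds_sets$gene),
      function(d) kaks_pairwise(setNames(d$cds, d$species), gene = d$gene[1], code = code)
    ))
    out$kaks_pairwise <- pw
    out$kaks_gene <- kaks_average(pw)
    cox <- intersect(paste0("cox", 1:3), out$kaks_gene$gene)
    nad <- intersect(c(paste0("nad", 1:6), "nad4L"), out$kaks_gene$gene)
    if (length(cox) && length(nad)) {
      out$kaks_contrast <- kaks_group_contrast(out$kaks_gene, cox, nad)
    }
  }

  if (!is.null(out_dir)) {
    write_bundle(out, out_dir,
      code = code, rscu_over = rscu_over,
      rscu_under = rscu_under, enc_band = enc_band, alpha = alpha
    )
  }
  invisible(out)
}

write_commented_tsv <- function(x, path, comment) {
  writeLines(paste0("# ", comment), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
}

write_bundle <- function(out, out_dir, code, rscu_over, rscu_under, enc_band, alpha) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_commented_tsv(
    out$composition, p("composition_per_gene.tsv"),
    paste0(
      "positional composition per gene; genetic code ", code$table_id,
      "; skews (A-T)/(A+T), (G-C)/(G+C); percentages 0-100"
    )
  )
  write_commented_tsv(
    out$species_composition, p("composition_per_species.tsv"),
    "positional composition of concatenated PCGs per species"
  )
  write_commented_tsv(
    out$rscu, p("rscu.tsv"),
    paste0(
      "RSCU = count * family_size / family_total; over > ", rscu_over,
      ", under < ", rscu_under
    )
  )
  if (!is.null(out$heatmap)) {
    write_commented_tsv(
      out$heatmap, p("rscu_heatmap.tsv"),
      "species x codon RSCU, rows in UPGMA leaf order (squared Euclidean distance)"
    )
    writeLines(out$newick, p("rscu_upgma.nwk"))
  }
  write_commented_tsv(
    out$enc, p("enc.tsv"),
    paste0(
      "ENC_exp = 2 + s + 29/(s^2 + (1-s)^2); ratio = (exp-obs)/exp; mutation band +/-",
      enc_band
    )
  )
  write_commented_tsv(
    out$enc_binomial, p("enc_binomial.tsv"),
    "binomial test: selection-called genes vs 50% chance, greater tail"
  )
  write_commented_tsv(
    out$pr2, p("pr2.tsv"),
    "PR2: x = G3/(G3+C3), y = A3/(A3+T3); quadrants 1-4, centre = parity"
  )
  write_commented_tsv(
    glance(out$neutrality_gene), p("neutrality_gene_fit.tsv"),
    paste0("neutrality regression GC12 ~ GC3, per-gene points; alpha = ", alpha)
  )
  write_commented_tsv(
    out$neutrality_gene$points, p("neutrality_gene_points.tsv"),
    "neutrality points (one per gene per species)"
  )
  if (!is.null(out$neutrality_species)) {
    write_commented_tsv(
      glance(out$neutrality_species), p("neutrality_species_fit.tsv"),
      "neutrality regression on per-species concatenated PCGs"
    )
  }
  if (!is.null(out$kaks_pairwise)) {
    write_commented_tsv(
      out$kaks_pairwise, p("kaks_pairwise.tsv"),
      "Nei-Gojobori (1986) Ka/Ks, Jukes-Cantor corrected, stop pathways excluded"
    )
    write_commented_tsv(
      out$kaks_gene, p("kaks_gene.tsv"),
      "per-gene means; ratio = mean of pairwise ratios"
    )
    if (!is.null(out$kaks_contrast)) {
      write_commented_tsv(
        out$kaks_contrast, p("kaks_cox_vs_nad.tsv"),
        "Mann-Whitney U on per-gene mean Ka/Ks: cox1-3 vs nad1-6+nad4L"
      )
    }
  }
  writeLines(
    c(
      paste0("mitocub ", as.character(utils::packageVersion("mitocub"))),
      paste0("genetic code: ", code$table_id),
      paste0(
        "flags: rscu_over=", rscu_over, " rscu_under=", rscu_under,
        " enc_band=", enc_band, " alpha=", alpha
      )
    ),
    p("run_log.txt")
  )
  invisible(out_dir)
}
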