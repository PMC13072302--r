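# Independent oracles used to cross-check the package implementations.
# These are written naively (explicit enumeration, seqinr for translation)
# and stay independent of the code paths they verify.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(x)), "")[[1]]), collapse = "")
}

oracle_translate <- function(codon, numcode) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]], numcode = numcode)
}

# brute-force Wright ENC: explicit family enumeration, plain class means,
# no imputation or capping (use only on counts where every class is
# estimable and homozygosity is positive)
oracle_enc <- function(counts, numcode) {
  aa <- vapply(counts$codon, oracle_translate, character(1), numcode = numcode)
  keep <- aa != "*"
  fam <- split(counts$count[keep], aa[keep])
  f_by_class <- list()
  n_by_class <- list()
  for (a in names(fam)) {
    k <- as.character(length(fam[[a]]))
    n_by_class[[k]] <- c(n_by_class[[k]], 1)
    n <- sum(fam[[a]])
    if (n >= 2) {
      p <- fam[[a]] / n
      f_by_class[[k]] <- c(f_by_class[[k]], (n * sum(p^2) - 1) / (n - 1))
    }
  }
  enc <- 0
  for (k in names(n_by_class)) {
    nk <- sum(n_by_class[[k]])
    if (k == "1") {
      enc <- enc + nk
    } else {
      f <- mean(f_by_class[[k]])
      enc <- enc + nk / f
    }
  }
  enc
}

# random codon counts in which every synonymous family is well sampled
random_counts <- function(code, min_count = 2, max_count = 60) {
  sense <- setdiff(names(code$codon_to_aa), code$stop_codons)
  sense <- sort(sense)
  tibble::tibble(
    codon = sense,
    aa = unname(code$codon_to_aa[sense]),
    count = sample(min_count:max_count, length(sense), replace = TRUE)
  )
}

# brute-force NG86 site fractions via mutant enumeration
oracle_ng86_sites <- function(codon, numcode) {
  bases <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon, numcode)
  s <- 0
  n <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      aa1 <- oracle_translate(mut, numcode)
      if (aa1 == "*") next
      if (aa1 == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

# brute-force pathway averaging between two sense codons
oracle_ng86_diffs <- function(c1, c2, numcode) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) {
    return(c(sd = 0, nd = 0))
  }
  perms <- if (length(pos) == 1) {
    matrix(pos)
  } else {
    do.call(rbind, combinat_perms(pos))
  }
  counts <- list()
  for (r in seq_len(nrow(perms))) {
    cur <- c1
    sd <- 0
    nd <- 0
    okay <- TRUE
    for (p in perms[r, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt, numcode) == "*") {
        okay <- FALSE
        break
      }
      if (oracle_translate(nxt, numcode) == oracle_translate(cur, numcode)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (okay) counts[[length(counts) + 1]] <- c(sd, nd)
  }
  m <- do.call(rbind, counts)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

combinat_perms <- function(v) {
  if (length(v) == 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# a minimal GenBank flat file assembled in code (text fixture, no file on disk)
make_gb_text <- function(sequence = NULL, features = NULL) {
  len <- if (!is.null(sequence)) nchar(sequence) else 16607L
  lines <- c(
    sprintf(
      "LOCUS       TEST%20d bp    DNA     circular VRT 01-JAN-2024",
      len
    ),
    "ACCESSION   TEST0001",
    "FEATURES             Location/Qualifiers"
  )
  lines <- c(lines, features)
  if (!is.null(sequence)) {
    lines <- c(lines, "ORIGIN")
    starts <- seq(1, nchar(sequence), by = 60)
    for (s in starts) {
      chunk <- substr(sequence, s, min(s + 59, nchar(sequence)))
      groups <- gsub("(.{10})", "\\1 ", chunk)
      lines <- c(lines, sprintf("%9d %s", s, tolower(groups)))
    }
    lines <- c(lines, "//")
  }
  lines
}
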