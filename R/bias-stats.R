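#' Wright's effective number of codons (observed)
#'
#' Wright's estimator of how far synonymous codon usage departs from
#' uniformity. For each synonymous family with at least two counted codons,
#' the homozygosity is estimated as `F = (n * sum(p^2) - 1) / (n - 1)`;
#' family estimates are averaged within each degeneracy class k and the ENC
#' is `N1 + N2/F2 + N3/F3 + N4/F4 + N6/F6`, with class sizes `Nk` fixed by
#' the genetic code. A class with no estimable family borrows its estimate
#' from the estimable classes (the 3-fold class as `(F2 + F4)/2`, otherwise
#' by interpolating the per-family effective-codon fraction). The result is
#' bounded below by 20 (one effective codon per amino acid) and clamped
#' above at the code maximum (61 standard, 60 vertebrate mitochondrial);
#' the unclamped value is kept in the `pre_clamp` attribute.
#'
#' @param counts A codon count tibble over sense codons ([count_codons()]
#'   with `drop_stops = TRUE`).
#' @param code A [genetic_code()].
#' @return ENC as a single number (`NA` if no family is estimable), with
#'   attribute `pre_clamp`.
#' @examples
#' uniform <- count_codons(paste(genetic_code(1)$sense_codons, collapse = ""),
#'   code = genetic_code(1)
#' )
#' enc_observed(uniform, genetic_code(1)) # 61
#' @export
enc_observed <- function(counts, code = genetic_code(2)) {
  if (sum(counts$count) == 0L) abort("empty codon counts")
  fam_stats <- counts %>%
    filter(!.data$codon %in% code$stop_codons) %>%
    group_by(.data$aa) %>%
    summarise(
      k = n(),
      n = sum(.data$count),
      f_hat = if (sum(.data$count) >= 2) {
        nn <- sum(.data$count)
        (nn * sum((.data$count / nn)^2) - 1) / (nn - 1)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  classes <- fam_stats %>%
    group_by(.data$k) %>%
    summarise(
      n_fam = n(),
      f_bar = mean(.data$f_hat, na.rm = TRUE),
      estimable = sum(!is.na(.data$f_hat)),
      .groups = "drop"
    ) %>%
    mutate(f_bar = ifelse(.data$estimable > 0, .data$f_bar, NA_real_))
  est <- filter(classes, !is.na(.data$f_bar), .data$k > 1L)
  if (nrow(est) == 0L && !any(classes$k == 1L)) {
    return(structure(NA_real_, pre_clamp = NA_real_))
  }
  f_of <- function(k) {
    hit <- est$f_bar[est$k == k]
    if (length(hit)) {
      return(hit)
    }
    # missing class: 3-fold borrows the 2- and 4-fold mean (Wright's rule);
    # otherwise interpolate the scaled effective-codon fraction
    if (k == 3L) {
      f2 <- est$f_bar[est$k == 2L]
      f4 <- est$f_bar[est$k == 4L]
      if (length(f2) && length(f4)) {
        return((f2 + f4) / 2)
      }
    }
    if (nrow(est) == 0L) {
      return(NA_real_)
    }
    rel <- (pmin(1 / est$f_bar, est$k) - 1) / (est$k - 1)
    1 / (1 + mean(rel) * (k - 1))
  }
  contrib <- purrr::map_dbl(seq_len(nrow(classes)), function(i) {
    k <- classes$k[i]
    nk <- classes$n_fam[i]
    if (k == 1L) {
      return(nk)
    }
    f <- f_of(k)
    if (is.na(f)) {
      return(NA_real_)
    }
    if (f <= 0) {
      return(Inf)
    } # a zero homozygosity estimate: no detectable bias
    nk / f
  })
  if (anyNA(contrib)) {
    return(structure(NA_real_, pre_clamp = NA_real_))
  }
  total <- sum(contrib)
  # Wright's formula is bounded below by the family count (20); sampling
  # noise can push it above the code maximum, where it is clamped
  structure(min(total, code$max_enc), pre_clamp = total)
}

#' Expected ENC at a given GC3s
#'
#' Wright's null curve: the ENC expected when codon usage bias is driven by
#' third-position composition alone,
#' `ENC_exp = 2 + s + 29 / (s^2 + (1 - s)^2)` for GC3s fraction `s`. An
#' `as_printed` variant with a constant denominator
#' (`ENC_exp = 31 + s`) is kept for auditability but is not the null curve
#' plotted in ENC-GC3s analyses.
#'
#' @param gc3s GC3s as a fraction in `[0, 1]` (vectorised).
#' @param formula `"wright"` (default) or `"as_printed"`.
#' @return Expected ENC value(s).
#' @examples
#' enc_expected(0.5) # 60.5
#' @export
enc_expected <- function(gc3s, formula = c("wright", "as_printed")) {
  formula <- match.arg(formula)
  if (any(gc3s < 0 | gc3s > 1, na.rm = TRUE)) {
    abort("`gc3s` must be a fraction in [0, 1]")
  }
  if (formula == "wright") {
    2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
  } else {
    2 + gc3s + 29 / (gc3s^2 + (1 - gc3s^2))
  }
}

#' ENC ratio and mutation-vs-selection call
#'
#' The ENC ratio `(ENC_exp - ENC_obs) / ENC_exp` measures relative deviation
#' from the null curve. Genes with `-band <= ratio <= band` (band edges
#' inclusive, default 0.05) sit on the curve: composition (mutation) alone
#' explains their bias; genes outside the band are called selection-driven.
#' `bias_strength` applies the conventional ENC < 35 cutoff for a strong
#' codon preference.
#'
#' @param enc_obs,enc_exp Observed and expected ENC (vectorised).
#' @param band Half-width of the mutation band. Default 0.05.
#' @param strong_cutoff ENC below which bias is called strong. Default 35.
#' @return A tibble `(enc_obs, enc_exp, enc_ratio, driver_call,
#'   bias_strength)`.
#' @examples
#' enc_ratio(45, 50)
#' @export
enc_ratio <- function(enc_obs, enc_exp, band = 0.05, strong_cutoff = 35) {
  if (any(enc_exp <= 0, na.rm = TRUE)) abort("`enc_exp` must be positive")
  ratio <- (enc_exp - enc_obs) / enc_exp
  tibble(
    enc_obs = enc_obs,
    enc_exp = enc_exp,
    enc_ratio = ratio,
    driver_call = case_when(
      is.na(ratio) ~ NA_character_,
      ratio >= -band & ratio <= band ~ "mutation",
      TRUE ~ "selection"
    ),
    bias_strength = case_when(
      is.na(enc_obs) ~ NA_character_,
      enc_obs < strong_cutoff ~ "strong",
      TRUE ~ "weak"
    )
  )
}

#' Parity rule 2 coordinates
#'
#' PR2 plots third-position AT bias `y = A3/(A3 + T3)` against GC bias
#' `x = G3/(G3 + C3)`. Under intra-strand parity (A = T, G = C) points fall
#' on the centre (0.5, 0.5). Quadrants are numbered 1-4 counter-clockwise
#' from the upper right (Q1 x > 0.5, y > 0.5; Q2 x < 0.5, y > 0.5; Q3 both
#' < 0.5; Q4 x > 0.5, y < 0.5); points on an axis belong to no quadrant.
#'
#' @param a3,t3,g3,c3 Third-position base counts (vectorised).
#' @param label Optional labels.
#' @return A tibble `(label, x, y, quadrant)`; a zero denominator yields an
#'   `NA` coordinate with a warning.
#' @examples
#' pr2_point(10, 20, 30, 15) # T > A, G > C: quadrant 4
#' @export
pr2_point <- function(a3, t3, g3, c3, label = NULL) {
  if (is.null(label)) label <- paste0("point", seq_along(a3))
  y <- ifelse(a3 + t3 > 0, a3 / (a3 + t3), NA_real_)
  x <- ifelse(g3 + c3 > 0, g3 / (g3 + c3), NA_real_)
  if (anyNA(x) || anyNA(y)) {
    warn("zero third-position denominator: PR2 coordinate reported as NA")
  }
  tibble(
    label = label, x = x, y = y,
    quadrant = case_when(
      is.na(x) | is.na(y) ~ NA_integer_,
      x > 0.5 & y > 0.5 ~ 1L,
      x < 0.5 & y > 0.5 ~ 2L,
      x < 0.5 & y < 0.5 ~ 3L,
      x > 0.5 & y < 0.5 ~ 4L,
      TRUE ~ NA_integer_ # on an axis or at the centre
    )
  )
}

#' PR2 coordinates from a composition table
#'
#' @param comp A tibble from [composition()] (columns `a3`, `t3`, `g3`,
#'   `c3`, `label`).
#' @return See [pr2_point()].
#' @export
pr2 <- function(comp) {
  pr2_point(comp$a3, comp$t3, comp$g3, comp$c3, label = comp$label)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Fits the neutrality regression `GC12 = a + b * GC3` (ordinary least
#' squares, percentages on the 0-100 scale) with a Pearson correlation test,
#' and classifies the dominant force on codon usage:
#' a non-significant correlation (`p >= alpha`) means positions 1-2 and 3
#' vary independently (`"uncorrelated"`); a significant correlation whose
#' slope is compatible with 1 (the 95% CI covers 1) means composition
#' changes equally at all three positions and mutation pressure dominates
#' (`"mutation_dominant"`); a significant correlation with a slope well
#' below 1 (upper CI bound below `slope_upper`) means positions 1-2 are
#' held back by selective constraint (`"selection_dominant"`). A
#' significant slope between those bands is reported `"intermediate"`.
#'
#' @param data A data frame of points.
#' @param gc3,gc12 Columns holding GC3 and GC12 percentages (tidy-eval;
#'   defaults `gc3`, `gc12`).
#' @param alpha Significance level for the Pearson test. Default 0.05.
#' @param slope_upper Upper CI bound below which the slope counts as
#'   "much less than 1". Default 0.5.
#' @return An object of class `neutrality_fit`; see [tidy()]/[glance()]
#'   methods and [autoplot.neutrality_fit()].
#' @examples
#' pts <- data.frame(gc3 = c(30, 40, 50, 35, 45), gc12 = c(40, 41, 42, 40.5, 41.4))
#' neutrality_fit(pts)
#' @export
neutrality_fit <- function(data, gc3 = gc3, gc12 = gc12, alpha = 0.05,
                           slope_upper = 0.5) {
  x <- dplyr::pull(data, {{ gc3 }})
  y <- dplyr::pull(data, {{ gc12 }})
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) abort("neutrality fit needs at least 3 points")
  if (stats::var(x) == 0) abort("no variance in GC3: regression is degenerate")
  fit <- lm(y ~ x)
  # an exactly collinear input ("perfect fit") is legitimate here; silence
  # the numerical-reliability warnings those degenerate cases trigger
  ci <- suppressWarnings(confint(fit, "x", level = 0.95))
  b <- unname(coef(fit)[2])
  if (stats::var(y) == 0) {
    # constant GC12: positions 1-2 do not respond to GC3 at all; reported
    # as zero correlation rather than an indeterminate 0/0
    r <- 0
    p_r <- 1
    r2 <- 0
  } else {
    ct <- suppressWarnings(cor.test(x, y, method = "pearson", alternative = "two.sided"))
    r <- unname(ct$estimate)
    p_r <- ct$p.value
    r2 <- r^2
  }
  eps <- 1e-08 # numerical slack for exactly-collinear inputs
  verdict <- if (p_r >= alpha) {
    "uncorrelated"
  } else if (ci[1] - eps <= 1 && 1 <= ci[2] + eps) {
    "mutation_dominant"
  } else if (ci[2] < slope_upper) {
    "selection_dominant"
  } else {
    "intermediate"
  }
  structure(
    list(
      points = tibble(gc3 = x, gc12 = y),
      fit = fit,
      n = length(x),
      r = r,
      p_r = p_r,
      a = unname(coef(fit)[1]),
      b = b,
      b_ci = c(ci[1], ci[2]),
      r2 = r2,
      alpha = alpha,
      slope_upper = slope_upper,
      verdict = verdict
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("<neutrality_fit> n =", x$n, "\n")
  cat(sprintf(
    "  GC12 = %.4g + %.4g * GC3   (R2 = %.4g)\n", x$a, x$b, x$r2
  ))
  cat(sprintf(
    "  Pearson r = %.4g, p = %.3g; slope 95%% CI [%.4g, %.4g]\n",
    x$r, x$p_r, x$b_ci[1], x$b_ci[2]
  ))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Exact binomial test
#'
#' Exact tail probability that `k` successes in `n` trials depart from
#' success probability `p0`, computed by direct summation of the binomial
#' mass function. The one-sided "greater" tail (used to ask whether the
#' proportion of selection-called genes exceeds the 50% chance level)
#' includes the observed count. The two-sided p sums all outcomes no more
#' probable than the observed one.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability. Default 0.5.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return A one-row tibble `(test_name, statistic, p_value, n,
#'   alternative)`.
#' @examples
#' binomial_test(1, 2) # greater tail: 0.75
#' @export
binomial_test <- function(k, n, p0 = 0.5, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(k >= 0, k <= n, n >= 1, p0 > 0, p0 < 1)
  pmf <- dbinom(0:n, n, p0)
  p <- switch(alternative,
    greater = sum(pmf[(k + 1):(n + 1)]),
    less = sum(pmf[1:(k + 1)]),
    two.sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-07)])
  )
  tibble(
    test_name = "exact binomial", statistic = as.numeric(k),
    p_value = min(p, 1), n = as.integer(n), alternative = alternative
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic counts,
#' over all pairs, how often a value from the first group exceeds one from
#' the second (ties count 1/2). The p-value is exact - computed by full
#' enumeration of group assignments of the pooled values, which handles
#' ties correctly - whenever `choose(na + nb, na)` does not exceed
#' `exact_limit`; otherwise a tie-corrected normal approximation with
#' continuity correction is used.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (first group tends larger / smaller).
#' @param exact_limit Maximum number of arrangements to enumerate.
#'   Default 20000.
#' @return A one-row tibble `(test_name, statistic, p_value, n,
#'   alternative, method)`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b, alternative = c("two.sided", "greater", "less"),
                           exact_limit = 20000) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) abort("both groups must be non-empty")
  u_stat <- function(xa, xb) {
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u <- u_stat(a, b)
  mu <- na * nb / 2
  pooled <- c(a, b)
  n_tot <- na + nb
  if (choose(n_tot, na) <= exact_limit) {
    combs <- combn(n_tot, na)
    us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
    p <- switch(alternative,
      greater = mean(us >= u - 1e-09),
      less = mean(us <= u + 1e-09),
      two.sided = mean(abs(us - mu) >= abs(u - mu) - 1e-09)
    )
    method <- "exact enumeration"
  } else {
    ranks <- rank(pooled)
    ties <- table(ranks)
    sigma2 <- na * nb / 12 * ((n_tot + 1) - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- 0.5
      z <- switch(alternative,
        greater = (u - mu - cc) / sqrt(sigma2),
        less = (u - mu + cc) / sqrt(sigma2),
        two.sided = (abs(u - mu) - cc) / sqrt(sigma2)
      )
      p <- switch(alternative,
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z),
        two.sided = 2 * pnorm(max(z, 0), lower.tail = FALSE)
      )
    }
    p <- min(max(p, 0), 1)
    method <- "normal approximation (tie-corrected)"
  }
  tibble(
    test_name = "Mann-Whitney U", statistic = u, p_value = p,
    n = as.integer(n_tot), alternative = alternative, method = method
  )
}
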