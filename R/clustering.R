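#' Assemble a species-by-codon RSCU matrix
#'
#' Rows are species (or any grouping label), columns the sense codons of the
#' active code in canonical order (grouped by amino acid, alphabetical
#' within). RSCU values that are undefined because a synonymous family has
#' zero usage are, under the default `missing = "zero"` policy, imputed as 0
#' with a warning; `missing = "drop_codon"` removes such columns instead.
#'
#' @param rscu_tables Named list of RSCU tibbles (from [rscu()]), one per
#'   species.
#' @param code A [genetic_code()].
#' @param missing `"zero"` (default) or `"drop_codon"`.
#' @return A numeric matrix (species x codons).
#' @export
rscu_matrix <- function(rscu_tables, code = genetic_code(2),
                        missing = c("zero", "drop_codon")) {
  missing <- match.arg(missing)
  stopifnot(length(rscu_tables) >= 1L)
  if (is.null(names(rscu_tables))) {
    names(rscu_tables) <- paste0("species", seq_along(rscu_tables))
  }
  cols <- setdiff(codon_order(code), code$stop_codons)
  mat <- do.call(rbind, purrr::map(rscu_tables, function(tb) {
    v <- setNames(tb$rscu, tb$codon)[cols]
    unname(v)
  }))
  dimnames(mat) <- list(names(rscu_tables), cols)
  if (anyNA(mat)) {
    if (missing == "zero") {
      warn(paste0(
        sum(is.na(mat)), " undefined RSCU value(s) (zero-usage families) imputed as 0"
      ))
      mat[is.na(mat)] <- 0
    } else {
      drop <- colnames(mat)[colSums(is.na(mat)) > 0]
      warn(paste0("dropping codon column(s) with undefined RSCU: ", paste(drop, collapse = ", ")))
      mat <- mat[, setdiff(colnames(mat), drop), drop = FALSE]
    }
  }
  mat
}

#' Squared Euclidean distance between RSCU vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `sum((a - b)^2)`.
#' @export
rscu_distance <- function(a, b) {
  if (length(a) != length(b)) abort("RSCU vectors differ in length")
  sum((a - b)^2)
}

#' Pairwise squared-Euclidean distance matrix
#'
#' @param mat A species-by-codon matrix (see [rscu_matrix()]).
#' @return A symmetric matrix of squared Euclidean distances.
#' @export
rscu_dist_matrix <- function(mat) {
  as.matrix(stats::dist(mat, method = "euclidean"))^2
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with unweighted average linkage: the two closest
#' clusters merge at their current distance, and distances to the merged
#' cluster are size-weighted averages. Ties in the minimal distance are
#' broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labelled by its smallest leaf), so
#' re-running on a permuted input yields the same tree.
#'
#' @param d A symmetric distance matrix (zero diagonal, non-negative) with
#'   row/column names, or a `dist` object.
#' @return An object of class `c("upgma", "hclust")` (standard `merge`,
#'   `height`, `order`, `labels` components), usable with
#'   [stats::cophenetic()], [ape::as.phylo()], etc.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' upgma(d)$height # 2, 8
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("`d` must be a square distance matrix")
  n <- nrow(d)
  if (n < 2L) abort("need at least 2 leaves to cluster")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  if (any(d < 0) || any(abs(diag(d)) > 1e-12) || any(abs(d - t(d)) > 1e-09)) {
    abort("`d` must be symmetric and non-negative with a zero diagonal")
  }
  labels <- rownames(d)
  # active clusters: id -> leaf indices; label = smallest leaf name
  active <- setNames(as.list(seq_len(n)), labels)
  ids <- setNames(-seq_len(n), labels) # hclust convention: leaves negative
  sizes <- setNames(rep(1L, n), labels)
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    labs <- rownames(dm)
    m <- length(labs)
    # find min off-diagonal, tie-break by sorted label pair
    best <- NULL
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- sort(c(labs[i], labs[j]))
        if (dm[i, j] < best_d - 1e-12 ||
          (abs(dm[i, j] - best_d) <= 1e-12 && !is.null(best) &&
            (key[1] < best[1] || (key[1] == best[1] && key[2] < best[2])))) {
          best_d <- dm[i, j]
          best <- key
        }
      }
    }
    a <- best[1]
    b <- best[2]
    merge[step, ] <- sort(c(ids[[a]], ids[[b]]))
    height[step] <- best_d
    new_label <- min(a, b)
    others <- setdiff(labs, c(a, b))
    new_d <- (sizes[[a]] * dm[a, others] + sizes[[b]] * dm[b, others]) /
      (sizes[[a]] + sizes[[b]])
    keep <- dm[others, others, drop = FALSE]
    dm <- rbind(cbind(keep, setNames(new_d, NULL)), c(new_d, 0))
    rownames(dm) <- colnames(dm) <- c(others, new_label)
    active[[new_label]] <- c(active[[a]], active[[b]])
    sizes[[new_label]] <- sizes[[a]] + sizes[[b]]
    ids[[new_label]] <- step
    gone <- setdiff(c(a, b), new_label)
    active[[gone]] <- NULL
  }
  order <- leaf_order_from_merge(merge, n)
  structure(
    list(
      merge = merge, height = height, order = order, labels = labels,
      method = "average", call = match.call(), dist.method = "squared euclidean"
    ),
    class = c("upgma", "hclust")
  )
}

leaf_order_from_merge <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) {
      return(-node)
    }
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Export a dendrogram as a Newick string
#'
#' Converts the tree to `ape`'s `phylo` representation (leaf-to-parent
#' branch lengths are half the merge heights, preserving the ultrametric)
#' and writes Newick.
#'
#' @param tree An `upgma`/`hclust` object.
#' @param path Optional file path; when given the string is also written
#'   there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Heatmap table ordered by dendrogram leaves
#'
#' @param mat A species-by-codon RSCU matrix.
#' @param tree An `upgma` tree over the same row labels.
#' @return A tibble with a `species` column followed by the codon columns,
#'   rows in dendrogram leaf order.
#' @export
heatmap_table <- function(mat, tree) {
  ord <- tree$labels[tree$order]
  if (!setequal(ord, rownames(mat))) {
    abort("tree leaves do not match matrix rows")
  }
  as_tibble(mat[ord, , drop = FALSE], rownames = "species")
}
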