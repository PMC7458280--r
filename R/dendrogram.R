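#' Attribute dendrogram from Rajski distances (Ward / Lance-Williams)
#'
#' Agglomerative clustering of the genetic attributes (plus, optionally, any
#' recoded versions) on their pairwise Rajski-distance matrix, using the
#' Lance-Williams recurrence with Ward coefficients
#' `alpha_i = (n_i + n_k) / (n_i + n_j + n_k)`,
#' `beta = -n_k / (n_i + n_j + n_k)`, `gamma = 0`. Leaf-pair edges are
#' annotated with the sign and magnitude of the interaction information
#' `I(A;B;C)` so synergy/redundancy can be read off the tree.
#'
#' @param gm A [genotype_table()] with at least two SNPs.
#' @param recode_models Optional named model vector as in [ig_report()].
#' @return An `epi_dendrogram` list: `merge` and `height` in
#'   [stats::hclust()] convention, `labels`, `distance` (the Rajski matrix),
#'   `interactions` (the [interaction_report()] tibble), `newick`.
#' @export
build_dendrogram <- function(gm, recode_models = NULL) {
  snps <- snp_names(gm)
  if (length(snps) < 2) abort("need at least 2 attributes for a dendrogram")
  attrs <- purrr::map(snps, function(s) {
    g <- gm[[s]]
    if (!is.null(recode_models) && s %in% names(recode_models)) {
      g <- recode_genotypes(g, recode_models[[s]])
    }
    g
  })
  names(attrs) <- snps
  n <- length(attrs)
  d <- matrix(0, n, n, dimnames = list(snps, snps))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- rajski_distance(attrs[[i]], attrs[[j]])
    }
  }
  hc <- lance_williams_ward(d)
  hc$labels <- snps
  tree <- hclust_from_parts(hc)
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = snps, distance = d,
         interactions = interaction_report(gm, recode_models),
         newick = ape::write.tree(ape::as.phylo(tree))),
    class = "epi_dendrogram"
  )
}

# Agglomerative clustering by the Lance-Williams recurrence with Ward
# coefficients, on a precomputed dissimilarity matrix.
lance_williams_ward <- function(d) {
  n <- nrow(d)
  size <- rep(1, n)
  id <- -seq_len(n) # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  work <- d
  diag(work) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- work[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(best)]; j <- idx[max(best)]
    height[step] <- work[i, j]
    pair <- sort(c(id[i], id[j]))
    merge[step, ] <- pair
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      tot <- ni + nj + nk
      new_d <- (ni + nk) / tot * work[i, k] +
        (nj + nk) / tot * work[j, k] -
        nk / tot * work[i, j]
      work[i, k] <- work[k, i] <- new_d
    }
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    work[j, ] <- work[, j] <- Inf
  }
  list(merge = merge, height = height, order = leaf_order(merge, n))
}

leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

hclust_from_parts <- function(parts) {
  structure(
    list(merge = parts$merge, height = parts$height, order = parts$order,
         labels = parts$labels, method = "ward.lw",
         call = match.call(), dist.method = "rajski"),
    class = "hclust"
  )
}

#' @export
print.epi_dendrogram <- function(x, ...) {
  cat("Attribute dendrogram (Rajski distance, Ward/Lance-Williams)\n")
  cat("  leaves:", length(x$labels), "\n")
  cat("  merge heights:", paste(signif(x$height, 4), collapse = ", "), "\n")
  cat("  newick:", x$newick, "\n")
  invisible(x)
}

#' Dendrogram merge table
#'
#' @param x An `epi_dendrogram`.
#' @param ... Unused.
#' @return A tibble with one row per merge: `step`, `left`, `right`
#'   (leaf names or `node<k>`), `height`.
#' @method tidy epi_dendrogram
#' @export
tidy.epi_dendrogram <- function(x, ...) {
  nm <- function(v) {
    vapply(v, function(k) if (k < 0) x$labels[-k] else paste0("node", k),
           character(1))
  }
  tibble(
    step = seq_along(x$height),
    left = nm(x$merge[, 1]),
    right = nm(x$merge[, 2]),
    height = x$height
  )
}
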