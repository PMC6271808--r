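#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: iteratively merges the
#' closest pair of clusters; the distance from a merged cluster to any other
#' is the size-weighted arithmetic mean of its parts' distances, and the
#' merge is placed at height `d/2` so leaf-to-node depth equals half the
#' merge distance (an ultrametric tree). Ties are broken deterministically by
#' the smallest pair of cluster indices in the current ordering, so runs are
#' exactly reproducible.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal and
#'   nonnegative entries.
#' @return object of class `upgma_tree`: list with hclust-style `merge`
#'   (negative entries are leaves, positive entries earlier merges),
#'   `heights` (merge distance / 2, nondecreasing), `labels`, and `supports`
#'   (`NULL` until [bootstrap_supports()] fills them, as percentages per
#'   internal node / merge row).
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' upgma(d)$heights  # 1, 4
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (any(d < 0)) stop("negative distances")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active clusters: id (negative leaf / positive merge row), size
  id <- -seq_len(n)
  size <- rep(1L, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  active <- seq_len(n)
  for (s in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); bmin <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- D[active[i], active[j]]
      if (dij < bmin - 1e-15) { bmin <- dij; best <- c(i, j) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    merge[s, ] <- sort(c(id[i], id[j]))
    heights[s] <- bmin / 2
    # size-weighted mean distances to the merged cluster, stored at slot i
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd; D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    active <- active[-best[2]]
  }
  structure(list(merge = merge, heights = heights, labels = labels,
                 supports = NULL),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("upgma_tree: ", length(x$labels), " leaves, root height ",
      sprintf("%.4g", max(x$heights)), sep = "")
  if (!is.null(x$supports))
    cat("; bootstrap supports ", sprintf("%.0f-%.0f%%", min(x$supports),
                                         max(x$supports)), sep = "")
  cat("\n")
  invisible(x)
}

# leaf label sets below each internal node (merge row)
.tree_clades <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  get <- function(idx) if (idx < 0) tree$labels[-idx] else sets[[idx]]
  for (s in seq_len(nrow(tree$merge)))
    sets[[s]] <- c(get(tree$merge[s, 1]), get(tree$merge[s, 2]))
  lapply(sets, sort)
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Pairwise distance at which two leaves first share a cluster
#' (2 x the merge height); equals the input distance for each merged pair.
#'
#' @param tree an `upgma_tree`
#' @return symmetric matrix over the tree's labels
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- vector("list", nrow(tree$merge))
  get <- function(idx) if (idx < 0) -idx else sets[[idx]]
  for (s in seq_len(nrow(tree$merge))) {
    a <- get(tree$merge[s, 1]); b <- get(tree$merge[s, 2])
    cm[a, b] <- cm[b, a] <- 2 * tree$heights[s]
    sets[[s]] <- c(a, b)
  }
  cm
}

.newick_string <- function(tree, digits = 10) {
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  sup <- tree$supports
  build <- function(idx, parent_h) {
    if (idx < 0)
      return(paste0(tree$labels[-idx], ":", fmt(parent_h)))
    h <- tree$heights[idx]
    lab <- if (!is.null(sup)) fmt(sup[idx]) else ""
    paste0("(", build(tree$merge[idx, 1], h), ",",
           build(tree$merge[idx, 2], h), ")", lab, ":",
           fmt(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$heights[root]
  lab <- if (!is.null(sup)) fmt(sup[root]) else ""
  paste0("(", build(tree$merge[root, 1], h), ",",
         build(tree$merge[root, 2], h), ")", lab, ";")
}

#' Write a UPGMA tree as Newick
#'
#' Branch lengths are differences of merge heights (leaves sit at height 0),
#' and bootstrap supports, when present, become internal-node labels. The
#' output parses with any standard Newick reader.
#'
#' @param tree an `upgma_tree`
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  writeLines(.newick_string(tree), path)
  invisible(NULL)
}

#' @importFrom ape as.phylo
#' @export
as.phylo.upgma_tree <- function(x, ...) {
  ape::read.tree(text = .newick_string(x))
}

#' @export
plot.upgma_tree <- function(x, ...) {
  phy <- as.phylo(x)
  ape::plot.phylo(phy, ...)
  if (!is.null(x$supports)) ape::nodelabels(phy$node.label, frame = "none")
  invisible(x)
}

# GS matrix from a raw 0/1 matrix (no class bookkeeping; bootstrap hot path)
.gs_values <- function(v) {
  a <- tcrossprod(v)
  rs <- rowSums(v)
  denom <- outer(rs, rs, "+")
  gs <- ifelse(denom == 0, 1, 2 * a / denom)
  diag(gs) <- 1
  gs
}

#' Bootstrap support values for the UPGMA dendrogram
#'
#' Builds the Nei-Li / UPGMA dendrogram from a band matrix, then resamples
#' bands (columns) with replacement `n_reps` times -- loci are the sampled
#' characters -- rebuilding the dendrogram each time, and reports for each
#' internal node of the original tree the percentage of replicates in which
#' the same leaf set appears as a cluster.
#'
#' @param m a [band_matrix()]
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed integer seed; identical seeds give identical supports
#' @return the original `upgma_tree` with `supports` filled (percent in
#'   \[0, 100\] per merge row)
#' @export
bootstrap_supports <- function(m, n_reps = 1000, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  v <- unclass(m)
  rownames(v) <- rownames(m)
  ref <- upgma(genetic_distance(.gs_values(v)))
  keys <- vapply(.tree_clades(ref), paste, "", collapse = "\r")
  counts <- stats::setNames(numeric(length(keys)), keys)
  if (!is.null(seed)) set.seed(seed)
  nb <- ncol(v)
  for (r in seq_len(n_reps)) {
    vb <- v[, sample.int(nb, nb, replace = TRUE), drop = FALSE]
    bt <- upgma(genetic_distance(.gs_values(vb)))
    bk <- unique(vapply(.tree_clades(bt), paste, "", collapse = "\r"))
    hit <- bk[bk %in% keys]
    counts[hit] <- counts[hit] + 1
  }
  ref$supports <- unname(100 * counts / n_reps)
  ref$n_reps <- n_reps
  ref
}
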