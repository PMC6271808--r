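#' Principal coordinate analysis
#'
#' Metric multidimensional scaling of a distance matrix: Gower
#' double-centering of `-d^2/2`, eigendecomposition, and coordinates equal
#' to eigenvectors scaled by the square root of their eigenvalues
#' (via [stats::cmdscale()]). Negative eigenvalues -- which arise when the
#' distance is not Euclidean-embeddable, as Nei-Li genetic distances can be
#' -- are reported as-is and excluded from the percent-variance denominator;
#' no Lingoes/Cailliez correction is applied.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal
#' @param n_axes number of coordinate axes to return; truncated with a
#'   warning if it exceeds the number of positive eigenvalues
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (accessions x axes), `eigenvalues` (all, descending) and
#'   `percent_variance` (per returned axis, percent of total positive
#'   eigenvalue mass)
#' @export
pcoa <- function(d, n_axes = 3) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  k <- min(n_axes, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > npos) {
    warning("requested ", n_axes, " axes but only ", npos,
            " positive eigenvalues; truncating")
    k <- npos
  }
  coords <- as.matrix(fit$points)[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  pos_mass <- sum(eig[eig > 0])
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 percent_variance = 100 * eig[seq_len(ncol(coords))] / pos_mass),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result: ", nrow(x$coordinates), " points, ",
      ncol(x$coordinates), " axes (",
      paste(sprintf("%.2f%%", x$percent_variance), collapse = ", "),
      " of positive eigenvalue mass)\n", sep = "")
  neg <- sum(x$eigenvalues < 0)
  if (neg) cat(neg, "negative eigenvalue(s) reported, not corrected\n")
  invisible(x)
}

#' Great-circle distance matrix between accessions
#'
#' Haversine distances (Earth radius 6371 km) between all pairs of
#' accessions with recorded coordinates. Accessions lacking coordinates are
#' excluded and listed in the `excluded` attribute -- they can still be used
#' everywhere else, only distance-based analyses drop them.
#'
#' @param records an `accession_table` (needs `code`, `latitude`,
#'   `longitude`)
#' @return square matrix of distances in kilometres over the included
#'   accessions, with attribute `excluded` naming the dropped codes
#' @export
geographic_distance_matrix <- function(records) {
  has <- !is.na(records$latitude) & !is.na(records$longitude)
  excluded <- records$code[!has]
  rec <- records[has, ]
  if (nrow(rec) < 2)
    stop("need at least 2 accessions with coordinates")
  pts <- cbind(rec$longitude, rec$latitude)
  dm <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(dm) <- list(rec$code, rec$code)
  attr(dm, "excluded") <- as.character(excluded)
  dm
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation `r` over the strict lower triangles of two distance
#' matrices on the same accessions, with a one-sided upper-tail permutation
#' p-value: rows and columns of `d2` are permuted jointly and
#' `p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`. A p-value near 1 means
#' the observed correlation is *smaller* than almost all permutations --
#' i.e. no isolation-by-distance signal.
#'
#' @param d1,d2 symmetric distance matrices with identical labels in
#'   identical order (checked when both are labelled)
#' @param n_perm number of permutations
#' @param seed integer seed for reproducibility
#' @return object of class `mantel_result`: list with `r`, `p`, `n_perm`
#' @export
mantel <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)))
    stop("distance matrices differ in dimension")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must have the same labels in the same order")
  if (n_perm < 1) stop("n_perm must be >= 1")
  lt <- lower.tri(d1)
  x <- d1[lt]
  if (stats::sd(x) == 0 || stats::sd(d2[lt]) == 0)
    stop("zero variance in a distance triangle; Mantel r undefined")
  r_obs <- stats::cor(x, d2[lt])
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d1)
  # precompute centred/scaled x once; r = <x*, y*>/(n-1)
  xs <- (x - mean(x)) / stats::sd(x)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    y <- d2[p, p][lt]
    r_perm[b] <- mean(xs * (y - mean(y))) / stats::sd(y) * length(x) / (length(x) - 1)
  }
  # epsilon guards ties (the identity permutation must count as >=)
  structure(list(r = r_obs, p = (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, upper tail)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}
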