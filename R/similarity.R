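#' Nei-Li (Dice) similarity between two band profiles
#'
#' `GS = 2a / (2a + b + c)` where `a` is the count of shared presences and
#' `b`, `c` the presences unique to each profile. Two all-zero profiles are
#' defined to have `GS = 1` (identical phenotype; the formula is 0/0 and
#' identity is its natural limit).
#'
#' @param x,y equal-length binary vectors
#' @return similarity in \[0, 1\]
#' @examples
#' nei_li_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
nei_li_similarity <- function(x, y) {
  if (length(x) != length(y))
    stop("band vectors differ in length (", length(x), " vs ", length(y), ")")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("band vectors must be binary")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1)
  if (a + b + c_ == 0) return(1)
  2 * a / (2 * a + b + c_)
}

#' Pairwise Nei-Li similarity matrix
#'
#' All-pairs [nei_li_similarity()] over the accessions of a band matrix.
#' The complementary genetic distance is `GD = 1 - GS`
#' (see [genetic_distance()]).
#'
#' @param m a [band_matrix()] with at least 2 accessions
#' @return square symmetric matrix of class `similarity_matrix`, unit
#'   diagonal. Accessions with an all-zero profile trigger a warning (the
#'   all-zero GS convention then applies).
#' @export
similarity_matrix <- function(m) {
  v <- unclass(m)
  n <- nrow(v)
  if (n < 2) stop("need at least 2 accessions")
  zero <- rowSums(v) == 0
  if (any(zero))
    warning("accession(s) with all-zero band profile: ",
            paste(rownames(v)[zero], collapse = ", "))
  # a = shared presences; row sums give a + b and a + c
  a <- tcrossprod(v)
  rs <- rowSums(v)
  denom <- outer(rs, rs, "+")          # 2a + b + c
  gs <- ifelse(denom == 0, 1, 2 * a / denom)
  diag(gs) <- 1
  dimnames(gs) <- list(rownames(v), rownames(v))
  structure(gs, class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x[lower.tri(x)]
  cat("similarity_matrix: ", nrow(x), " accessions; GS range ",
      sprintf("%.3f-%.3f", min(off), max(off)),
      ", mean ", sprintf("%.3f", mean(off)), "\n", sep = "")
  invisible(x)
}

#' Genetic distance from a similarity matrix
#' @param s a `similarity_matrix` (or any similarity matrix in \[0,1\])
#' @return matrix `1 - s` with zero diagonal
#' @export
genetic_distance <- function(s) {
  d <- 1 - unclass(s)
  diag(d) <- 0
  d
}
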