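#' Read per-K log-likelihood runs of a Bayesian clustering program
#'
#' Expects a delimited file with columns `K`, `run`, `lnP` -- one row per
#' independent run, `lnP` being the estimated log probability of the data
#' (LnP(D)) at that K.
#'
#' @param path delimited text file
#' @param sep field delimiter
#' @return data.frame of class `structure_runs`
#' @export
read_structure_runs <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE)
  structure_runs(df$K, df$run, df$lnP)
}

#' Assemble a table of clustering runs
#' @param K integer cluster counts (>= 1)
#' @param run run identifiers
#' @param lnP log-likelihood values
#' @return data.frame of class `structure_runs`
#' @export
structure_runs <- function(K, run, lnP) {
  if (any(is.na(K)) || any(K < 1)) stop("K must be >= 1")
  if (any(is.na(lnP))) stop("missing lnP values")
  df <- data.frame(K = as.integer(K), run = run, lnP = as.numeric(lnP))
  class(df) <- c("structure_runs", "data.frame")
  df
}

#' Evanno delta-K from clustering log-likelihoods
#'
#' The second-order rate-of-change statistic for choosing the number of
#' clusters K: with `L(K)` the mean LnP(D) over runs at each K,
#' `deltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, where the standard
#' deviation is the sample (n-1) deviation over runs at K. The endpoints of
#' the K range have no second difference and are reported as `NA`; a zero
#' run-to-run deviation makes deltaK undefined (`NA`, with a warning).
#'
#' @param runs a `structure_runs` table with at least three consecutive K
#'   values and >= 2 runs per K
#' @return data.frame with one row per K: `K`, `n_runs`, `mean_lnp`,
#'   `sd_lnp`, `delta_k`; attribute `best_k` holds the argmax of delta_k
#' @export
evanno_delta_k <- function(runs) {
  ks <- sort(unique(runs$K))
  if (length(ks) < 3 || !all(diff(ks) == 1))
    stop("need runs for at least three consecutive K values")
  agg <- do.call(rbind, lapply(ks, function(k) {
    l <- runs$lnP[runs$K == k]
    data.frame(K = k, n_runs = length(l), mean_lnp = mean(l),
               sd_lnp = if (length(l) > 1) stats::sd(l) else NA_real_)
  }))
  if (any(agg$n_runs < 2))
    warning("K value(s) with a single run: sd and delta_k undefined there")
  m <- agg$mean_lnp
  nk <- length(ks)
  dk <- rep(NA_real_, nk)
  for (i in 2:(nk - 1)) {
    sdv <- agg$sd_lnp[i]
    if (is.na(sdv)) next
    if (sdv == 0) {
      warning("sd(LnP) = 0 at K = ", ks[i], "; delta_k undefined")
      next
    }
    dk[i] <- abs(m[i + 1] - 2 * m[i] + m[i - 1]) / sdv
  }
  agg$delta_k <- dk
  attr(agg, "best_k") <- if (all(is.na(dk))) NA_integer_ else
    ks[which.max(dk)]
  class(agg) <- c("evanno_table", "data.frame")
  agg
}

#' @export
print.evanno_table <- function(x, digits = 4, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("best K by delta-K:", attr(x, "best_k"), "\n")
  invisible(x)
}

#' Read a Q-matrix of membership proportions
#'
#' First column: accession labels; remaining columns: per-cluster membership
#' proportions, which must sum to 1 within 1e-6 per row.
#'
#' @param path delimited text file with a header row
#' @param sep field delimiter
#' @return numeric matrix (accessions x clusters) of class `q_matrix`
#' @export
read_q_matrix <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE)
  q_matrix(as.matrix(df[, -1, drop = FALSE]), labels = as.character(df[[1]]))
}

#' Assemble and validate a Q-matrix
#' @param q numeric matrix of membership proportions
#' @param labels accession labels (default: rownames)
#' @return matrix of class `q_matrix`
#' @export
q_matrix <- function(q, labels = rownames(q)) {
  q <- as.matrix(q)
  if (is.null(labels)) labels <- paste0("A", seq_len(nrow(q)))
  if (any(q < -1e-9) || any(q > 1 + 1e-9))
    stop("membership proportions must lie in [0, 1]")
  bad <- which(abs(rowSums(q) - 1) > 1e-6)
  if (length(bad))
    stop("Q-matrix row(s) not summing to 1: ",
         paste(labels[bad], collapse = ", "))
  rownames(q) <- labels
  if (is.null(colnames(q))) colnames(q) <- paste0("Q", seq_len(ncol(q)))
  structure(q, class = c("q_matrix", "matrix", "array"))
}

#' Threshold-based cluster assignment from a Q-matrix
#'
#' Assigns each accession to the cluster whose membership proportion exceeds
#' the threshold; accessions with no proportion above it are labelled
#' `"admixed"`. Because the threshold must exceed 0.5, at most one cluster
#' can qualify, and raising the threshold can only move accessions *into*
#' the admixed class, never out of it.
#'
#' @param q a [q_matrix()]
#' @param threshold membership probability threshold in (0.5, 1\]
#' @param groups optional metadata grouping (named by accession or in row
#'   order) for the tally table
#' @return object of class `membership_assignment`: list with `assignments`
#'   (named character vector of cluster labels or `"admixed"`), `tally`
#'   (group x cluster contingency table when `groups` given, else overall
#'   counts), `prop_assigned`, `threshold`
#' @export
assign_memberships <- function(q, threshold = 0.6, groups = NULL) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  q <- q_matrix(unclass(q), labels = rownames(q))
  cl <- colnames(q)
  idx <- apply(unclass(q), 1, function(row) {
    j <- which(row > threshold)
    if (length(j)) cl[j[1]] else "admixed"
  })
  assignments <- stats::setNames(idx, rownames(q))
  lev <- c(cl, "admixed")
  af <- factor(assignments, levels = lev)
  if (!is.null(groups)) {
    gg <- if (!is.null(names(groups))) groups[rownames(q)] else groups
    tally <- table(group = gg, cluster = af)
  } else {
    tally <- table(cluster = af)
  }
  structure(list(assignments = assignments, tally = tally,
                 prop_assigned = mean(assignments != "admixed"),
                 threshold = threshold),
            class = "membership_assignment")
}

#' @export
print.membership_assignment <- function(x, ...) {
  cat(sprintf("membership threshold %.2f: %.1f%% of accessions assigned\n",
              x$threshold, 100 * x$prop_assigned))
  print(x$tally)
  invisible(x)
}
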