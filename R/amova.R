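#' Squared Euclidean distance between band profiles
#'
#' For binary profiles this is simply the mismatch (Hamming) count, the
#' distance AMOVA for dominant markers is built on.
#'
#' @param x,y equal-length binary vectors
#' @return nonnegative count
#' @export
squared_euclidean <- function(x, y) {
  if (length(x) != length(y))
    stop("band vectors differ in length (", length(x), " vs ", length(y), ")")
  sum((x - y)^2)
}

#' All-pairs squared Euclidean distances of a band matrix
#' @param m a [band_matrix()]
#' @return accessions x accessions matrix of mismatch counts
#' @export
squared_euclidean_matrix <- function(m) {
  as.matrix(stats::dist(unclass(m)))^2
}

# SS bookkeeping from a (squared) distance matrix and a factor
.amova_ss <- function(d, g) {
  n <- nrow(d)
  ss_total <- sum(d) / (2 * n)
  M <- rowsum(d, g)
  S <- rowsum(t(M), g)              # group x group pair sums (both orders)
  sizes <- tabulate(g)
  ss_within <- sum(diag(S) / (2 * sizes))
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

.phi_from_ss <- function(ss, sizes) {
  n <- sum(sizes); k <- length(sizes)
  ms_b <- ss[["between"]] / (k - 1)
  ms_w <- ss[["within"]] / (n - k)
  n0 <- (n - sum(sizes^2) / n) / (k - 1)
  sigma_a <- (ms_b - ms_w) / n0
  truncated <- sigma_a < 0
  if (truncated) sigma_a <- 0
  list(ms_b = ms_b, ms_w = ms_w, n0 = n0, sigma_a = sigma_a, sigma_w = ms_w,
       phi = sigma_a / (sigma_a + ms_w), truncated = truncated)
}

#' AMOVA variance components and Phi-PT for dominant markers
#'
#' Two-level analysis of molecular variance on a squared Euclidean distance
#' matrix: `SS_total = sum_{i<j} d_ij / N`, `SS_within` the analogous
#' per-group sums, `SS_between` by subtraction; `df = (k - 1, N - k)`;
#' `sigma^2_w = MS_within` and `sigma^2_a = (MS_between - MS_within) / n0`
#' with `n0 = (N - sum n_g^2 / N) / (k - 1)` the unbalanced-design average
#' group size. Negative between-group components are truncated to 0 and
#' flagged. `Phi_PT = sigma^2_a / (sigma^2_a + sigma^2_w)` is the
#' dominant-marker analogue of F_ST.
#'
#' @param d square matrix of squared Euclidean distances (see
#'   [squared_euclidean_matrix()])
#' @param groups group assignment (named by accession, or in row order)
#' @return object of class `amova`: list with `df`, `SS`, `MS`, `var_comp`,
#'   `pvc` (percent of total variance), `phi_pt`, `n0`, `group_sizes`,
#'   `truncated`, and `p_value`/`n_perm` of `NA` until
#'   [amova_permutation()] fills them
#' @export
amova_fit <- function(d, groups) {
  d <- as.matrix(d)
  g <- .match_groups_d(d, groups)
  k <- nlevels(g); n <- nrow(d)
  if (k < 2) stop("need at least 2 groups")
  sizes <- tabulate(g)
  if (any(sizes < 1)) stop("empty group")
  if (all(d == 0)) stop("all distances zero; Phi_PT undefined")
  ss <- .amova_ss(d, g)
  comp <- .phi_from_ss(ss, sizes)
  var_total <- comp$sigma_a + comp$sigma_w
  structure(list(
    df = c(between = k - 1L, within = n - k, total = n - 1L),
    SS = c(between = ss[["between"]], within = ss[["within"]],
           total = ss[["total"]]),
    MS = c(between = comp$ms_b, within = comp$ms_w),
    var_comp = c(between = comp$sigma_a, within = comp$sigma_w),
    pvc = 100 * c(between = comp$sigma_a, within = comp$sigma_w) / var_total,
    phi_pt = comp$phi, n0 = comp$n0,
    group_sizes = stats::setNames(sizes, levels(g)),
    truncated = comp$truncated,
    p_value = NA_real_, n_perm = NA_integer_),
    class = "amova")
}

.match_groups_d <- function(d, groups) {
  ids <- rownames(d)
  if (!is.null(names(groups)) && !is.null(ids)) {
    miss <- setdiff(ids, names(groups))
    if (length(miss))
      stop("accessions without a group: ", paste(miss, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != nrow(d)) {
    stop("`groups` must be named by accession or match the matrix order")
  }
  droplevels(as.factor(as.character(groups)))
}

#' @export
print.amova <- function(x, ...) {
  tab <- data.frame(
    df = c(x$df[["between"]], x$df[["within"]], x$df[["total"]]),
    SS = round(c(x$SS[["between"]], x$SS[["within"]], x$SS[["total"]]), 3),
    MS = c(round(x$MS[["between"]], 3), round(x$MS[["within"]], 3), NA),
    Est.Var = c(round(x$var_comp[["between"]], 3),
                round(x$var_comp[["within"]], 3),
                round(sum(x$var_comp), 3)),
    PVC = sprintf("%.2f%%", c(x$pvc[["between"]], x$pvc[["within"]], 100)),
    row.names = c("Between groups", "Within groups", "Total"))
  print(tab)
  cat(sprintf("Phi_PT = %.3f", x$phi_pt))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_perm))
  if (x$truncated) cat("  [negative between-group component truncated to 0]")
  cat("\n")
  invisible(x)
}

#' Permutation p-value for Phi-PT
#'
#' Shuffles whole-accession group labels (the natural permutation unit in a
#' two-level design with no within-individual stratum), recomputes Phi_PT
#' for each permutation, and returns the upper-tail probability
#' `p = (#\{Phi_perm >= Phi_obs\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams amova_fit
#' @param n_perm number of label permutations
#' @param seed integer seed
#' @return the [amova_fit()] object with `p_value` and `n_perm` filled
#' @export
amova_permutation <- function(d, groups, n_perm = 9999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- as.matrix(d)
  g <- .match_groups_d(d, groups)
  if (nlevels(g) < 2) stop("degenerate single-group permutation space")
  fit <- amova_fit(d, groups)
  sizes <- tabulate(g)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  phi_perm <- numeric(n_perm)
  gi <- as.integer(g)
  for (b in seq_len(n_perm)) {
    gp <- gi[sample.int(n)]
    ss <- .amova_ss(d, gp)
    phi_perm[b] <- .phi_from_ss(ss, sizes)$phi
  }
  fit$p_value <- (sum(phi_perm >= fit$phi_pt) + 1) / (n_perm + 1)
  fit$n_perm <- n_perm
  fit
}

#' Phi-PT from variance components
#'
#' `Phi_PT = sigma^2_between / (sigma^2_between + sigma^2_within)`; exposed
#' so published variance components can be turned into the differentiation
#' coefficient directly.
#'
#' @param var_between,var_within estimated variance components
#' @return Phi_PT in \[0, 1\]
#' @export
phi_pt <- function(var_between, var_within) {
  var_between / (var_between + var_within)
}

#' Pairwise Phi-PT between groups
#'
#' Runs a two-group [amova_fit()] plus [amova_permutation()] for every pair
#' of groups. P-values are reported unadjusted; optionally a sequential
#' Bonferroni (Holm) adjusted matrix is added.
#'
#' @inheritParams amova_permutation
#' @param sequential_bonferroni also report Holm-adjusted p-values
#' @return object of class `pairwise_phipt`: list with symmetric matrices
#'   `phi` (diagonal 0) and `p` (and `p_adj` when requested)
#' @export
pairwise_phipt <- function(d, groups, n_perm = 999, seed = NULL,
                           sequential_bonferroni = FALSE) {
  d <- as.matrix(d)
  g <- .match_groups_d(d, groups)
  gl <- levels(g)
  if (length(gl) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  k <- length(gl)
  phi <- matrix(0, k, k, dimnames = list(gl, gl))
  p <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- g %in% c(gl[i], gl[j])
    fit <- amova_permutation(d[sel, sel, drop = FALSE],
                             droplevels(g[sel]), n_perm = n_perm)
    phi[i, j] <- phi[j, i] <- fit$phi_pt
    p[i, j] <- p[j, i] <- fit$p_value
  }
  out <- list(phi = phi, p = p, n_perm = n_perm)
  if (sequential_bonferroni) {
    adj <- p
    adj[upper.tri(adj)] <- stats::p.adjust(p[upper.tri(p)], "holm")
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    out$p_adj <- adj
  }
  structure(out, class = "pairwise_phipt")
}

#' @export
print.pairwise_phipt <- function(x, ...) {
  cat("Pairwise Phi_PT (lower) / p-values (upper):\n")
  m <- x$phi
  m[upper.tri(m)] <- x$p[upper.tri(x$p)]
  print(round(m, 3))
  invisible(x)
}
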