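#' Shannon diversity partition within and between groups
#'
#' Partitions band diversity into within- and between-group components.
#' For every globally polymorphic band (0 < f < 1 over all accessions) the
#' two-state Shannon entropy (nats) of its presence frequency is computed
#' within each group (`H_zone`, with bands monomorphic inside a group
#' contributing 0) and over all accessions pooled (`H_W`); per-group values
#' are means over this common band set, `H_A` is the unweighted mean of
#' `H_zone` over groups, and the intra-/inter-group diversity components are
#' `H_A / H_W` and `(H_W - H_A) / H_W`. Pooling concavity guarantees
#' `H_A <= H_W`.
#'
#' @param m a [band_matrix()]
#' @param groups group assignment for every accession: a named character
#'   vector/factor (names = accession ids) or an unnamed one in accession
#'   order. Every group needs >= 2 accessions, and >= 2 groups are required.
#' @return object of class `shannon_partition`: list with `h_zone` (named
#'   per-group means), `h_a`, `h_w`, `intra_fraction`, `inter_fraction`,
#'   `n_bands` (polymorphic bands used), `band_h_zone` (bands x groups
#'   entropy matrix, for downstream tests) and `per_primer` breakdown.
#' @export
shannon_partition <- function(m, groups) {
  g <- .match_groups(m, groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2))
    stop("group(s) with < 2 accessions: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  v <- unclass(m)
  f_all <- colMeans(v)
  poly <- f_all > 0 & f_all < 1
  if (!any(poly)) stop("no polymorphic bands")
  hz_bands <- sapply(levels(g), function(gl)
    shannon_band(colMeans(v[g == gl, poly, drop = FALSE])))
  h_zone <- colMeans(hz_bands)
  h_w_bands <- shannon_band(f_all[poly])
  h_w <- mean(h_w_bands)
  h_a <- mean(h_zone)
  pr <- primers(m)[poly]
  per_primer <- do.call(rbind, lapply(unique(pr), function(pc) {
    j <- pr == pc
    data.frame(primer = pc, n_poly = sum(j),
               H_A = mean(colMeans(hz_bands[j, , drop = FALSE])),
               H_W = mean(h_w_bands[j]), stringsAsFactors = FALSE)
  }))
  structure(list(h_zone = h_zone, h_a = h_a, h_w = h_w,
                 intra_fraction = h_a / h_w,
                 inter_fraction = (h_w - h_a) / h_w,
                 n_bands = sum(poly),
                 band_h_zone = hz_bands,
                 per_primer = per_primer),
            class = "shannon_partition")
}

#' @export
print.shannon_partition <- function(x, ...) {
  cat("Shannon diversity partition over", x$n_bands, "polymorphic bands\n")
  print(round(data.frame(H_zone = x$h_zone), 4))
  cat(sprintf("H_A = %.4f, H_W = %.4f; within %.2f%%, between %.2f%%\n",
              x$h_a, x$h_w, 100 * x$intra_fraction, 100 * x$inter_fraction))
  invisible(x)
}

# groups argument -> factor aligned with accessions(m)
.match_groups <- function(m, groups) {
  acc <- accessions(m)
  if (!is.null(names(groups))) {
    miss <- setdiff(acc, names(groups))
    if (length(miss))
      stop("accessions without a group: ", paste(miss, collapse = ", "))
    groups <- groups[acc]
  } else if (length(groups) != length(acc)) {
    stop("`groups` must be named by accession or match the accession count")
  }
  g <- as.factor(as.character(groups))
  names(g) <- acc
  droplevels(g)
}

#' Pairwise permutation test of group diversity differences
#'
#' Treats the per-band within-group entropies (the `band_h_zone` columns of
#' [shannon_partition()]) as replicates and tests each pair of groups with
#' an unpaired mean-difference permutation test (two-sided). Groups are then
#' summarised with a compact letter display at each declared alpha level:
#' groups sharing a letter are not significantly different.
#'
#' @inheritParams shannon_partition
#' @param n_perm permutations per pair
#' @param seed integer seed
#' @param alpha significance levels for the letter groupings
#' @return object of class `group_diff_test`: list with `pairs` (data.frame
#'   of pairwise mean differences and p-values) and `letters` (one character
#'   vector of letter codes per alpha level, ordered by decreasing group
#'   mean)
#' @export
group_difference_test <- function(m, groups, n_perm = 999, seed = NULL,
                                  alpha = c(0.05, 0.01)) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  sp <- shannon_partition(m, groups)
  hz <- sp$band_h_zone
  gl <- colnames(hz)
  if (!is.null(seed)) set.seed(seed)
  cmb <- utils::combn(gl, 2)
  pairs <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                      mean1 = NA_real_, mean2 = NA_real_,
                      diff = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(cmb))) {
    a <- hz[, cmb[1, k]]; b <- hz[, cmb[2, k]]
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b); na <- length(a)
    perm <- replicate(n_perm, {
      s <- sample(pool)
      abs(mean(s[seq_len(na)]) - mean(s[-seq_len(na)]))
    })
    pairs$mean1[k] <- mean(a); pairs$mean2[k] <- mean(b)
    pairs$diff[k] <- mean(a) - mean(b)
    pairs$p[k] <- (sum(perm >= obs) + 1) / (n_perm + 1)
  }
  letters_by_alpha <- lapply(alpha, function(al)
    .letter_display(gl, sp$h_zone[gl], pairs, al))
  names(letters_by_alpha) <- paste0("alpha_", alpha)
  structure(list(pairs = pairs, letters = letters_by_alpha,
                 alpha = alpha, n_perm = n_perm),
            class = "group_diff_test")
}

# insert-and-absorb compact letter display
.letter_display <- function(gl, means, pairs, alpha) {
  ord <- gl[order(-means)]
  sig <- function(a, b) {
    i <- (pairs$group1 == a & pairs$group2 == b) |
      (pairs$group1 == b & pairs$group2 == a)
    any(pairs$p[i] <= alpha)
  }
  sets <- list(ord)
  for (k in seq_len(nrow(pairs))) {
    if (pairs$p[k] > alpha) next
    a <- pairs$group1[k]; b <- pairs$group2[k]
    repeat {
      offending <- which(vapply(sets, function(s) a %in% s && b %in% s, TRUE))
      if (!length(offending)) break
      s <- sets[[offending[1]]]
      sets[[offending[1]]] <- setdiff(s, a)
      sets <- c(sets, list(setdiff(s, b)))
      # absorb sets contained in another
      keep <- !vapply(seq_along(sets), function(i)
        any(vapply(seq_along(sets), function(j)
          i != j && all(sets[[i]] %in% sets[[j]]), TRUE)), TRUE)
      sets <- sets[keep]
    }
  }
  lab <- stats::setNames(rep("", length(gl)), gl)
  for (i in seq_along(sets))
    lab[sets[[i]]] <- paste0(lab[sets[[i]]], LETTERS[i])
  vapply(strsplit(lab, ""), function(ch) paste(sort(ch), collapse = ""),
         "", USE.NAMES = TRUE)
}

#' @export
print.group_diff_test <- function(x, ...) {
  print(transform(x$pairs, p = signif(p, 3)), row.names = FALSE)
  for (nm in names(x$letters)) {
    cat(nm, ": ", paste(names(x$letters[[nm]]), x$letters[[nm]],
                        sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Allele frequency behind a dominant band
#'
#' Under a diploid dominant-phenotype model with inbreeding coefficient `f`,
#' absence of a band (the null phenotype) requires two null alleles, so the
#' absence frequency is `(1 - p)^2 + f p (1 - p)` where `p` is the
#' band-allele frequency. This solves that quadratic for `p`; at `f = 0` it
#' reduces to the square-root estimator `p = 1 - sqrt(absence_freq)`.
#'
#' @param band_absence_freq observed frequency of the absent phenotype, in
#'   \[0, 1\] (vectorised)
#' @param inbreeding_f inbreeding coefficient in \[0, 1\]
#' @return list with `p` (band-allele frequency) and `q = 1 - p`
#'   (null-allele frequency)
#' @export
dominant_allele_freq <- function(band_absence_freq, inbreeding_f = 0) {
  A <- band_absence_freq
  if (any(is.na(A)) || any(A < 0) || any(A > 1))
    stop("band_absence_freq must lie in [0, 1]")
  f <- inbreeding_f
  if (length(f) != 1 || is.na(f) || f < 0 || f > 1)
    stop("inbreeding_f must be a single value in [0, 1]")
  if (f == 1) {
    q <- A            # absence = q under full inbreeding
  } else {
    # (1-f) q^2 + f q - A = 0 in q = 1 - p
    q <- (-f + sqrt(f^2 + 4 * (1 - f) * A)) / (2 * (1 - f))
  }
  if (any(q < -1e-12 | q > 1 + 1e-12))
    stop("no allele-frequency root in [0, 1]")
  q <- pmin(pmax(q, 0), 1)
  list(p = 1 - q, q = q)
}

#' Nei-style G_ST partition from dominant bands
#'
#' Estimates, per band and group, the band-allele frequency via
#' [dominant_allele_freq()] applied to the within-group absence frequency,
#' turns it into an expected heterozygosity `H = 2 p (1 - p)`, and
#' partitions: `H_S` per group is the mean over bands, `H_S_bar` the
#' unweighted mean over groups, `H_T` the mean heterozygosity of the
#' group-mean allele frequencies, and `G_ST = (H_T - H_S_bar) / H_T`.
#'
#' A diploid dominant-phenotype model is assumed regardless of actual
#' ploidy; no polyploid dosage model is used (documented limitation).
#'
#' @inheritParams shannon_partition
#' @param inbreeding_f inbreeding coefficient passed to
#'   [dominant_allele_freq()]
#' @return object of class `gst_partition`: list with `h_s_group`,
#'   `h_s_bar`, `h_t`, `ratio` (`h_s_bar / h_t`), `g_st`, `p_hat`
#'   (bands x groups allele-frequency estimates), `inbreeding_f`
#' @seealso [gst_summary()] for the pure arithmetic on externally supplied
#'   per-group heterozygosities
#' @export
gst_partition <- function(m, groups, inbreeding_f = 0) {
  g <- .match_groups(m, groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  v <- unclass(m)
  p_hat <- sapply(levels(g), function(gl) {
    absent <- 1 - colMeans(v[g == gl, , drop = FALSE])
    dominant_allele_freq(absent, inbreeding_f)$p
  })
  h_group <- 2 * p_hat * (1 - p_hat)
  h_s_group <- colMeans(h_group)
  h_s_bar <- mean(h_s_group)
  p_bar <- rowMeans(p_hat)
  h_t <- mean(2 * p_bar * (1 - p_bar))
  if (h_t == 0) stop("H_T = 0; G_ST undefined")
  structure(list(h_s_group = h_s_group, h_s_bar = h_s_bar, h_t = h_t,
                 ratio = h_s_bar / h_t, g_st = (h_t - h_s_bar) / h_t,
                 p_hat = p_hat, inbreeding_f = inbreeding_f),
            class = "gst_partition")
}

#' @export
print.gst_partition <- function(x, ...) {
  print(round(data.frame(H_S = x$h_s_group), 4))
  cat(sprintf("H_S_bar = %.4f, H_T = %.4f, H_S/H_T = %.4f, G_ST = %.4f\n",
              x$h_s_bar, x$h_t, x$ratio, x$g_st))
  invisible(x)
}

#' G_ST summary arithmetic from per-group heterozygosities
#'
#' The pure partition arithmetic on externally supplied per-group expected
#' heterozygosities and a total heterozygosity: `H_S_bar` is their
#' unweighted mean, and `G_ST = (H_T - H_S_bar) / H_T`.
#'
#' @param h_s numeric vector of per-group expected heterozygosities
#' @param h_t total expected heterozygosity (> 0)
#' @return list with `h_s_bar`, `ratio` (`h_s_bar / h_t`) and `g_st`
#' @examples
#' gst_summary(c(0.3621, 0.3696, 0.3720, 0.3614), 0.3841)
#' @export
gst_summary <- function(h_s, h_t) {
  if (h_t <= 0) stop("H_T must be > 0")
  h_s_bar <- mean(h_s)
  list(h_s_bar = h_s_bar, ratio = h_s_bar / h_t, g_st = (h_t - h_s_bar) / h_t)
}
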