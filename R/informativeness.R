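#' Per-band presence frequencies
#'
#' @param m a [band_matrix()]
#' @return named numeric vector `f`, the fraction of accessions carrying each
#'   band.
#' @export
band_frequencies <- function(m) {
  if (nrow(m) < 1L || ncol(m) < 1L) stop("empty band matrix")
  colMeans(unclass(m))
}

.check_freq <- function(f, what = "f") {
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("`", what, "` must lie in [0, 1]")
  f
}

#' Polymorphic information content of a dominant band
#'
#' For a dominant (presence/absence) band with presence frequency `f`,
#' `PIC = 2 f (1 - f)`, maximal at 0.5 when `f = 0.5`.
#'
#' @param f presence frequency in \[0, 1\] (vectorised)
#' @return PIC values in \[0, 0.5\]
#' @export
pic_band <- function(f) {
  2 * .check_freq(f) * (1 - f)
}

#' Shannon diversity of a dominant band
#'
#' Two-state entropy of a presence/absence band in nats:
#' `H = -(f ln f + (1 - f) ln(1 - f))` with `0 ln 0 = 0`; maximum `ln 2` at
#' `f = 0.5`.
#'
#' @param f presence frequency in \[0, 1\] (vectorised)
#' @return entropies in \[0, ln 2\]
#' @export
shannon_band <- function(f) {
  .check_freq(f)
  xlx <- function(p) ifelse(p > 0, p * log(p), 0)
  -(xlx(f) + xlx(1 - f))
}

#' Band informativeness
#'
#' `Ib = 1 - 2 |0.5 - p|`: how close a band's presence proportion `p` is to
#' the maximally discriminating 50/50 split. Summed over a primer's bands it
#' gives that primer's resolving power Rp.
#'
#' @param p presence proportion in \[0, 1\] (vectorised)
#' @return Ib values in \[0, 1\]
#' @export
band_informativeness <- function(p) {
  1 - 2 * abs(0.5 - .check_freq(p, "p"))
}

#' Per-primer informativeness summary
#'
#' Computes, for each primer, the standard dominant-marker informativeness
#' battery:
#' \describe{
#'   \item{TNB, NPB, PPB}{total and polymorphic band counts (a band is
#'     polymorphic when `0 < f < 1`, no minor-frequency threshold) and
#'     `PPB = 100 NPB / TNB`.}
#'   \item{H, PIC}{mean per-band Shannon diversity and PIC over that
#'     primer's *polymorphic* bands (monomorphic bands carry no information
#'     and are excluded from the means).}
#'   \item{MI}{marker index = effective multiplex ratio (NPB) times mean
#'     PIC.}
#'   \item{Rp}{resolving power = sum of `Ib` over all the primer's bands.}
#'   \item{GI}{genotype index = distinct banding profiles the primer alone
#'     induces among the accessions, divided by the number of accessions.}
#' }
#' Two collection-wide polymorphism rates are deliberately distinct and both
#' reported: `ppb_overall = 100 * sum(NPB) / sum(TNB)` and `ppb_mean`, the
#' unweighted mean of the per-primer PPB values.
#'
#' @param m a [band_matrix()]
#' @return data.frame of class `primer_summary`, one row per primer, with
#'   attribute `overall` (a list with `tnb_total`, `npb_total`,
#'   `ppb_overall`, `ppb_mean`, and totals of MI and Rp). Primers with zero
#'   bands are excluded with a warning. `summary()` prints min/max/mean/total
#'   rows.
#' @export
primer_summary <- function(m) {
  pr <- primers(m)
  f <- band_frequencies(m)
  poly <- f > 0 & f < 1
  ib <- band_informativeness(f)
  codes <- unique(pr)
  n_acc <- nrow(m)
  rows <- lapply(codes, function(pc) {
    j <- which(pr == pc)
    if (!length(j)) return(NULL)
    tnb <- length(j)
    jp <- j[poly[j]]
    npb <- length(jp)
    h <- if (npb) mean(shannon_band(f[jp])) else NA_real_
    pic <- if (npb) mean(pic_band(f[jp])) else NA_real_
    profiles <- apply(unclass(m)[, j, drop = FALSE], 1, paste, collapse = "")
    data.frame(primer = pc, TNB = tnb, NPB = npb,
               PPB = 100 * npb / tnb, H = h, PIC = pic,
               MI = if (npb) npb * pic else 0,
               Rp = sum(ib[j]),
               GI = length(unique(profiles)) / n_acc,
               stringsAsFactors = FALSE)
  })
  empty <- setdiff(codes, unlist(lapply(rows, `[[`, "primer")))
  if (length(empty))
    warning("primers with zero bands excluded: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "overall") <- list(
    n_accessions = n_acc,
    tnb_total = sum(out$TNB), npb_total = sum(out$NPB),
    ppb_overall = 100 * sum(out$NPB) / sum(out$TNB),
    ppb_mean = mean(out$PPB),
    mi_total = sum(out$MI), rp_total = sum(out$Rp))
  class(out) <- c("primer_summary", "data.frame")
  out
}

#' @export
summary.primer_summary <- function(object, ...) {
  ov <- attr(object, "overall")
  num <- object[, c("TNB", "NPB", "PPB", "H", "PIC", "MI", "Rp", "GI")]
  rbind(
    Min. = vapply(num, min, 0, na.rm = TRUE),
    Max. = vapply(num, max, 0, na.rm = TRUE),
    Mean = vapply(num, mean, 0, na.rm = TRUE),
    Total = c(ov$tnb_total, ov$npb_total, ov$ppb_overall, NA, NA,
              ov$mi_total, ov$rp_total, NA))
}

#' @export
print.primer_summary <- function(x, digits = 3, ...) {
  print.data.frame(x, digits = digits, row.names = FALSE)
  ov <- attr(x, "overall")
  cat(sprintf(
    "total bands %d, polymorphic %d; overall PPB %.2f%%, per-primer mean PPB %.2f%%\n",
    ov$tnb_total, ov$npb_total, ov$ppb_overall, ov$ppb_mean))
  invisible(x)
}

#' Pearson correlations among primer informativeness indices
#'
#' Pairwise Pearson correlations (with two-sided p-values from the
#' t-approximation) among the per-primer indices PIC, Rp, MI, GI and H.
#' A zero-variance column yields `NA` (undefined), never 0.
#'
#' @param rows a `primer_summary` (or any data.frame with the five columns)
#' @param columns which index columns to correlate
#' @return list with matrices `r` and `p` and the sample size `n`
#' @export
index_correlations <- function(rows,
                               columns = c("PIC", "Rp", "MI", "GI", "H")) {
  x <- as.data.frame(rows)[, columns, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 primers for correlations")
  k <- length(columns)
  r <- diag(1, k); dimnames(r) <- list(columns, columns)
  p <- r; p[] <- NA; diag(p) <- NA
  sds <- vapply(x, stats::sd, 0)
  if (any(sds == 0))
    warning("zero-variance column(s): ", paste(columns[sds == 0], collapse = ", "),
            "; correlations undefined")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sds[i] == 0 || sds[j] == 0) { r[i, j] <- r[j, i] <- NA; next }
    rij <- stats::cor(x[[i]], x[[j]])
    r[i, j] <- r[j, i] <- rij
    tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
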