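#' Simulation configuration for dominant-marker band matrices
#'
#' Defaults describe the germplasm-survey design the package was built
#' around: 37 accessions in four unbalanced geographic groups (7/9/13/8),
#' 25 primers producing 5-24 bands each, ancestral band frequencies uniform
#' on \[0.05, 0.95\], weak between-group differentiation (`F = 0.08`,
#' yielding Phi_PT in the 0.05-0.15 range), and roughly a fifth of bands
#' monomorphic so the polymorphism rate lands near 77%.
#'
#' @param group_sizes accession counts per group (sum >= 4)
#' @param n_primers number of primers (assays)
#' @param bands_per_primer inclusive range of band counts per primer
#' @param ancestral_freq_range uniform law for the per-band ancestral
#'   presence frequency
#' @param differentiation_F Balding-Nichols differentiation parameter in
#'   \[0, 1): per-group frequencies are Beta-distributed around the
#'   ancestral frequency with variance `F * p * (1 - p)`
#' @param mode `"phenotype"` (band frequencies modelled directly; the
#'   default, since hexaploid dosage is unmodellable) or
#'   `"diploid-dominant"` (two allele draws per accession, band shown
#'   unless homozygous null)
#' @param monomorphic_fraction expected fraction of bands that are
#'   all-present (monomorphic)
#' @param clone_pairs number of within-group accession duplications (exact
#'   clones, GS = 1)
#' @param seed integer seed; every simulated artifact is reproducible from
#'   the config alone
#' @return list of class `sim_config`
#' @export
sim_config <- function(group_sizes = c(7, 9, 13, 8),
                       n_primers = 25,
                       bands_per_primer = c(5, 24),
                       ancestral_freq_range = c(0.05, 0.95),
                       differentiation_F = 0.08,
                       mode = c("phenotype", "diploid-dominant"),
                       monomorphic_fraction = 0.22,
                       clone_pairs = 0,
                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(sum(group_sizes) >= 4, all(group_sizes >= 1),
            differentiation_F >= 0, differentiation_F < 1,
            monomorphic_fraction >= 0, monomorphic_fraction <= 1,
            length(bands_per_primer) == 2,
            bands_per_primer[1] >= 1,
            bands_per_primer[1] <= bands_per_primer[2],
            ancestral_freq_range[1] >= 0, ancestral_freq_range[2] <= 1,
            clone_pairs >= 0)
  structure(list(group_sizes = group_sizes, n_primers = n_primers,
                 bands_per_primer = bands_per_primer,
                 ancestral_freq_range = ancestral_freq_range,
                 differentiation_F = differentiation_F, mode = mode,
                 monomorphic_fraction = monomorphic_fraction,
                 clone_pairs = clone_pairs, seed = seed),
            class = "sim_config")
}

.default_group_labels <- function(k) {
  if (k == 4) c("GZ", "CQ", "CDP", "YL") else paste0("G", seq_len(k))
}

#' Simulate a dominant-marker band matrix with group structure
#'
#' Balding-Nichols-style generator: each polymorphic band gets an ancestral
#' presence frequency `p`; each group draws its own frequency from a Beta
#' distribution with mean `p` and variance `F p (1 - p)` (a point mass at
#' `p` when `F = 0`); accessions then show the band with that group
#' frequency (`"phenotype"` mode) or carry two alleles and show it unless
#' homozygous null (`"diploid-dominant"` mode). Configured monomorphic
#' (all-present) bands and exact clone pairs are appended afterwards.
#'
#' @param cfg a [sim_config()]
#' @param seed optional integer overriding `cfg$seed`
#' @return list of class `sim_band_data`: `matrix` (a [band_matrix()]),
#'   `records` (accession metadata with group labels), `truth` (the config
#'   plus generating frequencies: `ancestral_freq`, `group_freq`,
#'   `monomorphic`, `clones`)
#' @export
simulate_band_matrix <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  k <- length(cfg$group_sizes)
  n <- sum(cfg$group_sizes)
  glab <- .default_group_labels(k)
  g <- factor(rep(glab, cfg$group_sizes), levels = glab)
  nb_primer <- sample(seq(cfg$bands_per_primer[1], cfg$bands_per_primer[2]),
                      cfg$n_primers, replace = TRUE)
  primer_codes <- sprintf("P%02d", seq_len(cfg$n_primers))
  primer_of_band <- rep(primer_codes, nb_primer)
  tnb <- length(primer_of_band)
  band_ids <- unlist(lapply(seq_len(cfg$n_primers), function(i)
    paste0(primer_codes[i], "_", seq_len(nb_primer[i]))))
  mono <- stats::runif(tnb) < cfg$monomorphic_fraction
  p_anc <- stats::runif(tnb, cfg$ancestral_freq_range[1],
                        cfg$ancestral_freq_range[2])
  p_anc[mono] <- 1
  FF <- cfg$differentiation_F
  group_freq <- matrix(rep(p_anc, k), tnb, k, dimnames = list(band_ids, glab))
  if (FF > 0) {
    for (j in seq_len(k)) {
      pj <- p_anc[!mono]
      a <- pj * (1 - FF) / FF
      b <- (1 - pj) * (1 - FF) / FF
      group_freq[!mono, j] <- stats::rbeta(length(pj), a, b)
    }
  }
  v <- matrix(0L, n, tnb)
  for (j in seq_len(k)) {
    rows <- which(g == glab[j])
    pf <- group_freq[, j]
    if (cfg$mode == "phenotype") {
      v[rows, ] <- matrix(stats::rbinom(length(rows) * tnb, 1,
                                        rep(pf, each = length(rows))),
                          length(rows), tnb)
    } else {
      # two allele draws; band absent only when homozygous null
      show_p <- 1 - (1 - pf)^2
      v[rows, ] <- matrix(stats::rbinom(length(rows) * tnb, 1,
                                        rep(show_p, each = length(rows))),
                          length(rows), tnb)
    }
  }
  v[, mono] <- 1L
  codes <- sprintf("S%02d", seq_len(n))
  clones <- NULL
  if (cfg$clone_pairs > 0) {
    eligible <- which(cfg$group_sizes >= 2)
    for (cp in seq_len(cfg$clone_pairs)) {
      gj <- glab[sample(eligible, 1)]
      pair <- sample(which(g == gj), 2)
      v[pair[2], ] <- v[pair[1], ]
      clones <- rbind(clones, data.frame(source = codes[pair[1]],
                                         copy = codes[pair[2]]))
    }
  }
  m <- band_matrix(v, primers = primer_of_band,
                   accession_ids = codes, band_ids = band_ids)
  records <- data.frame(code = codes, group = as.character(g),
                        stringsAsFactors = FALSE)
  class(records) <- c("accession_table", "data.frame")
  structure(list(matrix = m, records = records,
                 truth = list(config = cfg, seed = seed,
                              ancestral_freq = stats::setNames(p_anc, band_ids),
                              group_freq = group_freq,
                              monomorphic = stats::setNames(mono, band_ids),
                              clones = clones)),
            class = "sim_band_data")
}

#' @export
print.sim_band_data <- function(x, ...) {
  cat("sim_band_data (F = ", x$truth$config$differentiation_F, ", mode = ",
      x$truth$config$mode, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Simulate collection coordinates, optionally with isolation by distance
#'
#' Places each group's centroid uniformly in a bounding box spanning the
#' southwest-China collection region (lat 25-31, lon 101-108) and jitters
#' accessions around it. With `ibd_strength > 0` a genetic distance matrix
#' must be supplied; coordinates are then blended with a 2-axis metric
#' embedding of the genetic distances scaled into the same box, so
#' geographic and genetic distances correlate (the blend weight is
#' `ibd_strength`). At 0 the placement is independent of the genetics.
#'
#' @param records accession metadata (needs `code` and `group`)
#' @param ibd_strength blend weight in \[0, 1\]
#' @param seed integer seed
#' @param gd genetic distance matrix over the same accessions (required
#'   when `ibd_strength > 0`)
#' @param jitter standard deviation (degrees) of accession scatter around
#'   the group centroid; 0 puts every accession exactly on it
#' @param bbox bounding box `c(lat_min, lat_max, lon_min, lon_max)`
#' @return the records with `latitude`/`longitude` columns filled
#' @export
simulate_coordinates <- function(records, ibd_strength = 0, seed = NULL,
                                 gd = NULL, jitter = 0.35,
                                 bbox = c(25, 31, 101, 108)) {
  stopifnot(ibd_strength >= 0, ibd_strength <= 1)
  if (ibd_strength > 0 && is.null(gd))
    stop("`gd` (genetic distance matrix) required when ibd_strength > 0")
  if (!is.null(seed)) set.seed(seed)
  g <- factor(records$group)
  k <- nlevels(g)
  n <- nrow(records)
  cen_lat <- stats::runif(k, bbox[1], bbox[2])
  cen_lon <- stats::runif(k, bbox[3], bbox[4])
  lat <- cen_lat[as.integer(g)] + stats::rnorm(n, 0, jitter)
  lon <- cen_lon[as.integer(g)] + stats::rnorm(n, 0, jitter)
  if (ibd_strength > 0) {
    emb <- stats::cmdscale(stats::as.dist(as.matrix(gd)), k = 2)
    rescale <- function(x, lo, hi)
      if (diff(range(x)) == 0) rep(mean(c(lo, hi)), length(x)) else
        lo + (x - min(x)) / diff(range(x)) * (hi - lo)
    lat <- (1 - ibd_strength) * lat + ibd_strength * rescale(emb[, 1], bbox[1], bbox[2])
    lon <- (1 - ibd_strength) * lon + ibd_strength * rescale(emb[, 2], bbox[3], bbox[4])
  }
  records$latitude <- lat
  records$longitude <- lon
  records$has_coordinates <- TRUE
  records
}
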