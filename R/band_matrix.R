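#' Construct a dominant-marker band matrix
#'
#' A band matrix is the substrate of every statistic in this package: an
#' accessions x bands table of 0/1 presence/absence calls, with every band
#' assigned to the primer (assay) that produced it. Entries must be exactly 0
#' or 1 -- only unequivocally scorable bands belong in the matrix, and missing
#' calls are not supported.
#'
#' @param values integer or numeric matrix of 0/1 calls; rows are accessions,
#'   columns are bands. Dimnames, when present, supply the default ids.
#' @param primers character vector mapping each band (column) to a primer
#'   code; recycled names are not allowed, length must equal `ncol(values)`.
#' @param accession_ids,band_ids optional label vectors overriding dimnames.
#' @return An object of class `band_matrix`: the integer matrix with a
#'   `primers` attribute.
#' @examples
#' m <- band_matrix(rbind(A = c(1, 0, 1), B = c(0, 0, 1)),
#'                  primers = c("P1", "P1", "P2"))
#' band_frequencies(m)
#' @export
band_matrix <- function(values, primers, accession_ids = NULL, band_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(accession_ids)) accession_ids <- rownames(values)
  if (is.null(band_ids)) band_ids <- colnames(values)
  if (is.null(accession_ids)) accession_ids <- paste0("A", seq_len(nrow(values)))
  if (is.null(band_ids)) band_ids <- paste0("b", seq_len(ncol(values)))
  if (anyDuplicated(accession_ids))
    stop("duplicate accession ids: ",
         paste(unique(accession_ids[duplicated(accession_ids)]), collapse = ", "))
  if (anyDuplicated(band_ids))
    stop("duplicate band ids: ",
         paste(unique(band_ids[duplicated(band_ids)]), collapse = ", "))
  if (length(primers) != ncol(values))
    stop("`primers` must map every band to exactly one primer code (length ",
         length(primers), " != ", ncol(values), " bands)")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop("non-binary value ", values[bad[1]], " at accession ", accession_ids[i],
         " (row ", i, "), band ", band_ids[j], " (column ", j, ")")
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(accession_ids, band_ids)
  structure(values, primers = stats::setNames(as.character(primers), band_ids),
            class = c("band_matrix", "matrix", "array"))
}

#' @export
print.band_matrix <- function(x, ...) {
  p <- primers(x)
  cat("band_matrix: ", nrow(x), " accessions x ", ncol(x), " bands (",
      length(unique(p)), " primers)\n", sep = "")
  f <- colMeans(unclass(x))
  cat("polymorphic bands: ", sum(f > 0 & f < 1), " (",
      sprintf("%.1f", 100 * mean(f > 0 & f < 1)), "%)\n", sep = "")
  invisible(x)
}

#' Band-to-primer map of a band matrix
#' @param m a `band_matrix`
#' @return named character vector, band id -> primer code
#' @export
primers <- function(m) attr(m, "primers")

#' Accession and band labels
#' @param m a `band_matrix`
#' @return character vector of labels
#' @export
accessions <- function(m) rownames(m)

#' @rdname accessions
#' @export
bands <- function(m) colnames(m)

#' Read a band matrix from delimited text
#'
#' Expected layout: first header row gives band ids, second header row gives
#' the primer code of each band, then one row per accession whose first field
#' is the accession id. Alternatively the primer map may live in a separate
#' two-column file (band id, primer code) passed as `primer_file`, in which
#' case the matrix file has a single header row.
#'
#' Cell tokens other than "0"/"1" are rejected with the offending position
#' named; a strict reader fails fast rather than imputing missing calls.
#'
#' @param path file to read.
#' @param sep field delimiter; `"\t"` (default) or `","`.
#' @param primer_file optional two-column delimited file mapping band id to
#'   primer code.
#' @return a [band_matrix()].
#' @export
read_band_matrix <- function(path, sep = "\t", primer_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  split1 <- strsplit(lines, sep, fixed = TRUE)
  band_ids <- trimws(split1[[1]][-1])
  if (is.null(primer_file)) {
    primer_row <- trimws(split1[[2]][-1])
    if (length(primer_row) != length(band_ids))
      stop("primer header row has ", length(primer_row),
           " entries for ", length(band_ids), " bands")
    primer_map <- stats::setNames(primer_row, band_ids)
    body <- split1[-(1:2)]
  } else {
    pm <- utils::read.delim(primer_file, sep = sep, header = FALSE,
                            colClasses = "character", strip.white = TRUE)
    primer_map <- stats::setNames(pm[[2]], pm[[1]])
    body <- split1[-1]
  }
  missing_primer <- setdiff(band_ids, names(primer_map))
  if (length(missing_primer))
    stop("bands without a primer mapping: ",
         paste(missing_primer, collapse = ", "))
  acc <- vapply(body, function(r) trimws(r[1]), "")
  vals <- matrix(NA_integer_, length(body), length(band_ids))
  for (i in seq_along(body)) {
    row <- trimws(body[[i]][-1])
    if (length(row) != length(band_ids))
      stop("row for accession ", acc[i], " has ", length(row),
           " cells; expected ", length(band_ids))
    bad <- which(!(row %in% c("0", "1")))
    if (length(bad))
      stop("non-binary token \"", row[bad[1]], "\" at accession ", acc[i],
           " (row ", i, "), band ", band_ids[bad[1]],
           " (column ", bad[1], ")")
    vals[i, ] <- as.integer(row)
  }
  band_matrix(vals, primers = unname(primer_map[band_ids]),
              accession_ids = acc, band_ids = band_ids)
}

#' Write a band matrix as delimited text
#'
#' Inverse of [read_band_matrix()]: two header rows (band ids, primer codes)
#' followed by one 0/1 row per accession.
#'
#' @param m a `band_matrix`
#' @param path output file
#' @param sep field delimiter
#' @export
write_band_matrix <- function(m, path, sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("band", bands(m)), collapse = sep), con)
  writeLines(paste(c("primer", unname(primers(m))), collapse = sep), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(accessions(m)[i], unclass(m)[i, ]), collapse = sep), con)
  invisible(NULL)
}
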