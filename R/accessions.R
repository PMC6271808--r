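#' Convert degree-minute-second strings to decimal degrees
#'
#' Accepts decimal degrees (passed through), or DMS strings such as
#' `25°20'18"` with either ASCII (`'`, `"`) or typographic
#' (`′`, `″`, `’`, `”`) minute/second marks. For integer
#' degree/minute/second fields the result is exactly
#' `deg + min/60 + sec/3600`. `"-"`, `""` and `NA` give `NA`.
#'
#' @param x character (or numeric) vector of coordinates.
#' @return numeric vector of decimal degrees.
#' @examples
#' parse_dms("25°20'18\"")   # 25.33833...
#' @export
parse_dms <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  empty <- is.na(x) | x == "" | x == "-"
  # normalise typographic marks to ASCII
  x <- gsub("[′’`]", "'", x)
  x <- gsub("[″”“]|''", "\"", x)
  dms <- regmatches(x, regexec(
    "^([0-9]+(?:\\.[0-9]+)?)°\\s*(?:([0-9]+(?:\\.[0-9]+)?)')?\\s*(?:([0-9]+(?:\\.[0-9]+)?)\")?\\s*([NSEW])?$",
    x))
  for (i in seq_along(x)) {
    if (empty[i]) next
    m <- dms[[i]]
    if (length(m)) {
      deg <- as.numeric(m[2])
      mins <- if (nzchar(m[3])) as.numeric(m[3]) else 0
      secs <- if (nzchar(m[4])) as.numeric(m[4]) else 0
      val <- deg + mins / 60 + secs / 3600
      if (m[5] %in% c("S", "W")) val <- -val
      out[i] <- val
    } else {
      val <- suppressWarnings(as.numeric(x[i]))
      if (is.na(val)) stop("cannot parse coordinate: \"", x[i], "\"")
      out[i] <- val
    }
  }
  out
}

#' Read an accession metadata table
#'
#' Reads a delimited table of accession records: code, origin, latitude,
#' longitude (decimal degrees or DMS strings), altitude (m), geographic
#' group, morphotype and ploidy. Coordinates are normalised to decimal
#' degrees; records with missing coordinates (cultivars of unrecorded
#' provenance, say) are kept and flagged, not dropped.
#'
#' @param path delimited text file; must contain at least columns `code` and
#'   `group`, and typically `latitude`, `longitude`, `altitude`,
#'   `morphotype`, `ploidy`.
#' @param sep field delimiter.
#' @param group_levels,morphotype_levels,ploidy_levels optional declared
#'   category sets; labels outside the set raise an error.
#' @return data.frame of class `accession_table`, one row per accession,
#'   with `latitude`/`longitude` numeric and a logical `has_coordinates`.
#' @export
read_accession_table <- function(path, sep = "\t", group_levels = NULL,
                                 morphotype_levels = NULL, ploidy_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE, quote = "",
                          colClasses = "character", strip.white = TRUE,
                          encoding = "UTF-8", check.names = TRUE)
  if (!all(c("code", "group") %in% names(df)))
    stop("accession table must have `code` and `group` columns")
  if (anyDuplicated(df$code))
    stop("duplicate accession codes: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  if ("latitude" %in% names(df)) df$latitude <- parse_dms(df$latitude)
  if ("longitude" %in% names(df)) df$longitude <- parse_dms(df$longitude)
  if ("altitude" %in% names(df))
    df$altitude <- suppressWarnings(as.numeric(gsub("-$", "", df$altitude)))
  check_cat <- function(col, levels, what) {
    if (!is.null(levels) && col %in% names(df)) {
      bad <- setdiff(unique(df[[col]]), levels)
      if (length(bad))
        stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "))
    }
  }
  check_cat("group", group_levels, "group")
  check_cat("morphotype", morphotype_levels, "morphotype")
  check_cat("ploidy", ploidy_levels, "ploidy")
  if ("latitude" %in% names(df)) {
    bad <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
    if (length(bad))
      stop("latitude out of [-90, 90] for: ", paste(df$code[bad], collapse = ", "))
  }
  if ("longitude" %in% names(df)) {
    bad <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
    if (length(bad))
      stop("longitude out of [-180, 180] for: ", paste(df$code[bad], collapse = ", "))
  }
  df$has_coordinates <- !is.na(df$latitude) & !is.na(df$longitude)
  class(df) <- c("accession_table", "data.frame")
  df
}

#' Packaged whipgrass accession metadata
#'
#' The 37-accession whipgrass (*Hemarthria compressa*) collection from
#' southwest China that motivated this package: wild clones plus three
#' registered cultivars, in four geographic groups (GZ, CQ, CDP, YL) of
#' sizes 7/9/13/8, with morphotype and ploidy calls. The three cultivars
#' have no recorded collection coordinates.
#'
#' @return an `accession_table` (see [read_accession_table()]).
#' @export
whipgrass_accessions <- function() {
  read_accession_table(
    system.file("extdata", "whipgrass_accessions.tsv", package = "scotdiv"),
    group_levels = c("GZ", "CQ", "CDP", "YL"),
    morphotype_levels = c("I", "II", "III"),
    ploidy_levels = c("4x", "6x"))
}
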