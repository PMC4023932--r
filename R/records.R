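#' Specimen record sets
#'
#' A `record_set` is a data frame of digitised voucher specimens, one row per
#' pinned individual. The canonical columns are `voucher_id`, `sex`, `morph`,
#' `morph_group`, `subspecies`, `country`, `locality`, `latitude`, `longitude`
#' and `geocode_error_km`; any further columns in the source file are carried
#' along untouched. Missing coordinates and missing geocode errors are `NA`,
#' never zero. Row order is stable and meaningful (input order).
#'
#' @name record_set
NULL

.record_columns <- c(
  "voucher_id", "sex", "morph", "morph_group", "subspecies",
  "country", "locality", "latitude", "longitude", "geocode_error_km"
)

#' Construct a record set from a data frame
#'
#' Validates the invariants of the data model: unique non-empty voucher ids
#' (duplicates are a hard error naming the offending rows), coordinates either
#' both present or both missing (a lone coordinate is blanked and reported as
#' a problem), non-negative geocode errors, and sexes coerced to
#' `male`/`female`/`unknown`. A morph on a non-female record is tolerated with
#' a warning, since historic labels are messy.
#'
#' @param df data frame with at least the canonical columns (missing ones are
#'   added empty).
#' @param provenance free-text label recording where the records came from.
#' @return A `record_set` (data frame) with attributes `provenance` and
#'   `problems` (a data frame of row-level validation issues).
#' @export
record_set <- function(df, provenance = "unspecified") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in .record_columns) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("latitude", "longitude", "geocode_error_km")) {
        NA_real_
      } else {
        ""
      }
    }
  }
  problems <- data.frame(
    row = integer(), voucher_id = character(), field = character(),
    message = character(), stringsAsFactors = FALSE
  )
  note <- function(row, field, message) {
    problems[nrow(problems) + 1L, ] <<- list(
      row, as.character(df$voucher_id[row]), field, message
    )
  }

  df$voucher_id <- trimws(as.character(df$voucher_id))
  if (any(df$voucher_id == "" | is.na(df$voucher_id))) {
    stop("voucher_id must be non-empty for every record (rows ",
         paste(which(df$voucher_id == "" | is.na(df$voucher_id)), collapse = ", "),
         ")")
  }
  dup <- duplicated(df$voucher_id)
  if (any(dup)) {
    v <- df$voucher_id[dup][1L]
    rows <- which(df$voucher_id == v)
    stop("duplicate voucher_id '", v, "' at rows ",
         paste(rows, collapse = " and "))
  }

  for (col in c("latitude", "longitude", "geocode_error_km")) {
    if (!is.numeric(df[[col]])) {
      raw <- trimws(as.character(df[[col]]))
      raw[raw == ""] <- NA_character_
      parsed <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(parsed))
      for (r in bad) note(r, col, paste0("unparseable value '", raw[r], "'"))
      df[[col]] <- parsed
    }
  }

  bad_lat <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
  for (r in bad_lat) note(r, "latitude", "latitude outside [-90, 90]")
  df$latitude[bad_lat] <- NA_real_
  bad_lon <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
  for (r in bad_lon) note(r, "longitude", "longitude outside [-180, 180]")
  df$longitude[bad_lon] <- NA_real_
  bad_err <- which(!is.na(df$geocode_error_km) & df$geocode_error_km < 0)
  for (r in bad_err) note(r, "geocode_error_km", "negative geocode error")
  df$geocode_error_km[bad_err] <- NA_real_

  lone <- xor(is.na(df$latitude), is.na(df$longitude))
  for (r in which(lone)) {
    note(r, "coordinates", "only one of latitude/longitude present; both dropped")
  }
  df$latitude[lone] <- NA_real_
  df$longitude[lone] <- NA_real_

  df$sex <- tolower(trimws(as.character(df$sex)))
  df$sex[df$sex %in% c("m", "male")] <- "male"
  df$sex[df$sex %in% c("f", "female")] <- "female"
  df$sex[!(df$sex %in% c("male", "female"))] <- "unknown"

  for (col in c("morph", "morph_group", "subspecies", "country", "locality")) {
    df[[col]] <- trimws(as.character(df[[col]]))
    df[[col]][is.na(df[[col]])] <- ""
  }

  sexed <- df$morph != "" & df$sex != "female"
  if (any(sexed)) {
    warning(sum(sexed), " record(s) carry a morph label but are not sexed female ",
            "(e.g. voucher ", df$voucher_id[which(sexed)[1L]], ")")
    for (r in which(sexed)) note(r, "morph", "morph label on non-female record")
  }

  rownames(df) <- NULL
  structure(df,
            provenance = provenance,
            problems = problems,
            class = c("record_set", "data.frame"))
}

#' @export
print.record_set <- function(x, ...) {
  cat("Record set:", nrow(x), "specimen record(s)\n")
  cat("  provenance:", attr(x, "provenance"), "\n")
  geo <- sum(!is.na(x$latitude) & !is.na(x$longitude))
  cat("  geocoded:", geo, "of", nrow(x), "\n")
  pr <- attr(x, "problems")
  if (!is.null(pr) && nrow(pr) > 0) {
    cat("  validation problems:", nrow(pr),
        "(see record_problems())\n")
  }
  invisible(x)
}

#' Row-level validation problems of a record set
#'
#' @param rs a `record_set`.
#' @return data frame with columns `row`, `voucher_id`, `field`, `message`.
#' @export
record_problems <- function(rs) {
  pr <- attr(rs, "problems")
  if (is.null(pr)) {
    pr <- data.frame(row = integer(), voucher_id = character(),
                     field = character(), message = character(),
                     stringsAsFactors = FALSE)
  }
  pr
}

#' Read specimen records from CSV
#'
#' The file must have a header row naming at least the canonical columns (see
#' [record_set]); unknown columns are preserved as opaque metadata. Blank
#' coordinate and error cells become missing values. Duplicate voucher ids are
#' a hard error; an unparseable coordinate is collected as a record-level
#' problem and the coordinate set missing.
#'
#' @param path path to a UTF-8 CSV file.
#' @param provenance source label; defaults to the file path.
#' @return a [record_set].
#' @export
read_records <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(c("voucher_id"), names(df))
  if (length(missing_cols) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  record_set(df, provenance = provenance)
}

#' Write specimen records to CSV
#'
#' Inverse of [read_records]: canonical columns first, extra columns after,
#' missing values as empty cells. `write_records` followed by [read_records]
#' is the identity on all fields.
#'
#' @param rs a [record_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path) {
  df <- as.data.frame(rs)
  extra <- setdiff(names(df), .record_columns)
  df <- df[, c(.record_columns, extra), drop = FALSE]
  for (col in c("latitude", "longitude", "geocode_error_km")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", format_num(df[[col]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

# fixed-format numeric rendering so that identical data give identical bytes
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.10g", v)
  }, character(1))
  out
}

#' Filter records to reliably geocoded ones
#'
#' Retains exactly the records with both coordinates present and a geocode
#' error strictly below `max_error_km` (records with no recorded error are
#' treated as unverified and dropped). The default threshold of 40 km matches
#' the gazetteer-matching accuracy cut used when the collection was geocoded;
#' the inequality is strict, so an error of exactly 40 km is excluded. Order
#' is preserved and the operation is idempotent and monotone in the threshold.
#'
#' @param rs a [record_set].
#' @param max_error_km positive threshold in kilometres (default 40).
#' @return the filtered [record_set].
#' @export
filter_geocoded <- function(rs, max_error_km = 40) {
  stopifnot(is.numeric(max_error_km), length(max_error_km) == 1L,
            max_error_km > 0)
  keep <- !is.na(rs$latitude) & !is.na(rs$longitude) &
    !is.na(rs$geocode_error_km) & rs$geocode_error_km < max_error_km
  out <- rs[keep, , drop = FALSE]
  rownames(out) <- NULL
  pr <- record_problems(rs)
  attr(out, "provenance") <- attr(rs, "provenance")
  attr(out, "problems") <- pr[pr$row %in% which(keep), , drop = FALSE]
  class(out) <- c("record_set", "data.frame")
  out
}

#' Tabulate records by a categorical field
#'
#' Counts records per level of `by`, sorted by decreasing count with
#' alphabetical tie-break. Counts always sum to the number of records; empty
#' labels are tallied under `""`.
#'
#' @param rs a [record_set].
#' @param by one of `"country"`, `"sex"`, `"morph_group"`, `"subspecies"`,
#'   `"morph"`.
#' @return data frame with columns `key` and `count`.
#' @export
tabulate_records <- function(rs,
                             by = c("country", "sex", "morph_group",
                                    "subspecies", "morph")) {
  by <- match.arg(by)
  if (nrow(rs) == 0) {
    return(data.frame(key = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(rs[[by]])
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
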