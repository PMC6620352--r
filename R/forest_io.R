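#' Read a stem census table
#'
#' Reads a one-row-per-stem census CSV into the canonical in-memory form:
#' a data frame with columns `tag` (unique stem identifier), `species`
#' (species code), `dbh` (diameter at breast height, cm) and optional plot
#' coordinates `x`, `y` (m). Rows that cannot be interpreted (non-numeric or
#' non-positive dbh, missing tag or species) are rejected and returned with
#' a reason rather than silently dropped; missing mandatory columns are a
#' fatal error naming the column.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Optional named list (or path to a YAML file) mapping
#'   canonical column names (`tag`, `species`, `dbh`, `x`, `y`) to the names
#'   used in the file, e.g. `list(tag = "StemTag", dbh = "DBH_cm")`.
#' @return A list with `trees` (accepted records, columns
#'   `tag, species, dbh[, x, y]`), `rejected` (data frame of rejected rows
#'   with a `reason` column), and counts `n_accepted`, `n_rejected`.
#' @seealso [write_census()], [filter_min_dbh()], [read_traits()]
#' @export
read_census <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("census file not found: ", path, call. = FALSE)
  dialect <- load_dialect(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (canon in names(dialect)) {
    from <- dialect[[canon]]
    if (from %in% names(raw)) names(raw)[names(raw) == from] <- canon
  }
  mandatory <- c("tag", "species", "dbh")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("census file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  dbh <- suppressWarnings(as.numeric(raw$dbh))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(dbh)] <- "non-numeric dbh"
  reason[!is.na(dbh) & dbh <= 0] <- "non-positive dbh"
  reason[is.na(reason) & !nzchar(trimws(raw$tag))] <- "missing tag"
  reason[is.na(reason) & !nzchar(trimws(raw$species))] <- "missing species"

  keep <- is.na(reason)
  dup <- duplicated(raw$tag[keep]) | duplicated(raw$tag[keep], fromLast = TRUE)
  if (any(dup)) {
    stop("duplicated stem tag(s) in census: ",
         paste(unique(raw$tag[keep][dup]), collapse = ", "), call. = FALSE)
  }

  trees <- data.frame(tag = raw$tag[keep], species = raw$species[keep],
                      dbh = dbh[keep], stringsAsFactors = FALSE)
  for (coord in c("x", "y")) {
    if (coord %in% names(raw)) {
      trees[[coord]] <- suppressWarnings(as.numeric(raw[[coord]][keep]))
    }
  }
  rejected <- cbind(raw[!keep, , drop = FALSE],
                    data.frame(reason = reason[!keep], stringsAsFactors = FALSE))
  rownames(trees) <- rownames(rejected) <- NULL
  list(trees = trees, rejected = rejected,
       n_accepted = nrow(trees), n_rejected = nrow(rejected))
}

load_dialect <- function(dialect) {
  if (is.null(dialect)) return(list())
  if (is.character(dialect) && length(dialect) == 1) {
    dialect <- yaml::read_yaml(dialect)
    if (!is.null(dialect$columns)) dialect <- dialect$columns
  }
  stopifnot(is.list(dialect))
  dialect
}

#' Write a census table to CSV
#'
#' Inverse of [read_census()]: the written file round-trips through
#' `read_census()` field-for-field.
#'
#' @param trees Census data frame (`tag, species, dbh[, x, y]`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(trees, path) {
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species-trait table
#'
#' Reads the per-species trait CSV: species code, genus, family, wood
#' specific gravity (`wsg`, g/cm^3, may be empty pending imputation), the
#' provenance of that value (`wsg_source`, one of `species_db`,
#' `field_sample`, `genus_median`, `family_median`, or empty), and the
#' pipe-delimited list of seed-disperser groups. Unknown group codes are a
#' fatal error naming the code.
#'
#' @param path Path to the traits CSV.
#' @param empty_groups What to do with an empty `dispersal_groups` cell:
#'   `"error"` (default) or `"unclassified"` (coerce to the unclassified
#'   group).
#' @return Data frame with columns `species, genus, family, wsg, wsg_source`
#'   and a list-column `dispersal_groups` of character vectors.
#' @export
read_traits <- function(path, empty_groups = c("error", "unclassified")) {
  empty_groups <- match.arg(empty_groups)
  if (!file.exists(path)) stop("traits file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  mandatory <- c("species", "genus", "family", "wsg", "dispersal_groups")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("traits file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$species)) {
    stop("duplicated species code(s) in traits: ",
         paste(unique(raw$species[duplicated(raw$species)]), collapse = ", "),
         call. = FALSE)
  }
  wsg <- suppressWarnings(as.numeric(raw$wsg))
  bad <- !is.na(wsg) & (wsg <= 0 | wsg >= 1.5)
  if (any(bad)) {
    stop("wood specific gravity outside (0, 1.5) for: ",
         paste(raw$species[bad], collapse = ", "), call. = FALSE)
  }
  traits <- data.frame(species = raw$species, genus = raw$genus,
                       family = raw$family, wsg = wsg,
                       wsg_source = if ("wsg_source" %in% names(raw))
                         raw$wsg_source else NA_character_,
                       stringsAsFactors = FALSE)
  traits$wsg_source[!nzchar(trimws(ifelse(is.na(traits$wsg_source), "",
                                          traits$wsg_source)))] <- NA_character_
  traits$dispersal_groups <- parse_groups(raw$dispersal_groups,
                                          empty = empty_groups)
  traits
}

#' Write a species-trait table to CSV
#'
#' Inverse of [read_traits()]; `dispersal_groups` is serialized as a
#' pipe-delimited code list.
#'
#' @param traits Traits data frame as returned by [read_traits()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traits <- function(traits, path) {
  out <- traits
  out$dispersal_groups <- format_groups(traits$dispersal_groups)
  out$wsg_source[is.na(out$wsg_source)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the minimum-diameter census filter
#'
#' The analysis considers stems with dbh at or above a threshold (5 cm by
#' convention for this allometry); the bound is inclusive. Input order is
#' preserved.
#'
#' @param trees Census data frame.
#' @param min_dbh Threshold in cm (> 0); default 5.
#' @return The subset of `trees` with `dbh >= min_dbh`.
#' @export
filter_min_dbh <- function(trees, min_dbh = 5) {
  stopifnot(is.numeric(min_dbh), length(min_dbh) == 1, min_dbh > 0)
  out <- trees[trees$dbh >= min_dbh, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check that every census species resolves in the trait table
#'
#' @param trees Census data frame.
#' @param traits Traits data frame.
#' @param strict If `TRUE` (default) unresolved species are a fatal error
#'   listing the codes; if `FALSE` the offending stems are dropped and
#'   reported in the `dropped` attribute.
#' @return `trees`, possibly subset, invisibly unchanged when all resolve.
#' @export
resolve_species <- function(trees, traits, strict = TRUE) {
  unresolved <- setdiff(unique(trees$species), traits$species)
  if (length(unresolved) == 0) return(trees)
  if (strict) {
    stop("census species missing from trait table: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }
  keep <- !(trees$species %in% unresolved)
  out <- trees[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- trees[!keep, , drop = FALSE]
  out
}
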