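#' @importFrom data.table fread fwrite as.data.table
NULL

META_COLS <- c("species", "plant_type", "elevation_m", "replicate")
PLANT_TYPES <- c("ephemeral", "non_ephemeral")

#' Validate a trait table
#'
#' Checks a wide-format trait table (one row per sample, one column per
#' trait code) against a catalog: mandatory metadata columns present,
#' plant types valid, elevations positive, no duplicated
#' (species, elevation, replicate) key, trait columns numeric. Missing
#' values stay `NA`; they are never silently replaced.
#'
#' @param table A data.frame with columns `species`, `plant_type`,
#'   `elevation_m`, `replicate` plus trait columns.
#' @param catalog Trait catalog (see [default_catalog()]).
#' @return The validated data.frame, invisibly augmented with attribute
#'   `"trait_codes"` (the catalog codes present).
#' @export
validate_trait_table <- function(table, catalog = default_catalog()) {
  stopifnot(is.data.frame(table))
  missing_meta <- setdiff(META_COLS, names(table))
  if (length(missing_meta))
    stop("trait table schema error: missing mandatory column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  bad_type <- setdiff(unique(table$plant_type), PLANT_TYPES)
  if (length(bad_type))
    stop("unknown plant_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(table$elevation_m) || any(!is.finite(table$elevation_m)) ||
      any(table$elevation_m <= 0))
    stop("elevation_m must be finite and > 0", call. = FALSE)
  key <- paste(table$species, table$elevation_m, table$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (species, elevation, replicate) key at row ",
         which(duplicated(key))[1], call. = FALSE)

  extra <- setdiff(names(table), c(META_COLS, catalog$code))
  if (length(extra))
    message("unknown column(s) ignored by analyses: ",
            paste(extra, collapse = ", "))
  codes <- intersect(catalog$code, names(table))
  if (!length(codes))
    stop("no catalog trait columns found in table", call. = FALSE)
  for (code in codes) {
    v <- table[[code]]
    if (!is.numeric(v)) {
      suspect <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in trait column '", code, "' at row ",
           if (length(suspect)) suspect[1] else 1L, call. = FALSE)
    }
  }
  attr(table, "trait_codes") <- codes
  table
}

#' Read a trait table from CSV
#'
#' Wide format: a header row naming the metadata columns (`species`,
#' `plant_type`, `elevation_m`, `replicate`) and one column per trait code.
#'
#' @inheritParams validate_trait_table
#' @param path Path to a comma-separated UTF-8 file with a header row.
#' @return A validated trait table (data.frame).
#' @export
read_trait_table <- function(path, catalog = default_catalog()) {
  df <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                        check.names = FALSE))
  validate_trait_table(df, catalog)
}

#' Write a trait table to CSV
#'
#' Numeric values are written with round-trip precision so that
#' `read_trait_table(write_trait_table(x))` reproduces `x` exactly.
#'
#' @param table A trait table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  out <- table
  for (j in names(out))
    if (is.double(out[[j]]) && j != "elevation_m")
      out[[j]] <- sprintf("%.17g", out[[j]])  # exact double round trip
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Convert a long trait table to wide format
#'
#' @param long A data.frame with columns `species`, `plant_type`,
#'   `elevation_m`, `replicate`, `trait` (code) and `value`.
#' @return A wide trait table, one column per trait code.
#' @export
long_to_wide <- function(long) {
  need <- c(META_COLS, "trait", "value")
  missing <- setdiff(need, names(long))
  if (length(missing))
    stop("long table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dt <- data.table::as.data.table(long)
  wide <- data.table::dcast(
    dt, species + plant_type + elevation_m + replicate ~ trait,
    value.var = "value")
  as.data.frame(wide)
}

#' Trait codes present in a table
#' @param table A trait table.
#' @param catalog Trait catalog.
#' @return Character vector of catalog codes found among the columns.
#' @export
trait_codes <- function(table, catalog = default_catalog()) {
  intersect(catalog$code, names(table))
}

#' Extract the numeric trait matrix from a trait table
#' @inheritParams trait_codes
#' @return Numeric matrix, samples x traits.
#' @keywords internal
trait_matrix <- function(table, catalog = default_catalog()) {
  codes <- trait_codes(table, catalog)
  as.matrix(table[, codes, drop = FALSE])
}
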