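#' Importance values from a quadrat survey
#'
#' For each species, computes its relative frequency (number of quadrats
#' occupied), relative density (total individual count) and relative
#' coverage (total cover), each normalized to sum to 1 over species, and
#' the importance value
#' `IV = (relative frequency + relative density + relative coverage) / 3`.
#'
#' @param survey A data.frame with columns `plot`, `quadrat`, `species`,
#'   `count` and `cover` (cover as a fraction of quadrat area).
#' @param frequency_unit Sampling unit used to count occurrences for the
#'   frequency component: `"quadrat"` (default) or `"plot"`.
#' @return A data.frame (one row per species, sorted by species) with
#'   columns `species`, `relative_frequency`, `relative_density`,
#'   `relative_coverage`, `importance_value`, plus attribute
#'   `"zero_cover"` flagging the degenerate all-zero-cover case (then the
#'   coverage component is set to 0 for all species and IV averages the
#'   remaining components over 3).
#' @export
importance_value <- function(survey, frequency_unit = c("quadrat", "plot")) {
  frequency_unit <- match.arg(frequency_unit)
  need <- c("plot", "quadrat", "species", "count", "cover")
  missing <- setdiff(need, names(survey))
  if (length(missing))
    stop("survey missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  survey <- survey[survey$count > 0 | survey$cover > 0, , drop = FALSE]
  if (!nrow(survey)) stop("empty survey", call. = FALSE)
  if (any(survey$count < 0) || any(survey$cover < 0))
    stop("counts and covers must be nonnegative", call. = FALSE)

  species <- sort(unique(survey$species))
  unit <- if (frequency_unit == "quadrat")
    paste(survey$plot, survey$quadrat, sep = "\r") else survey$plot
  freq <- vapply(species, function(s)
    length(unique(unit[survey$species == s])), numeric(1))
  dens <- vapply(species, function(s)
    sum(survey$count[survey$species == s]), numeric(1))
  cov <- vapply(species, function(s)
    sum(survey$cover[survey$species == s]), numeric(1))

  rel <- function(x) if (sum(x) > 0) x / sum(x) else rep(0, length(x))
  zero_cover <- sum(cov) == 0
  rf <- rel(freq); rd <- rel(dens); rc <- rel(cov)
  iv <- (rf + rd + rc) / 3
  out <- data.frame(species = species, relative_frequency = rf,
                    relative_density = rd, relative_coverage = rc,
                    importance_value = iv, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "zero_cover") <- zero_cover
  if (zero_cover)
    warning("all covers are zero; coverage component set to 0 for all species")
  out
}

#' Rank species by importance value
#'
#' @param iv An importance-value table from [importance_value()].
#' @param top_k Number of species to return (`>= 1`). When `top_k`
#'   exceeds the number of species, all are returned with a warning.
#' @return Character vector of species, by decreasing IV; ties are broken
#'   by species label in ascending order.
#' @export
rank_species <- function(iv, top_k = 15L) {
  if (top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  ord <- order(-iv$importance_value, iv$species)
  if (top_k > nrow(iv)) {
    warning("top_k exceeds number of species; returning all")
    top_k <- nrow(iv)
  }
  iv$species[ord][seq_len(top_k)]
}
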