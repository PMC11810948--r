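#' The default 26-trait catalog
#'
#' Returns the catalog of 26 plant functional traits used throughout the
#' package, grouped into three categories: 7 economic, 11 nutrient and 8
#' defensive traits. Ratio traits use an underscore in the code (`LC_N` is
#' the leaf C:N ratio) so codes are valid column names.
#'
#' Units are metadata only; no conversion is ever applied.
#'
#' @return A data.frame with columns `code`, `full_name`, `category`
#'   (one of `"economic"`, `"nutrient"`, `"defensive"`), `organ`
#'   (`"leaf"`, `"root"` or `"whole"`) and `units`.
#' @examples
#' cat26 <- default_catalog()
#' table(cat26$category)
#' @export
default_catalog <- function() {
  def <- function(code, full_name, category, organ, units)
    data.frame(code = code, full_name = full_name, category = category,
               organ = organ, units = units, stringsAsFactors = FALSE)
  out <- rbind(
    # economic (7)
    def("LDMC", "leaf dry matter content",                  "economic", "leaf", "g/g"),
    def("SLA",  "specific leaf area",                       "economic", "leaf", "cm2/g"),
    def("LC",   "leaf carbon concentration",                "economic", "leaf", "%"),
    def("LN",   "leaf nitrogen concentration",              "economic", "leaf", "%"),
    def("LP",   "leaf phosphorus concentration",            "economic", "leaf", "%"),
    def("LC_N", "leaf carbon to nitrogen ratio",            "economic", "leaf", "ratio"),
    def("LN_P", "leaf nitrogen to phosphorus ratio",        "economic", "leaf", "ratio"),
    # nutrient (11)
    def("RC",   "root carbon concentration",                "nutrient", "root", "%"),
    def("RN",   "root nitrogen concentration",              "nutrient", "root", "%"),
    def("RP",   "root phosphorus concentration",            "nutrient", "root", "%"),
    def("RC_N", "root carbon to nitrogen ratio",            "nutrient", "root", "ratio"),
    def("RN_P", "root nitrogen to phosphorus ratio",        "nutrient", "root", "ratio"),
    def("LSS",  "leaf soluble sugar concentration",         "nutrient", "leaf", "mg/g"),
    def("LS",   "leaf starch concentration",                "nutrient", "leaf", "mg/g"),
    def("LNSC", "leaf nonstructural carbohydrates",         "nutrient", "leaf", "mg/g"),
    def("RSS",  "root soluble sugar concentration",         "nutrient", "root", "mg/g"),
    def("RS",   "root starch concentration",                "nutrient", "root", "mg/g"),
    def("RNSC", "root nonstructural carbohydrates",         "nutrient", "root", "mg/g"),
    # defensive (8)
    def("LCC",  "leaf cellulose content",                   "defensive", "leaf", "mg/g"),
    def("LLC",  "leaf lignin content",                      "defensive", "leaf", "mg/g"),
    def("LTPC", "leaf total phenols concentration",         "defensive", "leaf", "mg/g"),
    def("LTFC", "leaf total flavonoids concentration",      "defensive", "leaf", "mg/g"),
    def("RCC",  "root cellulose content",                   "defensive", "root", "mg/g"),
    def("RLC",  "root lignin content",                      "defensive", "root", "mg/g"),
    def("RTPC", "root total phenols concentration",         "defensive", "root", "mg/g"),
    def("RTFC", "root total flavonoids concentration",      "defensive", "root", "mg/g")
  )
  stopifnot(!anyDuplicated(out$code))
  out
}

#' Trait categories as a named vector
#'
#' @param catalog A trait catalog, as returned by [default_catalog()].
#' @return Named character vector mapping trait code to category.
#' @keywords internal
trait_categories <- function(catalog = default_catalog()) {
  stats::setNames(catalog$category, catalog$code)
}
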