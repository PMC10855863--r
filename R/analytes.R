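#' Supported serum analytes
#'
#' The three placenta-derived serum biomarkers handled by the package:
#' the free beta-subunit of human chorionic gonadotropin (`"free_bhcg"`,
#' IU/L), pregnancy-associated plasma protein-A (`"pappa"`, IU/L) and
#' placental growth factor (`"plgf"`, pg/mL).
#'
#' @return Character vector of canonical analyte identifiers.
#' @export
#' @examples
#' analytes()
analytes <- function() c("free_bhcg", "pappa", "plgf")

# assay detection limits (lower limit of quantification), analyte units
.detection_limits <- c(free_bhcg = 0.16, pappa = 0.004, plgf = 3.6)

.analyte_units <- c(free_bhcg = "IU/L", pappa = "IU/L", plgf = "pg/mL")

#' Assay detection limits
#'
#' Lower detection limits of the immunoassays, in each analyte's
#' concentration units (free beta-hCG 0.16 IU/L, PAPP-A 0.004 IU/L,
#' PlGF 3.6 pg/mL).
#'
#' @return Named numeric vector keyed by analyte identifier.
#' @export
detection_limits <- function() .detection_limits

#' @rdname analytes
#' @param analyte Analyte identifier (any case; `"FREE_BHCG"`, `"free_bhcg"`,
#'   `"PAPP-A"` style punctuation is tolerated).
#' @export
match_analyte <- function(analyte) {
  key <- gsub("[^a-z0-9]", "_", tolower(as.character(analyte)))
  key <- sub("^papp_a$", "pappa", key)
  bad <- !key %in% analytes()
  if (any(bad)) {
    rlang::abort(sprintf(
      "Unknown analyte '%s'; expected one of %s.",
      paste(unique(analyte[bad]), collapse = ", "),
      paste(analytes(), collapse = ", ")
    ))
  }
  key
}

analyte_units <- function(analyte) unname(.analyte_units[match_analyte(analyte)])
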