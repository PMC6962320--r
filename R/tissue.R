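#' Tissue class codes and groups
#'
#' The eight lung-parenchyma tissue patterns handled by the package: normal
#' parenchyma (NP), the five interstitial patterns ground glass (GG),
#' reticular (RETIC), nodular (NOD), linear scar (LINSC) and subpleural line
#' (SUBPL), and the two emphysema patterns paraseptal (PS) and centrilobular
#' (CL). The class order is fixed and is the tie-break order used by the
#' ensemble decision rule (lowest index wins).
#'
#' @return `tissue_classes()` returns the character vector of the 8 codes in
#'   canonical order. `tissue_groups()` returns a named character vector
#'   mapping each code to one of `"healthy"`, `"interstitial"`,
#'   `"emphysema"`. `interstitial_classes()` returns the five interstitial
#'   codes (the default ILA-defining set).
#' @examples
#' tissue_classes()
#' tissue_groups()[["GG"]]
#' @export
tissue_classes <- function() {
  c("NP", "GG", "RETIC", "NOD", "LINSC", "SUBPL", "PS", "CL")
}

#' @rdname tissue_classes
#' @export
tissue_groups <- function() {
  c(NP = "healthy",
    GG = "interstitial", RETIC = "interstitial", NOD = "interstitial",
    LINSC = "interstitial", SUBPL = "interstitial",
    PS = "emphysema", CL = "emphysema")
}

#' @rdname tissue_classes
#' @export
interstitial_classes <- function() {
  names(tissue_groups())[tissue_groups() == "interstitial"]
}

# Validate a vector of labels against the 8-class enumeration; returns a
# factor with the canonical level order.
as_tissue_factor <- function(x) {
  x <- as.character(x)
  bad <- which(!(x %in% tissue_classes()))
  if (length(bad) > 0) {
    stop_lungtex(sprintf(
      "unknown tissue label(s) %s at row(s) %s; valid labels are %s",
      paste(unique(x[bad]), collapse = ", "),
      paste(head(bad, 10L), collapse = ", "),
      paste(tissue_classes(), collapse = ", ")),
      "lungtex_validation_error")
  }
  factor(x, levels = tissue_classes())
}
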