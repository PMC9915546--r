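#' Trace metals covered by the assessment
#'
#' The panel of trace metals handled throughout the package, in the fixed
#' order used for all tabular output.
#'
#' @return Character vector `c("Cd", "Cr", "Cu", "Pb", "V", "Zn")`.
#' @export
#' @examples
#' metal_ids()
metal_ids <- function() {
  c("Cd", "Cr", "Cu", "Pb", "V", "Zn")
}

#' Names of the soil physicochemical covariates
#'
#' pH (dimensionless), soil organic matter (g/kg), dithionite-citrate-
#' bicarbonate extractable free Fe and Al oxides (g/kg), and available
#' N, P, K (mg/kg).
#'
#' @return Character vector of column names.
#' @export
soil_covariates <- function() {
  c("pH", "som", "dcb_fe", "dcb_al", "avail_n", "avail_p", "avail_k")
}

# internal: assert a numeric vector is finite and strictly positive
check_positive <- function(x, what, rows = NULL) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    where <- if (is.null(rows)) which(bad) else rows[bad]
    stop(sprintf("non-positive concentration in %s (row %s)",
                 what, paste(where, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# internal: named numeric over all six metals, error listing whichever miss
check_metal_table <- function(x, what) {
  x <- unlist(x)
  missing <- setdiff(metal_ids(), names(x))
  if (length(missing) > 0) {
    stop(sprintf("config error: %s is missing metals: %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[metal_ids()]
  if (any(!is.finite(x) | x <= 0)) {
    stop(sprintf("config error: %s has non-positive entries", what),
         call. = FALSE)
  }
  x
}
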