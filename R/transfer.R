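#' Soil-to-vegetable bioaccumulation factors
#'
#' For every vegetable sample and metal, the bioaccumulation factor is the
#' ratio of the edible-part content (mg/kg fresh weight) to the paired soil
#' content (mg/kg dry weight): `BAF = C_veg(fw) / C_soil`.
#'
#' @param dataset A `paired_dataset`.
#' @return data.frame with one row per vegetable x metal: `vegetable_id`,
#'   `species`, `soil_id`, `metal`, `c_veg_fw`, `c_soil`, `baf`.
#' @export
compute_baf <- function(dataset) {
  stopifnot(inherits(dataset, "paired_dataset"))
  veg <- dataset$veg
  soil <- dataset$soil
  idx <- match(veg$soil_id, soil$sample_id)
  if (anyNA(idx)) {
    stop("unpaired vegetable sample(s): ",
         paste(veg$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  metals <- metal_ids()
  recs <- lapply(metals, function(m) {
    data.frame(vegetable_id = veg$sample_id,
               species = veg$species,
               soil_id = veg$soil_id,
               metal = m,
               c_veg_fw = veg[[m]],
               c_soil = soil[[m]][idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$baf <- out$c_veg_fw / out$c_soil
  out$metal <- factor(out$metal, levels = metals)
  out[order(out$metal, out$vegetable_id), , drop = FALSE]
}

#' Aggregate bioaccumulation factors per metal, overall or by species
#'
#' The default aggregate is the arithmetic mean of member BAFs; a geometric
#' mean is available since BAF distributions are strongly right-skewed.
#' Groups with a single member are kept and flagged.
#'
#' @param records BAF records from [compute_baf()].
#' @param by_species If `TRUE`, aggregate per species x metal; otherwise one
#'   "all" group per metal.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return data.frame with columns `species`, `metal`, `mean_baf`, `n`,
#'   `single` (logical flag for n = 1).
#' @export
summarize_baf <- function(records, by_species = FALSE,
                          method = c("arithmetic", "geometric")) {
  if (nrow(records) < 1) stop("summarize_baf: no records", call. = FALSE)
  method <- match.arg(method)
  agg <- function(x) if (method == "arithmetic") mean(x) else exp(mean(log(x)))
  group <- if (by_species) records$species else rep("all", nrow(records))
  key <- interaction(group, records$metal, drop = FALSE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    if (nrow(d) == 0) return(NULL)
    data.frame(species = if (by_species) d$species[1] else "all",
               metal = as.character(d$metal[1]),
               mean_baf = agg(d$baf),
               n = nrow(d),
               single = nrow(d) == 1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$metal <- factor(out$metal, levels = metal_ids())
  out[order(out$metal, out$species), , drop = FALSE]
}

#' Fraction of vegetable samples exceeding maximum permissible levels
#'
#' Strict exceedance (ties compliant) against the food-safety maximum
#' permissible levels; metals without a defined MPL are reported as `NA`
#' rather than raising an error.
#'
#' @param veg Vegetable data.frame (the `veg` element of a
#'   `paired_dataset`).
#' @param mpl Named numeric of MPLs (mg/kg fresh weight), e.g.
#'   `reference_tables()$veg_mpl`.
#' @return Named numeric over all metals; `NA` where no MPL is defined.
#' @export
mpl_exceedance <- function(veg, mpl) {
  vapply(metal_ids(), function(m) {
    if (!m %in% names(mpl)) return(NA_real_)
    exceedance_fraction(veg[[m]], mpl[[m]])
  }, numeric(1))
}

#' Correlation of bioaccumulation factors with soil properties
#'
#' For each metal, Pearson correlations (two-sided p-values) of the
#' per-sample BAF against each soil physicochemical covariate and against
#' the soil total content of the same metal. Computed on untransformed BAF
#' by default; `log_baf = TRUE` correlates `log(BAF)` instead. All species
#' are pooled unless `by_species` is set.
#'
#' @param dataset A `paired_dataset`.
#' @param records BAF records from [compute_baf()]; recomputed when `NULL`.
#' @param log_baf Correlate log-transformed BAF values.
#' @param by_species Add per-species stratified rows.
#' @return data.frame with columns `species`, `metal`, `covariate`, `r`,
#'   `p`, `n`; `r` is `NA` with zero-variance input.
#' @export
baf_property_correlation <- function(dataset, records = NULL,
                                     log_baf = FALSE, by_species = FALSE) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (is.null(records)) records <- compute_baf(dataset)
  soil <- dataset$soil
  covs <- c(soil_covariates(), "soil_total")
  one_group <- function(recs, label) {
    do.call(rbind, lapply(metal_ids(), function(m) {
      d <- recs[recs$metal == m, , drop = FALSE]
      if (nrow(d) < 3) return(NULL)
      sidx <- match(d$soil_id, soil$sample_id)
      y <- if (log_baf) log(d$baf) else d$baf
      do.call(rbind, lapply(covs, function(cv) {
        x <- if (cv == "soil_total") d$c_soil else soil[[cv]][sidx]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          return(data.frame(species = label, metal = m, covariate = cv,
                            r = NA_real_, p = NA_real_, n = nrow(d),
                            stringsAsFactors = FALSE))
        }
        ct <- stats::cor.test(x, y, method = "pearson")
        data.frame(species = label, metal = m, covariate = cv,
                   r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  out <- one_group(records, "all")
  if (by_species) {
    for (sp in unique(records$species)) {
      out <- rbind(out,
                   one_group(records[records$species == sp, , drop = FALSE], sp))
    }
  }
  rownames(out) <- NULL
  out
}
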