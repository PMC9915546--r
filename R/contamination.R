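#' Summary statistics for a vector of concentrations
#'
#' Computes the summary used for soil and vegetable content tables: minimum,
#' median, maximum, arithmetic mean and SD, geometric mean and geometric SD
#' (the multiplicative factor `exp(sd(log(x)))`), and the coefficient of
#' variation `sd_arith / mean_arith`.
#'
#' @param values Numeric vector, all finite and strictly positive.
#' @return A `conc_summary` object (named list of the statistics plus `n`).
#' @export
#' @examples
#' summarize_conc(c(2, 8))  # geometric mean 4, arithmetic mean 5
summarize_conc <- function(values) {
  if (length(values) < 1) stop("summarize_conc: empty input", call. = FALSE)
  check_positive(values, "summarize_conc input")
  lx <- log(values)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  out <- list(
    n = length(values),
    minimum = min(values),
    median = stats::median(values),
    maximum = max(values),
    mean_arith = mean(values),
    sd_arith = sd0(values),
    mean_geo = exp(mean(lx)),
    sd_geo = exp(sd0(lx)),
    cv = sd0(values) / mean(values)
  )
  structure(out, class = "conc_summary")
}

#' @export
print.conc_summary <- function(x, ...) {
  cat(sprintf(
    "n=%d  min=%.4g  median=%.4g  max=%.4g  mean=%.4g (SD %.4g)  geomean=%.4g (GSD %.4g)  CV=%.2f\n",
    x$n, x$minimum, x$median, x$maximum, x$mean_arith, x$sd_arith,
    x$mean_geo, x$sd_geo, x$cv))
  invisible(x)
}

#' Geo-accumulation index
#'
#' `igeo = log2(c_soil / (1.5 * bv))`: the base-2 log ratio of the measured
#' soil content to 1.5 times the geochemical background value, the factor
#' 1.5 absorbing natural background fluctuation.
#'
#' @param c_soil Soil content, mg/kg (vectorised).
#' @param bv Background value, mg/kg.
#' @return Dimensionless index value(s).
#' @export
#' @examples
#' igeo(11.3, 0.41)  # 4.20
igeo <- function(c_soil, bv) {
  if (any(!is.finite(c_soil) | c_soil <= 0)) {
    stop("igeo: c_soil must be positive", call. = FALSE)
  }
  if (any(!is.finite(bv) | bv <= 0)) {
    stop("igeo: bv must be positive", call. = FALSE)
  }
  log2(c_soil / (1.5 * bv))
}

#' Classify a geo-accumulation index value on a class ladder
#'
#' Classes are half-open intervals `lower < value <= upper`; values above
#' the last finite bound take the top label. Total over the reals.
#'
#' @param value Index value(s).
#' @param ladder data.frame with strictly increasing `upper` bounds and
#'   `label`, as in [default_igeo_classes()].
#' @return Character vector of class labels.
#' @export
classify_igeo <- function(value, ladder = default_igeo_classes()) {
  stopifnot(nrow(ladder) >= 1, !is.unsorted(ladder$upper, strictly = TRUE))
  idx <- vapply(value, function(v) {
    i <- which(ladder$upper >= v)
    if (length(i) == 0) nrow(ladder) else i[1]
  }, integer(1))
  ladder$label[idx]
}

#' Per-metal geo-accumulation assessment of a soil table
#'
#' Applies [igeo()] to every sample and metal, and tabulates per-metal mean
#' index values and the fraction of samples in each contamination class.
#'
#' @param soil data.frame of soil samples (the `soil` element of a
#'   `paired_dataset`).
#' @param references A `reference_tables` object supplying background values
#'   and the class ladder.
#' @return An `igeo_result`: list with `values` (samples x metals matrix),
#'   `mean_igeo` (named per metal), and `class_fractions` (classes x metals
#'   matrix, columns summing to 1).
#' @export
igeo_assess <- function(soil, references) {
  stopifnot(inherits(references, "reference_tables"))
  metals <- metal_ids()
  vals <- sapply(metals, function(m) igeo(soil[[m]], references$background[[m]]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(soil),
                                         dimnames = list(NULL, metals))
  ladder <- references$igeo_classes
  fracs <- sapply(metals, function(m) {
    cl <- factor(classify_igeo(vals[, m], ladder), levels = ladder$label)
    as.vector(table(cl)) / nrow(soil)
  })
  rownames(fracs) <- ladder$label
  structure(list(values = vals,
                 mean_igeo = colMeans(vals),
                 class_fractions = fracs,
                 ladder = ladder),
            class = "igeo_result")
}

#' @export
print.igeo_result <- function(x, digits = 2, ...) {
  cat("Geo-accumulation assessment (", nrow(x$values), " samples)\n", sep = "")
  ord <- order(x$mean_igeo, decreasing = TRUE)
  m <- x$mean_igeo[ord]
  cat("  mean Igeo: ",
      paste(sprintf("%s %.*f", names(m), digits, m), collapse = " > "), "\n")
  invisible(x)
}

#' Fraction of values strictly exceeding a threshold
#'
#' Ties count as compliant (strict `>`), following standards practice for
#' "exceeding" a guideline value.
#'
#' @param values Numeric vector, non-empty.
#' @param threshold Positive threshold.
#' @return Fraction in [0, 1].
#' @export
exceedance_fraction <- function(values, threshold) {
  if (length(values) < 1) stop("exceedance_fraction: empty input", call. = FALSE)
  if (!is.finite(threshold) || threshold <= 0) {
    stop("exceedance_fraction: threshold must be positive", call. = FALSE)
  }
  mean(values > threshold)
}

#' Per-metal screening-value exceedance for a soil table
#'
#' @param soil Soil data.frame.
#' @param references A `reference_tables` supplying screening values.
#' @return Named numeric: fraction of samples above the screening value per
#'   metal.
#' @export
screening_exceedance <- function(soil, references) {
  stopifnot(inherits(references, "reference_tables"))
  vapply(metal_ids(), function(m) {
    exceedance_fraction(soil[[m]], references$screening[[m]])
  }, numeric(1))
}

#' Pearson correlation matrix of soil metal contents
#'
#' Pairwise Pearson correlations (two-sided p-values from the t
#' approximation) over the six metal columns, computed on raw contents by
#' default. A zero-variance column yields `NA` correlations with that metal,
#' flagged rather than raised.
#'
#' @param soil Soil data.frame with at least 3 rows.
#' @param log_scale If `TRUE`, correlate log-transformed contents.
#' @return List with matrices `r` and `p` (metals x metals) and character
#'   vector `degenerate` naming zero-variance metals.
#' @export
metal_correlation <- function(soil, log_scale = FALSE) {
  if (nrow(soil) < 3) stop("metal_correlation: need at least 3 samples",
                           call. = FALSE)
  metals <- metal_ids()
  x <- as.matrix(soil[, metals])
  if (log_scale) x <- log(x)
  degenerate <- metals[apply(x, 2, stats::sd) == 0]
  k <- length(metals)
  r <- matrix(NA_real_, k, k, dimnames = list(metals, metals))
  p <- r
  diag(r) <- 1
  diag(p) <- 0
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (metals[i] %in% degenerate || metals[j] %in% degenerate) next
      ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, degenerate = degenerate)
}

#' Principal component analysis of soil metal contents
#'
#' PCA on z-score-standardized metal columns (i.e. the correlation matrix),
#' no rotation. Per-metal contributions to a component are the squared
#' loadings normalised to sum to 100 within the component.
#'
#' @param soil Soil data.frame with at least `n_components + 1` rows.
#' @param n_components Number of components to retain (default 2).
#' @return A `source_stats` object: `explained_variance` (percent per
#'   component, non-increasing), `loadings` (metals x components),
#'   `contributions` (percent, metals x components, columns summing to 100),
#'   and the full `correlation` output of [metal_correlation()].
#' @export
metal_pca <- function(soil, n_components = 2) {
  metals <- metal_ids()
  if (nrow(soil) < n_components + 1) {
    stop("metal_pca: need at least n_components + 1 samples", call. = FALSE)
  }
  x <- as.matrix(soil[, metals])
  const <- metals[apply(x, 2, stats::sd) == 0]
  if (length(const) > 0) {
    stop("metal_pca: constant metal column(s): ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ncomp <- min(n_components, ncol(pc$rotation))
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  loadings <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  contrib <- apply(loadings, 2, function(l) 100 * l^2 / sum(l^2))
  structure(list(explained_variance = ev[seq_len(ncomp)],
                 explained_variance_all = ev,
                 loadings = loadings,
                 contributions = contrib,
                 correlation = metal_correlation(soil)),
            class = "source_stats")
}

#' @export
print.source_stats <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("Source apportionment: %d components explain %.1f%% of variance\n",
              length(ev), sum(ev)))
  for (i in seq_along(ev)) {
    top <- sort(x$contributions[, i], decreasing = TRUE)[1:3]
    cat(sprintf("  PC%d (%.1f%%): top contributors %s\n", i, ev[i],
                paste(sprintf("%s %.1f%%", names(top), top), collapse = ", ")))
  }
  invisible(x)
}
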