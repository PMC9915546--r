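#' Write result families as delimited report files
#'
#' One CSV per result family, stable column order. Rounding is applied only
#' here, at write time (`signif` to `digits` significant figures); all
#' in-memory results stay unrounded.
#'
#' @param results Named list of data.frames, one per result family.
#' @param out_dir Output directory (created if needed).
#' @param digits Significant figures for numeric columns (default 4).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, out_dir, digits = 4) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(results)) {
    d <- results[[nm]]
    if (!is.data.frame(d)) next
    if (nrow(d) == 0) {
      warning("result family '", nm, "' is empty; writing headers only",
              call. = FALSE)
    }
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], signif, digits = digits)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(d, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}

# flatten an igeo_result into report tables
igeo_tables <- function(ig) {
  metals <- metal_ids()
  per_metal <- data.frame(metal = metals,
                          mean_igeo = unname(ig$mean_igeo[metals]),
                          class = classify_igeo(unname(ig$mean_igeo[metals]),
                                                ig$ladder),
                          stringsAsFactors = FALSE)
  fr <- as.data.frame(ig$class_fractions)
  fr <- cbind(data.frame(class = rownames(ig$class_fractions),
                         stringsAsFactors = FALSE), fr)
  rownames(fr) <- NULL
  list(igeo = per_metal, igeo_class_fractions = fr)
}

# flatten a risk_summary into one report row
risk_row <- function(rs) {
  metals <- metal_ids()
  row <- data.frame(receptor = rs$receptor, species = rs$species,
                    percentile = rs$percentile, n_iter = rs$n_iter,
                    seed = rs$seed, hi_p = rs$hi_p,
                    safe = rs$safe, stringsAsFactors = FALSE)
  for (m in metals) row[[paste0("hq_p_", m)]] <- unname(rs$hq_p[m])
  for (m in metals) row[[paste0("contrib_", m)]] <- unname(rs$contribution[m])
  row
}

#' Run the full assessment pipeline on a paired dataset
#'
#' Executes, in order: per-metal summary statistics (soil and vegetable),
#' geo-accumulation assessment and screening-value exceedance, source
#' statistics (correlation matrix and PCA), bioaccumulation factors with
#' per-species aggregation, MPL exceedance, BAF-soil-property correlations,
#' and Monte Carlo ingestion risk per receptor for the pooled data and per
#' species. All report families plus a run manifest are written to
#' `out_dir`; any stage error aborts with a stage-named message and nothing
#' is written.
#'
#' @param soil_path,veg_path Paths to the soil and vegetable CSVs.
#' @param config_path Path to the YAML config (default: shipped config).
#' @param out_dir Output directory.
#' @param seed Integer seed for the Monte Carlo stage.
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param percentile Reporting percentile (default 0.9).
#' @return Invisibly, the named list of result data.frames.
#' @export
run_all <- function(soil_path, veg_path, config_path = default_config_path(),
                    out_dir, seed = 1, n_iter = 10000, percentile = 0.9) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dataset <- stage("load", read_paired_dataset(soil_path, veg_path))
  cfg <- stage("config", load_config(config_path))
  refs <- cfg$references
  metals <- metal_ids()

  results <- list()
  results$summary <- stage("summarize", {
    do.call(rbind, lapply(c("soil", "veg"), function(tab) {
      do.call(rbind, lapply(metals, function(m) {
        s <- summarize_conc(dataset[[tab]][[m]])
        data.frame(table = tab, metal = m, n = s$n, minimum = s$minimum,
                   median = s$median, maximum = s$maximum,
                   mean_arith = s$mean_arith, sd_arith = s$sd_arith,
                   mean_geo = s$mean_geo, sd_geo = s$sd_geo, cv = s$cv,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  ig <- stage("igeo", igeo_assess(dataset$soil, refs))
  results <- c(results, igeo_tables(ig))
  results$screening_exceedance <- stage("exceedance", {
    data.frame(metal = metals,
               screening_value = unname(refs$screening[metals]),
               exceedance_fraction =
                 unname(screening_exceedance(dataset$soil, refs)),
               stringsAsFactors = FALSE)
  })
  results <- c(results, stage("sources", {
    src <- metal_pca(dataset$soil, n_components = 2)
    corr <- src$correlation
    list(sources_correlation =
           cbind(data.frame(metal = metals, stringsAsFactors = FALSE),
                 as.data.frame(corr$r)),
         sources_pca = data.frame(
           metal = rep(metals, 2),
           component = rep(c("PC1", "PC2"), each = length(metals)),
           loading = c(src$loadings[, 1], src$loadings[, 2]),
           contribution_pct = c(src$contributions[, 1],
                                src$contributions[, 2]),
           explained_variance_pct = rep(src$explained_variance,
                                        each = length(metals)),
           stringsAsFactors = FALSE))
  }))
  baf_records <- stage("baf", compute_baf(dataset))
  results$baf_records <- baf_records
  results$baf_summary <- stage("baf", {
    rbind(summarize_baf(baf_records, by_species = FALSE),
          summarize_baf(baf_records, by_species = TRUE))
  })
  results$mpl_exceedance <- stage("baf", {
    frac <- mpl_exceedance(dataset$veg, refs$veg_mpl)
    data.frame(metal = metals,
               mpl = unname(refs$veg_mpl[metals]),
               exceedance_fraction = unname(frac),
               stringsAsFactors = FALSE)
  })
  results$baf_correlation <- stage("baf_correlation",
                                   baf_property_correlation(dataset,
                                                            baf_records))
  results$risk <- stage("risk", {
    groups <- c(list(NULL), as.list(unique(dataset$veg$species)))
    do.call(rbind, unlist(recursive = FALSE, lapply(groups, function(sp) {
      dists <- content_distributions_from_data(dataset$veg, sp)
      lapply(cfg$scenarios, function(sc) {
        risk_row(summarize_risk(mc_risk(dists, sc, n_iter = n_iter,
                                        seed = seed),
                                percentile = percentile))
      })
    })))
  })

  paths <- write_report_tables(results, out_dir)
  manifest <- list(
    soil_path = soil_path, veg_path = veg_path, config_path = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed, n_iter = n_iter, percentile = percentile,
    package_version = as.character(utils::packageVersion("vegrisk")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(results)
}
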