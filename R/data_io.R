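#' Read a paired soil-vegetable dataset from two delimited files
#'
#' Reads a soil table and a vegetable table (comma-separated, header row
#' mandatory, UTF-8, "." decimal separator) and validates them into a
#' `paired_dataset`: every vegetable's `soil_id` must resolve to exactly one
#' soil sample, sample ids must be unique within each table, and all metal
#' contents must be finite and strictly positive.
#'
#' Soil columns: `sample_id`, the covariates of [soil_covariates()], and one
#' column per metal of [metal_ids()] (mg/kg dry weight). Vegetable columns:
#' `sample_id`, `species`, `soil_id`, and the metal columns (mg/kg fresh
#' weight).
#'
#' @param soil_path Path to the soil CSV.
#' @param veg_path Path to the vegetable CSV.
#' @return A `paired_dataset` object: list with data.frames `soil` and `veg`.
#' @export
read_paired_dataset <- function(soil_path, veg_path) {
  for (p in c(soil_path, veg_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  soil <- utils::read.csv(soil_path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  veg <- utils::read.csv(veg_path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  paired_dataset(soil, veg)
}

#' Construct and validate a paired dataset from in-memory tables
#'
#' @param soil data.frame of soil samples (see [read_paired_dataset()]).
#' @param veg data.frame of vegetable samples.
#' @return A validated `paired_dataset` object.
#' @export
paired_dataset <- function(soil, veg) {
  need_soil <- c("sample_id", soil_covariates(), metal_ids())
  need_veg <- c("sample_id", "species", "soil_id", metal_ids())
  miss_s <- setdiff(need_soil, names(soil))
  if (length(miss_s) > 0) {
    stop("soil table missing column(s): ", paste(miss_s, collapse = ", "),
         call. = FALSE)
  }
  miss_v <- setdiff(need_veg, names(veg))
  if (length(miss_v) > 0) {
    stop("vegetable table missing column(s): ", paste(miss_v, collapse = ", "),
         call. = FALSE)
  }
  soil$sample_id <- as.character(soil$sample_id)
  veg$sample_id <- as.character(veg$sample_id)
  veg$soil_id <- as.character(veg$soil_id)
  veg$species <- as.character(veg$species)

  for (tab in list(list(soil, "soil"), list(veg, "vegetable"))) {
    d <- tab[[1]]
    dup <- d$sample_id[duplicated(d$sample_id)]
    if (length(dup) > 0) {
      stop(sprintf("duplicate sample_id in %s table: %s", tab[[2]],
                   paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(soil) > 0) {
    for (cv in soil_covariates()) {
      x <- soil[[cv]]
      if (!is.numeric(x) || any(!is.finite(x))) {
        stop("unparseable numeric in soil column ", cv, call. = FALSE)
      }
      if (any(x < 0)) stop("negative covariate in soil column ", cv,
                           call. = FALSE)
    }
    if (any(soil$pH <= 0 | soil$pH >= 14)) {
      stop("soil pH outside (0, 14)", call. = FALSE)
    }
    for (m in metal_ids()) {
      if (!is.numeric(soil[[m]])) {
        stop("unparseable numeric in soil column ", m, call. = FALSE)
      }
      check_positive(soil[[m]], paste0("soil ", m))
    }
  }
  if (nrow(veg) > 0) {
    for (m in metal_ids()) {
      if (!is.numeric(veg[[m]])) {
        stop("unparseable numeric in vegetable column ", m, call. = FALSE)
      }
      check_positive(veg[[m]], paste0("vegetable ", m))
    }
    dangling <- setdiff(veg$soil_id, soil$sample_id)
    if (length(dangling) > 0) {
      stop("vegetable soil_id not found in soil table: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(soil = soil[, need_soil], veg = veg[, need_veg]),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("Paired soil-vegetable dataset\n")
  cat(sprintf("  soils:      %d samples\n", nrow(x$soil)))
  cat(sprintf("  vegetables: %d samples (%d species)\n", nrow(x$veg),
              length(unique(x$veg$species))))
  cat("  metals:     ", paste(metal_ids(), collapse = ", "), "\n")
  invisible(x)
}

#' Write a paired dataset to two CSV files
#'
#' Inverse of [read_paired_dataset()]; numeric fields are written at full
#' precision so that write-then-read round-trips exactly.
#'
#' @param dataset A `paired_dataset`.
#' @param soil_path,veg_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_paired_dataset <- function(dataset, soil_path, veg_path) {
  stopifnot(inherits(dataset, "paired_dataset"))
  write_csv_full <- function(d, p) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
    utils::write.csv(d, p, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  write_csv_full(dataset$soil, soil_path)
  write_csv_full(dataset$veg, veg_path)
  invisible(c(soil_path, veg_path))
}

#' Reference tables: background, screening and food-limit values
#'
#' Bundles the per-metal geochemical background values (BV, mg/kg dry soil),
#' regulatory soil screening values (SV, mg/kg), vegetable maximum
#' permissible levels (MPL, mg/kg fresh weight; defined only for some
#' metals), and the ordered geo-accumulation class ladder.
#'
#' @param background Named numeric, one entry per metal (mg/kg).
#' @param screening Named numeric, one entry per metal (mg/kg).
#' @param veg_mpl Named numeric over a subset of metals (mg/kg fresh).
#' @param igeo_classes data.frame with columns `upper` (strictly increasing
#'   upper bounds, last may be `Inf`) and `label`.
#' @param screening_source Optional named character flagging the provenance
#'   of individual screening values (e.g. the Canadian guideline for V).
#' @return A `reference_tables` object.
#' @export
reference_tables <- function(background, screening, veg_mpl = numeric(),
                             igeo_classes = default_igeo_classes(),
                             screening_source = character()) {
  background <- check_metal_table(background, "background values")
  screening <- check_metal_table(screening, "screening values")
  veg_mpl <- unlist(veg_mpl)
  if (length(veg_mpl) > 0) {
    bad <- setdiff(names(veg_mpl), metal_ids())
    if (length(bad) > 0) stop("unknown metal in veg_mpl: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    if (any(veg_mpl <= 0)) stop("config error: veg_mpl has non-positive entries",
                                call. = FALSE)
  }
  stopifnot(is.data.frame(igeo_classes),
            all(c("upper", "label") %in% names(igeo_classes)),
            nrow(igeo_classes) >= 1)
  up <- igeo_classes$upper
  if (any(diff(up) <= 0)) stop("igeo class bounds must be strictly increasing",
                               call. = FALSE)
  structure(list(background = background, screening = screening,
                 veg_mpl = veg_mpl, igeo_classes = igeo_classes,
                 screening_source = screening_source),
            class = "reference_tables")
}

#' The Muller geo-accumulation class ladder
#'
#' Seven contamination classes on the geo-accumulation index scale, from
#' unpolluted (index at or below 0) to extremely contaminated (above 5).
#' Bounds are half-open: a class covers `lower < Igeo <= upper`.
#'
#' @return data.frame with columns `upper` and `label`.
#' @export
default_igeo_classes <- function() {
  data.frame(
    upper = c(0, 1, 2, 3, 4, 5, Inf),
    label = c("unpolluted",
              "unpolluted to moderately contaminated",
              "moderately contaminated",
              "moderately to heavily contaminated",
              "heavily contaminated",
              "heavily to extremely contaminated",
              "extremely contaminated"),
    stringsAsFactors = FALSE
  )
}

#' Exposure scenario for ingestion risk
#'
#' Receptor-specific exposure parameters for the chronic-daily-intake model,
#' plus the per-metal oral reference doses.
#'
#' @param receptor Label, e.g. `"adult"` or `"child"`.
#' @param ir_veg Vegetable ingestion rate, g/day fresh weight.
#' @param ef Exposure frequency, days/year.
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param rfd Named numeric of oral reference doses, mg/kg/day, one per metal.
#' @param at Averaging time, days; defaults to `ed * 365` (non-carcinogenic
#'   convention).
#' @return An `exposure_scenario` object.
#' @export
exposure_scenario <- function(receptor, ir_veg, ef, ed, bw, rfd,
                              at = ed * 365) {
  pars <- c(ir_veg = ir_veg, ef = ef, ed = ed, bw = bw, at = at)
  if (any(!is.finite(pars) | pars <= 0)) {
    stop("exposure parameters must all be positive: ",
         paste(names(pars)[!is.finite(pars) | pars <= 0], collapse = ", "),
         call. = FALSE)
  }
  rfd <- check_metal_table(rfd, sprintf("rfd table for receptor '%s'", receptor))
  structure(list(receptor = as.character(receptor), ir_veg = ir_veg, ef = ef,
                 ed = ed, bw = bw, at = at, rfd = rfd),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario '%s': IR=%g g/d, EF=%g d/y, ED=%g y, BW=%g kg, AT=%g d\n",
              x$receptor, x$ir_veg, x$ef, x$ed, x$bw, x$at))
  cat("  RfD (mg/kg/d): ",
      paste(sprintf("%s=%g", names(x$rfd), x$rfd), collapse = ", "), "\n")
  invisible(x)
}

#' Load reference tables and exposure scenarios from a YAML config
#'
#' The config has two top-level sections: `references` (with `background`,
#' `screening`, optional `veg_mpl`, optional `igeo_classes`, optional
#' `screening_source`) and `scenarios` (one entry per receptor with keys
#' `ir_veg`, `ef`, `ed`, `bw`, optional `at`, and an `rfd` table). Missing
#' metals in `background` or any `rfd` table are a config error; `at`
#' defaults to `ed * 365` when unset.
#'
#' @param path Path to the YAML file.
#' @return List with elements `references` (a `reference_tables`) and
#'   `scenarios` (named list of `exposure_scenario`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("references", "scenarios")) {
    if (is.null(cfg[[key]])) {
      stop("config error: missing section '", key, "'", call. = FALSE)
    }
  }
  refs <- cfg$references
  for (key in c("background", "screening")) {
    if (is.null(refs[[key]])) {
      stop("config error: missing key 'references.", key, "'", call. = FALSE)
    }
  }
  ladder <- if (is.null(refs$igeo_classes)) {
    default_igeo_classes()
  } else {
    data.frame(
      upper = vapply(refs$igeo_classes, function(x) {
        u <- x$upper
        if (is.character(u)) u <- if (tolower(u) %in% c("inf", ".inf")) Inf else as.numeric(u)
        if (is.null(u)) Inf else as.numeric(u)
      }, numeric(1)),
      label = vapply(refs$igeo_classes, function(x) as.character(x$label),
                     character(1)),
      stringsAsFactors = FALSE
    )
  }
  references <- reference_tables(
    background = refs$background,
    screening = refs$screening,
    veg_mpl = if (is.null(refs$veg_mpl)) numeric() else refs$veg_mpl,
    igeo_classes = ladder,
    screening_source = if (is.null(refs$screening_source)) character()
                       else unlist(refs$screening_source)
  )
  scenarios <- lapply(names(cfg$scenarios), function(nm) {
    sc <- cfg$scenarios[[nm]]
    for (key in c("ir_veg", "ef", "ed", "bw", "rfd")) {
      if (is.null(sc[[key]])) {
        stop("config error: missing key 'scenarios.", nm, ".", key, "'",
             call. = FALSE)
      }
    }
    exposure_scenario(receptor = nm, ir_veg = sc$ir_veg, ef = sc$ef,
                      ed = sc$ed, bw = sc$bw, rfd = sc$rfd,
                      at = if (is.null(sc$at)) sc$ed * 365 else sc$at)
  })
  names(scenarios) <- names(cfg$scenarios)
  list(references = references, scenarios = scenarios)
}

#' Path to the packaged default configuration
#'
#' The shipped config carries the study-area background values and the
#' GB 15618-2018 soil screening values (Canadian guideline for V), the
#' GB 2762-2017 vegetable maximum permissible levels for Cd, Pb and Cr, the
#' Muller geo-accumulation ladder, and adult/child exposure scenarios with
#' handbook (non-study-specific) ingestion rates, body weights and oral
#' reference doses.
#'
#' @return Path to the YAML file installed with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "config.yaml", package = "vegrisk", mustWork = TRUE)
}

#' Convert dry-weight to fresh-weight concentrations
#'
#' Vegetable inputs to this package are fresh-weight concentrations; this
#' helper converts dry-weight contents using the sample moisture fraction.
#' It is never applied implicitly.
#'
#' @param c_dry Concentration, mg/kg dry weight.
#' @param moisture Moisture mass fraction of the fresh tissue, in [0, 1).
#' @return Concentration in mg/kg fresh weight: `c_dry * (1 - moisture)`.
#' @export
dry_to_fresh <- function(c_dry, moisture) {
  stopifnot(all(moisture >= 0 & moisture < 1))
  c_dry * (1 - moisture)
}
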