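#' Chronic daily intake via vegetable ingestion
#'
#' `CDI = IR_veg * C_veg(fw) * EF * ED / (BW * AT)` in mg/kg/day. The
#' ingestion rate is supplied in g/day in the scenario and converted to
#' kg/day internally, since contents are per kg. With the non-carcinogenic
#' convention `AT = ED * 365`, CDI is independent of ED.
#'
#' @param c_veg_fw Vegetable content, mg/kg fresh weight (vectorised,
#'   non-negative).
#' @param scenario An `exposure_scenario`.
#' @return Dose in mg/kg/day.
#' @export
#' @examples
#' sc <- exposure_scenario("x", ir_veg = 100, ef = 365, ed = 1, bw = 60,
#'                         rfd = stats::setNames(rep(1, 6), metal_ids()))
#' cdi(1, sc)  # 1.667e-3
cdi <- function(c_veg_fw, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(c_veg_fw < 0)) stop("cdi: negative content", call. = FALSE)
  ir_kg <- scenario$ir_veg / 1000
  ir_kg * c_veg_fw * scenario$ef * scenario$ed / (scenario$bw * scenario$at)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD`; values above 1 flag potential non-carcinogenic concern.
#'
#' @param cdi_value Chronic daily intake, mg/kg/day (vectorised).
#' @param rfd Oral reference dose, mg/kg/day, positive.
#' @return Dimensionless quotient.
#' @export
hq <- function(cdi_value, rfd) {
  if (any(!is.finite(rfd) | rfd <= 0)) stop("hq: rfd must be positive",
                                            call. = FALSE)
  cdi_value / rfd
}

#' Hazard index
#'
#' Sum of per-metal hazard quotients; an index below 1 is interpreted as
#' safe for ingestion.
#'
#' @param hq_values Numeric vector of non-negative HQs.
#' @return List with `hi` (the sum) and `safe` (`hi < 1`).
#' @export
hi <- function(hq_values) {
  if (any(hq_values < 0)) stop("hi: negative HQ", call. = FALSE)
  s <- sum(hq_values)
  list(hi = s, safe = s < 1)
}

#' Method-of-moments log-normal fit
#'
#' Given an arithmetic mean and SD, returns the log-space location and scale
#' of the log-normal with exactly those moments:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2 / 2`.
#'
#' @param mean Arithmetic mean, positive.
#' @param sd Arithmetic SD, non-negative (`sd = 0` gives a point mass).
#' @return List with `mu` and `sigma`.
#' @export
#' @examples
#' fit_lognormal(22.1, 19.6)  # sigma 0.762, mu 2.805
fit_lognormal <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("fit_lognormal: mean must be positive",
                                          call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("fit_lognormal: sd must be non-negative",
                                     call. = FALSE)
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Content distribution for Monte Carlo sampling
#'
#' A per-metal, per-species log-normal model of the vegetable content,
#' parameterised by arithmetic mean and SD (method of moments) and truncated
#' at the observed minimum and maximum.
#'
#' @param metal Metal code (one of [metal_ids()]).
#' @param species Species label (or `"all"`).
#' @param mean,sd Arithmetic moments, mg/kg fresh weight.
#' @param minimum,maximum Truncation bounds, mg/kg fresh weight; default
#'   untruncated (`0`, `Inf`).
#' @return A `content_distribution` object.
#' @export
content_distribution <- function(metal, species, mean, sd,
                                 minimum = 0, maximum = Inf) {
  stopifnot(metal %in% metal_ids())
  if (!(minimum >= 0 && minimum <= maximum)) {
    stop("content_distribution: need 0 <= minimum <= maximum", call. = FALSE)
  }
  fit <- fit_lognormal(mean, sd)
  structure(list(metal = metal, species = species, mean = mean, sd = sd,
                 minimum = minimum, maximum = maximum,
                 mu = fit$mu, sigma = fit$sigma),
            class = "content_distribution")
}

#' Build per-metal content distributions from raw vegetable samples
#'
#' For each metal, fits the log-normal by method of moments to the observed
#' contents of the selected species (all pooled by default) and truncates at
#' the observed minimum and maximum.
#'
#' @param veg Vegetable data.frame.
#' @param species Optional species label to subset on.
#' @return Named list of `content_distribution`, one per metal.
#' @export
content_distributions_from_data <- function(veg, species = NULL) {
  label <- if (is.null(species)) "all" else species
  if (!is.null(species)) veg <- veg[veg$species == species, , drop = FALSE]
  if (nrow(veg) < 1) stop("no vegetable samples for species ", label,
                          call. = FALSE)
  out <- lapply(metal_ids(), function(m) {
    s <- summarize_conc(veg[[m]])
    content_distribution(m, label, mean = s$mean_arith, sd = s$sd_arith,
                         minimum = s$minimum, maximum = s$maximum)
  })
  stats::setNames(out, metal_ids())
}

#' Sample vegetable contents from a truncated log-normal
#'
#' Rejection sampling from the log-normal, keeping draws inside
#' `[minimum, maximum]`, so the distribution retains the log-normal shape
#' within the bounds. A degenerate `sigma = 0` yields the mean (clipped into
#' the bounds). An acceptance probability below 1e-4 is an error advising a
#' bounds check.
#'
#' @param dist A `content_distribution`.
#' @param n Number of draws.
#' @param seed Optional integer seed (set when not `NULL`).
#' @return Numeric vector of `n` contents, mg/kg fresh weight.
#' @export
sample_contents <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "content_distribution"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (dist$sigma == 0) {
    return(rep(min(max(dist$mean, dist$minimum), dist$maximum), n))
  }
  accept <- stats::plnorm(dist$maximum, dist$mu, dist$sigma) -
    stats::plnorm(dist$minimum, dist$mu, dist$sigma)
  if (accept < 1e-4) {
    stop(sprintf(
      "sample_contents: truncation acceptance probability %.2g < 1e-4 for %s/%s; check bounds",
      accept, dist$metal, dist$species), call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / accept * 1.1) + 16
    x <- stats::rlnorm(m, dist$mu, dist$sigma)
    out <- c(out, x[x >= dist$minimum & x <= dist$maximum])
  }
  out[seq_len(n)]
}

#' Monte Carlo non-carcinogenic risk simulation
#'
#' Per iteration, draws each metal's vegetable content independently from
#' its truncated log-normal, computes the chronic daily intake and hazard
#' quotient per metal, and sums to the hazard index. Full draws are stored.
#'
#' @param dists Named list of `content_distribution`, one per metal (names
#'   are metal codes).
#' @param scenario An `exposure_scenario`; must supply an RfD for every
#'   metal in `dists` (checked before any sampling).
#' @param n_iter Number of iterations (default 10000).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `risk_distribution`: `hq_draws` (n_iter x metals matrix),
#'   `hi_draws`, `n_iter`, `seed`, `receptor`, `species`, and the scenario.
#' @export
mc_risk <- function(dists, scenario, n_iter = 10000, seed = 1) {
  stopifnot(inherits(scenario, "exposure_scenario"), n_iter >= 1)
  metals <- names(dists)
  stopifnot(length(metals) > 0, all(metals %in% metal_ids()))
  no_rfd <- metals[!metals %in% names(scenario$rfd)]
  if (length(no_rfd) > 0) {
    stop("mc_risk: scenario lacks RfD for metal(s): ",
         paste(no_rfd, collapse = ", "), call. = FALSE)
  }
  species <- unique(vapply(dists, function(d) d$species, character(1)))
  species <- if (length(species) == 1) species else "mixed"
  set.seed(seed)
  hq_draws <- vapply(metals, function(m) {
    contents <- sample_contents(dists[[m]], n_iter)
    hq(cdi(contents, scenario), scenario$rfd[[m]])
  }, numeric(n_iter))
  if (is.null(dim(hq_draws))) {
    hq_draws <- matrix(hq_draws, nrow = n_iter,
                       dimnames = list(NULL, metals))
  }
  structure(list(hq_draws = hq_draws, hi_draws = rowSums(hq_draws),
                 n_iter = n_iter, seed = seed,
                 receptor = scenario$receptor, species = species,
                 scenario = scenario),
            class = "risk_distribution")
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("Monte Carlo risk distribution: %s / %s, %d iterations (seed %d)\n",
              x$receptor, x$species, x$n_iter, x$seed))
  q <- stats::quantile(x$hi_draws, c(0.5, 0.9), type = 7)
  cat(sprintf("  HI median %.3g, P90 %.3g\n", q[1], q[2]))
  invisible(x)
}

#' @export
summary.risk_distribution <- function(object, percentile = 0.9, ...) {
  summarize_risk(object, percentile)
}

#' @export
quantile.risk_distribution <- function(x, probs = c(0.5, 0.9), ...) {
  stats::quantile(x$hi_draws, probs = probs, type = 7, ...)
}

#' Percentile summary and per-metal contributions of a risk distribution
#'
#' The reporting percentile (default the 90th, the conservative convention)
#' is the empirical type-7 quantile (linear interpolation between order
#' statistics) of the hazard index and of each metal's hazard quotient. The
#' contribution of a metal is `mean(HQ_m) / mean(HI)`, so contributions sum
#' to 1.
#'
#' @param dist A `risk_distribution`.
#' @param percentile Fraction in (0, 1); default 0.9.
#' @return A `risk_summary`: `receptor`, `species`, `percentile`, `hq_p`
#'   (named per metal), `hi_p`, `contribution` (named per metal, sums to 1),
#'   `safe` (`hi_p < 1`).
#' @export
summarize_risk <- function(dist, percentile = 0.9) {
  stopifnot(inherits(dist, "risk_distribution"),
            percentile > 0, percentile < 1)
  hq_p <- apply(dist$hq_draws, 2, stats::quantile, probs = percentile,
                type = 7)
  hi_p <- unname(stats::quantile(dist$hi_draws, percentile, type = 7))
  contribution <- colMeans(dist$hq_draws) / mean(dist$hi_draws)
  structure(list(receptor = dist$receptor, species = dist$species,
                 percentile = percentile, hq_p = hq_p, hi_p = hi_p,
                 contribution = contribution, safe = hi_p < 1,
                 n_iter = dist$n_iter, seed = dist$seed),
            class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("Risk summary: %s / %s at P%g (n_iter=%d)\n", x$receptor,
              x$species, 100 * x$percentile, x$n_iter))
  cat(sprintf("  HI = %.3g (%s)\n", x$hi_p,
              if (x$safe) "safe, < 1" else "potential concern, >= 1"))
  cat("  HQ: ", paste(sprintf("%s %.3g", names(x$hq_p), x$hq_p),
                      collapse = ", "), "\n")
  cat("  contribution: ",
      paste(sprintf("%s %.1f%%", names(x$contribution),
                    100 * x$contribution), collapse = ", "), "\n")
  invisible(x)
}

#' Deterministic hazard quotients and hazard index
#'
#' Point-estimate risk for fixed vegetable contents (no Monte Carlo): HQ per
#' metal from the chronic daily intake, and their sum HI.
#'
#' @param contents Named numeric of vegetable contents, mg/kg fresh weight,
#'   names are metal codes.
#' @param scenario An `exposure_scenario`.
#' @return List with `hq` (named), `hi`, `safe`.
#' @export
deterministic_risk <- function(contents, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  metals <- names(contents)
  stopifnot(length(metals) > 0, all(metals %in% metal_ids()))
  hqs <- vapply(metals, function(m) {
    hq(cdi(contents[[m]], scenario), scenario$rfd[[m]])
  }, numeric(1))
  res <- hi(hqs)
  list(hq = hqs, hi = res$hi, safe = res$safe)
}
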