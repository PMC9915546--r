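# tiny in-code fixtures shared across test files

tiny_soil <- function(n = 2, metals = NULL) {
  d <- data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    pH = seq(5, 6, length.out = n),
    som = rep(25, n),
    dcb_fe = rep(1.5, n),
    dcb_al = rep(0.7, n),
    avail_n = rep(60, n),
    avail_p = rep(0.04, n),
    avail_k = rep(80, n),
    stringsAsFactors = FALSE
  )
  if (is.null(metals)) {
    metals <- list(Cd = 10, Cr = 100, Cu = 30, Pb = 90, V = 400, Zn = 300)
  }
  for (m in metal_ids()) d[[m]] <- rep_len(metals[[m]], n)
  d
}

tiny_veg <- function(soil, species = "pak choi", baf = 0.01) {
  n <- nrow(soil)
  d <- data.frame(
    sample_id = sprintf("V%d", seq_len(n)),
    species = rep_len(species, n),
    soil_id = soil$sample_id,
    stringsAsFactors = FALSE
  )
  for (m in metal_ids()) d[[m]] <- soil[[m]] * baf
  d
}

tiny_dataset <- function(n = 2, ...) {
  s <- tiny_soil(n)
  paired_dataset(s, tiny_veg(s, ...))
}

# minimal valid config written to a temp file; `drop` removes a nested key
# by path, e.g. c("scenarios", "adult", "rfd", "Zn")
write_tiny_config <- function(path = tempfile(fileext = ".yaml"),
                              drop = NULL) {
  rfd <- list(Cd = 0.001, Cr = 0.003, Cu = 0.04, Pb = 0.0035, V = 0.009,
              Zn = 0.3)
  cfg <- list(
    references = list(
      background = list(Cd = 0.41, Cr = 33.9, Cu = 8.56, Pb = 32.7,
                        V = 95.6, Zn = 118),
      screening = list(Cd = 0.30, Cr = 150, Cu = 50.0, Pb = 90.0, V = 130,
                       Zn = 200),
      veg_mpl = list(Cd = 0.20, Pb = 0.30, Cr = 1.0)
    ),
    scenarios = list(
      adult = list(ir_veg = 345, ef = 365, ed = 30, bw = 61.8, rfd = rfd),
      child = list(ir_veg = 232, ef = 365, ed = 6, bw = 23.6, rfd = rfd)
    )
  )
  if (!is.null(drop)) {
    expr <- paste0("cfg", paste(sprintf("[['%s']]", drop), collapse = ""))
    eval(parse(text = paste0(expr, " <- NULL")))
  }
  yaml::write_yaml(cfg, path)
  path
}

default_scenario <- function(receptor = "adult") {
  load_config(default_config_path())$scenarios[[receptor]]
}

# a unit scenario where CDI = C / 1000 and all RfDs are 1
unit_scenario <- function(rfd = 1) {
  exposure_scenario("unit", ir_veg = 1, ef = 365, ed = 1, bw = 1,
                    rfd = stats::setNames(rep(rfd, 6), metal_ids()))
}
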