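test_that("default generator emulates the study layout and loads cleanly", {
  d <- generate_dataset(generator_config(seed = 17))
  expect_s3_class(d, "paired_dataset")
  expect_equal(nrow(d$soil), 51)
  expect_equal(nrow(d$veg), 51)
  expect_equal(sort(unique(d$veg$species)),
               sort(c("asparagus lettuce", "pak choi", "coriander",
                      "flowering Chinese cabbage", "garland chrysanthemum",
                      "garlic sprout", "lettuce")))
  expect_equal(as.vector(table(d$veg$species)[c("asparagus lettuce",
                                                "pak choi")]), c(11L, 6L))
  for (m in metal_ids()) {
    expect_true(all(d$soil[[m]] > 0))
    expect_true(all(d$veg[[m]] > 0))
  }
  expect_true(all(d$veg$soil_id %in% d$soil$sample_id))
})

test_that("generation is deterministic: same config and seed, same bytes", {
  cfg <- generator_config(seed = 23)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  sp1 <- tempfile(); vp1 <- tempfile()
  sp2 <- tempfile(); vp2 <- tempfile()
  write_paired_dataset(d1, sp1, vp1)
  write_paired_dataset(d2, sp2, vp2)
  expect_identical(readLines(sp1), readLines(sp2))
  expect_identical(readLines(vp1), readLines(vp2))
  d3 <- generate_dataset(generator_config(seed = 24))
  expect_false(identical(d1$soil$Cd, d3$soil$Cd))
})

test_that("degenerate configs collapse to deterministic values", {
  cfg <- generator_config(n_sites = 4, seed = 1, source_sigma = c(0, 0))
  cfg$source_loadings[] <- 0
  cfg$metal_noise_sigma[] <- 0
  for (cv in names(cfg$soil_covariate_params)) {
    cfg$soil_covariate_params[[cv]]$sd <- 0
  }
  soils <- generate_soils(cfg)
  for (m in metal_ids()) {
    expect_equal(soils[[m]], rep(cfg$background[[m]], 4))
  }
  # zero transfer noise and offsets: BAF identical across samples per metal
  cfg$baf_model$resid_sigma[] <- 0
  cfg$baf_model$species_offsets[] <- 0
  for (b in c("beta_ph", "beta_som", "beta_fe", "beta_k")) {
    cfg$baf_model[[b]][] <- 0
  }
  veg <- generate_vegetables(soils, cfg)
  recs <- compute_baf(paired_dataset(soils, veg))
  for (m in metal_ids()) {
    expect_equal(length(unique(recs$baf[recs$metal == m])), 1)
  }
})

test_that("empty and inconsistent configurations are handled", {
  d0 <- generate_dataset(generator_config(n_sites = 0))
  expect_equal(nrow(d0$soil), 0)
  expect_equal(nrow(d0$veg), 0)
  expect_error(generator_config(n_sites = 10,
                                species_plan = c("pak choi" = 3)),
               "sum to n_sites")
})

test_that("soil calibration reproduces the published geometric means", {
  # population check at large n, where sampling noise is negligible
  cfg <- generator_config(n_sites = 4900, species_plan = NULL, seed = 31)
  soils <- generate_soils(cfg)
  gm_target <- c(Cd = 11.3, Cr = 121, Cu = 27.8, Pb = 88.2, V = 409,
                 Zn = 329)
  for (m in metal_ids()) {
    gm <- exp(mean(log(soils[[m]])))
    expect_lt(abs(gm / gm_target[[m]] - 1), 0.25)
  }
})

test_that("planted Pb-Zn source correlation is recovered across seeds", {
  hits <- 0
  for (i in 1:20) {
    d <- generate_soils(generator_config(seed = 100 + i))
    mc <- metal_correlation(d)
    hits <- hits + (mc$r["Pb", "Zn"] > 0 && mc$p["Pb", "Zn"] < 0.05)
  }
  expect_gte(hits, 18)
})

test_that("generator output drives the full pipeline end to end", {
  d <- generate_dataset(generator_config(seed = 3))
  sp <- tempfile(); vp <- tempfile()
  write_paired_dataset(d, sp, vp)
  out <- tempfile()
  res <- run_all(sp, vp, default_config_path(), out_dir = out, seed = 3,
                 n_iter = 200)
  families <- c("summary", "igeo", "igeo_class_fractions",
                "screening_exceedance", "sources_correlation", "sources_pca",
                "baf_records", "baf_summary", "mpl_exceedance",
                "baf_correlation", "risk")
  for (f in families) {
    expect_true(file.exists(file.path(out, paste0(f, ".csv"))), label = f)
  }
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_equal(nrow(res$risk), 2 * (1 + 7))
})
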