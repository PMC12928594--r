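toy_csv <- function(path) {
  df <- data.frame(
    sex = c("m", "m", "f", "f"),
    center = "A",
    mass = c(1.2, 1.4, 1.1, 1.3),
    length = c(10, 12, 9, 11)
  )
  write.csv(df, path, row.names = FALSE)
  df
}

test_that("study tables are read, typed, and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  toy_csv(f)
  st <- read_study_table(f, group_col = "sex", trait_cols = c("mass", "length"),
                         stratum_cols = "center")
  expect_s3_class(st, "study_table")
  expect_equal(st$group_levels, c("f", "m"))
  expect_equal(sum(st$data$sex == "m"), 2)
  expect_error(read_study_table(f, "nope", "mass"), class = "momentdiff_config_error")
  df3 <- rbind(toy_csv(f), data.frame(sex = "x", center = "A", mass = 1, length = 1))
  expect_error(read_study_table(df3, "sex", "mass"), "f, m, x",
               class = "momentdiff_invalid_input")
})

test_that("unparseable trait cells are counted and treated as missing", {
  df <- data.frame(sex = c("m", "m", "m", "m", "m", "f", "f", "f", "f", "f"),
                   mass = c("1.0", "2.0", "oops", "3.0", "4", "1", "2", "3", "4", "5"),
                   stringsAsFactors = FALSE)
  st <- read_study_table(df, "sex", "mass")
  expect_equal(st$n_bad_trait, 1)
  expect_type(st$data$mass, "double")
})

test_that("effect CSVs round-trip losslessly", {
  mg <- make_moment_groups()
  tab <- effects_to_table(list(
    delta_skewness(mg$g1, mg$g2, warn_small_n = FALSE),
    delta_kurtosis(mg$g1, mg$g2, warn_small_n = FALSE)
  ))
  f <- withr::local_tempfile(fileext = ".csv")
  write_effect_csv(tab, f)
  back <- read_effect_csv(f)
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-12)
  expect_equal(back$effect_kind, tab$effect_kind)
  expect_equal(names(back), names(tab))
  expect_error(read_effect_csv(withr::local_tempfile()), class = "momentdiff_config_error")
})

test_that("the fixture generator is deterministic and labelled with its truths", {
  cfg <- fixture_config(centers = "c1", strains = c("s1", "s2"), n_per_group = 60)
  a <- generate_fixture(cfg, seed = 7)
  b <- generate_fixture(cfg, seed = 7)
  expect_identical(a, b)
  c_ <- generate_fixture(cfg, seed = 8)
  expect_false(identical(a$table, c_$table))
  expect_equal(nrow(a$table), 2 * 2 * 60)
  expect_equal(a$truth$delta_zr, atanh(0.4) - atanh(0.6))
  expect_equal(a$truth$group1, "male")
  d <- withr::local_tempdir()
  generate_fixture(cfg, seed = 7, dir = d)
  expect_true(file.exists(file.path(d, "study_table.csv")))
  tr <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(tr$delta_sk, a$truth$delta_sk, tolerance = 1e-9)
})

test_that("the per-stratum effect pipeline produces the full schema and honors group order", {
  fx <- generate_fixture(fixture_config(centers = c("c1", "c2"), strains = "s1",
                                        n_per_group = 120), seed = 3)
  st <- read_study_table(fx$table, "sex", c("fat_mass", "heart_weight"),
                         c("center", "strain"))
  eff <- suppressWarnings(effect_table(st, types = "all", group_order = c("male", "female")))
  # 2 strata x (4 per-trait kinds x 2 traits + dzr)
  expect_equal(nrow(eff), 2 * (4 * 2 + 1))
  expect_true(all(is.na(eff$reason)))
  expect_true(all(is.finite(eff$estimate)))
  swapped <- suppressWarnings(effect_table(st, types = "dzr", group_order = c("female", "male")))
  fwd <- eff[eff$effect_kind == "delta_zr", ]
  expect_equal(swapped$estimate, -fwd$estimate, tolerance = 1e-12)
  # undefined strata yield NA rows with a reason, not a failure
  df <- fx$table
  df$fat_mass[df$center == "c2"] <- 1 # constant trait in one stratum
  st2 <- read_study_table(df, "sex", c("fat_mass", "heart_weight"), c("center", "strain"))
  eff2 <- suppressWarnings(effect_table(st2, types = "dsk"))
  expect_true(any(!is.na(eff2$reason)))
  expect_true(any(is.na(eff2$estimate)))
})

test_that("effect and meta pipelines run end-to-end from files", {
  fx <- generate_fixture(fixture_config(n_per_group = 150), seed = 11)
  d <- withr::local_tempdir()
  in_csv <- file.path(d, "study.csv")
  write.csv(fx$table, in_csv, row.names = FALSE)
  eff_csv <- file.path(d, "effects.csv")
  eff <- suppressWarnings(run_effect_pipeline(
    in_csv, eff_csv, types = c("dzr", "dsk"),
    group_col = "sex", trait_cols = c("fat_mass", "heart_weight"),
    stratum_cols = c("center", "strain"), group_order = c("male", "female")
  ))
  expect_true(file.exists(eff_csv))
  meta_csv <- file.path(d, "meta.csv")
  res <- run_meta_pipeline(eff_csv, meta_csv, random_factors = c("center", "strain"))
  expect_true(file.exists(meta_csv))
  dzr <- res[res$effect_kind == "delta_zr", ]
  expect_equal(nrow(dzr), 1)
  expect_true(dzr$ci_lower <= fx$truth$delta_zr && fx$truth$delta_zr <= dzr$ci_upper)
})

test_that("the full pipeline recovers the configured truths across seeds", {
  cfg <- fixture_config(centers = c("c1", "c2", "c3"), strains = "s1",
                        n_per_group = 250)
  hit <- 0
  for (s in 1:15) {
    fx <- generate_fixture(cfg, seed = 100 + s)
    st <- read_study_table(fx$table, "sex", c("fat_mass", "heart_weight"),
                           c("center", "strain"))
    eff <- effect_table(st, types = "dzr", group_order = c("male", "female"))
    fit <- random_effects_meta(eff)
    if (fit$ci[1] <= fx$truth$delta_zr && fx$truth$delta_zr <= fit$ci[2]) hit <- hit + 1
  }
  expect_gte(hit, 13) # ~95% nominal coverage, allow Monte-Carlo slack
})

test_that("simulation configs are parsed and validated, and dry runs count cells", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("families: [zr]", "reps: 10", "seed: 3"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$families, "zr")
  scen <- suppressMessages(run_simulation_pipeline(f, dry_run = TRUE))
  expect_equal(nrow(scen), 768)
  expect_message(run_simulation_pipeline(list(families = "skew"), dry_run = TRUE),
                 "1200 cells")
  fbad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bogus_key: 1", fbad)
  expect_error(read_sim_config(fbad), class = "momentdiff_config_error")
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"families": ["zr"], "n_set": [10], "r_values": [0, 0.4]}', fj)
  scen2 <- suppressMessages(run_simulation_pipeline(fj, dry_run = TRUE))
  expect_equal(nrow(scen2), 4)
})
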