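test_that("single-islet analysis handles limits and contracts", {
  # zero-noise, infinite wave speed: the HG network is complete
  p <- quiet_params(n_cells = 10, seed = 4, wave_speed_um_s = Inf,
                    onset_delay_max_s = 0, offset_delay_max_s = 0,
                    bleach_linear = 5e-5, bleach_exp_amp = 0.1,
                    noise_sd = 0.01)
  g <- generate_geometry(p)
  tr <- simulate_traces(g, p)
  res <- analyze_islet(tr, g, p$schedule, seed = 1)
  hg <- res$summary[res$summary$regime == "HG", ]
  expect_equal(hg$k_avg, 9)
  expect_equal(hg$C_avg, 1)
  expect_equal(hg$E_glob, 1)

  # fewer than 3 classified beta cells aborts
  p3 <- sim_params(n_cells = 5, seed = 2, nonbeta_fraction = 0.8)
  g3 <- generate_geometry(p3)
  tr3 <- simulate_traces(g3, p3)
  expect_error(analyze_islet(tr3, g3, p3$schedule), "beta cells")

  # sub-significant threshold is recorded as a warning
  cfg <- analysis_config(R_th = 0.2)
  res2 <- analyze_islet(tr, g, p$schedule, cfg, seed = 1)
  expect_true(any(grepl("critical", res2$warnings)))
})

test_that("aggregation reports medians and ranges per regime", {
  p <- sim_params(n_cells = 30, seed = 5)
  g <- generate_geometry(p)
  tr <- simulate_traces(g, p)
  a1 <- analyze_islet(tr, g, p$schedule, seed = 1)
  a2 <- a1; a3 <- a1
  a2$summary$S <- a1$summary$S * 2
  a3$summary$S <- a1$summary$S * 4
  agg <- aggregate_islets(list(a1, a2, a3))
  s_med <- agg$medians[agg$medians$metric == "S" &
                         agg$medians$regime == "HG", ]
  s_hg <- a1$summary$S[a1$summary$regime == "HG"]
  expect_equal(s_med$median, 2 * s_hg)
  expect_equal(s_med$min, s_hg)
  expect_equal(s_med$max, 4 * s_hg)
  expect_equal(nrow(agg$table1), 3)
  expect_setequal(names(agg$table1)[-1],
                  c("C_avg", "E_glob", "C_rand", "E_rand",
                    "clustering_ratio", "efficiency_ratio", "S"))
  expect_error(aggregate_islets(list(a1)), "at least 2")
})

test_that("regime statistics follow the Friedman + Wilcoxon protocol", {
  mk_long <- function(vals) {
    # vals: islets x 3 matrix for one metric
    data.frame(metric = "m", islet = rep(seq_len(nrow(vals)), 3),
               regime = rep(c("LG1", "HG", "LG2"), each = nrow(vals)),
               value = c(vals))
  }
  same <- mk_long(matrix(5, 9, 3))
  st <- compare_regimes(same)
  expect_true(all(st$friedman_p == 1))
  expect_false(any(st$significant))
  expect_false(any(st$posthoc_licensed))

  # constant shift of one regime across 9 islets: exact p = 2/512
  set.seed(2)
  base <- rnorm(9)
  shifted <- cbind(base, base + 10 + rnorm(9, sd = 0.01),
                   base + rnorm(9, sd = 0.01))
  st2 <- compare_regimes(mk_long(shifted))
  lg1_hg <- st2[st2$comparison == "LG1-HG", ]
  expect_equal(lg1_hg$wilcoxon_p, 2 / 512, tolerance = 1e-12)
  expect_true(lg1_hg$significant)

  # islet exchangeability: permuting islets leaves p-values unchanged
  perm <- shifted[sample(9), ]
  st3 <- compare_regimes(mk_long(perm))
  expect_equal(st3$wilcoxon_p, st2$wilcoxon_p)
  expect_equal(st3$friedman_p, st2$friedman_p)

  incomplete <- mk_long(shifted)[-1, ]
  expect_error(compare_regimes(incomplete), "paired")
})

test_that("the study pipeline is reproducible and correctly shaped", {
  st <- run_study(n_islets = 3, seed = 7, n_cells_range = c(25, 35))
  expect_length(st$analyses, 3)
  expect_equal(nrow(st$aggregate$table1), 3)
  expect_true(all(c("LG1", "HG", "LG2") %in% st$aggregate$table1$regime))
  expect_true(all(c("R_avg", "k_avg", "C_avg", "E_glob") %in%
                    st$stats$metric))
  st_b <- run_study(n_islets = 3, seed = 7, n_cells_range = c(25, 35))
  expect_identical(st$aggregate$table1, st_b$aggregate$table1)
  expect_identical(st$stats, st_b$stats)
  expect_error(run_study(n_islets = 1), "at least 2")
})

test_that("the CLI runs simulate/analyze/study end to end", {
  out_sim <- withr::local_tempdir()
  out_an <- withr::local_tempdir()
  expect_equal(run_cli(c("simulate", "--out", out_sim, "--n-islets", "1",
                         "--seed", "5", "--n-cells", "30")), 0L)
  fixture <- file.path(out_sim, "islet_01")
  expect_true(file.exists(file.path(fixture, "traces.csv")))
  expect_true(file.exists(file.path(out_sim, "config_echo.json")))

  expect_equal(run_cli(c("analyze", "--fixture", fixture, "--out", out_an,
                         "--seed", "5")), 0L)
  summ <- read.csv(file.path(out_an, "summary.csv"))
  expect_equal(nrow(summ), 5)
  expect_true(file.exists(file.path(out_an, "edges_HG.csv")))

  # determinism: rerunning produces byte-identical outputs
  out_an2 <- withr::local_tempdir()
  run_cli(c("analyze", "--fixture", fixture, "--out", out_an2,
            "--seed", "5"))
  expect_identical(readLines(file.path(out_an, "summary.csv")),
                   readLines(file.path(out_an2, "summary.csv")))

  expect_equal(suppressWarnings(
    run_cli(c("analyze", "--fixture", "/nonexistent", "--out", out_an))),
    1L)
  expect_equal(run_cli(c("frobnicate")), 1L)
})

test_that("a small study writes its report tables", {
  out <- withr::local_tempdir()
  rep_dir <- withr::local_tempdir()
  expect_equal(run_cli(c("study", "--out", out, "--n-islets", "2",
                         "--seed", "11")), 0L)
  for (f in c("summary.csv", "table1.csv", "stats.csv",
              "config_echo.json"))
    expect_true(file.exists(file.path(out, f)))
  expect_equal(run_cli(c("report", "--study", out, "--out", rep_dir)), 0L)
  expect_true(file.exists(file.path(rep_dir, "report.csv")))
})
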