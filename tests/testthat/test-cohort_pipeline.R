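# small cohort/scheme sets keep the pipeline tests fast
small_setting <- function(n = 5, seed = 3) {
  co <- generate_cohort(cohort_spec(n_patients = n, seed = seed,
                                    volumes = seq(1, 11, length.out = n)))
  schemes <- default_schemes()[c("1x30", "3x15", "4x12", "6x10")]
  res <- suppressMessages(evaluate_cohort(co, schemes))
  list(cohort = co, schemes = schemes, result = res,
       manifest = cohort_manifest(co))
}

test_that("evaluate_cohort produces a complete, deterministic matrix", {
  st <- small_setting()
  res <- st$result
  expect_equal(nrow(res$entries), 5 * 4 * 10)
  counts <- table(res$entries$metric)
  expect_true(all(counts == 20))
  # BED10 column is analytic
  expect_equal(res$schemes$bed10[res$schemes$scheme == "4x12"], 105.6)
  expect_equal(res$schemes$bed10[res$schemes$scheme == "3x15"], 112.5)
  # Fenwick lung NTCP is NA when unconfigured
  expect_true(all(is.na(
    res$entries$value[res$entries$metric == "ntcp_fenwick"]
  )))
  res2 <- suppressMessages(evaluate_cohort(st$cohort, st$schemes))
  expect_identical(res$entries, res2$entries)
  # summary means recompute from the entries
  for (i in sample(nrow(res$summary), 10)) {
    row <- res$summary[i, ]
    vals <- res$entries$value[res$entries$scheme == row$scheme &
                                res$entries$metric == row$metric]
    expect_equal(mean(vals), row$mean)
  }
})

test_that("a single-patient cohort yields mean = value and zero SD", {
  co <- generate_cohort(cohort_spec(n_patients = 1, seed = 8, volumes = 5))
  res <- suppressMessages(
    evaluate_cohort(co, default_schemes()["4x12"])
  )
  s <- res$summary
  expect_true(all(s$sd == 0))
  m <- res$entries$value[res$entries$metric == "tcp_median"]
  expect_equal(s$mean[s$metric == "tcp_median"], m)
})

test_that("paired Wilcoxon matches hand cases and is order-symmetric", {
  x <- c(1, 2, 3, 4)
  r_same <- paired_result(list(a = x, b = x))
  expect_warning(p_same <- wilcoxon_pairwise(r_same, "tcp_median"),
                 "zero")
  expect_equal(p_same$p_value, 1)

  # all sixteen differences share a sign (distinct magnitudes keep the
  # signed-rank distribution tie-free, so the exact path applies)
  shifted <- paired_result(
    list(a = seq_len(16), b = seq_len(16) + seq(0.1, 1.6, by = 0.1))
  )
  p <- wilcoxon_pairwise(shifted, "tcp_median")$p_value
  expect_equal(p, 2 / 2^16, tolerance = 1e-12)

  set.seed(21)
  v1 <- rnorm(12)
  v2 <- rnorm(12)
  pa <- wilcoxon_pairwise(paired_result(list(a = v1, b = v2)))$p_value
  pb <- wilcoxon_pairwise(paired_result(list(a = v2, b = v1)))$p_value
  expect_equal(pa, pb)
  expect_error(wilcoxon_pairwise(paired_result(list(a = v1))), "two schemes")
})

test_that("exact Wilcoxon agrees with full sign enumeration for n <= 10", {
  set.seed(31)
  for (n in c(4, 6, 8, 10)) {
    for (rep in 1:5) {
      v1 <- rnorm(n)
      v2 <- rnorm(n)
      p_pkg <- wilcoxon_pairwise(paired_result(list(a = v1, b = v2)))$p_value
      expect_equal(p_pkg, signed_rank_enum_p(v1 - v2), tolerance = 1e-12)
    }
  }
})

test_that("stratification partitions the cohort and skips empty strata", {
  st <- small_setting(n = 6, seed = 12)
  res <- st$result
  man <- st$manifest
  str <- stratify(res, man)
  per_scheme <- stats::aggregate(n ~ scheme, str$lung, sum)
  expect_true(all(per_scheme$n == 6))
  per_scheme_cw <- stats::aggregate(n ~ scheme, str$chest_wall, sum)
  expect_true(all(per_scheme_cw$n == 6))
  expect_setequal(str$assignment$patient_id, man$patient_id)

  # force everyone into one stratum: the other must be absent, not NaN
  man_one <- man
  man_one$cw_distance <- 30
  man_one$r_ratio <- 1000
  s1 <- stratify(res, man_one)
  expect_setequal(unique(s1$lung$stratum), "lowrisk")
  expect_setequal(unique(s1$chest_wall$stratum), "far")
  expect_false(any(is.na(s1$lung$mean)))
})

test_that("the decision rule honors tolerances, dominance and order", {
  st <- small_setting(n = 8, seed = 4)
  res <- st$result
  str <- stratify(res, st$manifest)
  # zero tolerance: nothing can beat the reference on every axis here,
  # so it recommends itself
  r0 <- recommend(res, str, reference = "4x12",
                  ntcp_margin = 0, meud_margin = 0)
  expect_equal(r0$recommended_scheme, c("4x12", "4x12"))
  expect_equal(r0$tcp_delta, c(0, 0))
  # huge tolerances admit every scheme; the single-fraction one wins
  r_all <- recommend(res, str, reference = "4x12",
                     ntcp_margin = 1, meud_margin = 100)
  expect_equal(unique(r_all$n_fractions), 1L)
  # invariance to scheme list order
  res_rev <- suppressMessages(
    evaluate_cohort(st$cohort, rev(st$schemes))
  )
  str_rev <- stratify(res_rev, st$manifest)
  r_fwd <- recommend(res, str)
  r_rev <- recommend(res_rev, str_rev)
  expect_equal(r_fwd$recommended_scheme, r_rev$recommended_scheme)
  expect_error(recommend(res, str, reference = "2x25"), "not in the result")
})

test_that("report files are complete and regeneration is byte-identical", {
  st <- small_setting(n = 4, seed = 6)
  str <- stratify(st$result, st$manifest)
  rec <- recommend(st$result, str)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(st$result, str, rec, d1)
  write_report(st$result, str, rec, d2)
  files <- c("results_long.csv", "summary_table.csv", "strata_lung.csv",
             "strata_chest_wall.csv", "recommendations.csv", "summary.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  long <- utils::read.csv(file.path(d1, "results_long.csv"))
  expect_equal(nrow(long), nrow(st$result$entries))
  # BED10 row of the summary table round-trips to the analytic values
  tab <- utils::read.csv(file.path(d1, "summary_table.csv"),
                         check.names = FALSE)
  bed_row <- tab[tab$metric == "bed10", -1, drop = FALSE]
  for (lab in names(bed_row)) {
    expect_equal(as.numeric(bed_row[[lab]]),
                 bed(st$schemes[[lab]], 10), tolerance = 0.05)
  }
})

test_that("the shipped default config reproduces the package defaults", {
  cfg <- read_config(system.file("extdata", "default_config.yaml",
                                 package = "sbrtfx"))
  expect_length(cfg$schemes, 10)
  expect_equal(vapply(cfg$schemes, bed, 0, alpha_beta = 10),
               vapply(default_schemes(), bed, 0, alpha_beta = 10))
  expect_equal(cfg$params$martel, martel_params())
  expect_equal(cfg$params$webb_nahum, webb_nahum_params())
  expect_null(cfg$params$fenwick_ntcp)
  expect_equal(cfg$alpha_betas, alpha_beta_set())
})

test_that("a long entry table round-trips through as_cohort_result", {
  st <- small_setting(n = 3, seed = 10)
  rebuilt <- as_cohort_result(st$result$entries, st$schemes)
  expect_equal(rebuilt$summary, st$result$summary)
  expect_equal(rebuilt$schemes, st$result$schemes)
  expect_error(as_cohort_result(st$result$entries, default_schemes()["4x12"]),
               "no fraction_scheme")
})

test_that("the simulate CLI writes a readable cohort", {
  cli <- system.file("cli", "sbrtfx.R", package = "sbrtfx")
  out <- file.path(withr::local_tempdir(), "cohort")
  res <- withr::with_envvar(
    c(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep)),
    system2("Rscript", c(cli, "simulate", "--seed", "3", "--out", out),
            stdout = TRUE, stderr = TRUE)
  )
  expect_true(file.exists(file.path(out, "manifest.csv")))
  co <- read_cohort(out)
  expect_length(co, 16)
})

test_that("config files override schemes, parameters and the decision rule", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "schemes:",
    "  - {n_fractions: 4, dose_per_fraction: 12}",
    "  - {n_fractions: 1, dose_per_fraction: 30, label: single30}",
    "alpha_beta: {tumor: 10, lung: 1.3, chest_wall: 3}",
    "tcp_models:",
    "  martel: {d50: 80, gamma: 2}",
    "toxicity_models:",
    "  fenwick_ntcp: {d50: 30.5, m: 0.37}",
    "decision_rule: {ntcp_margin: 0.05}"
  ), p)
  cfg <- read_config(p)
  expect_setequal(names(cfg$schemes), c("4x12", "single30"))
  expect_equal(cfg$params$martel$d50, 80)
  expect_equal(cfg$params$fenwick_ntcp$m, 0.37)
  expect_equal(cfg$params$lkb$td50, 26.8)
  expect_equal(cfg$decision_rule$ntcp_margin, 0.05)
  expect_equal(cfg$decision_rule$meud_margin, 0.35)
  expect_error(read_config(file.path(tempdir(), "none.yaml")), "not found")
})
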