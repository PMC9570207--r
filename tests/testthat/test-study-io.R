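# Dataset files and the pipeline: round trips, validation, determinism.

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

ds_header <- "subject_id,group,body_weight,time,event,amount,conc"

test_that("write/read round-trips a simulated study losslessly", {
  ds <- simulate_study(ref_params(), rat_study_design(), seed = 21)
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_length(back$subjects, 9)
  for (i in 1:9) {
    expect_identical(back$subjects[[i]]$times, ds$subjects[[i]]$times)
    expect_identical(back$subjects[[i]]$conc, ds$subjects[[i]]$conc)
    expect_identical(back$subjects[[i]]$body_weight,
                     ds$subjects[[i]]$body_weight)
    expect_identical(back$subjects[[i]]$dose$amount,
                     ds$subjects[[i]]$dose$amount)
  }
  # 9 dose rows + 45 observation rows (3x5 + 3x6 + 3x4 schedules) + header
  expect_length(readLines(f), 1 + 9 + 45)
  # tab-delimited dialect round-trips too
  ft <- tempfile(fileext = ".tsv")
  write_dataset(ds, ft)
  expect_identical(read_dataset(ft)$subjects[[5]]$conc, ds$subjects[[5]]$conc)
})

test_that("writing the same dataset twice is byte-identical", {
  ds <- simulate_study(ref_params(), rat_study_design(), seed = 4)
  f1 <- tempfile(); f2 <- tempfile()
  write_dataset(ds, f1); write_dataset(ds, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every dataset-file invariant has a rejecting fixture", {
  ok_dose <- "r1,1,320,0,dose,640,"
  ok_obs <- c("r1,1,320,0,observation,,10.1", "r1,1,320,1,observation,,95")
  # duplicate dosing rows, cited by line
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, ok_dose, ok_dose, ok_obs))),
    "exactly one dosing row.*line\\(s\\) 2, 3")
  # non-positive concentration
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, ok_dose, "r1,1,320,0.5,observation,,-2", ok_obs[2]))),
    "non-positive")
  # unsorted observation times
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, ok_dose, ok_obs[2], ok_obs[1]))),
    "strictly increasing")
  # observation row carrying an amount
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, ok_dose, "r1,1,320,1,observation,640,95"))),
    "carries an amount")
  # dosing row carrying a concentration
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, "r1,1,320,0,dose,640,10", ok_obs))),
    "carries a concentration")
  # dose not at time zero
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, "r1,1,320,1,dose,640,", ok_obs))),
    "time 0")
  # bad event flag
  expect_error(read_dataset(write_lines_tmp(
    c(ds_header, ok_dose, "r1,1,320,1,sample,,95"))),
    "event flag")
  # missing column
  expect_error(read_dataset(write_lines_tmp(
    c("subject_id,group,body_weight,time,event,amount", "r1,1,320,0,dose,640"))),
    "missing column")
})

test_that("unit declarations convert and alias correctly", {
  ds <- simulate_study(ref_params(), rat_study_design(), seed = 6)
  f <- tempfile()
  write_dataset(ds, f)
  a <- read_dataset(f, units = list(concentration = "mg/L", weight = "g"))
  b <- read_dataset(f, units = list(concentration = "ug/mL", weight = "g"))
  fa <- mi_fit(a); fb <- mi_fit(b)
  expect_equal(fa$estimates, fb$estimates)
  expect_equal(fa$loglik, fb$loglik)
  kg <- read_dataset(f, units = list(concentration = "mg/L", weight = "kg"))
  expect_equal(kg$subjects[[1]]$body_weight, 1000 * a$subjects[[1]]$body_weight)
  expect_error(read_dataset(f, units = list(concentration = "mmol/L")),
               "unsupported")
})

test_that("pipeline on noise-free data recovers the generating values", {
  out <- withr::local_tempdir()
  cfg <- list(seed = 11,
              model = list(ka = 1.89, cl_f = 0.853, v_f = 5.1, c0 = 10,
                           sigma = 0),
              fit = list(enabled = TRUE, mode = "pooled", n_starts = 4))
  res <- run_pipeline(cfg, out_dir = out)
  expect_true(res$fit$converged)
  expect_equal(res$fit$estimates$cl_f, 0.853, tolerance = 1e-3)
  expect_equal(res$fit$estimates$c0, 10, tolerance = 1e-3)
  # the secondary block ties the endogenous input to the fitted c0 and CL/F
  expect_equal(res$secondary$k_in, 8.53, tolerance = 1e-2)
  expect_true(all(file.exists(file.path(out, c("dataset.csv",
                                               "parameters.csv",
                                               "obs_pred.csv",
                                               "manifest.json")))))
  pt <- read.csv(file.path(out, "parameters.csv"))
  expect_equal(pt$parameter,
               c("V/F", "CL/F", "ka", "C0", "sigma2",
                 "k_el", "t_half", "k_in", "AUC"))
})

test_that("identical config and seed give byte-identical report bundles", {
  cfg <- list(seed = 33, fit = list(enabled = TRUE, n_starts = 4,
                                    mode = "pooled"))
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = o1)
  run_pipeline(cfg, out_dir = o2)
  for (f in c("dataset.csv", "parameters.csv", "obs_pred.csv",
              "manifest.json"))
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)))
})

test_that("a fit-free config yields a simulation-only bundle", {
  out <- withr::local_tempdir()
  res <- run_pipeline(list(seed = 2, fit = list(enabled = FALSE)),
                      out_dir = out)
  expect_null(res$fit)
  expect_true(file.exists(file.path(out, "dataset.csv")))
  expect_false(file.exists(file.path(out, "parameters.csv")))
})

test_that("pipeline failures name the stage and remove partial outputs", {
  out <- withr::local_tempdir()
  expect_error(run_pipeline(list(data = file.path(out, "absent.csv")),
                            out_dir = out), "stage 'input'")
  expect_error(run_pipeline(list(simulate = FALSE, data = NULL),
                            out_dir = out), "stage 'input'")
  expect_length(list.files(out), 0)
})
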