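test_that("replication seeds pair methods but separate streams", {
  s1 <- replication_seed(42, "1PL", 250, 10, 1, 1)
  expect_identical(s1, replication_seed(42, "1PL", 250, 10, 1, 1))
  expect_false(s1 == replication_seed(42, "1PL", 250, 10, 1, 2))
  expect_false(s1 == replication_seed(42, "1PL", 250, 10, 2, 1))
  expect_false(s1 == replication_seed(42, "2PL", 250, 10, 1, 1))
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("a condition run is deterministic and shares data across methods", {
  c1 <- run_condition("1PL", "CML", 80, 6, 2, root_seed = 7)
  c2 <- run_condition("1PL", "CML", 80, 6, 2, root_seed = 7)
  expect_identical(c1, c2)
  c3 <- run_condition("1PL", "VB-matched", 80, 6, 2, root_seed = 7)
  expect_identical(c1$checksum, c3$checksum) # same response matrices
  expect_false(identical(c1$rmse_theta, c3$rmse_theta))
  expect_true(all(c1$ok))
  expect_identical(names(c1)[1:5], c("model", "method", "S", "L", "rep"))
})

test_that("estimator failures are recorded as missing, never dropped", {
  flaky <- function(data, model, method, seed, mcmc, vb) {
    if (sum(data) %% 2 == 0) stop("synthetic failure for testing")
    fit_cml(data)
  }
  cs <- run_condition("1PL", "CML", 60, 5, 6, root_seed = 11,
                      fitter = flaky)
  expect_identical(nrow(cs), 6L)
  expect_true(any(!cs$ok))
  expect_true(any(cs$ok))
  expect_true(all(is.na(cs$rmse_theta[!cs$ok])))
  expect_match(cs$error[!cs$ok][1], "synthetic failure")
})

test_that("unknown methods and invalid pairings error early", {
  expect_error(run_condition("2PL", "CML", 50, 5, 1, 1), "1PL")
  expect_error(run_condition("1PL", "EAP-matched", 50, 5, 1, 1),
               "unknown estimation method")
  expect_setequal(study_methods("1PL"),
                  c("CML", "MML", "MCMC-matched", "MCMC-stdvague",
                    "MCMC-hierarchical", "VB-matched", "VB-stdvague",
                    "VB-hierarchical"))
  expect_false("CML" %in% study_methods("2PL"))
})

test_that("studies resume from per-cell files and enumerate all cells", {
  outdir <- file.path(tempdir(), "irtlab-study-test")
  unlink(outdir, recursive = TRUE)
  cfg <- list(models = "1PL", sample_sizes = c(40, 60), test_lengths = c(5),
              methods = c("CML", "VB-matched"), replications = 2,
              root_seed = 5)
  res <- run_study(cfg, outdir, verbose = FALSE)
  files <- list.files(outdir, pattern = "^cell_")
  expect_length(files, 4) # 2 sample sizes x 1 length x 2 methods
  expect_identical(nrow(res), 8L)
  # deleting one cell recomputes only that cell (others keep their mtime)
  victim <- file.path(outdir, files[1])
  keeper <- file.path(outdir, files[2])
  before <- file.mtime(keeper)
  Sys.sleep(1.1)
  unlink(victim)
  res2 <- run_study(cfg, outdir, verbose = FALSE)
  expect_identical(file.mtime(keeper), before)
  expect_true(file.exists(victim))
  # resumed study reproduces the identical combined summary
  expect_equal(res2[order(res2$method, res2$S, res2$rep), ],
               res[order(res$method, res$S, res$rep), ],
               ignore_attr = TRUE)
  unlink(outdir, recursive = TRUE)
})

test_that("empty designs produce empty results without error", {
  outdir <- file.path(tempdir(), "irtlab-empty-study")
  unlink(outdir, recursive = TRUE)
  cfg <- list(models = "1PL", sample_sizes = integer(0),
              test_lengths = c(5), methods = "CML", replications = 1,
              root_seed = 1)
  res <- run_study(cfg, outdir, verbose = FALSE)
  expect_null(res)
  unlink(outdir, recursive = TRUE)
})

test_that("marginal tables aggregate cells with equal weight", {
  # synthetic summary with known per-cell values
  mk <- function(method, S, L, val) {
    data.frame(model = "1PL", method = method, S = S, L = L, rep = 1:2,
               rmse_theta = val, rmse_b = val / 2, rmse_a = 0,
               rmse_p = val / 4, mean_se_theta = val, mean_se_b = val,
               mean_se_a = 0, align_s = 1, align_t = 0, checksum = 0,
               ok = TRUE, error = "")
  }
  summ <- rbind(mk("CML", 250, 10, 0.8), mk("CML", 250, 20, 0.6),
                mk("CML", 500, 10, 0.4), mk("CML", 500, 20, 0.2),
                mk("MML", 250, 10, 1.0), mk("MML", 250, 20, 1.0),
                mk("MML", 500, 10, 1.0), mk("MML", 500, 20, 1.0))
  t3 <- tabulate_results(summ, "T3")
  expect_equal(t3$ability_rmse[t3$method == "CML"], mean(c(0.8, 0.6, 0.4,
                                                           0.2)))
  expect_equal(t3$difficulty_rmse[t3$method == "MML"], 0.5)
  t4 <- tabulate_results(summ, "T4")
  row <- t4[t4$metric == "ab_rmse" & t4$level == 10, ]
  expect_equal(row$CML, mean(c(0.8, 0.4)))
  expect_equal(row$MML, 1.0)
  expect_error(tabulate_results(summ, "T8"), "no 2PL results")
})

test_that("single-cell studies degenerate to that cell's means", {
  cs <- run_condition("1PL", "CML", 60, 5, 3, root_seed = 13)
  t3 <- tabulate_results(cs, "T3")
  expect_identical(nrow(t3), 1L)
  expect_equal(t3$ability_rmse, mean(cs$rmse_theta))
  expect_equal(t3$probability_rmse, mean(cs$rmse_p))
})

test_that("study configurations validate and read from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("models: 1PL", "sample_sizes: [40]", "test_lengths: [5]",
               "methods: [CML]", "replications: 2", "root_seed: 3"), f)
  cfg <- read_study_config(f)
  expect_identical(cfg$models, "1PL")
  expect_identical(cfg$replications, 2L)
  unlink(f)
  expect_error(validate_study_config(list(models = "3PL",
                                          sample_sizes = 10,
                                          test_lengths = 5,
                                          replications = 1)))
})
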