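# I/O round trips, configuration validation, and the umbrella pipeline.

test_that("window files round-trip and malformed input is reported with line numbers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  w1 <- sample_gaussian_work(1, 2, n_f = 20, n_r = 20, seed = 1,
                             lambda_low = 0, lambda_high = 0.5)
  w2 <- sample_gaussian_work(2, 2, n_f = 20, n_r = 20, seed = 2,
                             lambda_low = 0.5, lambda_high = 1)
  write_window_file(list(w1, w2), tmp)
  back <- read_window_file(tmp)
  expect_length(back, 2L)
  expect_equal(back[[1]]$dU_forward, w1$dU_forward, tolerance = 1e-12)
  expect_equal(back[[2]]$dU_backward, w2$dU_backward, tolerance = 1e-12)
  expect_equal(back[[1]]$lambda_high, 0.5)

  # empty file is an input error, not an empty result
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("lambda_low\tlambda_high\tdirection\tdU", empty)
  expect_error(read_window_file(empty), "empty")

  # a NaN cell is reported with its line number
  badf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lambda_low\tlambda_high\tdirection\tdU",
               "0\t1\tfwd\t1.5",
               "0\t1\tfwd\tNaN",
               "0\t1\trev\t-1.0",
               "0\t1\trev\t-2.0"), badf)
  expect_error(read_window_file(badf), "line\\(s\\): 3")

  baddir <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lambda_low\tlambda_high\tdirection\tdU",
               "0\t1\tsideways\t1.5"), baddir)
  expect_error(read_window_file(baddir), "direction")
})

test_that("u_kn files round-trip with their lambda schedule and temperature", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  rps <- sample_harmonic_alchemy(1, 4, lambda_schedule = c(0, 0.5, 1),
                                 n_per_state = 15, seed = 4, temperature = 310)
  write_ukn_file(rps, tmp)
  back <- read_ukn_file(tmp)
  expect_equal(back$lambdas, rps$lambdas)
  expect_equal(back$temperature, 310)
  expect_equal(back$u, rps$u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$origin, rps$origin)
})

test_that("network edge/ligand files round-trip including conformer selections", {
  ed <- withr::local_tempfile(fileext = ".csv")
  li <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("from,to,value,se,conformer,selected",
               "81,82,-13.2,0.5,conf1,TRUE",
               "81,82,-16.4,0.5,conf2,FALSE",
               "82,ref,13.3,0.3,conf1,FALSE",
               "82,ref,16.4,0.3,conf2,TRUE"), ed)
  writeLines(c("id,set,exp_dg,is_reference",
               "81,1,-38.2,FALSE",
               "82,1,-28.2,FALSE",
               "ref,1,NA,TRUE"), li)
  net <- read_network_files(ed, li)
  expect_equal(relative_affinity(net, "81", "ref")$value, 3.2,
               tolerance = 1e-12)
})

test_that("run configurations validate inputs and merge YAML thresholds", {
  expect_error(run_config(temperature = -10), "positive")
  expect_error(run_config(n_boot = 1), ">= 2")
  expect_error(run_config(windows_file = "does/not/exist.tsv"), "not found")
  expect_error(run_config(thresholds = list(omega = 0.7)), "thresholds")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("temperature: 310",
               "seed: 12",
               "thresholds:",
               "  omega: 0.8"), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$temperature, 310)
  expect_equal(cfg$seed, 12L)
  expect_equal(cfg$thresholds$omega, 0.8)
  expect_equal(cfg$thresholds$wmax, 0.3)  # default retained
})

test_that("the pipeline runs end-to-end on synthetic inputs and is reproducible", {
  dir_in <- withr::local_tempdir()
  wfile <- file.path(dir_in, "windows.tsv")
  kt <- kT(300)
  wins <- lapply(1:3, function(i) {
    lam <- c(0, 0.4, 0.7, 1)
    sample_gaussian_work(1, 0.3 * kt, n_f = 100, n_r = 100, seed = i,
                         lambda_low = lam[i], lambda_high = lam[i + 1])
  })
  write_window_file(wins, wfile)

  # network inputs from a synthetic ground-truth graph
  node_dg <- c(A = -30, B = -35, C = -28, ref = -20)
  net <- generate_network(node_dg, rbind(c("A", "ref"), c("B", "ref"),
                                         c("C", "ref")),
                          reference_ids = "ref", noise_sd = 0.3, seed = 3)
  sel <- fesbench:::pn_select_conformers(net)
  efile <- file.path(dir_in, "edges.csv"); lfile <- file.path(dir_in, "ligands.csv")
  write.csv(sel, efile, row.names = FALSE)
  write.csv(data.frame(id = net$ligands$id, set = 1,
                       exp_dg = net$ligands$exp_dg,
                       is_reference = net$ligands$is_reference),
            lfile, row.names = FALSE)

  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg1 <- run_config(windows_file = wfile, edges_file = efile,
                     ligands_file = lfile, n_boot = 50, seed = 42,
                     out_dir = out1)
  res1 <- run_pipeline(cfg1)

  # window stage: three windows diagnosed, none needing refinement
  expect_length(res1$windows$per_window, 3L)
  expect_equal(res1$windows$n_refine, 0L)
  # the summed BAR over the path recovers the planted total within 3 SE
  implied <- sum(vapply(wins, attr, numeric(1), "implied_dg"))
  expect_lt(abs(res1$windows$total_bar - implied),
            3 * res1$windows$total_bar_se)

  # network stage recovers the true node differences (noise 0.3/edge)
  tab <- res1$network$table
  truth <- node_dg[tab$to] - node_dg[tab$from]
  expect_lt(max(abs(tab$calc - truth)), 3 * 0.3 * sqrt(2))

  # reruns with the same seed are byte-identical
  cfg2 <- run_config(windows_file = wfile, edges_file = efile,
                     ligands_file = lfile, n_boot = 50, seed = 42,
                     out_dir = out2)
  run_pipeline(cfg2)
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))

  expect_true(file.exists(file.path(out1, "relative_affinities.csv")))
})

test_that("stage failures abort with a stage-tagged error", {
  dir_in <- withr::local_tempdir()
  wfile <- file.path(dir_in, "w.tsv")
  writeLines(c("lambda_low\tlambda_high\tdirection\tdU",
               "0\t1\tfwd\tNaN"), wfile)
  cfg <- run_config(windows_file = wfile)
  expect_error(run_pipeline(cfg), "stage `windows` failed")
})
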