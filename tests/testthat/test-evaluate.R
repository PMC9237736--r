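test_that("self-evaluation of a corpus against itself is perfect", {
  sim <- generate_dataset(synthetic_config(d = 7), 280, seed = 2)
  rep <- evaluate(sim$data, sim$data, dag = sim$dag, subset_size = 20, seed = 3)
  row <- rep$rows[[1]]
  expect_equal(row$mmd, 0, tolerance = 1e-12)
  expect_equal(row$gaussian_mmd, 0, tolerance = 1e-6)
  expect_equal(row$mrr, 1)
  expect_equal(row$mrr_b, 1)
  expect_equal(row$delta_entropy, 0)
  expect_equal(row$delta_distance, 0)
  expect_true(all(unlist(row$per_label_ranks) == 1))
})

test_that("vocabulary mismatches are reported with the offending terms", {
  sim <- generate_dataset(synthetic_config(d = 7), 100, seed = 4)
  gen <- sim$data
  gen$vocabulary <- c(gen$vocabulary, "TX")
  gen$labels[[1]] <- c(gen$labels[[1]], "TX")
  expect_error(evaluate(sim$data, gen), "TX")
})

test_that("controls bracket the model row as in a positive/negative design", {
  sim <- generate_dataset(synthetic_config(d = 7, signal = 0.6), 400, seed = 5)
  gen <- generate_dataset(synthetic_config(d = 7, signal = 0.6), 400, seed = 6)
  rep <- evaluate(sim$data, gen$data, dag = sim$dag, subset_size = 25,
                  controls = TRUE, seed = 7)
  models <- vapply(rep$rows, `[[`, character(1), "model")
  expect_setequal(models, c("model", "positive_control", "negative_control"))
  pos <- rep$rows[[which(models == "positive_control")]]
  neg <- rep$rows[[which(models == "negative_control")]]
  expect_lt(pos$mmd, 0.1)          # real-vs-real: near zero
  expect_gte(pos$mrr, 0.75)        # near-maximal up to finite-subset noise
  expect_gt(neg$mmd, 1)            # constant sequence: large distribution shift
  expect_lt(abs(neg$mrr - sum(1 / (1:7)) / 7), 0.1)  # randomized labels
  expect_lt(neg$delta_entropy, 0)  # repeated sequence: diversity collapse
  expect_lt(neg$delta_distance, 0)
})

test_that("reports round-trip through JSON with identical values", {
  sim <- generate_dataset(synthetic_config(d = 7), 150, seed = 8)
  rep <- evaluate(sim$data, sim$data, dag = sim$dag, subset_size = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  for (nm in c("mmd", "gaussian_mmd", "mrr", "mrr_b",
               "delta_entropy", "delta_distance")) {
    expect_equal(back$rows[[1]][[nm]], rep$rows[[1]][[nm]])
  }
  expect_true(file.exists(sub("\\.json$", ".tsv", f)))
  expect_output(print(rep), "MRR")
})

test_that("the end-to-end file pipeline and CLI complete on simulated data", {
  dir <- withr::local_tempdir()
  code <- cli_main(c("simulate", "--d", "7", "--n", "300", "--seed", "1",
                     "--out", dir))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(dir, "sequences.fasta")))
  # n-gram generation from the simulated corpus
  gdir <- file.path(dir, "gen")
  code <- cli_main(c("generate", "--mode", "per_label",
                     "--fasta", file.path(dir, "sequences.fasta"),
                     "--labels", file.path(dir, "labels.tsv"),
                     "--count", "30", "--seed", "2", "--out", gdir))
  expect_equal(code, 0L)
  out_json <- file.path(dir, "report.json")
  expect_output(code <- cli_main(c(
    "evaluate",
    "--real-fasta", file.path(dir, "sequences.fasta"),
    "--real-labels", file.path(dir, "labels.tsv"),
    "--gen-fasta", file.path(gdir, "generated.fasta"),
    "--gen-labels", file.path(gdir, "generated_labels.tsv"),
    "--dag", file.path(dir, "dag.tsv"),
    "--subset-size", "15", "--seed", "3", "--out", out_json)))
  expect_equal(code, 0L)
  rep <- read_report(out_json)
  row <- rep$rows[[1]]
  for (nm in c("mmd", "gaussian_mmd", "mrr", "mrr_b",
               "delta_entropy", "delta_distance"))
    expect_true(is.finite(row[[nm]]))
  # unknown subcommand: usage + exit 2
  expect_output(expect_equal(cli_main("frobnicate"), 2L), "usage")
})
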