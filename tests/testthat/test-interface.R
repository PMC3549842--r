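test_that("amino-acid classification partitions the twenty letters 10/10", {
  expect_identical(hp_from_protein("GAVL"), "HHHH")
  expect_identical(hp_from_protein("STCN"), "PPPP")
  expect_identical(hp_from_protein("GS"), "HP")
  all20 <- "GAPVLIMFYWSTCNQKHRDE"
  mapped <- strsplit(hp_from_protein(all20), "")[[1]]
  expect_equal(sum(mapped == "H"), 10L)
  expect_equal(sum(mapped == "P"), 10L)
  for (bad in c("B", "Z", "X", "GAZL"))
    expect_error(hp_from_protein(bad), "unknown")
})

test_that("sequence files read in hp and FASTA formats with strict validation", {
  hp_file <- tempfile()
  writeLines("HPHH", hp_file)
  expect_identical(read_hp_sequence(hp_file), "HPHH")
  writeLines(c("HPH", " HPP "), hp_file)
  expect_identical(read_hp_sequence(hp_file, "hp"), "HPHHPP")
  writeLines("HPZ", hp_file)
  expect_error(read_hp_sequence(hp_file, "hp"), "invalid character")
  writeLines("", hp_file)
  expect_error(read_hp_sequence(hp_file, "hp"), "empty")
  expect_error(read_hp_sequence(tempfile()), "no such file")

  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x", "GS"), fa)
  expect_identical(as.character(read_hp_sequence(fa)), "HP")
  expect_identical(attr(read_hp_sequence(fa), "source_aa"), "GS")
  writeLines(c(">x", "GS", ">y", "AC"), fa)
  expect_error(read_hp_sequence(fa), "multi-record")
  expect_identical(as.character(read_hp_sequence(fa, record = "y")), "HP")
})

test_that("relative improvement reproduces the published comparison cells", {
  expect_equal(relative_improvement(-339, -326, -384), 22.41)
  expect_equal(relative_improvement(-340, -330, -385), 18.18)
  expect_equal(relative_improvement(-397, -375, -455), 27.50)
  expect_equal(relative_improvement(-304, -287, -355), 25)
  expect_equal(relative_improvement(-10, -10, -50), 0)
  expect_error(relative_improvement(-5, -7, -7), "undefined")
  # algebraic identity: RI * (el - er) recovers the numerator, so swapping
  # eo and er around the same el flips exactly the numerator's sign
  set.seed(6)
  for (k in 1:50) {
    v <- sort(runif(3, -400, -100))
    el <- v[1]; eo <- v[2]; er <- v[3]
    ri <- relative_improvement(eo, er, el, digits = 12)
    expect_equal(ri * (el - er), (eo - er) * 100)
    ri_swapped <- relative_improvement(er, eo, el, digits = 12)
    expect_equal(sign(ri_swapped * (el - eo)), -sign(eo - er))
  }
})

test_that("fixture sequences honour composition bounds and seeds", {
  expect_identical(generate_fixture_sequence(10, 1), strrep("H", 10))
  expect_identical(generate_fixture_sequence(10, 0), strrep("P", 10))
  expect_identical(generate_fixture_sequence(30, 0.4, seed = 5),
                   generate_fixture_sequence(30, 0.4, seed = 5))
  s <- generate_fixture_sequence(12, 0.2, seed = 9, min_h = 4)
  expect_gte(sum(strsplit(s, "")[[1]] == "H"), 4L)
  expect_error(generate_fixture_sequence(5, 0, min_h = 1), "unattainable")
})

test_that("fold results serialize completely and reproducibly", {
  r <- run_fold("HPHHPH", search_params(max_iterations = 300, seed = 2))
  dir <- tempfile()
  files <- write_fold_result(r, dir, pdb = TRUE)
  expect_true(all(file.exists(files)))
  summ <- jsonlite::read_json(files[["summary"]])
  expect_equal(summ$best_energy, r$best_energy)
  expect_equal(summ$seed, 2L)
  tr <- utils::read.csv(files[["trace"]])
  expect_equal(nrow(tr), 300L)
  expect_true(all(c("iteration", "current_fitness", "current_energy",
                    "best_energy", "event") %in% names(tr)))
  back <- read_conformation_tsv(files[["coords"]])
  expect_equal(back$coords, r$best_conformation$coords)
})

test_that("the fold CLI runs end to end and is seed-reproducible", {
  seq_file <- tempfile()
  writeLines("PPPPPP", seq_file)
  out1 <- tempfile(); out2 <- tempfile()
  argv <- function(out) c("--seq", seq_file, "--max-iter", "100",
                          "--seed", "7", "--out", out)
  expect_output(code <- cli_fold(argv(out1)), "best_energy=0")
  expect_equal(code, 0L)
  expect_output(cli_fold(argv(out2)))
  s1 <- readLines(file.path(out1, "summary.json"))
  s2 <- readLines(file.path(out2, "summary.json"))
  expect_identical(s1, s2)
  expect_equal(suppressMessages(cli_fold(c("--seq", tempfile()))), 1L)
})

test_that("the auxiliary CLI subcommands work", {
  conf_file <- tempfile(fileext = ".tsv")
  write_conformation_tsv(rhombus_conf(), conf_file)
  expect_output(code <- cli_encode(c("--coords", conf_file)),
                "canonical: 0,1,2")
  expect_equal(code, 0L)
  expect_output(code <- cli_report(c("--eo", "-339", "--er", "-326",
                                     "--el", "-384")), "22.41%")
  expect_equal(code, 0L)
  expect_output(code <- hpfold_cli(c("enumerate", "--length", "3",
                                     "--count-only")), "4 walks")
  expect_equal(code, 0L)
  expect_equal(suppressMessages(hpfold_cli("nonsense")), 1L)
})

test_that("a YAML or JSON config file can supply fold options", {
  seq_file <- tempfile()
  writeLines("PPPP", seq_file)
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seq = seq_file, max_iterations = 50, seed = 3),
                       cfg, auto_unbox = TRUE)
  out <- tempfile()
  expect_output(code <- cli_fold(c("--config", cfg, "--out", out)),
                "iterations=50")
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "summary.json")))

  ycfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seq = seq_file, max_iterations = 40, seed = 3), ycfg)
  out2 <- tempfile()
  expect_output(code <- cli_fold(c("--config", ycfg, "--out", out2)),
                "iterations=40")
  expect_equal(code, 0L)
})
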