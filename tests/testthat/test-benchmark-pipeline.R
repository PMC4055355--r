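# Assembly building, the end-to-end benchmark run, report I/O, and the CLI.

two_site_model <- function() {
  # open helix with two planted labels on one chain, well separated
  h <- make_helix(26)
  r1 <- spinlabelr:::attach_r1(h, "A", 7, c(-60, 180, -60, 180, -90))
  r2 <- spinlabelr:::attach_r1(r1$model, "A", 20, c(-60, 180, -60, 180, -90))
  r2$model
}

test_that("assembly building keeps monomeric input, strips solvent, flags completeness", {
  m <- two_site_model()
  wat <- data.frame(record = "HETATM", serial = 999L, name = "O",
                    altloc = "", resname = "HOH", chain = "W", resno = 1L,
                    icode = "", x = 50, y = 50, z = 50, occ = 1, b = 0,
                    element = "O", vdw = 1.52, stringsAsFactors = FALSE)
  m$atoms <- rbind(m$atoms, wat)
  sites <- list(list(chain = "A", resno = 7), list(chain = "A", resno = 20))
  asm <- build_benchmark_assembly(m, sites, cutoff = 0)
  expect_false("HOH" %in% asm$model$atoms$resname)
  expect_true("R1A" %in% asm$model$atoms$resname)
  expect_setequal(unique(asm$model$atoms$chain), "A")
  expect_true(all(asm$site_complete))
  expect_error(build_benchmark_assembly(m, list(list(chain = "Z",
                                                     resno = 1)), 0),
               "not found")
})

test_that("assembly expansion pulls in lattice contacts and detects truncated environments", {
  m <- two_site_model()
  m$cell <- crystal_cell(24, 26, 30)   # tight cell: lattice images touch
  sites <- list(list(chain = "A", resno = 7))
  asm <- build_benchmark_assembly(m, sites, cutoff = 10)
  expect_gt(length(unique(asm$model$atoms$chain)), 1L)
  # with a generous completeness radius but a tiny packing cutoff, the
  # selection must be flagged as truncated
  asm2 <- build_benchmark_assembly(m, sites, cutoff = 0.5, env_radius = 12)
  expect_false(all(asm2$site_complete))
})

test_that("the benchmark run is complete and byte-identical under a fixed seed", {
  m <- two_site_model()
  lib <- make_synthetic_library(40, seed = 5)
  cfg <- benchmark_config(
    sites = list(list(chain = "A", resno = 7), list(chain = "A", resno = 20)),
    library = lib, seed = 42, n_conformers = 30, max_trials = 600)
  rep1 <- run_benchmark(m, cfg)
  expect_length(rep1$sites, 2L)
  expect_length(rep1$pairs, 1L)
  for (s in rep1$sites) {
    expect_named(s$ensembles, c("accessible_volume", "rotamer"),
                 ignore.order = TRUE)
    expect_false(is.null(s$observed))
    expect_false(is.null(s$chi_deviation))
  }
  p <- rep1$pairs[[1]]
  expect_false(is.na(p$experimental_distance))
  expect_named(p$predicted, c("accessible_volume", "rotamer"),
               ignore.order = TRUE)
  for (q in p$predicted) {
    expect_gte(q$distance, 0)
    expect_gte(q$vector_angle_deviation, 0)
    expect_lte(q$vector_angle_deviation, 180)
  }
  rep2 <- run_benchmark(m, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep1, d1); write_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_identical(readLines(file.path(d1, "distances.tsv")),
                   readLines(file.path(d2, "distances.tsv")))
})

test_that("the planted conformer lies inside the accessible-volume acceptance region", {
  for (site in list(make_open_site(), make_tight_site())) {
    work <- spinlabelr:::strip_label(site$model, site$site)
    env <- clash_environment(work, site$site)
    expect_lte(clash_count(site$planted_conformer, env, scale = 0.75), 5L)
  }
})

test_that("a library missing the planted conformation reproduces the tight-site failure mode", {
  tight <- make_tight_site()
  lib <- make_synthetic_library(150, seed = 10)
  near <- apply(abs(circular_diff(as.matrix(lib$entries[, 1:5]),
                                  matrix(tight$planted_chi, 150, 5,
                                         byrow = TRUE))), 1, max) <= 30
  excl <- lib
  excl$entries <- lib$entries[!near, ]
  excl$entries$weight <- excl$entries$weight / sum(excl$entries$weight)
  ens <- place_rotamers(tight$model, tight$site, excl)
  expect_lt(length(ens$conformers), nrow(excl$entries))
  retained_chi <- t(vapply(ens$conformers, `[[`, numeric(5), "chi"))
  worst <- apply(abs(circular_diff(retained_chi,
                                   matrix(tight$planted_chi,
                                          nrow(retained_chi), 5,
                                          byrow = TRUE))), 1, max)
  expect_true(all(worst > 30))
  expect_gt(chi_deviation(tight$planted_chi, excl)$max_abs_delta, 30)
})

test_that("ensemble PDB files round-trip conformers and weights", {
  open <- make_open_site()
  ens <- sample_accessible_volume(open$model, open$site, n_conformers = 15,
                                  max_trials = 400, seed = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  chi <- read_ensemble_chi(f)
  expect_equal(nrow(chi), 15L)
  sampled <- t(vapply(ens$conformers, `[[`, numeric(5), "chi"))
  expect_lt(max(abs(circular_diff(chi, sampled))), 0.2)
})

test_that("the CLI round-trips simulate -> label -> measure-chi and fails loudly", {
  out <- withr::local_tempdir()
  expect_equal(slr_cli(c("simulate", "--out", out, "--seed", "4")), 0L)
  expect_true(all(file.exists(file.path(out, c("open_site.pdb",
                                               "tight_site.pdb",
                                               "library.txt",
                                               "manifest.json")))))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  # measure-chi on the planted fixture prints the planted chi
  txt <- capture.output(
    code <- slr_cli(c("measure-chi", "--pdb",
                      file.path(out, "open_site.pdb"))))
  expect_equal(code, 0L)
  row <- strsplit(txt[grepl("^A\t", txt)], "\t")[[1]]
  got <- as.numeric(row[3:7])
  expect_equal(abs(circular_diff(got,
                                 unlist(manifest$planted_chi))),
               rep(0, 5), tolerance = 0.2, ignore_attr = TRUE)
  # label writes an ensemble whose models all carry sampled chi
  ef <- file.path(out, "ens.pdb")
  expect_equal(slr_cli(c("label", "--pdb", file.path(out, "open_site.pdb"),
                         "--chain", "A", "--resno",
                         as.character(manifest$site), "--method",
                         "accessible_volume", "--n", "10",
                         "--seed", "2", "--out", ef)), 0L)
  expect_equal(nrow(read_ensemble_chi(ef)), 10L)
  # distances between an ensemble and itself is zero mean-position distance
  txt2 <- capture.output(
    code2 <- slr_cli(c("distances", "--ens", ef, "--ens2", ef)))
  expect_equal(code2, 0L)
  mpd <- as.numeric(strsplit(grep("mean_position_distance", txt2,
                                  value = TRUE), "\t")[[1]][2])
  expect_equal(mpd, 0, tolerance = 1e-6)
  # missing input: non-zero exit, no R error
  expect_gt(slr_cli(c("benchmark")), 0L)
  expect_gt(slr_cli(c("label", "--pdb", "absent.pdb", "--chain", "A",
                      "--resno", "5", "--method", "accessible_volume",
                      "--out", ef)), 0L)
  expect_equal(slr_cli(character(0)), 2L)
})

test_that("the benchmark CLI runs end-to-end from a config file", {
  out <- withr::local_tempdir()
  expect_equal(slr_cli(c("simulate", "--out", out, "--seed", "3")), 0L)
  cfg <- file.path(out, "bench.cfg")
  writeLines(c(paste0("pdb=", file.path(out, "tight_site.pdb")),
               "sites=A:9",
               "methods=accessible_volume,rotamer",
               paste0("library=", file.path(out, "library.txt")),
               "n_conformers=20", "max_trials=500",
               paste0("out=", file.path(out, "rep"))), cfg)
  txt <- capture.output(code <- slr_cli(c("benchmark", "--config", cfg,
                                          "--seed", "11")))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "rep", "report.json")))
  expect_true(file.exists(file.path(out, "rep", "resolved_config.txt")))
  rj <- jsonlite::read_json(file.path(out, "rep", "report.json"))
  expect_length(rj$sites, 1L)
  expect_equal(rj$seed, 11L)
})
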