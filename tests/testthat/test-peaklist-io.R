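test_that("sparky rows map to resonance peaks with parsed labels", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("# Assignment w1 w2",
               "V10N-H\t121.3\t8.45",
               "A11N-H 119.2 7.90"), f)
  pk <- read_peaklist(f)
  expect_equal(pk$residue_index, c(10L, 11L))
  expect_equal(pk$residue_label, c("V10", "A11"))
  expect_equal(pk$delta_H, c(8.45, 7.90))   # w2 is 1H in Sparky order
  expect_equal(pk$delta_N, c(121.3, 119.2))
  expect_true(all(pk$status == "observed"))
})

test_that("degenerate and malformed peak lists are handled", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(character(0), f)
  expect_equal(nrow(read_peaklist(f)), 0L)

  writeLines(c("V10N-H\t121.3\t8.45", "A11N-H\txx\t7.9"), f)
  expect_error(read_peaklist(f), "line 2")

  writeLines(c("V10N-H\t121.3\t8.45", "A10N-H\t119.0\t7.9"), f)
  expect_error(read_peaklist(f), "duplicate residue index 10")

  writeLines(c("???\t121.3\t8.45", "A11N-H\t119.0\t7.9"), f)
  expect_warning(pk <- read_peaklist(f), "unparseable")
  expect_equal(pk$status, c("unassigned", "observed"))
})

test_that("write/read round trip of a simulated series is bit-exact", {
  sim <- simulate_titration(simulation_config(seed = 11, n_broadened = 3L))
  dir <- withr::local_tempdir()
  man <- write_series(sim, dir)
  back <- read_series_manifest(man)
  expect_equal(length(back$points), length(sim$series$points))
  expect_equal(back$reference_index, sim$series$reference_index)
  for (j in seq_along(back$points)) {
    a <- sim$series$points[[j]]$peaks
    b <- back$points[[j]]$peaks
    expect_identical(b$delta_H, a$delta_H)    # bit-exact shifts, NA included
    expect_identical(b$delta_N, a$delta_N)
    expect_equal(b$status, a$status)
    expect_equal(back$points[[j]]$ligand_conc,
                 sim$series$points[[j]]$ligand_conc)
  }
})

test_that("manifest ratios expand to ligand concentrations and sort points", {
  dir <- withr::local_tempdir()
  pk <- peaks_frame(1:5, H = seq(7, 8, length.out = 5),
                    N = seq(110, 120, length.out = 5))
  for (i in 1:3) write_peaklist(pk, file.path(dir, sprintf("p%d.list", i)))
  yaml::write_yaml(list(
    series_id = "s", ligand_name = "pep", protein_conc_mM = 0.1,
    reference = 2,
    points = list(list(file = "p1.list", ratio = 4),
                  list(file = "p2.list", ratio = 0),
                  list(file = "p3.list", ratio = 10))),
    file.path(dir, "man.yaml"))
  s <- read_series_manifest(file.path(dir, "man.yaml"))
  expect_equal(vapply(s$points, function(p) p$ligand_conc, numeric(1)),
               c(0, 0.4, 1.0))
  expect_equal(s$reference_index, 1L)  # ratio-0 point after sorting

  # micromolar unit tag converts on read
  yaml::write_yaml(list(
    series_id = "s", protein_conc_uM = 100, reference = 1,
    points = list(list(file = "p1.list", ratio = 0),
                  list(file = "p2.list", ratio = 10))),
    file.path(dir, "man2.yaml"))
  s2 <- read_series_manifest(file.path(dir, "man2.yaml"))
  expect_equal(s2$points[[2]]$ligand_conc, 1.0)
})

test_that("manifest errors name the defect", {
  dir <- withr::local_tempdir()
  pk <- peaks_frame(1:3, H = c(7, 7.5, 8), N = c(110, 115, 120))
  write_peaklist(pk, file.path(dir, "p1.list"))
  base <- list(series_id = "s", protein_conc_mM = 0.1, reference = 1)

  m <- c(base, list(points = list(list(file = "p1.list", ratio = 0),
                                  list(file = "nope.list", ratio = 1))))
  yaml::write_yaml(m, file.path(dir, "m.yaml"))
  expect_error(read_series_manifest(file.path(dir, "m.yaml")),
               "point 2.*nope.list")

  m$points[[2]] <- list(file = "p1.list")  # neither ratio nor conc
  yaml::write_yaml(m, file.path(dir, "m.yaml"))
  expect_error(read_series_manifest(file.path(dir, "m.yaml")),
               "neither ratio nor ligand_conc")

  m$points[[2]] <- list(file = "p1.list", ratio = 1)
  m$reference <- NULL
  yaml::write_yaml(m, file.path(dir, "m.yaml"))
  expect_error(read_series_manifest(file.path(dir, "m.yaml")),
               "reference")
})

test_that("residues absent from later points get missing/broadened status", {
  dir <- withr::local_tempdir()
  ref <- peaks_frame(1:4, H = c(7, 7.5, 8, 8.5), N = c(110, 112, 114, 116))
  write_peaklist(ref, file.path(dir, "ref.list"))
  write_peaklist(ref[1:2, ], file.path(dir, "end.list"))
  yaml::write_yaml(list(
    series_id = "s", protein_conc_mM = 0.1, reference = 1,
    prolines = list("P9"),
    points = list(list(file = "ref.list", ratio = 0),
                  list(file = "end.list", ratio = 10,
                       broadened = list("A3")))),
    file.path(dir, "m.yaml"))
  s <- read_series_manifest(file.path(dir, "m.yaml"))
  end <- s$points[[2]]$peaks
  expect_equal(end$status[match(3:4, end$residue_index)],
               c("broadened", "missing"))
  expect_true("proline" %in% s$points[[1]]$peaks$status)
  expect_equal(s$points[[1]]$peaks$residue_label[
    s$points[[1]]$peaks$status == "proline"], "P9")
})

test_that("results tables round-trip and render lower limits with '>'", {
  fits <- data.frame(residue_index = 1:3, residue_label = paste0("A", 1:3),
                     delta_endpoint = c(0.11, 0.32, 0.05),
                     status = "ok", significant = c(TRUE, TRUE, FALSE),
                     kd = c(0.61234567, 0.7, NA), dmax = c(0.1, 0.2, NA),
                     rss = c(1e-6, 2e-6, NA), n_points = c(6L, 6L, NA),
                     converged = c(TRUE, TRUE, NA),
                     retained = c(TRUE, TRUE, FALSE))
  glob <- aggregate_global_kd(
    data.frame(residue_index = 1:2, kd = c(0.61234567, 0.7),
               converged = TRUE), significant = 1:2)
  dir <- withr::local_tempdir()
  write_results(fits, glob, dir)
  back <- read_results(dir)
  expect_equal(nrow(back$fits), 3L)
  expect_equal(back$fits$kd[1], 0.61234567, tolerance = 1e-7)
  expect_equal(back$summary$kd_mean_mM, glob$kd_mean, tolerance = 1e-12)
  expect_false(back$summary$lower_limit)

  glob$lower_limit <- TRUE
  glob$reported <- format_global_kd(glob$kd_mean, glob$kd_sd, TRUE)
  write_results(fits, glob, dir)
  expect_match(read_results(dir)$summary$reported, "^> ")
})
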