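# Compound library and synthetic-data generators.

test_that("the shipped library has 12 validated compounds with ranges", {
  lib <- load_drug_library()
  expect_length(lib, 12)
  expect_true(all(c("dofetilide", "verapamil") %in% names(lib)))
  rg <- attr(lib, "ranges")
  expect_equal(rownames(rg), c("min", "max"))
  for (p in colnames(rg)) {
    vals <- vapply(lib, `[[`, numeric(1), p)
    expect_true(all(vals >= rg["min", p] & vals <= rg["max", p]))
  }
})

test_that("example-drug aliases map to the documented compounds", {
  expect_equal(get_drug("example drug T")$name, "dofetilide")
  expect_equal(get_drug("T")$name, "dofetilide")
  expect_equal(get_drug("example drug N")$name, "verapamil")
  expect_equal(get_drug("N")$name, "verapamil")
  expect_error(get_drug("aspirin"), "unknown compound")
})

test_that("library round trip through CSV is lossless", {
  lib <- load_drug_library()
  path <- file.path(tempdir(), "lib.csv")
  write_drug_library(lib, path)
  lib2 <- load_drug_library(path)
  expect_equal(names(lib2), names(lib))
  for (nm in names(lib))
    for (p in c("Kmax", "Ku", "n", "EC50", "Vhalf_trap", "Kt"))
      expect_equal(lib2[[nm]][[p]], lib[[nm]][[p]])
})

test_that("schema violations are reported by column name", {
  tab <- utils::read.csv(system.file("extdata", "drug_library.csv",
                                     package = "hergblock"))
  tab$EC50 <- NULL
  path <- file.path(tempdir(), "broken.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(load_drug_library(path), "EC50")
  expect_error(load_drug_library(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("virtual-drug sampling is reproducible and respects ranges", {
  lib <- load_drug_library()
  rg <- attr(lib, "ranges")
  a <- sample_virtual_drugs(10, seed = 7)
  b <- sample_virtual_drugs(10, seed = 7)
  expect_length(a, 10)
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$Kmax, b[[i]]$Kmax)
    expect_equal(a[[i]]$Ku, b[[i]]$Ku)
    expect_equal(a[[i]]$Vhalf_trap, b[[i]]$Vhalf_trap)
    expect_true(a[[i]]$Kmax >= rg["min", "Kmax"] &&
                a[[i]]$Kmax <= rg["max", "Kmax"])
    expect_true(a[[i]]$Ku >= rg["min", "Ku"] && a[[i]]$Ku <= rg["max", "Ku"])
    expect_true(a[[i]]$Vhalf_trap >= rg["min", "Vhalf_trap"] &&
                a[[i]]$Vhalf_trap <= rg["max", "Vhalf_trap"])
    expect_equal(a[[i]]$n, 1)
    expect_equal(a[[i]]$EC50, 1)
  }
  expect_length(sample_virtual_drugs(0, seed = 1), 0)
  # a different seed moves the draws
  d <- sample_virtual_drugs(10, seed = 8)
  expect_false(all(vapply(seq_along(a), function(i)
    a[[i]]$Kmax == d[[i]]$Kmax, logical(1))))
})

test_that("synthetic Hill data generator matches its closed form", {
  concs <- 10^seq(0, 4, length.out = 8)
  dr <- generate_hill_data(h = 1, IC50 = 50, concs = concs)
  expect_equal(dr$response, 50 / (50 + concs), tolerance = 1e-12)
  dr2 <- generate_hill_data(h = 2, IC50 = concs[4], concs = concs)
  expect_equal(dr2$response[4], 0.5)
  # noise is reproducible and clipped
  n1 <- generate_hill_data(1, 50, concs, noise_sd = 0.5, seed = 3)
  n2 <- generate_hill_data(1, 50, concs, noise_sd = 0.5, seed = 3)
  expect_equal(n1$response, n2$response)
  expect_true(all(n1$response >= 0 & n1$response <= 1.05))
  expect_error(generate_hill_data(1, 50, concs, noise_sd = -1), "noise_sd")
})
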