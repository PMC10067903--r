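# Virtual-drug sweep machinery: normalisation, lattice construction,
# boundary refinement, and the Hill-coefficient insensitivity of the
# model-difference metric (at reduced resolution).

test_that("concentration normalisation is D / EC50", {
  expect_equal(normalise_concentration(50, 50), 1)
  expect_equal(normalise_concentration(0, 50), 0)
  expect_equal(normalise_concentration(500, 50), 10)
  expect_error(normalise_concentration(1, 0), "EC50")
  expect_error(normalise_concentration(-1, 10), "D")
})

test_that("the sweep lattice spans the library ranges with the right spacing", {
  g <- sweep_grid(5)
  rg <- attr(load_drug_library(), "ranges")
  expect_length(g$Kmax, 5)
  expect_equal(range(g$Vhalf_trap),
               unname(rg[, "Vhalf_trap"]))
  expect_equal(range(g$Kmax), unname(rg[, "Kmax"]))
  # log spacing for Kmax/Ku, linear for Vhalf_trap
  expect_equal(diff(log10(g$Kmax)), rep(diff(log10(g$Kmax))[1], 4))
  expect_equal(diff(g$Vhalf_trap), rep(diff(g$Vhalf_trap)[1], 4))
})

# build a synthetic vd_sweep object without running the pipeline
fake_sweep <- function(grid, rmsd_fun) {
  pts <- expand.grid(Vhalf_trap = grid$Vhalf_trap, Kmax = grid$Kmax,
                     Ku = grid$Ku, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(pts, signed_rmsd = NA_real_, rmsd = NA_real_,
                    md = NA_real_, hill_h = 1, hill_ic50 = 1,
                    n_points = 4L, status = "ok")
  out$rmsd <- mapply(rmsd_fun, pts$Vhalf_trap, pts$Kmax, pts$Ku)
  out$signed_rmsd <- out$rmsd
  out$md <- out$rmsd
  out$interchangeable <- out$rmsd < 30
  out$refined <- FALSE
  attr(out, "grid") <- grid
  attr(out, "interchange_ms") <- 30
  attr(out, "pipeline_args") <- list(
    conc_mult_calib = 10^seq(-2, 2, length.out = 8),
    conc_mult_compare = 10^seq(-1, 1.5, length.out = 3),
    max_beats = 100, apd_tol = 0.02)
  class(out) <- c("vd_sweep", "data.frame")
  out
}

test_that("no flag transition means no refinement points", {
  g <- list(Vhalf_trap = c(-100, -50), Kmax = c(10, 100), Ku = c(1e-4, 1e-3))
  sw <- fake_sweep(g, function(v, k, u) 5)  # uniformly interchangeable
  out <- refine_boundary(sw)
  expect_identical(nrow(out), nrow(sw))
})

test_that("a single flag transition is bracketed by a refined midpoint", {
  # transition along the Kmax axis only; the midpoint runs the real
  # pipeline, so keep the lattice minimal
  g <- list(Vhalf_trap = -50, Kmax = c(1e2, 1e6), Ku = c(1e-4))
  sw <- fake_sweep(g, function(v, k, u) if (k > 1e4) 100 else 5)
  out <- refine_boundary(sw)
  new <- out[out$refined, ]
  expect_equal(nrow(new), 1)
  expect_equal(new$Kmax, sqrt(1e2 * 1e6))  # log-midpoint
  expect_equal(new$Vhalf_trap, -50)
  expect_true(new$status == "ok")
  expect_true(is.finite(new$signed_rmsd))
  expect_identical(new$interchangeable, new$rmsd < 30)
})

test_that("the model-difference metric is insensitive to the Hill
           coefficient once concentrations track the transition", {
  # vary n over the library's range for the non-trapped example compound
  # (the fast-converging one), holding the other parameters fixed. The
  # comparison grid follows each variant's effective midpoint, so the
  # variants are compared index-wise at matched relative doses; indices
  # where any variant shows EAD-like behaviour are dropped for all, which
  # isolates the shape effect of n from the composition of the grid. The
  # RMSD must then fluctuate within 25 ms.
  n_lib <- range(vapply(load_drug_library(), `[[`, numeric(1), "n"))
  d0 <- drug_N
  tabs <- lapply(c(n_lib[1], d0$n, n_lib[2]), function(nn) {
    dd <- drug_params(Kmax = d0$Kmax, Ku = d0$Ku, n = nn, EC50 = d0$EC50,
                      Vhalf_trap = d0$Vhalf_trap,
                      name = sprintf("%s(n=%.3g)", d0$name, nn))
    compare_models(dd,
                   concentrations = effective_midpoint(dd) *
                     10^seq(-1, 1.5, length.out = 6),
                   max_beats = 500)$table
  })
  excl <- Reduce(`|`, lapply(tabs, function(tb)
    tb$ead_sd | tb$ead_cs | is.na(tb$apd90_sd) | is.na(tb$apd90_cs)))
  expect_gte(sum(!excl), 3)
  rmsds <- vapply(tabs, function(tb)
    rmsd(tb$apd90_sd, tb$apd90_cs, excl), numeric(1))
  expect_lt(diff(range(rmsds)), 25)
})
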