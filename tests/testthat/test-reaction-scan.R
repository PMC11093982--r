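# Constraint schedules, constrained minimisation and the scan driver.

test_that("schedule follows the coarse -> switch -> fine rule", {
  p <- scanProtocol(c("L/1/C1", "A/164/SG"), startDistance = 4.0,
                    covalentTarget = 1.8)
  sched <- scanSchedule(p)
  # enumerated by hand from the stated rule: 0.4 A steps until within
  # 1.0 A of the covalent distance, then 0.1 A steps down to it
  expect_equal(sched, c(4.0, 3.6, 3.2, 2.8, seq(2.7, 1.8, by = -0.1)))
  # degenerate start: single point
  p1 <- scanProtocol(c("a", "b"), startDistance = 1.8, covalentTarget = 1.8)
  expect_equal(scanSchedule(p1), 1.8)
})

test_that("schedule gaps are coarse, fine or a final remainder, ending exactly at target", {
  set.seed(42)
  for (i in 1:25) {
    cov <- runif(1, 1.3, 2.2)
    p <- scanProtocol(c("a", "b"),
                      startDistance = cov + runif(1, 0.3, 4),
                      covalentTarget = cov,
                      coarseStep = runif(1, 0.25, 0.6),
                      fineStep = runif(1, 0.05, 0.2),
                      switchOffset = runif(1, 0.5, 1.5))
    sched <- scanSchedule(p)
    expect_equal(sched[1], p@startDistance)
    expect_equal(sched[length(sched)], cov)
    gaps <- -diff(sched)
    expect_true(all(gaps > 0))
    ok <- abs(gaps - p@coarseStep) < 1e-9 | abs(gaps - p@fineStep) < 1e-9 |
      gaps < p@fineStep + 1e-9
    expect_true(all(ok))
    # coarse steps only while above covalent + offset
    coarse_at <- sched[-length(sched)][abs(gaps - p@coarseStep) < 1e-9]
    if (p@coarseStep != p@fineStep)
      expect_true(all(coarse_at > cov + p@switchOffset - 1e-9))
  }
  expect_error(scanSchedule(scanProtocol(c("a", "b"), 100, 1.5,
                                         maxPoints = 50)),
               "cap")
})

test_that("constrained minimisation hits the constraint and lowers energy", {
  ss <- makeScanSystem(barrierHeight = 30, barrierPosition = 2.5, seed = 301)
  res <- constrainedMinimize(ss$model, ss$backend, ss$protocol@pair, d = 2.0)
  at <- atoms(ss$model)
  keys <- paste0(at$chain, "/", at$resno, "/", at$name)
  ij <- match(ss$protocol@pair, keys)
  d <- sqrt(sum((res$coords[ij[1], ] - res$coords[ij[2], ])^2))
  expect_equal(d, 2.0, tolerance = 1e-6)
  expect_true(res$converged)
  # rigid atoms bit-identical
  rigid <- which(ss$model@mobility == "rigid")
  orig <- as.matrix(at[, c("x", "y", "z")])
  expect_identical(unname(res$coords[rigid, ]), unname(orig[rigid, ]))
  # fixed point: re-minimising from the solution changes nothing material
  res2 <- constrainedMinimize(ss$model, ss$backend, ss$protocol@pair, d = 2.0,
                              coords = res$coords)
  expect_equal(res2$energy, res$energy, tolerance = 1e-4)
})

test_that("a two-atom Morse system minimises to -De at its own minimum", {
  at <- fx_atoms(c("SG", "C1"), c("CYS", "LIG"), c("A", "L"), c(164, 1),
                 c(0, 0, 0, 1.81, 0, 0), element = c("S", "C"),
                 record = c("ATOM", "HETATM"))
  s <- buildStructure(at)
  model <- methods::new("ActiveSiteModel", structure = s, source = s,
                        sourceEntry = "toy", catalytic = "A/164", radius = 12,
                        ligandKey = "L/1",
                        caps = data.frame(residue = character(0),
                                          type = character(0),
                                          atomName = character(0),
                                          serial = integer(0)),
                        truncations = data.frame(residue = character(0),
                                                 side = character(0),
                                                 atomName = character(0),
                                                 dx = numeric(0),
                                                 dy = numeric(0),
                                                 dz = numeric(0)),
                        mobility = c("rigid", "mobile"))
  De <- 80
  backend <- methods::new("PESBackend", name = "pure-morse",
                          energy = function(xyz, model = NULL) {
                            r <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
                            morseEnergy(r, De, 1.8, 1.81)
                          }, gradient = NULL)
  res <- constrainedMinimize(model, backend, c("A/164/SG", "L/1/C1"), d = 1.81)
  expect_equal(res$energy, -De, tolerance = 1e-4)
})

test_that("scan barrier matches the dense-grid oracle on seeded systems", {
  heights <- c(18, 35, 47)
  positions <- c(2.2, 2.45, 2.7)
  for (i in seq_along(heights)) {
    ss <- makeScanSystem(barrierHeight = heights[i],
                         barrierPosition = positions[i], seed = 310 + i)
    prof <- runScan(ss$model, ss$backend, ss$protocol)
    oracle <- fx_grid_barrier(ss$manifest)
    expect_lt(abs(activationEnergy(prof) - oracle$height), 0.1)
    expect_lt(abs(transitionState(prof)$distance - oracle$position),
              0.1 + 1e-9)
    expect_false(prof@partial)
  }
})

test_that("a purely attractive profile has its TS at the first state", {
  ss <- makeScanSystem(barrierHeight = 20, barrierPosition = 2.5, seed = 320)
  at <- atoms(ss$model)
  keys <- paste0(at$chain, "/", at$resno, "/", at$name)
  ij <- match(ss$protocol@pair, keys)
  attract <- methods::new("PESBackend", name = "single-morse",
                          energy = function(xyz, model = NULL) {
                            r <- sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2))
                            morseEnergy(r, 60, 1.5, ss$protocol@covalentTarget)
                          }, gradient = NULL)
  prof <- runScan(ss$model, attract, ss$protocol)
  expect_equal(prof@tsIndex, 1L)
  expect_equal(activationEnergy(prof), 0)
  expect_lt(reactionEnthalpy(prof), 0)
})

test_that("profile endpoints reproduce direct backend evaluations", {
  ss <- makeScanSystem(barrierHeight = 25, barrierPosition = 2.4, seed = 321)
  prof <- runScan(ss$model, ss$backend, ss$protocol)
  n <- length(prof@distances)
  e_first <- ss$backend@energy(prof@coords[[1]], ss$model)
  e_last <- ss$backend@energy(prof@coords[[n]], ss$model)
  expect_identical(prof@energies[1], e_first)
  expect_identical(prof@energies[n], e_last)
})

test_that("activation energy is invariant to a constant energy shift", {
  ss <- makeScanSystem(barrierHeight = 22, barrierPosition = 2.5, seed = 322)
  prof0 <- runScan(ss$model, ss$backend, ss$protocol)
  base <- ss$backend@energy
  shifted <- methods::new("PESBackend", name = "shifted",
                          energy = function(xyz, model = NULL)
                            base(xyz, model) + 123.456,
                          gradient = NULL)
  prof1 <- runScan(ss$model, shifted, ss$protocol)
  expect_equal(activationEnergy(prof1), activationEnergy(prof0),
               tolerance = 1e-6)
  expect_equal(reactionEnthalpy(prof1), reactionEnthalpy(prof0),
               tolerance = 1e-6)
})

test_that("profiles rank by activation energy with labels preserved", {
  lo <- makeScanSystem(barrierHeight = 40, barrierPosition = 2.4, seed = 330)
  hi <- makeScanSystem(barrierHeight = 50, barrierPosition = 2.4, seed = 331)
  p_lo <- runScan(lo$model, lo$backend, lo$protocol, label = "k1")
  p_hi <- runScan(hi$model, hi$backend, hi$protocol, label = "k2")
  tab <- compareProfiles(list(p_hi, p_lo))
  expect_equal(tab$label, c("k1", "k2"))
  expect_true(tab$activation_energy[1] < tab$activation_energy[2])
  one <- compareProfiles(list(p_lo))
  expect_equal(nrow(one), 1L)
})

test_that("zero coupling reduces the adiabat to the lower diabat with a cusp", {
  d <- seq(1.8, 4, by = 0.01)
  e1 <- 0.5 * 20 * (d - 4)^2
  e2 <- morseEnergy(d, 90, 1.7, 1.81) + 30
  expect_equal(adiabaticEnergy(e1, e2, 0), pmin(e1, e2))
  # positive coupling strictly lowers the surface at the crossing
  w <- adiabaticEnergy(e1, e2, 5)
  expect_true(all(w <= pmin(e1, e2)))
})

test_that("external backend adapter parses engine output and fails cleanly", {
  expect_error(externalBackend("no-such-engine-xyz"), "not found")
  mock <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'FINAL HEAT OF FORMATION = -42.75 KCAL/MOL'"),
             mock)
  Sys.chmod(mock, "0755")
  be <- externalBackend(mock)
  e <- be@energy(matrix(0, 2, 3))
  expect_equal(e, -42.75)
  # a coordinate-dependent mock drives a scan end to end
  mock2 <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "n=$(awk 'NR==9 {print $2}' \"$1\")",
               "echo \"FINAL HEAT OF FORMATION = $n KCAL/MOL\""), mock2)
  Sys.chmod(mock2, "0755")
  be2 <- externalBackend(mock2)
  ss <- makeScanSystem(barrierHeight = 20, barrierPosition = 2.5, seed = 340)
  prof <- runScan(ss$model, be2, ss$protocol)
  expect_length(prof@energies, length(scanSchedule(ss$protocol)))
})
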