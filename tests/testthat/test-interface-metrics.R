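# SASA, buried interface area and interaction-pair finders.

test_that("isolated-nitrogen SASA matches the analytic sphere within 1%", {
  s <- fx_structure("N", "ALA", "A", 1, c(0, 0, 0), element = "N")
  got <- sasa(s, probe = 1.4, n = 960)
  analytic <- 4 * pi * (1.55 + 1.4)^2
  expect_lt(abs(got$total - analytic) / analytic, 0.01)
  expect_equal(got$total, sum(got$perAtom))
})

test_that("adding an atom never increases another atom's exposed area", {
  set.seed(11)
  base <- fx_atoms(paste0("C", 1:8), "LIG", "L", 1,
                   as.vector(t(matrix(rnorm(24, sd = 2), ncol = 3))),
                   element = "C", record = "HETATM")
  s0 <- buildStructure(base)
  before <- sasa(s0, probe = 1.4, n = 480)$perAtom
  extra <- rbind(base, transform(base[1, ], serial = 9L, name = "C9",
                                 x = 1.1, y = 0.4, z = -0.2))
  after <- sasa(buildStructure(extra), probe = 1.4, n = 480)$perAtom[1:8]
  expect_true(all(after <= before + 1e-9))
})

test_that("cluster SASA agrees with a 10x denser sampling", {
  set.seed(13)
  at <- fx_atoms(paste0("C", 1:20), "LIG", "L", 1,
                 as.vector(t(matrix(rnorm(60, sd = 2.2), ncol = 3))),
                 element = "C", record = "HETATM")
  s <- buildStructure(at)
  coarse <- sasa(s, probe = 1.4, n = 960)$total
  dense <- sasa(s, probe = 1.4, n = 9600)$total
  expect_lt(abs(coarse - dense) / dense, 0.01)
})

test_that("buried interface area is symmetric and vanishes for far chains", {
  dm <- makeDimerFixture(2, 3, 4, seed = 401)
  ab <- buriedInterfaceArea(dm$a, dm$b, n = 480)
  ba <- buriedInterfaceArea(dm$b, dm$a, n = 480)
  expect_equal(ab, ba)
  expect_gt(ab, 0)
  far <- applyTransform(dm$b, Transform(translation = c(500, 0, 0)))
  expect_equal(buriedInterfaceArea(dm$a, far, n = 480), 0)
})

test_that("salt bridges respect atom typing and the 4.0 A cutoff", {
  asp <- fx_structure(c("CG", "OD1", "OD2"), "ASP", "A", 96,
                      c(0, 0, 0, 1.2, 0.5, 0, 1.2, -0.5, 0),
                      element = c("C", "O", "O"))
  arg_near <- fx_structure(c("CZ", "NH1"), "ARG", "B", 259,
                           c(5.9, 0.5, 0, 4.7, 0.5, 0), element = c("C", "N"))
  got <- findSaltBridges(asp, arg_near)   # OD1-NH1 at 3.5 A
  expect_equal(nrow(got), 1L)
  expect_equal(got$resA, "A/96")
  expect_equal(got$dist, 3.5, tolerance = 1e-6)
  arg_far <- fx_structure(c("CZ", "NH1"), "ARG", "B", 259,
                          c(6.9, 0.5, 0, 5.7, 0.5, 0), element = c("C", "N"))
  expect_equal(nrow(findSaltBridges(asp, arg_far)), 0L)  # 4.5 A
  # ordering does not matter
  expect_equal(nrow(findSaltBridges(arg_near, asp)), 1L)
})

test_that("hydrogen bonds use distance, plus angle when hydrogens exist", {
  donor <- fx_structure("N", "GLY", "A", 1, c(0, 0, 0), element = "N")
  acc_near <- fx_structure("O", "GLY", "B", 1, c(2.9, 0, 0), element = "O")
  acc_far <- fx_structure("O", "GLY", "B", 1, c(3.5, 0, 0), element = "O")
  expect_equal(nrow(findHbonds(donor, acc_near)), 1L)
  expect_equal(nrow(findHbonds(donor, acc_far)), 0L)
  # with an H pointing toward the acceptor the bond is kept ...
  donor_h_to <- fx_structure(c("N", "H"), "GLY", "A", 1,
                             c(0, 0, 0, 1.0, 0, 0), element = c("N", "H"))
  expect_equal(nrow(findHbonds(donor_h_to, acc_near)), 1L)
  # ... with the H pointing away (D-H...A angle < 90) it is rejected
  donor_h_away <- fx_structure(c("N", "H"), "GLY", "A", 1,
                               c(0, 0, 0, -1.0, 0, 0), element = c("N", "H"))
  expect_equal(nrow(findHbonds(donor_h_away, acc_near)), 0L)
})

test_that("nonbonded contacts count heavy-atom pairs minus hydrogen bonds", {
  a <- fx_structure(c("CA", "CB"), "ALA", "A", 1, c(0, 0, 0, 1.5, 0, 0),
                    element = c("C", "C"))
  b <- fx_structure("CB", "ALA", "B", 1, c(5.3, 0, 0), element = "C")
  got <- nonbondedContacts(a, b)      # CB...CB at 3.8; CA...CB at 5.3
  expect_equal(got$count, 1L)
  far <- fx_structure("CB", "ALA", "B", 1, c(50, 0, 0), element = "C")
  expect_equal(nonbondedContacts(a, far)$count, 0L)
  # an O...N pair inside hbond range is excluded from the nonbonded count
  d <- fx_structure("O", "GLY", "A", 1, c(0, 0, 0), element = "O")
  e <- fx_structure("N", "GLY", "B", 1, c(2.9, 0, 0), element = "N")
  expect_equal(nonbondedContacts(d, e)$count, 0L)
})

test_that("planted dimer counts are recovered exactly and match the O(n^2) oracle", {
  dm <- makeDimerFixture(4, 7, 11, seed = 402)
  rep <- interfaceReport(dm$a, dm$b, n = 240)
  expect_equal(nrow(rep$saltBridges), 4L)
  expect_equal(nrow(rep$hbonds), 7L)
  expect_equal(rep$nonbondedCount, 11L)
  # brute-force cross-check: every heavy pair within 3.9 A, minus hbonds
  expect_equal(rep$nonbondedCount + nrow(rep$hbonds),
               fx_pair_count(dm$a, dm$b, 3.9) +
                 sum(rep$hbonds$dist > 3.9))
  expect_gt(rep$buriedAreaPerProtomer, 0)
})

test_that("polar contacts pick N/O/S pairs within 3.5 A with distances", {
  lig <- fx_structure(c("C1", "O1"), "LIG", "L", 1,
                      c(0, 0, 0, 1.2, 0, 0), element = c("C", "O"),
                      record = "HETATM")
  prot <- fx_structure(c("NZ", "CB"), "LYS", "A", 269,
                       c(4.0, 0, 0, 3.0, 2.0, 0), element = c("N", "C"))
  got <- polarContacts(lig, prot)
  expect_equal(nrow(got), 1L)
  expect_equal(got$dist, 2.8, tolerance = 0.01)
  none <- polarContacts(lig, applyTransform(prot, Transform(translation = c(20, 0, 0))))
  expect_equal(nrow(none), 0L)
})

test_that("interface reports are invariant under rigid motion of the complex", {
  dm <- makeDimerFixture(3, 5, 8, seed = 403)
  th <- 1.1
  rot <- Transform(rotation = rbind(c(cos(th), -sin(th), 0),
                                    c(sin(th), cos(th), 0),
                                    c(0, 0, 1)),
                   translation = c(7, -3, 11))
  a2 <- applyTransform(dm$a, rot)
  b2 <- applyTransform(dm$b, rot)
  r1 <- interfaceReport(dm$a, dm$b, n = 240)
  r2 <- interfaceReport(a2, b2, n = 240)
  expect_equal(nrow(r1$saltBridges), nrow(r2$saltBridges))
  expect_equal(nrow(r1$hbonds), nrow(r2$hbonds))
  expect_equal(r1$nonbondedCount, r2$nonbondedCount)
  # deterministic sampling directions are fixed in space, so the buried
  # area is rotation invariant only up to the sampling resolution
  expect_equal(r1$buriedAreaPerProtomer, r2$buriedAreaPerProtomer,
               tolerance = 0.02)
})
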