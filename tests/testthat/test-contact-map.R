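# Probe surfaces, contact-area classification, traces and mutagenesis.

test_that("isolated-atom exposed area matches the analytic sphere within 1%", {
  at <- fx_atoms("C1", "LIG", "L", 1, c(0, 0, 0), element = "C",
                 record = "HETATM")
  surf <- sampleSurface(at, probe = 1.5, n = 960)
  analytic <- 4 * pi * (1.70 + 1.5)^2
  expect_lt(abs(totalArea(surf) - analytic) / analytic, 0.01)
  # coincident identical atoms fully occlude each other
  at2 <- rbind(at, transform(at, serial = 2L, name = "C2"))
  expect_equal(totalArea(sampleSurface(buildStructure(at2), probe = 1.5)), 0)
  expect_error(sampleSurface(at, n = 50), "92")
  expect_error(sampleSurface(transform(at, element = "XX")), "XX")
})

test_that("cluster surface area converges with sampling density", {
  set.seed(7)
  at <- fx_atoms(paste0("C", 1:10), "LIG", "L", 1,
                 as.vector(t(matrix(rnorm(30, sd = 1.6), ncol = 3))),
                 element = "C", record = "HETATM")
  coarse <- totalArea(sampleSurface(at, probe = 1.5, n = 960))
  dense <- totalArea(sampleSurface(at, probe = 1.5, n = 9600))
  expect_lt(abs(coarse - dense) / dense, 0.01)
})

test_that("contact classification boundary at 0.5 A^2 is exact", {
  expect_equal(classifyContact(0), "none")
  expect_equal(classifyContact(0.49), "minor")
  expect_equal(classifyContact(0.5), "major")
  expect_equal(classifyContact(0.4999999), "minor")
  expect_equal(classifyContact(3.7), "major")
  expect_error(classifyContact(-0.1), "negative")
})

test_that("contact areas match the brute-force point-assignment oracle", {
  # planted: one receptor atom 2.5 A from the substrate atom, decoys > 6 A
  sub <- fx_atoms("C1", "LIG", "L", 1, c(0, 0, 0), element = "C",
                  record = "HETATM")
  rec <- fx_structure(c("CB", "CB", "CB"), c("ALA", "ALA", "ALA"), "A",
                      1:3, c(5.7, 0, 0, 12, 0, 0, 0, 13, 0), element = "C")
  surf <- sampleSurface(sub, probe = 1.5, n = 960)
  got <- residueContactAreas(surf, rec, cutoff = 3.0)
  expect_equal(got$residue, "A/1")
  expect_gt(got$area, 0)
  oracle <- fx_contact_oracle(surf, rec, cutoff = 3.0)
  expect_equal(got$area, unname(oracle["A/1"]))

  # multi-residue case: nearest-assignment equals the oracle and partitions
  rec2 <- fx_structure(c("CB", "OG", "NZ"), c("ALA", "SER", "LYS"), "A",
                       1:3, c(5.5, 0, 0, 0, 5.4, 0.4, -5.3, 0.5, 0),
                       element = c("C", "O", "N"))
  got2 <- residueContactAreas(surf, rec2, cutoff = 3.0)
  oracle2 <- fx_contact_oracle(surf, rec2, cutoff = 3.0)
  expect_setequal(got2$residue, names(oracle2))
  expect_equal(got2$area[order(got2$residue)],
               unname(oracle2[order(names(oracle2))]))
  # partition: per-residue areas never exceed the exposed surface total
  expect_lte(sum(got2$area), totalArea(surf) + 1e-9)

  # receptor beyond the cutoff everywhere: empty record list
  far <- fx_structure("CB", "ALA", "A", 1, c(50, 0, 0), element = "C")
  expect_equal(nrow(residueContactAreas(surf, far, cutoff = 3.0)), 0L)
})

test_that("contact traces are consistent per state and drop absent contacts", {
  sub_at <- fx_atoms("C1", "LIG", "L", 1, c(0, 0, 0), element = "C",
                     record = "HETATM")
  rec_at <- fx_atoms(c("CB", "OG"), c("ALA", "SER"), "A", 1:2,
                     c(5.5, 0, 0, 0, 5.6, 0), element = c("C", "O"))
  state1 <- fx_bind(rec_at, sub_at)
  # state 2: ligand moved 10 A away
  sub_far <- transform(sub_at, x = x + 10, y = y + 10)
  state2 <- fx_bind(rec_at, sub_far)
  trace <- contactTrace(list(bound = state1, apart = state2), "LIG")
  expect_true(all(trace$class[trace$state == "apart"] == "none"))
  # single state equals residueContactAreas directly
  single <- contactTrace(list(only = state1), "LIG")
  split1 <- qnsmech:::.split_substrate(state1, "LIG")
  direct <- residueContactAreas(sampleSurface(split1$ligand, 1.5, 960),
                                split1$receptor, 3.0)
  expect_equal(sort(single$area[single$area > 0]), sort(direct$area))
  # per-state classes match a brute-force recomputation on a 3-state path
  sub_mid <- transform(sub_at, x = x + 2.0)
  state3 <- fx_bind(rec_at, sub_mid)
  tr3 <- contactTrace(list(s1 = state1, s2 = state3, s3 = state2), "LIG")
  for (lab in c("s1", "s2", "s3")) {
    st <- list(s1 = state1, s2 = state3, s3 = state2)[[lab]]
    sp <- qnsmech:::.split_substrate(st, "LIG")
    oracle <- fx_contact_oracle(sampleSurface(sp$ligand, 1.5, 960),
                                sp$receptor, 3.0)
    for (res in unique(tr3$residue)) {
      want <- if (res %in% names(oracle)) unname(oracle[res]) else 0
      expect_equal(tr3$area[tr3$residue == res & tr3$state == lab], want)
    }
  }
  expect_error(contactTrace(list(a = state1), "ZZZ"), "missing from state")
})

test_that("supported mutations edit the expected atom sets", {
  s <- fx_bind(fx_residue("LEU", "A", 263), fx_residue("SER", "A", 338, c(8, 0, 0)),
               fx_residue("ASN", "A", 336, c(16, 0, 0)))
  # L -> A: side chain reduced to CB
  la <- applyMutation(s, mutationSpec("A/263", "LEU", "ALA"))
  at <- atoms(la)
  expect_setequal(at$name[at$resno == 263], c("N", "CA", "C", "O", "CB"))
  expect_equal(unique(at$resname[at$resno == 263]), "ALA")
  # S -> T: exactly one heavy atom added at 1.52 A from CB
  st <- applyMutation(s, mutationSpec("A/338", "SER", "THR"))
  at2 <- atoms(st)
  added <- at2[at2$resno == 338 & at2$name == "CG2", ]
  expect_equal(nrow(added), 1L)
  cb <- at2[at2$resno == 338 & at2$name == "CB", ]
  blen <- sqrt((added$x - cb$x)^2 + (added$y - cb$y)^2 + (added$z - cb$z)^2)
  expect_equal(blen, 1.52, tolerance = 0.01)
  expect_equal(nAtoms(st), nAtoms(s) + 1L)
  expect_true("OG1" %in% at2$name[at2$resno == 338])
  # N -> S: amide gone, CG retyped to oxygen in place
  ns <- applyMutation(s, mutationSpec("A/336", "ASN", "SER"))
  at3 <- atoms(ns)
  r336 <- at3[at3$resno == 336, ]
  expect_setequal(r336$name, c("N", "CA", "C", "O", "CB", "OG"))
  expect_equal(r336$element[r336$name == "OG"], "O")
  # L -> V and L -> I keep one/both delta positions plus a new gamma methyl
  lv <- atoms(applyMutation(s, mutationSpec("A/263", "LEU", "VAL")))
  expect_setequal(lv$name[lv$resno == 263],
                  c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  li <- atoms(applyMutation(s, mutationSpec("A/263", "LEU", "ILE")))
  expect_setequal(li$name[li$resno == 263],
                  c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"))
  # unsupported edits are rejected explicitly; wrong source residue too
  expect_error(mutationSpec("A/265", "VAL", "PHE"), "unsupported")
  expect_error(applyMutation(s, mutationSpec("A/338", "LEU", "ALA")), "not LEU")
  # identity no-op returns the structure unchanged
  id <- applyMutation(s, mutationSpec("A/263", "LEU", "LEU"))
  expect_identical(atoms(id), atoms(s))
})

test_that("removing atoms never increases that residue's contact area", {
  # ligand sphere adjacent to a serine whose OG faces it
  lig <- fx_atoms("C1", "LIG", "L", 1, c(0, 0, 0), element = "C",
                  record = "HETATM")
  ser <- fx_residue("SER", "A", 132, origin = c(4.6, 1.0, 0.5))
  s <- fx_bind(ser, lig)
  sp <- qnsmech:::.split_substrate(s, "LIG")
  surf <- sampleSurface(sp$ligand, 1.5, 960)
  before <- residueContactAreas(surf, sp$receptor, 3.0)
  a_before <- if ("A/132" %in% before$residue)
    before$area[before$residue == "A/132"] else 0
  mut <- applyMutation(sp$receptor, mutationSpec("A/132", "SER", "GLY"))
  after <- residueContactAreas(surf, mut, 3.0)
  a_after <- if ("A/132" %in% after$residue)
    after$area[after$residue == "A/132"] else 0
  expect_gt(a_before, 0)
  expect_lte(a_after, a_before)
})

test_that("mutation screening localises planted contact changes", {
  lig <- fx_atoms("C1", "LIG", "L", 1, c(0, 0, 0), element = "C",
                  record = "HETATM")
  # state A: serine far; state B: serine close enough that the added
  # threonine methyl lands near the ligand surface
  stateA <- fx_bind(fx_residue("SER", "A", 338, origin = c(12, 0, 0)), lig)
  stateB <- fx_bind(fx_residue("SER", "A", 338, origin = c(6.4, 1.2, 0.8)), lig)
  m <- mutationSpec("A/338", "SER", "THR")
  rep <- screenMutation(list(A = stateA, B = stateB), m, "LIG")
  expect_equal(rep$delta[rep$state == "A"], 0)
  # identity mutation reproduces the wild-type trace exactly
  rep0 <- screenMutation(list(A = stateA, B = stateB),
                         mutationSpec("A/338", "SER", "SER"), "LIG")
  expect_equal(rep0$area_mut, rep0$area_wt)
  expect_true(all(rep0$delta == 0))
})
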