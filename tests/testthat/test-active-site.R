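# Active-site cluster extraction, capping, ligand truncation, mobility.

test_that("inclusion respects the 12 A boundary exactly", {
  tr <- makeToyReceptor(seed = 201)
  m <- extractActiveSite(tr$structure, tr$manifest$catalytic, radius = 12.0)
  inc <- residueKeys(m)
  planned <- tr$manifest$plannedDistances
  r_in <- planned$residue[abs(planned$dist - 11.9) < 1e-9]
  r_out <- planned$residue[abs(planned$dist - 12.1) < 1e-9]
  expect_true(r_in %in% inc)
  expect_false(r_out %in% inc)
})

test_that("inclusion set equals the brute-force all-pairs distance oracle", {
  for (seed in c(202, 203)) {
    tr <- makeToyReceptor(seed = seed)
    at <- atoms(tr$structure)
    heavy <- at[!toupper(at$element) %in% c("H", "D"), ]
    rk <- paste0(heavy$chain, "/", heavy$resno)
    cat_xyz <- as.matrix(heavy[rk == tr$manifest$catalytic, c("x", "y", "z")])
    oracle <- unique(vapply(unique(rk), function(key) {
      xyz <- as.matrix(heavy[rk == key, c("x", "y", "z")])
      dmin <- min(apply(xyz, 1, function(p)
        min(sqrt(colSums((t(cat_xyz) - p)^2)))))
      if (dmin <= 12.0) key else NA_character_
    }, character(1)))
    oracle <- oracle[!is.na(oracle)]
    m <- extractActiveSite(tr$structure, tr$manifest$catalytic, radius = 12.0)
    expect_setequal(residueKeys(m), oracle)
    expect_setequal(residueKeys(m), tr$manifest$included12)
  }
})

test_that("inclusion is monotone in the radius", {
  tr <- makeToyReceptor(seed = 204)
  radii <- c(5, 8, 12, 16, 20)
  sets <- lapply(radii, function(r)
    residueKeys(extractActiveSite(tr$structure, tr$manifest$catalytic, r)))
  for (i in seq_len(length(radii) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("a lone catalytic residue yields a one-residue model", {
  s <- fx_bind(fx_residue("SER", "A", 164))
  m <- extractActiveSite(s, "A/164", radius = 12)
  expect_equal(residueKeys(m), "A/164")
  expect_error(extractActiveSite(s, "A/999"), "A/999")
})

test_that("capping places amine/aldehyde hydrogens only at truncation breaks", {
  # contiguous chain fully inside the sphere: zero caps
  s <- fx_bind(fx_residue("SER", "A", 1), fx_residue("GLY", "A", 2, c(3, 0, 0)),
               fx_residue("LEU", "A", 3, c(6, 0, 0)))
  m <- neutralizeTermini(extractActiveSite(s, "A/2", radius = 50))
  expect_equal(nrow(capRecords(m)), 0L)

  # one excised middle residue: exactly two caps, one of each type
  s2 <- fx_bind(fx_residue("SER", "A", 1), fx_residue("GLY", "A", 2, c(30, 0, 0)),
                fx_residue("LEU", "A", 3, c(3.5, 0, 0)))
  m2 <- extractActiveSite(s2, "A/1", radius = 12)
  expect_setequal(residueKeys(m2), c("A/1", "A/3"))
  m2 <- suppressWarnings(neutralizeTermini(m2))
  caps <- capRecords(m2)
  expect_equal(nrow(caps), 2L)
  expect_setequal(caps$type, c("neutral-amine", "aldehyde"))

  # k truncation points on a generated shell: 2k caps at ideal bond lengths
  tr <- makeToyReceptor(seed = 205)
  m3 <- extractActiveSite(tr$structure, tr$manifest$catalytic, radius = 12)
  k <- nrow(m3@truncations)
  m3 <- suppressWarnings(neutralizeTermini(m3))
  caps3 <- capRecords(m3)
  expect_equal(nrow(caps3), k)
  at <- atoms(m3)
  for (i in seq_len(nrow(caps3))) {
    cap_row <- which(at$serial == caps3$serial[i])
    host_name <- if (caps3$type[i] == "neutral-amine") "N" else "C"
    rk <- paste0(at$chain, "/", at$resno)
    host_row <- which(rk == caps3$residue[i] & at$name == host_name)
    blen <- sqrt((at$x[cap_row] - at$x[host_row])^2 +
                 (at$y[cap_row] - at$y[host_row])^2 +
                 (at$z[cap_row] - at$z[host_row])^2)
    ideal <- if (caps3$type[i] == "neutral-amine") 1.01 else 1.09
    expect_equal(blen, ideal, tolerance = 1e-3)
  }
  # capping never changes any original atom coordinate
  orig <- atoms(extractActiveSite(tr$structure, tr$manifest$catalytic, 12))
  expect_identical(at$x[seq_len(nrow(orig))], orig$x)
  expect_identical(at$z[seq_len(nrow(orig))], orig$z)
})

test_that("ligand truncation keeps the anchor and caps severed bonds", {
  tr <- makeToyReceptor(seed = 206)
  lig <- selectAtoms(tr$structure, ligand = TRUE)
  anchor <- tr$manifest$ligandAnchor
  cut <- truncateLigand(lig, keep = anchor)
  at <- atoms(cut)
  heavy <- at[at$element != "H", ]
  expect_setequal(heavy$name, anchor)
  # hydrogens only where a heavy-heavy bond was severed, at 1.09 A
  hs <- at[at$element == "H", ]
  if (nrow(hs)) {
    for (i in seq_len(nrow(hs))) {
      dmin <- min(sqrt((heavy$x - hs$x[i])^2 + (heavy$y - hs$y[i])^2 +
                       (heavy$z - hs$z[i])^2))
      expect_equal(dmin, 1.09, tolerance = 1e-3)
    }
  }
  # identity: a ligand equal to its own keep-spec is unchanged
  same <- truncateLigand(cut, keep = anchor)
  expect_setequal(atoms(same)$name, atoms(cut)$name)
  # absent spec atoms are reported by name
  expect_error(truncateLigand(lig, keep = c("S1", "QQ9")), "QQ9")
})

test_that("mobility partitions atoms into ligand/reactive side chains vs rest", {
  tr <- makeToyReceptor(seed = 207)
  m <- extractActiveSite(tr$structure, tr$manifest$catalytic, radius = 12)
  m <- suppressWarnings(neutralizeTermini(m))
  # empty reactive set: mobile = ligand + caps only
  m0 <- assignMobility(m, reactive = character(0))
  lig_n <- sum(atoms(m0)$resname == "LIG")
  cap_n <- nrow(capRecords(m0))
  expect_equal(length(mobileAtoms(m0)), lig_n + cap_n)
  # catalytic side chain (CB, SG) mobile, its backbone rigid
  m1 <- assignMobility(m, reactive = tr$manifest$catalytic)
  mob <- mobileAtoms(m1)
  expect_true(all(paste0(tr$manifest$catalytic, "/", c("CB", "SG")) %in% mob))
  expect_false(any(paste0(tr$manifest$catalytic, "/", c("N", "CA", "C", "O")) %in% mob))
  # partition property
  expect_equal(length(mobileAtoms(m1)) + length(rigidAtoms(m1)), nAtoms(m1))
  expect_length(intersect(mobileAtoms(m1), rigidAtoms(m1)), 0)
  expect_error(assignMobility(m, reactive = "Z/1"), "Z/1")
})
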