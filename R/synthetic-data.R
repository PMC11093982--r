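# Seeded synthetic fixtures with planted ground truth. Geometry is
# idealised (canonical bond lengths, scripted distances) rather than
# physically realistic: the fixtures exist to make cutoff logic and
# oracles exact, not to fold proteins. All randomness flows through one
# seeded generator (default seed 20240514); regeneration from the same
# seed is bit-reproducible.

.default_seed <- 20240514

# assemble an atom table row
.atom_row <- function(serial, name, resname, chain, resno, xyz,
                      element, record = "ATOM") {
  data.frame(serial = as.integer(serial), name = name, resname = resname,
             chain = chain, resno = as.integer(resno), insert = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = 0,
             element = element, record = record, cap = FALSE,
             stringsAsFactors = FALSE)
}

# run code under a local, seeded RNG without disturbing the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

.rand_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Toy receptor with a scripted active-site geometry
#'
#' Builds a pseudo-protein shell around a catalytic cysteine-like
#' residue, with every shell residue's nearest heavy atom placed at a
#' scripted distance from the catalytic residue, so the inclusion set at
#' any radius is known exactly. Two residues are always planted just
#' inside (11.9 Angstrom) and just outside (12.1 Angstrom) the default
#' inclusion radius. A rigid pseudo-ligand ("LIG", HETATM) sits in the
#' pocket at \code{pocketRadius} from the catalytic SG; it carries a
#' thioethyl-like anchor (S1, C1, C2), an acyl head (CM) and bulk atoms
#' (B1...) so that ligand truncation has a known target set.
#'
#' @param nResidues number of shell residues (>= 5; default 40).
#' @param pocketRadius ligand distance from the catalytic SG, Angstrom
#'   (default 4; values below 2 flag a ligand clash).
#' @param seed RNG seed.
#' @return list(structure = \linkS4class{Structure}, manifest = list).
#' @export
makeToyReceptor <- function(nResidues = 40, pocketRadius = 4,
                            seed = .default_seed) {
  stopifnot(nResidues >= 5)
  .with_seed(seed, {
    cat_resno <- 164L
    # compact catalytic residue: SG at the origin, backbone close by
    cat_atoms <- rbind(
      .atom_row(1, "N",  "CYS", "A", cat_resno, c(-1.2, 0.9, 0.3), "N"),
      .atom_row(2, "CA", "CYS", "A", cat_resno, c(-0.8, 0.2, -0.4), "C"),
      .atom_row(3, "C",  "CYS", "A", cat_resno, c(-1.5, -0.9, 0.1), "C"),
      .atom_row(4, "O",  "CYS", "A", cat_resno, c(-2.1, -0.8, 1.1), "O"),
      .atom_row(5, "CB", "CYS", "A", cat_resno, c(-0.6, 1.0, -1.2), "C"),
      .atom_row(6, "SG", "CYS", "A", cat_resno, c(0, 0, 0), "S"))
    cat_xyz <- .coords_of(cat_atoms)

    n_shell <- nResidues - 1L
    dists <- c(11.9, 12.1, stats::runif(n_shell - 2, min = 4, max = 20))
    dirs <- .rand_unit(n_shell)
    resnames <- sample(c("ALA", "SER", "LEU"), n_shell, replace = TRUE)
    # shell residue numbers run below and above the catalytic residue so
    # that consecutive numbering creates realistic truncation breaks
    shell_resno <- setdiff(seq(cat_resno - ceiling(n_shell / 2),
                               by = 1L, length.out = n_shell + 1L), cat_resno)
    shell_resno <- shell_resno[seq_len(n_shell)]
    rows <- list(cat_atoms)
    serial <- 7L
    planned <- data.frame(residue = character(0), dist = numeric(0),
                          stringsAsFactors = FALSE)
    for (i in seq_len(n_shell)) {
      u <- dirs[i, ]
      # anchor on the catalytic atom extreme along u, so the scripted
      # distance is exactly the residue's minimum distance to the residue
      proj <- cat_xyz %*% u
      base <- cat_xyz[which.max(proj), ]
      nearest <- base + dists[i] * u
      res <- rbind(
        .atom_row(serial,     "CB", resnames[i], "A", shell_resno[i], nearest, "C"),
        .atom_row(serial + 1, "CA", resnames[i], "A", shell_resno[i], nearest + 1.52 * u, "C"),
        .atom_row(serial + 2, "N",  resnames[i], "A", shell_resno[i], nearest + 2.40 * u + 0.8 * .perp(u), "N"),
        .atom_row(serial + 3, "C",  resnames[i], "A", shell_resno[i], nearest + 2.60 * u - 0.8 * .perp(u), "C"),
        .atom_row(serial + 4, "O",  resnames[i], "A", shell_resno[i], nearest + 3.70 * u - 0.9 * .perp(u), "O"))
      rows[[length(rows) + 1L]] <- res
      serial <- serial + 5L
      planned <- rbind(planned, data.frame(
        residue = .res_key("A", shell_resno[i]), dist = dists[i],
        stringsAsFactors = FALSE))
    }
    # pseudo-ligand in the pocket, anchored at pocketRadius from SG
    u <- c(0.53, -0.64, 0.56); u <- .unit(u)
    lig0 <- pmax(pocketRadius, 0.1) * u
    lig <- rbind(
      .atom_row(serial,     "S1", "LIG", "L", 1, lig0, "S", "HETATM"),
      .atom_row(serial + 1, "C1", "LIG", "L", 1, lig0 + c(1.52, 0.4, 0.0), "C", "HETATM"),
      .atom_row(serial + 2, "C2", "LIG", "L", 1, lig0 + c(2.60, 1.2, 0.3), "C", "HETATM"),
      .atom_row(serial + 3, "CM", "LIG", "L", 1, lig0 + c(-0.9, 1.3, 0.6), "C", "HETATM"),
      .atom_row(serial + 4, "B1", "LIG", "L", 1, lig0 + c(3.9, 1.9, 0.7), "C", "HETATM"),
      .atom_row(serial + 5, "B2", "LIG", "L", 1, lig0 + c(5.1, 2.6, 1.2), "C", "HETATM"),
      .atom_row(serial + 6, "B3", "LIG", "L", 1, lig0 + c(6.3, 3.3, 1.6), "O", "HETATM"))
    at <- do.call(rbind, c(rows, list(lig)))
    s <- .structure(at, entryId = sprintf("toy-receptor-%d", seed))
    clash <- pocketRadius < 2
    if (clash) warning("pocketRadius ", pocketRadius,
                       " places the ligand inside the catalytic residue")
    manifest <- list(
      seed = seed, kind = "toy_receptor",
      catalytic = .res_key("A", cat_resno),
      plannedDistances = planned,
      included12 = c(.res_key("A", cat_resno),
                     planned$residue[planned$dist <= 12.0],
                     if (pocketRadius <= 12) "L/1"),
      ligandKey = "L/1",
      ligandAtoms = lig$name,
      ligandAnchor = c("S1", "C1", "C2", "CM"),
      ligandClash = clash)
    list(structure = s, manifest = manifest)
  })
}

#' Dimer interface fixture with planted interaction counts
#'
#' Two chains carrying exactly \code{kBridges} salt bridges (Asp OD1 to
#' Arg NH1 at 3.95 Angstrom: inside the 4.0 salt-bridge cutoff, outside
#' the 3.9 nonbonded cutoff), \code{mHbonds} hydrogen bonds (backbone O
#' to N at 2.90 Angstrom), and \code{pContacts} nonbonded contacts
#' (Ala CB to CB at 3.70 Angstrom), plus decoy pairs placed at least
#' 1.0 Angstrom outside every cutoff. Planted pairs sit on a 12 Angstrom
#' grid so they cannot interfere with one another.
#'
#' @param kBridges,mHbonds,pContacts planted counts (>= 0).
#' @param seed RNG seed.
#' @return list(a, b = \linkS4class{Structure} protomers, manifest = list).
#' @export
makeDimerFixture <- function(kBridges = 6, mHbonds = 32, pContacts = 318,
                             seed = .default_seed) {
  stopifnot(kBridges >= 0, mHbonds >= 0, pContacts >= 0)
  .with_seed(seed, {
    n_decoy <- 3L
    total <- kBridges + mHbonds + pContacts + n_decoy
    side <- ceiling(total^(1 / 3))
    if (side > 60) stop("requested interaction density is infeasible")
    idx <- seq_len(total) - 1L
    grid <- cbind((idx %% side), ((idx %/% side) %% side),
                  (idx %/% (side * side))) * 12
    dirs <- .rand_unit(total)
    specs <- c(rep("salt", kBridges), rep("hbond", mHbonds),
               rep("contact", pContacts), rep("decoy", n_decoy))
    a_rows <- list(); b_rows <- list()
    sa <- 1L; sb <- 1L; ra <- 1L; rb <- 1L
    for (i in seq_along(specs)) {
      p <- grid[i, ]
      u <- dirs[i, ]
      kind <- specs[i]
      if (kind == "salt") {
        a_rows[[length(a_rows) + 1L]] <-
          .atom_row(sa, "OD1", "ASP", "A", ra, p, "O")
        b_rows[[length(b_rows) + 1L]] <-
          .atom_row(sb, "NH1", "ARG", "B", rb, p + 3.95 * u, "N")
      } else if (kind == "hbond") {
        a_rows[[length(a_rows) + 1L]] <-
          .atom_row(sa, "O", "GLY", "A", ra, p, "O")
        b_rows[[length(b_rows) + 1L]] <-
          .atom_row(sb, "N", "GLY", "B", rb, p + 2.90 * u, "N")
      } else if (kind == "contact") {
        a_rows[[length(a_rows) + 1L]] <-
          .atom_row(sa, "CB", "ALA", "A", ra, p, "C")
        b_rows[[length(b_rows) + 1L]] <-
          .atom_row(sb, "CB", "ALA", "B", rb, p + 3.70 * u, "C")
      } else {
        # decoys: one of each interaction type, > cutoff + 1.0 margin
        off <- c(salt = 5.5, hbond = 4.7, contact = 5.2)
        dk <- c("OD1", "O", "CB")[(i - 1L) %% 3L + 1L]
        rn <- c("ASP", "GLY", "ALA")[(i - 1L) %% 3L + 1L]
        partner <- list(c("NH1", "ARG"), c("N", "GLY"), c("CB", "ALA"))[[(i - 1L) %% 3L + 1L]]
        el <- c("O", "O", "C")[(i - 1L) %% 3L + 1L]
        a_rows[[length(a_rows) + 1L]] <-
          .atom_row(sa, dk, rn, "A", ra, p, el)
        b_rows[[length(b_rows) + 1L]] <-
          .atom_row(sb, partner[1], partner[2], "B", rb,
                    p + off[(i - 1L) %% 3L + 1L] * u,
                    if (partner[1] == "CB") "C" else "N")
      }
      sa <- sa + 1L; sb <- sb + 1L; ra <- ra + 1L; rb <- rb + 1L
    }
    a <- .structure(if (length(a_rows)) do.call(rbind, a_rows) else
                      .atom_row(1, "CA", "GLY", "A", 1, c(0, 0, 0), "C")[0, ],
                    entryId = sprintf("dimer-A-%d", seed))
    b <- .structure(if (length(b_rows)) do.call(rbind, b_rows) else
                      .atom_row(1, "CA", "GLY", "B", 1, c(0, 0, 0), "C")[0, ],
                    entryId = sprintf("dimer-B-%d", seed))
    manifest <- list(seed = seed, kind = "dimer_fixture",
                     saltBridges = kBridges, hbonds = mHbonds,
                     nonbonded = pContacts, decoys = n_decoy)
    list(a = a, b = b, manifest = manifest)
  })
}

#' Analytic reactive system with a planted barrier
#'
#' Builds a minimal cluster model (a rigid catalytic thiolate-like atom,
#' a mobile approaching ligand carbon with one tethered companion, and a
#' rigid shell) plus a built-in analytic backend whose avoided-crossing
#' parameters are solved so that a dense-grid scan of the closed-form
#' adiabat has the requested barrier height (within 0.05 kcal/mol) at
#' the requested position (within 0.02 Angstrom), measured relative to
#' the energy at the start distance.
#'
#' @param barrierHeight requested barrier, kcal/mol.
#' @param barrierPosition requested barrier location, Angstrom (strictly
#'   between \code{covalentTarget} and \code{startDistance}).
#' @param covalentTarget covalent distance, Angstrom (default 1.81, a
#'   C-S bond from the covalent-radius sum table).
#' @param seed RNG seed (fixes the shell geometry).
#' @param startDistance scan start, Angstrom.
#' @return list(model = \linkS4class{ActiveSiteModel},
#'   backend = \linkS4class{PESBackend},
#'   protocol = \linkS4class{ScanProtocol}, manifest = list).
#' @export
makeScanSystem <- function(barrierHeight = 40, barrierPosition = 2.4,
                           covalentTarget = 1.81, seed = .default_seed,
                           startDistance = covalentTarget + 2.19) {
  stopifnot(barrierPosition > covalentTarget + 0.1,
            barrierPosition < startDistance - 0.1,
            barrierHeight > 0)
  # reactant-channel stiffness chosen so the diabatic crossing sits ~50%
  # above the requested barrier; the coupling then lowers it to target
  kR <- 3 * barrierHeight / (barrierPosition - startDistance)^2
  pars <- list(De = 100 + 2 * barrierHeight, a = 1.7, rc = covalentTarget,
               kR = kR, dR = startDistance, C = 0, W = 1)
  grid <- seq(covalentTarget, startDistance, by = 0.0025)
  # smooth barrier measure: bracket the interior maximum on a coarse grid,
  # then localise it continuously (a grid argmax quantises the position
  # and stalls the solver on plateaus)
  measure <- function(pars) {
    e <- .toy_adiabat(grid, pars)
    ref <- .toy_adiabat(pars$dR, pars)
    imax <- which.max(e)
    lo <- grid[max(imax - 2, 1)]
    hi <- grid[min(imax + 2, length(grid))]
    if (imax == 1 || imax == length(grid))
      return(c(height = e[imax] - ref, pos = grid[imax]))
    opt <- stats::optimize(function(d) .toy_adiabat(d, pars),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    c(height = opt$objective - ref, pos = opt$maximum)
  }
  # nested monotone solve: with the coupling fixed, the barrier position
  # is monotone decreasing in the product-channel offset C (inner root),
  # and with the position pinned the barrier height is monotone
  # increasing in the reactant stiffness kR (outer root)
  # coupling scales with the requested height so the barrier stays a
  # smooth single maximum (near-zero coupling degenerates to a cusp at
  # the diabatic crossing, which no finite-step scan can localise)
  pars$W <- max(2, 0.12 * barrierHeight)
  C_for_pos <- function(kR) {
    p <- pars
    p$kR <- kR
    C0 <- 0.5 * kR * (barrierPosition - p$dR)^2 -
      morseEnergy(barrierPosition, p$De, p$a, p$rc)
    f <- function(C) {
      p$C <- C
      measure(p)["pos"] - barrierPosition
    }
    stats::uniroot(f, C0 + c(-1, 1) * (30 + 0.5 * abs(C0)),
                   extendInt = "downX", tol = 1e-9)$root
  }
  h_err <- function(kR) {
    p <- pars
    p$kR <- kR
    p$C <- C_for_pos(kR)
    measure(p)["height"] - barrierHeight
  }
  kR0 <- (barrierHeight + pars$W + 5) /
    (0.5 * (barrierPosition - pars$dR)^2)
  solved <- tryCatch({
    kR <- stats::uniroot(h_err, c(0.3 * kR0, 4 * kR0), extendInt = "upX",
                         tol = 1e-9)$root
    pars$kR <- kR
    pars$C <- C_for_pos(kR)
    TRUE
  }, error = function(e) FALSE)
  if (!solved) {
    # fallback: joint polish of all three shape parameters from the
    # analytic initialisation
    pars$kR <- kR0
    pars$C <- 0.5 * kR0 * (barrierPosition - pars$dR)^2 -
      morseEnergy(barrierPosition, pars$De, pars$a, pars$rc)
    loss <- function(par) {
      p <- pars; p$C <- par[1]; p$W <- exp(par[2]); p$kR <- exp(par[3])
      m <- measure(p)
      ((m["height"] - barrierHeight) / 0.01)^2 +
        ((m["pos"] - barrierPosition) / 0.002)^2
    }
    sol <- stats::optim(c(pars$C, log(pars$W), log(pars$kR)), loss,
                        control = list(maxit = 2000, reltol = 1e-13))
    pars$C <- sol$par[1]
    pars$W <- exp(sol$par[2])
    pars$kR <- exp(sol$par[3])
  }
  got <- measure(pars)
  if (abs(got["height"] - barrierHeight) > 0.05 ||
      abs(got["pos"] - barrierPosition) > 0.02)
    stop(sprintf(paste0("unattainable barrier request: solved %.3f kcal/mol",
                        " at %.3f A for target %.3f at %.3f"),
                 got["height"], got["pos"], barrierHeight, barrierPosition))

  .with_seed(seed, {
    shell <- .rand_unit(4) * 6
    at <- rbind(
      .atom_row(1, "SG", "CYS", "A", 164, c(0, 0, 0), "S"),
      .atom_row(2, "CB", "CYS", "A", 164, c(-1.2, 0.9, 0), "C"),
      .atom_row(3, "CA", "ALA", "A", 150, shell[1, ], "C"),
      .atom_row(4, "CA", "ALA", "A", 151, shell[2, ], "C"),
      .atom_row(5, "CA", "ALA", "A", 152, shell[3, ], "C"),
      .atom_row(6, "CA", "ALA", "A", 153, shell[4, ], "C"),
      .atom_row(7, "C1", "LIG", "L", 1, c(startDistance, 0, 0), "C", "HETATM"),
      .atom_row(8, "C2", "LIG", "L", 1, c(startDistance + 1.4, 0.6, 0.2), "C",
                "HETATM"))
    s <- .structure(at, entryId = sprintf("scan-system-%d", seed))
    model <- methods::new(
      "ActiveSiteModel", structure = s, source = s,
      sourceEntry = s@entryId, catalytic = "A/164", radius = 12,
      ligandKey = "L/1",
      caps = data.frame(residue = character(0), type = character(0),
                        atomName = character(0), serial = integer(0),
                        stringsAsFactors = FALSE),
      truncations = data.frame(residue = character(0), side = character(0),
                               atomName = character(0), dx = numeric(0),
                               dy = numeric(0), dz = numeric(0),
                               stringsAsFactors = FALSE),
      mobility = ifelse(.res_keys_of(at) == "L/1", "mobile", "rigid"))
    pair <- c("L/1/C1", "A/164/SG")
    backend <- toyBackend(model, pair, pars, tetherK = 20)
    protocol <- scanProtocol(pair, startDistance = startDistance,
                             covalentTarget = covalentTarget)
    manifest <- list(seed = seed, kind = "scan_system",
                     barrierHeight = unname(got["height"]),
                     barrierPosition = unname(got["pos"]),
                     requested = c(height = barrierHeight,
                                   position = barrierPosition),
                     covalentTarget = covalentTarget,
                     startDistance = startDistance, pars = pars)
    list(model = model, backend = backend, protocol = protocol,
         manifest = manifest)
  })
}

#' Sensorgram set with known kinetic truth
#'
#' @param ka,kd,Rmax kinetic truth.
#' @param concs analyte concentrations, M.
#' @param noiseSd Gaussian noise, RU.
#' @param seed RNG seed (each curve uses seed + its index).
#' @param times sample times, seconds.
#' @param tAssocEnd end of association, seconds.
#' @return list(sensorgrams = list of \linkS4class{Sensorgram}, manifest).
#' @export
makeSensorgramSet <- function(ka = 1e5, kd = 1e-2, Rmax = 120,
                              concs = c(0.1, 0.3, 1, 3, 10) * kd / ka,
                              noiseSd = 0, seed = .default_seed,
                              times = seq(0, 600, by = 2), tAssocEnd = 300) {
  sgs <- lapply(seq_along(concs), function(i)
    simulateSensorgram(ka, kd, Rmax, concs[i], times, tAssocEnd,
                       noiseSd = noiseSd, seed = seed + i))
  manifest <- list(seed = seed, kind = "sensorgram_set",
                   ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka,
                   concs = concs, noiseSd = noiseSd)
  list(sensorgrams = sgs, manifest = manifest)
}
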