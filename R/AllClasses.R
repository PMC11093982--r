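# S4 containers for the pipeline: macromolecular structures, truncated
# active-site cluster models, reaction-coordinate scan protocols and
# profiles, probe surfaces, sensorgrams and kinetic fits.

.atom_cols <- c("serial", "name", "resname", "chain", "resno", "insert",
                "x", "y", "z", "occ", "b", "element", "record", "cap")

#' Structure: a hierarchical atom set
#'
#' Atoms are stored as a flat table with one row per atom carrying chain,
#' residue and record classification; residues are the unique
#' (chain, resno, insert) groups. Coordinates are in Angstrom; residue
#' numbering follows the numbering deposited by the authors.
#'
#' @slot entryId character entry identifier.
#' @slot atoms data.frame with columns serial, name, resname, chain,
#'   resno, insert, x, y, z, occ, b, element, record ("ATOM"/"HETATM"),
#'   cap (logical: terminus-capping atom added by the package).
#' @slot cell numeric(6) unit cell (a, b, c, alpha, beta, gamma) or
#'   numeric(0) when absent.
#' @slot spaceGroup character space-group symbol ("" when absent).
#' @slot operators list of assembly operators, each
#'   \code{list(rotation = 3x3 matrix, translation = numeric(3))}.
#' @export
setClass("Structure", representation(
  entryId = "character",
  atoms = "data.frame",
  cell = "numeric",
  spaceGroup = "character",
  operators = "list"
))

setValidity("Structure", function(object) {
  at <- object@atoms
  msg <- character()
  if (!all(.atom_cols %in% names(at)))
    msg <- c(msg, paste("atoms table must have columns:",
                        paste(setdiff(.atom_cols, names(at)), collapse = ", ")))
  if (nrow(at) > 0 && all(c("x", "y", "z") %in% names(at))) {
    if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
      msg <- c(msg, "atom coordinates must be finite")
    if ("element" %in% names(at) && any(is.na(at$element) | at$element == ""))
      msg <- c(msg, "every atom needs a non-empty element symbol")
    if ("occ" %in% names(at) && any(at$occ < 0 | at$occ > 1, na.rm = TRUE))
      msg <- c(msg, "occupancies must lie in [0, 1]")
  }
  if (length(object@cell) != 0) {
    if (length(object@cell) != 6)
      msg <- c(msg, "cell must have 6 parameters or be absent")
    else if (any(object@cell[1:3] <= 0))
      msg <- c(msg, "cell lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Transform: rigid-body operator
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), Angstrom.
#' @export
setClass("Transform", representation(
  rotation = "matrix",
  translation = "numeric"
))

setValidity("Transform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation determinant must be +1")
  }
  if (length(object@translation) != 3)
    msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' Transform constructor
#' @param rotation 3x3 orthonormal matrix, determinant +1 (within 1e-6).
#' @param translation numeric(3) in Angstrom.
#' @return a \linkS4class{Transform}.
#' @export
Transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  methods::new("Transform", rotation = rotation, translation = as.numeric(translation))
}

#' ActiveSiteModel: truncated active-site cluster
#'
#' The set of whole residues with at least one non-hydrogen atom within
#' the inclusion radius of the catalytic residue, together with the bound
#' (possibly truncated) ligand, capping records at truncation-created
#' chain breaks, and a mobile/rigid partition of the atoms.
#'
#' @slot structure the cluster as a \linkS4class{Structure}.
#' @slot source the full parent \linkS4class{Structure} (kept so that
#'   severed-bond geometry is available for capping).
#' @slot sourceEntry character entry id of the parent.
#' @slot catalytic residue key "chain/resno" of the catalytic residue.
#' @slot radius inclusion radius in Angstrom (default 12.0).
#' @slot ligandKey residue key of the bound ligand ("" when none).
#' @slot caps data.frame (residue, type, atomName, serial) of placed caps.
#' @slot truncations data.frame of chain breaks created by truncation
#'   (residue, side "N"/"C", atomName, dx, dy, dz severed-bond direction).
#' @slot mobility character per-atom flags "mobile"/"rigid"
#'   (length 0 until \code{assignMobility} is called).
#' @export
setClass("ActiveSiteModel", representation(
  structure = "Structure",
  source = "Structure",
  sourceEntry = "character",
  catalytic = "character",
  radius = "numeric",
  ligandKey = "character",
  caps = "data.frame",
  truncations = "data.frame",
  mobility = "character"
))

setValidity("ActiveSiteModel", function(object) {
  n <- nrow(object@structure@atoms)
  msg <- character()
  if (length(object@mobility) != 0) {
    if (length(object@mobility) != n)
      msg <- c(msg, "mobility must flag every atom (or be empty)")
    if (!all(object@mobility %in% c("mobile", "rigid")))
      msg <- c(msg, "mobility flags must be 'mobile' or 'rigid'")
  }
  if (length(object@radius) != 1 || object@radius <= 0)
    msg <- c(msg, "inclusion radius must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ScanProtocol: constrained stepwise approach schedule
#'
#' Distances descend from \code{startDistance} in coarse steps (default
#' 0.4 Angstrom) until within \code{switchOffset} (default 1.0) of the
#' expected covalent distance, then in fine steps (default 0.1) down to
#' exactly \code{covalentTarget}.
#'
#' @slot pair character(2) atom keys "chain/resno/name" of the reacting pair.
#' @slot coarseStep,fineStep,switchOffset,covalentTarget,startDistance numeric, Angstrom.
#' @slot direction "approach" or "retreat".
#' @slot maxPoints schedule length cap (default 500).
#' @export
setClass("ScanProtocol", representation(
  pair = "character",
  coarseStep = "numeric",
  fineStep = "numeric",
  switchOffset = "numeric",
  covalentTarget = "numeric",
  startDistance = "numeric",
  direction = "character",
  maxPoints = "numeric"
))

setValidity("ScanProtocol", function(object) {
  msg <- character()
  if (length(object@pair) != 2) msg <- c(msg, "pair must name exactly two atoms")
  if (!(object@coarseStep > object@fineStep && object@fineStep > 0))
    msg <- c(msg, "need coarseStep > fineStep > 0")
  if (object@switchOffset < 0) msg <- c(msg, "switchOffset must be >= 0")
  if (object@covalentTarget <= 0) msg <- c(msg, "covalentTarget must be > 0")
  if (!object@direction %in% c("approach", "retreat"))
    msg <- c(msg, "direction must be 'approach' or 'retreat'")
  if (object@direction == "approach" &&
      object@startDistance < object@covalentTarget)
    msg <- c(msg, "approach requires startDistance >= covalentTarget")
  if (length(msg)) msg else TRUE
})

#' ScanProtocol constructor
#' @param pair character(2) atom keys of the reacting atoms.
#' @param startDistance,covalentTarget Angstrom.
#' @param coarseStep,fineStep,switchOffset Angstrom; defaults 0.4, 0.1, 1.0.
#' @param direction "approach" (default) or "retreat".
#' @param maxPoints schedule length cap.
#' @return a \linkS4class{ScanProtocol}.
#' @export
scanProtocol <- function(pair, startDistance, covalentTarget,
                         coarseStep = 0.4, fineStep = 0.1,
                         switchOffset = 1.0, direction = "approach",
                         maxPoints = 500) {
  methods::new("ScanProtocol", pair = pair, coarseStep = coarseStep,
               fineStep = fineStep, switchOffset = switchOffset,
               covalentTarget = covalentTarget, startDistance = startDistance,
               direction = direction, maxPoints = maxPoints)
}

#' PESBackend: potential-energy-surface contract
#'
#' Any engine that maps coordinates of a cluster model to an energy in
#' kcal/mol. The built-in analytic backend (Morse / Lennard-Jones /
#' Coulomb terms with a two-state avoided crossing along the reacting
#' pair) makes transition-state logic testable at desk scale; an
#' external-engine adapter wraps command-line quantum chemistry codes.
#'
#' @slot name character backend label.
#' @slot energy function(coords n x 3 matrix, model) -> kcal/mol.
#' @slot gradient optional function with the same signature returning an
#'   n x 3 gradient in kcal/mol/Angstrom, or NULL.
#' @export
setClass("PESBackend", representation(
  name = "character",
  energy = "function",
  gradient = "ANY"
))

#' ReactionProfile: ordered constrained-scan states
#'
#' @slot distances constraint distances, Angstrom, strictly monotone.
#' @slot energies energies at each state, kcal/mol.
#' @slot coords list of coordinate snapshots (n x 3 matrices).
#' @slot tsIndex index of the maximum-energy state.
#' @slot tsDistance,tsEnergy transition state after one bisection
#'   refinement pass at half the fine step.
#' @slot activationEnergy E(TS) - E(first state), kcal/mol.
#' @slot reactionEnthalpy E(last) - E(first), kcal/mol.
#' @slot label optional profile label (e.g. "R", "k1", "P1").
#' @slot converged logical per state.
#' @slot partial TRUE when any state failed to converge.
#' @export
setClass("ReactionProfile", representation(
  distances = "numeric",
  energies = "numeric",
  coords = "list",
  tsIndex = "integer",
  tsDistance = "numeric",
  tsEnergy = "numeric",
  activationEnergy = "numeric",
  reactionEnthalpy = "numeric",
  label = "character",
  converged = "logical",
  partial = "logical"
))

setValidity("ReactionProfile", function(object) {
  d <- object@distances
  msg <- character()
  if (length(d) > 1 && !(all(diff(d) < 0) || all(diff(d) > 0)))
    msg <- c(msg, "constraint distances must be strictly monotone")
  if (length(object@energies) != length(d))
    msg <- c(msg, "one energy per scheduled distance required")
  if (length(d) > 0) {
    if (object@tsIndex < 1 || object@tsIndex > length(d))
      msg <- c(msg, "tsIndex out of range")
    else if (abs(max(object@energies) - object@energies[object@tsIndex]) > 1e-9)
      msg <- c(msg, "tsIndex must maximise the profile energy")
    if (object@activationEnergy < -1e-9)
      msg <- c(msg, "activation energy must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SurfaceSample: probe-expanded atomic sphere sampling
#'
#' Deterministic golden-spiral points on spheres of radius (vdW + probe),
#' with points buried inside a neighbouring atom's expanded sphere
#' removed (Shrake-Rupley exclusion). Each retained point carries an area
#' weight of 4 pi (r + probe)^2 / n for its parent atom.
#'
#' @slot points m x 3 matrix of exposed points, Angstrom.
#' @slot weights per-point areas, Angstrom^2.
#' @slot atomIndex integer parent-atom row for each point.
#' @slot probe probe radius, Angstrom.
#' @slot nPerAtom points placed per atom before exclusion.
#' @slot atoms the atom table the surface was built on.
#' @export
setClass("SurfaceSample", representation(
  points = "matrix",
  weights = "numeric",
  atomIndex = "integer",
  probe = "numeric",
  nPerAtom = "numeric",
  atoms = "data.frame"
))

#' Sensorgram: SPR response-vs-time curve
#'
#' @slot times seconds, strictly increasing.
#' @slot response resonance units (RU).
#' @slot conc analyte concentration, molar.
#' @slot tAssocEnd end of the association phase, seconds.
#' @slot noiseSd Gaussian noise level used when synthetic (RU).
#' @slot seed RNG seed used when synthetic.
#' @export
setClass("Sensorgram", representation(
  times = "numeric",
  response = "numeric",
  conc = "numeric",
  tAssocEnd = "numeric",
  noiseSd = "numeric",
  seed = "numeric"
))

setValidity("Sensorgram", function(object) {
  msg <- character()
  if (length(object@times) != length(object@response))
    msg <- c(msg, "times and response must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (object@conc <= 0) msg <- c(msg, "analyte concentration must be positive")
  if (length(msg)) msg else TRUE
})

#' KineticFit: fitted 1:1 Langmuir parameters
#'
#' @slot ka association rate, 1/(M s).
#' @slot kd dissociation rate, 1/s.
#' @slot Rmax surface capacity, RU.
#' @slot KD equilibrium dissociation constant kd/ka (exact ratio), M.
#' @slot rss residual sum of squares, RU^2.
#' @slot stderr named numeric standard errors for ka, kd, Rmax.
#' @slot nobs number of fitted points.
#' @slot messages fit diagnostics (e.g. identifiability warnings).
#' @export
setClass("KineticFit", representation(
  ka = "numeric",
  kd = "numeric",
  Rmax = "numeric",
  KD = "numeric",
  rss = "numeric",
  stderr = "numeric",
  nobs = "numeric",
  messages = "character"
))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (object@ka <= 0 || object@kd <= 0 || object@Rmax <= 0)
    msg <- c(msg, "ka, kd and Rmax must be positive")
  if (object@KD != object@kd / object@ka)
    msg <- c(msg, "KD must equal kd/ka exactly")
  if (length(msg)) msg else TRUE
})
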