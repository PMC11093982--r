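# Generics and accessor methods; slot access stays internal.

#' Atom table accessor
#' @param x a Structure, ActiveSiteModel or SurfaceSample.
#' @return data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Number of atoms
#' @param x a Structure or ActiveSiteModel.
#' @return integer count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Entry identifier
#' @param x a Structure.
#' @return character id.
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))

#' Residue keys ("chain/resno") in deterministic (chain, resno) order
#' @param x a Structure or ActiveSiteModel.
#' @return character vector of residue keys.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Unit-cell parameters (a, b, c, alpha, beta, gamma) or numeric(0)
#' @param x a Structure.
#' @return numeric(6) or numeric(0).
#' @export
setGeneric("cellParams", function(x) standardGeneric("cellParams"))

#' Space-group symbol ("" when absent)
#' @param x a Structure.
#' @return character.
#' @export
setGeneric("spaceGroup", function(x) standardGeneric("spaceGroup"))

#' Assembly operators parsed from the file (possibly empty list)
#' @param x a Structure.
#' @return list of list(rotation, translation).
#' @export
setGeneric("assemblyOperators", function(x) standardGeneric("assemblyOperators"))

#' Atom keys ("chain/resno/name") of mobile atoms
#' @param x an ActiveSiteModel with assigned mobility.
#' @return character vector.
#' @export
setGeneric("mobileAtoms", function(x) standardGeneric("mobileAtoms"))

#' Atom keys of rigid atoms
#' @param x an ActiveSiteModel with assigned mobility.
#' @return character vector.
#' @export
setGeneric("rigidAtoms", function(x) standardGeneric("rigidAtoms"))

#' Cap records placed by neutralizeTermini
#' @param x an ActiveSiteModel.
#' @return data.frame (residue, type, atomName, serial).
#' @export
setGeneric("capRecords", function(x) standardGeneric("capRecords"))

#' Activation energy E(TS) - E(first state), kcal/mol
#' @param x a ReactionProfile.
#' @return numeric.
#' @export
setGeneric("activationEnergy", function(x) standardGeneric("activationEnergy"))

#' Reaction enthalpy E(last) - E(first), kcal/mol
#' @param x a ReactionProfile.
#' @return numeric.
#' @export
setGeneric("reactionEnthalpy", function(x) standardGeneric("reactionEnthalpy"))

#' Transition-state summary (index, distance, energy after refinement)
#' @param x a ReactionProfile.
#' @return list(index, distance, energy).
#' @export
setGeneric("transitionState", function(x) standardGeneric("transitionState"))

#' Total exposed area of a surface sample, Angstrom^2
#' @param x a SurfaceSample.
#' @return numeric.
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))

#' Fitted kinetic parameters as a named vector (ka, kd, Rmax, KD)
#' @param x a KineticFit.
#' @return named numeric(4).
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))

## ---- methods -------------------------------------------------------------

#' @describeIn atoms atoms of a Structure
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @describeIn atoms atoms of the cluster model
#' @export
setMethod("atoms", "ActiveSiteModel", function(x) x@structure@atoms)

#' @describeIn atoms atoms the surface was sampled on
#' @export
setMethod("atoms", "SurfaceSample", function(x) x@atoms)

#' @describeIn nAtoms atom count of a Structure
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @describeIn nAtoms atom count of the cluster model
#' @export
setMethod("nAtoms", "ActiveSiteModel", function(x) nrow(x@structure@atoms))

#' @describeIn entryId entry id of a Structure
#' @export
setMethod("entryId", "Structure", function(x) x@entryId)

#' @describeIn residueKeys residues of a Structure
#' @export
setMethod("residueKeys", "Structure", function(x) {
  at <- x@atoms
  if (nrow(at) == 0) return(character(0))
  keys <- .res_keys_of(at)
  first <- !duplicated(keys)
  ord <- .order_residues(at$chain[first], at$resno[first], at$insert[first])
  keys[first][ord]
})

#' @describeIn residueKeys residues of the cluster model
#' @export
setMethod("residueKeys", "ActiveSiteModel", function(x) residueKeys(x@structure))

#' @describeIn cellParams cell of a Structure
#' @export
setMethod("cellParams", "Structure", function(x) x@cell)

#' @describeIn spaceGroup space group of a Structure
#' @export
setMethod("spaceGroup", "Structure", function(x) x@spaceGroup)

#' @describeIn assemblyOperators operators of a Structure
#' @export
setMethod("assemblyOperators", "Structure", function(x) x@operators)

#' @describeIn mobileAtoms mobile atoms of an ActiveSiteModel
#' @export
setMethod("mobileAtoms", "ActiveSiteModel", function(x) {
  if (length(x@mobility) == 0) stop("mobility not assigned; call assignMobility()")
  .atom_keys_of(x@structure@atoms)[x@mobility == "mobile"]
})

#' @describeIn rigidAtoms rigid atoms of an ActiveSiteModel
#' @export
setMethod("rigidAtoms", "ActiveSiteModel", function(x) {
  if (length(x@mobility) == 0) stop("mobility not assigned; call assignMobility()")
  .atom_keys_of(x@structure@atoms)[x@mobility == "rigid"]
})

#' @describeIn capRecords caps of an ActiveSiteModel
#' @export
setMethod("capRecords", "ActiveSiteModel", function(x) x@caps)

#' @describeIn activationEnergy of a ReactionProfile
#' @export
setMethod("activationEnergy", "ReactionProfile", function(x) x@activationEnergy)

#' @describeIn reactionEnthalpy of a ReactionProfile
#' @export
setMethod("reactionEnthalpy", "ReactionProfile", function(x) x@reactionEnthalpy)

#' @describeIn transitionState of a ReactionProfile
#' @export
setMethod("transitionState", "ReactionProfile", function(x) {
  list(index = x@tsIndex, distance = x@tsDistance, energy = x@tsEnergy)
})

#' @describeIn totalArea of a SurfaceSample
#' @export
setMethod("totalArea", "SurfaceSample", function(x) sum(x@weights))

#' @describeIn kineticParams of a KineticFit
#' @export
setMethod("kineticParams", "KineticFit", function(x) {
  c(ka = x@ka, kd = x@kd, Rmax = x@Rmax, KD = x@KD)
})

## ---- show ----------------------------------------------------------------

setMethod("show", "Structure", function(object) {
  at <- object@atoms
  nres <- length(residueKeys(object))
  cat("Structure", if (nzchar(object@entryId)) sQuote(object@entryId) else "",
      "\n  ", nrow(at), " atoms in ", nres, " residues, ",
      length(unique(at$chain)), " chain(s)\n", sep = "")
  if (length(object@cell) == 6)
    cat("  cell: ", paste(format(object@cell, digits = 6), collapse = " "),
        if (nzchar(object@spaceGroup)) paste0("  [", object@spaceGroup, "]"),
        "\n", sep = "")
  if (length(object@operators))
    cat("  assembly operators:", length(object@operators), "\n")
})

setMethod("show", "ActiveSiteModel", function(object) {
  cat("ActiveSiteModel around ", object@catalytic,
      " (radius ", object@radius, " A)\n", sep = "")
  cat("  ", nAtoms(object), " atoms in ", length(residueKeys(object)),
      " residues; ligand: ",
      if (nzchar(object@ligandKey)) object@ligandKey else "<none>", "\n", sep = "")
  cat("  caps: ", nrow(object@caps), "; mobility ",
      if (length(object@mobility)) paste0(sum(object@mobility == "mobile"),
                                          " mobile / ",
                                          sum(object@mobility == "rigid"), " rigid")
      else "unassigned", "\n", sep = "")
})

setMethod("show", "ReactionProfile", function(object) {
  cat("ReactionProfile", if (nzchar(object@label)) sQuote(object@label) else "",
      "with", length(object@distances), "states\n")
  cat(sprintf("  TS at %.3f A (state %d), activation %.3f kcal/mol, enthalpy %.3f kcal/mol\n",
              object@tsDistance, object@tsIndex,
              object@activationEnergy, object@reactionEnthalpy))
  if (object@partial) cat("  [partial: some states did not converge]\n")
})

setMethod("show", "SurfaceSample", function(object) {
  cat(sprintf("SurfaceSample: %d exposed points on %d atoms (probe %.2f A, %d pts/atom)\n",
              nrow(object@points), nrow(object@atoms), object@probe,
              as.integer(object@nPerAtom)))
  cat(sprintf("  total exposed area %.2f A^2\n", sum(object@weights)))
})

setMethod("show", "Sensorgram", function(object) {
  cat(sprintf("Sensorgram: %d points, C = %.3g M, association ends at %.1f s\n",
              length(object@times), object@conc, object@tAssocEnd))
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("Langmuir 1:1 fit: ka = %.4g 1/(M s), kd = %.4g 1/s, Rmax = %.4g RU\n",
              object@ka, object@kd, object@Rmax))
  cat(sprintf("  KD = kd/ka = %.4g M; RSS = %.4g RU^2 over %d points\n",
              object@KD, object@rss, as.integer(object@nobs)))
  if (length(object@messages)) cat("  ", paste(object@messages, collapse = "\n  "), "\n")
})

setMethod("show", "PESBackend", function(object) {
  cat("PESBackend:", object@name,
      if (!is.null(object@gradient)) "(analytic gradient)" else "(numeric gradient)",
      "\n")
})

setMethod("show", "ScanProtocol", function(object) {
  cat(sprintf("ScanProtocol: %s -> %s, %.2f A to %.2f A (coarse %.2f, fine %.2f, switch %.2f)\n",
              object@pair[1], object@pair[2], object@startDistance,
              object@covalentTarget, object@coarseStep, object@fineStep,
              object@switchOffset))
})
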