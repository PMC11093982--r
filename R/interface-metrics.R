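# Interface descriptors: solvent-accessible surface area, buried dimer
# interface area, salt bridges, hydrogen bonds, nonbonded and polar
# contacts. Pair finders are plain O(n^2) distance scans; fixtures and
# single interfaces are small enough that no spatial index is needed,
# and the brute-force form doubles as its own specification.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic golden-spiral sampling of probe-expanded spheres; probe
#' defaults to 1.4 Angstrom (water), the solvent convention used for
#' interface areas, distinct from the 1.5 Angstrom contact probe.
#'
#' @param s a \linkS4class{Structure}.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n points per atom (default 960).
#' @return list(perAtom = numeric per-atom areas, total = their sum), Angstrom^2.
#' @export
sasa <- function(s, probe = 1.4, n = 960) {
  at <- .as_atoms(s)
  surf <- sampleSurface(at, probe = probe, n = n)
  per <- numeric(nrow(at))
  if (length(surf@weights)) {
    agg <- tapply(surf@weights, surf@atomIndex, sum)
    per[as.integer(names(agg))] <- as.numeric(agg)
  }
  list(perAtom = per, total = sum(per))
}

#' Buried interface area per protomer
#'
#' (SASA(a) + SASA(b) - SASA(a united with b)) / 2; symmetric in its
#' arguments and zero for chains too far apart to share any buried
#' surface.
#'
#' @param a,b \linkS4class{Structure} protomers with disjoint atoms.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n points per atom.
#' @return buried area per protomer, Angstrom^2.
#' @export
buriedInterfaceArea <- function(a, b, probe = 1.4, n = 960) {
  (sasa(a, probe, n)$total + sasa(b, probe, n)$total -
     sasa(combineStructures(a, b), probe, n)$total) / 2
}

.acid_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.base_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))

.charged_rows <- function(at, table) {
  hits <- rep(FALSE, nrow(at))
  for (rn in names(table)) {
    hits <- hits | (at$resname == rn & at$name %in% table[[rn]])
  }
  which(hits)
}

#' Find salt bridges across an interface
#'
#' Unique residue pairs with at least one carboxylate oxygen
#' (Asp OD1/OD2, Glu OE1/OE2) within \code{cutoff} of a protonatable
#' nitrogen (Lys NZ, Arg NE/NH1/NH2, His ND1/NE2) across the a/b
#' partition. Histidine is counted as a potential cation.
#'
#' @param a,b \linkS4class{Structure} partners.
#' @param cutoff Angstrom (default 4.0).
#' @return data.frame (resA, resB, dist) with the minimum O-N distance per pair.
#' @export
findSaltBridges <- function(a, b, cutoff = 4.0) {
  ata <- .as_atoms(a); atb <- .as_atoms(b)
  one_way <- function(acid_at, base_at) {
    ai <- .charged_rows(acid_at, .acid_atoms)
    bi <- .charged_rows(base_at, .base_atoms)
    if (!length(ai) || !length(bi)) return(NULL)
    d <- .cross_dist(.coords_of(acid_at[ai, , drop = FALSE]),
                     .coords_of(base_at[bi, , drop = FALSE]))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    data.frame(resAcid = .res_keys_of(acid_at)[ai[hit[, 1]]],
               resBase = .res_keys_of(base_at)[bi[hit[, 2]]],
               dist = d[hit], stringsAsFactors = FALSE)
  }
  fwd <- one_way(ata, atb)
  if (!is.null(fwd)) fwd <- data.frame(resA = fwd$resAcid, resB = fwd$resBase,
                                       dist = fwd$dist)
  bwd <- one_way(atb, ata)
  if (!is.null(bwd)) bwd <- data.frame(resA = bwd$resBase, resB = bwd$resAcid,
                                       dist = bwd$dist)
  allp <- rbind(fwd, bwd)
  if (is.null(allp) || nrow(allp) == 0)
    return(data.frame(resA = character(0), resB = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE))
  key <- paste(allp$resA, allp$resB)
  mins <- tapply(allp$dist, key, min)
  first <- allp[match(names(mins), key), c("resA", "resB")]
  out <- data.frame(resA = first$resA, resB = first$resB,
                    dist = as.numeric(mins), stringsAsFactors = FALSE)
  out <- out[order(out$resA, out$resB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# hydrogens bonded to a given heavy-atom row (same structure, < 1.3 A)
.attached_h <- function(at, row) {
  h <- which(.is_hydrogen_el(at$element))
  if (!length(h)) return(integer(0))
  d <- sqrt((at$x[h] - at$x[row])^2 + (at$y[h] - at$y[row])^2 +
            (at$z[h] - at$z[row])^2)
  h[d < 1.3]
}

#' Find hydrogen bonds across an interface
#'
#' N/O to N/O heavy-atom pairs with distance at most \code{dMax}. When
#' hydrogens are present on a candidate donor the D-H...A angle must
#' additionally be at least 90 degrees; for structures without hydrogens
#' (the usual case for deposited crystal structures) the criterion is
#' distance-only.
#'
#' @param a,b \linkS4class{Structure} partners.
#' @param dMax Angstrom (default 3.35).
#' @return data.frame (atomA, atomB, resA, resB, dist).
#' @export
findHbonds <- function(a, b, dMax = 3.35) {
  ata <- .as_atoms(a); atb <- .as_atoms(b)
  ia <- which(ata$element %in% c("N", "O"))
  ib <- which(atb$element %in% c("N", "O"))
  empty <- data.frame(atomA = character(0), atomB = character(0),
                      resA = character(0), resB = character(0),
                      dist = numeric(0), stringsAsFactors = FALSE)
  if (!length(ia) || !length(ib)) return(empty)
  d <- .cross_dist(.coords_of(ata[ia, , drop = FALSE]),
                   .coords_of(atb[ib, , drop = FALSE]))
  hit <- which(d <= dMax, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ok <- logical(nrow(hit))
  for (k in seq_len(nrow(hit))) {
    ra <- ia[hit[k, 1]]; rb <- ib[hit[k, 2]]
    ha <- .attached_h(ata, ra)
    hb <- .attached_h(atb, rb)
    if (!length(ha) && !length(hb)) { ok[k] <- TRUE; next }
    angle_ok <- function(at_d, dr, hs, at_a, ar) {
      any(vapply(hs, function(hrow) {
        v1 <- c(at_d$x[dr] - at_d$x[hrow], at_d$y[dr] - at_d$y[hrow],
                at_d$z[dr] - at_d$z[hrow])
        v2 <- c(at_a$x[ar] - at_d$x[hrow], at_a$y[ar] - at_d$y[hrow],
                at_a$z[ar] - at_d$z[hrow])
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        acos(pmin(pmax(cosang, -1), 1)) * 180 / pi >= 90
      }, logical(1)))
    }
    ok[k] <- (length(ha) && angle_ok(ata, ra, ha, atb, rb)) ||
             (length(hb) && angle_ok(atb, rb, hb, ata, ra))
  }
  hit <- hit[ok, , drop = FALSE]
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    atomA = .atom_keys_of(ata)[ia[hit[, 1]]],
    atomB = .atom_keys_of(atb)[ib[hit[, 2]]],
    resA = .res_keys_of(ata)[ia[hit[, 1]]],
    resB = .res_keys_of(atb)[ib[hit[, 2]]],
    dist = d[hit], stringsAsFactors = FALSE)
  out <- out[order(out$atomA, out$atomB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count nonbonded contacts across an interface
#'
#' Non-hydrogen atom pairs across the a/b partition within \code{dMax},
#' excluding pairs already classified as hydrogen bonds (at the hydrogen
#' bond module default of 3.35 Angstrom).
#'
#' @param a,b \linkS4class{Structure} partners.
#' @param dMax Angstrom (default 3.9).
#' @param hbonds optionally, a precomputed \code{\link{findHbonds}} table.
#' @return list(count, pairs = data.frame(atomA, atomB, dist)).
#' @export
nonbondedContacts <- function(a, b, dMax = 3.9, hbonds = NULL) {
  ata <- .as_atoms(a); atb <- .as_atoms(b)
  ia <- which(!.is_hydrogen_el(ata$element))
  ib <- which(!.is_hydrogen_el(atb$element))
  empty <- list(count = 0L, pairs = data.frame(atomA = character(0),
                                               atomB = character(0),
                                               dist = numeric(0),
                                               stringsAsFactors = FALSE))
  if (!length(ia) || !length(ib)) return(empty)
  d <- .cross_dist(.coords_of(ata[ia, , drop = FALSE]),
                   .coords_of(atb[ib, , drop = FALSE]))
  hit <- which(d <= dMax, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  pairs <- data.frame(atomA = .atom_keys_of(ata)[ia[hit[, 1]]],
                      atomB = .atom_keys_of(atb)[ib[hit[, 2]]],
                      dist = d[hit], stringsAsFactors = FALSE)
  if (is.null(hbonds)) hbonds <- findHbonds(a, b)
  if (nrow(hbonds)) {
    hb_key <- paste(hbonds$atomA, hbonds$atomB)
    pairs <- pairs[!paste(pairs$atomA, pairs$atomB) %in% hb_key, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$atomA, pairs$atomB), , drop = FALSE]
  rownames(pairs) <- NULL
  list(count = nrow(pairs), pairs = pairs)
}

#' Polar contacts between a ligand and the protein
#'
#' Ligand N/O/S atoms to protein N/O/S atoms within \code{dMax}.
#'
#' @param ligand \linkS4class{Structure} holding the ligand atoms.
#' @param protein \linkS4class{Structure} holding the protein atoms.
#' @param dMax Angstrom (default 3.5).
#' @return data.frame (ligAtom, protAtom, protRes, dist).
#' @export
polarContacts <- function(ligand, protein, dMax = 3.5) {
  la <- .as_atoms(ligand); pa <- .as_atoms(protein)
  il <- which(la$element %in% c("N", "O", "S"))
  ip <- which(pa$element %in% c("N", "O", "S"))
  empty <- data.frame(ligAtom = character(0), protAtom = character(0),
                      protRes = character(0), dist = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(il) || !length(ip)) return(empty)
  d <- .cross_dist(.coords_of(la[il, , drop = FALSE]),
                   .coords_of(pa[ip, , drop = FALSE]))
  hit <- which(d <= dMax, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- data.frame(ligAtom = .atom_keys_of(la)[il[hit[, 1]]],
                    protAtom = .atom_keys_of(pa)[ip[hit[, 2]]],
                    protRes = .res_keys_of(pa)[ip[hit[, 2]]],
                    dist = d[hit], stringsAsFactors = FALSE)
  out <- out[order(out$ligAtom, out$protAtom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full interface report for a dimer
#'
#' @param a,b \linkS4class{Structure} protomers.
#' @param saltCutoff,hbondMax,nonbondedMax,probe cutoffs, Angstrom.
#' @param n surface points per atom.
#' @return list with buriedAreaPerProtomer, saltBridges, hbonds,
#'   nonbondedCount and nonbondedPairs.
#' @export
interfaceReport <- function(a, b, saltCutoff = 4.0, hbondMax = 3.35,
                            nonbondedMax = 3.9, probe = 1.4, n = 960) {
  hb <- findHbonds(a, b, dMax = hbondMax)
  nbc <- nonbondedContacts(a, b, dMax = nonbondedMax, hbonds = hb)
  list(buriedAreaPerProtomer = buriedInterfaceArea(a, b, probe = probe, n = n),
       saltBridges = findSaltBridges(a, b, cutoff = saltCutoff),
       hbonds = hb,
       nonbondedCount = nbc$count,
       nonbondedPairs = nbc$pairs)
}
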