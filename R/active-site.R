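# Truncated active-site cluster construction: whole-residue inclusion
# within a radius of the catalytic residue, terminus neutralisation by
# amine/aldehyde caps, ligand truncation to its reactive anchor, and the
# mobile/rigid atom partition used by the constrained scan.

#' Extract a truncated active-site cluster
#'
#' Includes every residue with at least one non-hydrogen atom within
#' \code{radius} (default 12.0 Angstrom) of any non-hydrogen atom of the
#' catalytic residue (or of a single named atom when \code{centerAtom}
#' is given). Residues are included whole; the catalytic residue is
#' always included. Chain breaks created by the truncation are recorded
#' with their severed-bond directions so that \code{\link{neutralizeTermini}}
#' can cap them.
#'
#' @param s a \linkS4class{Structure}.
#' @param catalytic residue key "chain/resno" of the catalytic residue.
#' @param radius inclusion radius, Angstrom (> 0; default 12.0).
#' @param centerAtom optional atom name (e.g. "SG") to measure from,
#'   instead of the whole catalytic residue.
#' @return an \linkS4class{ActiveSiteModel}.
#' @export
extractActiveSite <- function(s, catalytic, radius = 12.0, centerAtom = NULL) {
  stopifnot(radius > 0)
  at <- s@atoms
  rk <- .res_keys_of(at)
  cat_rows <- which(rk == catalytic)
  if (!length(cat_rows)) stop("catalytic residue not found: ", catalytic)
  heavy <- !.is_hydrogen_el(at$element)
  center_rows <- cat_rows[heavy[cat_rows]]
  if (!is.null(centerAtom)) {
    center_rows <- cat_rows[at$name[cat_rows] == centerAtom]
    if (!length(center_rows))
      stop("catalytic residue ", catalytic, " has no atom named ", centerAtom)
  }
  ref <- .coords_of(at[center_rows, , drop = FALSE])
  # per-residue minimum heavy-atom distance to the catalytic reference set
  cand <- which(heavy)
  d <- .cross_dist(.coords_of(at[cand, , drop = FALSE]), ref)
  mind <- apply(d, 1, min)
  res_min <- tapply(mind, rk[cand], min)
  included <- names(res_min)[res_min <= radius]
  included <- union(included, catalytic)
  keep <- rk %in% included
  cluster <- at[keep, , drop = FALSE]

  # record truncation-created chain breaks among included polymer residues
  cls <- .classify_residues(at)
  trunc <- list()
  res_tab <- unique(at[, c("chain", "resno", "insert", "resname")])
  inc_pol <- unique(cluster[.classify_residues(cluster)$polymer,
                            c("chain", "resno", "insert"), drop = FALSE])
  if (nrow(inc_pol)) {
    for (i in seq_len(nrow(inc_pol))) {
      ch <- inc_pol$chain[i]; rn <- inc_pol$resno[i]; ins <- inc_pol$insert[i]
      key <- .res_key(ch, rn, ins)
      for (side in c("N", "C")) {
        nb <- if (side == "N") rn - 1L else rn + 1L
        nb_rows <- which(at$chain == ch & at$resno == nb & cls$polymer)
        if (!length(nb_rows)) next                     # true chain end, no break
        if (.res_key(ch, nb) %in% included) next       # neighbour retained
        this_atom <- if (side == "N") "N" else "C"
        nb_atom <- if (side == "N") "C" else "N"
        a_row <- which(at$chain == ch & at$resno == rn & at$insert == ins &
                       at$name == this_atom)
        b_row <- nb_rows[at$name[nb_rows] == nb_atom]
        if (!length(a_row) || !length(b_row)) next
        dir <- .unit(c(at$x[b_row[1]] - at$x[a_row[1]],
                       at$y[b_row[1]] - at$y[a_row[1]],
                       at$z[b_row[1]] - at$z[a_row[1]]))
        trunc[[length(trunc) + 1L]] <- data.frame(
          residue = key, side = side, atomName = this_atom,
          dx = dir[1], dy = dir[2], dz = dir[3], stringsAsFactors = FALSE)
      }
    }
  }
  trunc <- if (length(trunc)) do.call(rbind, trunc) else
    data.frame(residue = character(0), side = character(0),
               atomName = character(0), dx = numeric(0), dy = numeric(0),
               dz = numeric(0), stringsAsFactors = FALSE)

  lig_keys <- unique(.res_keys_of(cluster)[.classify_residues(cluster)$ligand])
  methods::new("ActiveSiteModel",
               structure = .structure(cluster, entryId = s@entryId),
               source = s, sourceEntry = s@entryId, catalytic = catalytic,
               radius = radius,
               ligandKey = if (length(lig_keys)) lig_keys[1] else "",
               caps = data.frame(residue = character(0), type = character(0),
                                 atomName = character(0), serial = integer(0),
                                 stringsAsFactors = FALSE),
               truncations = trunc, mobility = character(0))
}

#' Neutralise truncated termini
#'
#' Every backbone discontinuity created by the truncation receives a cap:
#' N-side breaks become neutral amines (an H placed 1.01 Angstrom from the
#' backbone N along the severed N-C direction), C-side breaks become
#' aldehydes (an H placed 1.09 Angstrom from the backbone C along the
#' severed C-N direction). Caps carry zero formal charge. A cap landing
#' within 0.8 Angstrom of an existing atom is displaced along the
#' bisector away from the colliding atom, with a warning. Original atom
#' coordinates are never changed.
#'
#' @param m an \linkS4class{ActiveSiteModel} from \code{\link{extractActiveSite}}.
#' @return the model with cap atoms added and cap records filled.
#' @export
neutralizeTermini <- function(m) {
  tr <- m@truncations
  if (!nrow(tr)) return(m)
  at <- m@structure@atoms
  rk <- .res_keys_of(at)
  caps <- m@caps
  next_serial <- if (nrow(at)) max(at$serial) + 1L else 1L
  for (i in seq_len(nrow(tr))) {
    host <- which(rk == tr$residue[i] & at$name == tr$atomName[i])
    if (!length(host)) next
    host <- host[1]
    bond_len <- if (tr$side[i] == "N") 1.01 else 1.09
    dir <- c(tr$dx[i], tr$dy[i], tr$dz[i])
    pos <- c(at$x[host], at$y[host], at$z[host]) + bond_len * dir
    # collision guard
    d_all <- sqrt((at$x - pos[1])^2 + (at$y - pos[2])^2 + (at$z - pos[3])^2)
    clash <- which(d_all < 0.8)
    if (length(clash)) {
      warning("cap at ", tr$residue[i], " ", tr$side[i],
              "-side collides with an existing atom; displacing along bisector")
      away <- .unit(pos - c(at$x[clash[1]], at$y[clash[1]], at$z[clash[1]]))
      dir <- .unit(dir + away)
      pos <- c(at$x[host], at$y[host], at$z[host]) + bond_len * dir
    }
    cap_name <- if (tr$side[i] == "N") "HN2" else "HC1"
    at <- rbind(at, data.frame(
      serial = next_serial, name = cap_name, resname = at$resname[host],
      chain = at$chain[host], resno = at$resno[host], insert = at$insert[host],
      x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0, element = "H",
      record = at$record[host], cap = TRUE, stringsAsFactors = FALSE))
    caps <- rbind(caps, data.frame(
      residue = tr$residue[i],
      type = if (tr$side[i] == "N") "neutral-amine" else "aldehyde",
      atomName = cap_name, serial = next_serial, stringsAsFactors = FALSE))
    next_serial <- next_serial + 1L
    rk <- .res_keys_of(at)
  }
  m@structure <- .structure(at, entryId = m@structure@entryId)
  m@caps <- caps
  if (length(m@mobility)) m@mobility <- c(m@mobility, rep("mobile", nrow(caps)))
  m
}

#' Truncate a ligand to its reactive anchor
#'
#' Retains only the named anchor atoms (by default the thioethyl group
#' plus attached acyl head, standing in for the reactive end of a CoA
#' thioester whose bulk pantetheine/nucleotide moiety is removed for
#' computational efficiency). Valences severed by the truncation are
#' capped with hydrogens at 1.09 Angstrom along the removed-bond
#' direction.
#'
#' @param lig a single-residue \linkS4class{Structure} (the ligand).
#' @param keep character vector of heavy-atom names to retain.
#' @param bondCutoff heavy-atom bond detection distance, Angstrom.
#' @return the truncated ligand as a \linkS4class{Structure}.
#' @export
truncateLigand <- function(lig, keep, bondCutoff = 1.9) {
  at <- lig@atoms
  if (length(unique(.res_keys_of(at))) != 1)
    stop("truncateLigand expects a single-residue ligand")
  missing <- setdiff(keep, at$name)
  if (length(missing))
    stop("keep-spec atoms absent from ligand: ", paste(missing, collapse = ", "))
  heavy <- !.is_hydrogen_el(at$element)
  kept <- at$name %in% keep
  # hydrogens already bonded to kept atoms ride along
  if (any(!heavy)) {
    dh <- .cross_dist(.coords_of(at[!heavy, , drop = FALSE]),
                      .coords_of(at[kept & heavy, , drop = FALSE]))
    ride <- apply(dh, 1, min) < 1.3
    kept[which(!heavy)[ride]] <- TRUE
  }
  removed_heavy <- which(heavy & !kept)
  out <- at[kept, , drop = FALSE]
  # cap severed heavy-heavy bonds
  next_serial <- max(at$serial) + 1L
  nh <- 0L
  for (i in which(kept & heavy)) {
    for (j in removed_heavy) {
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
      if (d <= bondCutoff) {
        dir <- .unit(c(at$x[j] - at$x[i], at$y[j] - at$y[i], at$z[j] - at$z[i]))
        pos <- c(at$x[i], at$y[i], at$z[i]) + 1.09 * dir
        nh <- nh + 1L
        out <- rbind(out, data.frame(
          serial = next_serial, name = paste0("HX", nh),
          resname = at$resname[i], chain = at$chain[i], resno = at$resno[i],
          insert = at$insert[i], x = pos[1], y = pos[2], z = pos[3],
          occ = 1, b = 0, element = "H", record = at$record[i], cap = TRUE,
          stringsAsFactors = FALSE))
        next_serial <- next_serial + 1L
      }
    }
  }
  .structure(out, entryId = lig@entryId)
}

#' Assign the mobile/rigid atom partition
#'
#' Receptor backbone atoms are held rigid, as are the side chains of all
#' residues not participating directly in the reaction. Mobile atoms are
#' the ligand, the side chains of the reactive residues, and any cap
#' atoms. By default the reactive set should be the catalytic triad plus
#' user additions.
#'
#' @param m an \linkS4class{ActiveSiteModel}.
#' @param reactive character vector of residue keys whose side chains move.
#' @return the model with per-atom mobility flags assigned.
#' @export
assignMobility <- function(m, reactive = character(0)) {
  at <- m@structure@atoms
  rk <- .res_keys_of(at)
  unknown <- setdiff(reactive, unique(rk))
  if (length(unknown))
    stop("reactive residues not in model: ", paste(unknown, collapse = ", "))
  cls <- .classify_residues(at)
  is_backbone <- at$name %in% .backbone_names & cls$polymer
  mobile <- cls$ligand | at$cap |
    (rk %in% reactive & !is_backbone)
  m@mobility <- ifelse(mobile, "mobile", "rigid")
  methods::validObject(m)
  m
}
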