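# Probe surfaces (Shrake-Rupley point sampling), residue-substrate
# contact areas with minor/major classification, contact traces over
# reaction states, and in-silico side-chain mutagenesis screening.

# deterministic golden-spiral points on the unit sphere
.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.as_atoms <- function(x) {
  if (methods::is(x, "Structure")) x@atoms
  else if (methods::is(x, "ActiveSiteModel")) x@structure@atoms
  else if (is.data.frame(x)) x
  else stop("expected a Structure, ActiveSiteModel or atom table")
}

#' Sample a probe-expanded molecular surface
#'
#' Places \code{n} deterministic golden-spiral points on each atom's
#' sphere of radius (vdW + probe) and removes points buried inside any
#' other atom's expanded sphere (Shrake-Rupley exclusion; a point exactly
#' on a neighbour's expanded sphere counts as buried). No RNG is
#' involved, so areas are exactly reproducible.
#'
#' @param x a \linkS4class{Structure} or atom table whose surface is sampled.
#' @param probe probe radius, Angstrom (default 1.5, the contact probe).
#' @param n points per atom (>= 92; default 960).
#' @param occluders optional second atom set that additionally buries
#'   points (default: only \code{x} itself occludes).
#' @return a \linkS4class{SurfaceSample} of exposed points.
#' @export
sampleSurface <- function(x, probe = 1.5, n = 960, occluders = NULL) {
  at <- .as_atoms(x)
  if (nrow(at) == 0) stop("cannot sample the surface of zero atoms")
  if (n < 92) stop("need at least 92 points per atom")
  rad <- vdwRadius(at$element) + probe
  occ <- if (is.null(occluders)) at else rbind(at, .as_atoms(occluders))
  occ_xyz <- .coords_of(occ)
  occ_rad <- vdwRadius(occ$element) + probe
  sphere <- .golden_spiral(n)
  pts <- list(); wts <- list(); idx <- list()
  xyz <- .coords_of(at)
  for (i in seq_len(nrow(at))) {
    p <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    # candidate occluders: expanded spheres that can reach atom i's surface;
    # the atom itself (row i of the combined table) never buries its own points
    dc <- sqrt(colSums((t(occ_xyz) - xyz[i, ])^2))
    nb <- setdiff(which(dc < rad[i] + occ_rad), i)
    exposed <- rep(TRUE, n)
    if (length(nb)) {
      d2 <- .cross_dist(p, occ_xyz[nb, , drop = FALSE])
      buried <- d2 <= matrix(occ_rad[nb] + 1e-9, nrow = n, ncol = length(nb),
                             byrow = TRUE)
      exposed <- !apply(buried, 1, any)
    }
    if (any(exposed)) {
      pts[[length(pts) + 1L]] <- p[exposed, , drop = FALSE]
      wts[[length(wts) + 1L]] <- rep(4 * pi * rad[i]^2 / n, sum(exposed))
      idx[[length(idx) + 1L]] <- rep(i, sum(exposed))
    }
  }
  methods::new("SurfaceSample",
               points = if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 3),
               weights = if (length(wts)) unlist(wts) else numeric(0),
               atomIndex = if (length(idx)) as.integer(unlist(idx)) else integer(0),
               probe = probe, nPerAtom = n, atoms = at)
}

#' Classify a contact area
#'
#' Zero area is no contact; areas below 0.5 Angstrom^2 are minor
#' contacts; areas of 0.5 Angstrom^2 or more are major contacts.
#'
#' @param area numeric vector of areas, Angstrom^2 (>= 0).
#' @return character vector in {"none", "minor", "major"}.
#' @export
classifyContact <- function(area) {
  if (any(area < 0)) stop("contact areas cannot be negative")
  ifelse(area == 0, "none", ifelse(area < 0.5, "minor", "major"))
}

#' Residue-substrate contact areas
#'
#' Each exposed substrate surface point lying within \code{cutoff}
#' (default 3.0 Angstrom) of at least one receptor atom is assigned to
#' the residue owning the nearest such atom; per-residue contact area is
#' the sum of assigned point weights. Assignment to the single nearest
#' residue partitions the contacted surface, so per-residue areas sum
#' exactly to the total contacted area. With
#' \code{assign = "all"} a point instead counts for every residue with an
#' atom in range (double counting allowed).
#'
#' @param surface \linkS4class{SurfaceSample} built on the substrate atoms only.
#' @param receptor \linkS4class{Structure} of the receptor (substrate excluded).
#' @param cutoff proximity cutoff from surface point to receptor atom
#'   centre, Angstrom (default 3.0).
#' @param assign "nearest" (default) or "all".
#' @return data.frame (residue, chain, resno, resname, area, class) for
#'   contacting residues only, ordered by chain then residue number.
#' @export
residueContactAreas <- function(surface, receptor, cutoff = 3.0,
                                assign = c("nearest", "all")) {
  assign <- match.arg(assign)
  rat <- .as_atoms(receptor)
  empty <- data.frame(residue = character(0), chain = character(0),
                      resno = integer(0), resname = character(0),
                      area = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(rat) == 0 || nrow(surface@points) == 0) return(empty)
  d <- .cross_dist(surface@points, .coords_of(rat))
  rk <- .res_keys_of(rat)
  if (assign == "nearest") {
    in_range <- d <= cutoff
    hit <- which(apply(in_range, 1, any))
    if (!length(hit)) return(empty)
    dmask <- d
    dmask[!in_range] <- Inf
    nearest <- apply(dmask[hit, , drop = FALSE], 1, which.min)
    res <- rk[nearest]
    area <- tapply(surface@weights[hit], res, sum)
  } else {
    contacted <- lapply(unique(rk), function(key) {
      cols <- which(rk == key)
      rows <- which(apply(d[, cols, drop = FALSE] <= cutoff, 1, any))
      sum(surface@weights[rows])
    })
    names(contacted) <- unique(rk)
    area <- unlist(contacted)
    area <- area[area > 0]
    if (!length(area)) return(empty)
  }
  first <- rat[match(names(area), rk), c("chain", "resno", "resname")]
  out <- data.frame(residue = names(area), chain = first$chain,
                    resno = first$resno, resname = first$resname,
                    area = as.numeric(area),
                    class = classifyContact(as.numeric(area)),
                    stringsAsFactors = FALSE)
  out <- out[.order_residues(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact trace over reaction states
#'
#' Computes residue-substrate contact areas for each labelled reaction
#' state and tabulates them residue x state. Residues never in contact
#' are dropped; residue ordering is deterministic (chain, residue
#' number); state ordering follows the input.
#'
#' @param states named list of \linkS4class{Structure} objects, one per
#'   reaction state.
#' @param substrate residue key "chain/resno" or residue name identifying
#'   the substrate in every state.
#' @param cutoff,probe,n surface parameters (defaults 3.0, 1.5, 960).
#' @return long-format data.frame (residue, chain, resno, resname, state,
#'   area, class) covering every contacting residue in every state.
#' @export
contactTrace <- function(states, substrate, cutoff = 3.0, probe = 1.5,
                         n = 960) {
  if (is.null(names(states)) || any(names(states) == ""))
    names(states) <- paste0("state", seq_along(states))
  per_state <- lapply(names(states), function(lab) {
    s <- states[[lab]]
    sub <- .split_substrate(s, substrate, lab)
    surf <- sampleSurface(sub$ligand, probe = probe, n = n)
    rec <- residueContactAreas(surf, sub$receptor, cutoff = cutoff)
    if (nrow(rec)) rec$state <- lab
    rec
  })
  res_info <- unique(do.call(rbind, lapply(per_state, function(r)
    r[, c("residue", "chain", "resno", "resname")])))
  if (is.null(res_info) || nrow(res_info) == 0)
    return(data.frame(residue = character(0), chain = character(0),
                      resno = integer(0), resname = character(0),
                      state = character(0), area = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  res_info <- res_info[.order_residues(res_info$chain, res_info$resno), ,
                       drop = FALSE]
  grid <- merge(res_info, data.frame(state = names(states)), by = NULL)
  long <- do.call(rbind, per_state)
  out <- merge(grid, long[, c("residue", "state", "area")],
               by = c("residue", "state"), all.x = TRUE)
  out$area[is.na(out$area)] <- 0
  out$class <- classifyContact(out$area)
  out <- out[order(match(out$residue, res_info$residue),
                   match(out$state, names(states))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("residue", "chain", "resno", "resname", "state", "area", "class")]
}

# split a state into substrate and receptor, failing with the state name
.split_substrate <- function(s, substrate, label = "?") {
  at <- s@atoms
  rk <- .res_keys_of(at)
  is_sub <- if (grepl("/", substrate)) rk == substrate else at$resname == substrate
  if (!any(is_sub))
    stop("substrate '", substrate, "' missing from state '", label, "'")
  list(ligand = .structure(at[is_sub, , drop = FALSE], entryId = s@entryId),
       receptor = .structure(at[!is_sub, , drop = FALSE], entryId = s@entryId))
}

## ---- in-silico mutagenesis -------------------------------------------------

#' Mutation specification
#'
#' Supported edits are expressible as terminal heavy-atom deletions
#' and/or one ideal-geometry methyl addition (C-C 1.52 Angstrom,
#' staggered direction): LEU>ALA, LEU>VAL, LEU>ILE, SER>GLY, SER>THR and
#' ASN>SER (the last deletes the amide and retypes CG to a hydroxyl
#' oxygen at the same position). Anything else (e.g. a mutation adding a
#' ring) is rejected as unsupported.
#'
#' @param residue residue key "chain/resno".
#' @param from,to three-letter residue codes.
#' @return a mutation spec (list) consumed by \code{\link{applyMutation}}.
#' @export
mutationSpec <- function(residue, from, to) {
  from <- toupper(from); to <- toupper(to)
  key <- paste0(from, ">", to)
  if (!key %in% names(.mutation_edits) && from != to)
    stop("unsupported mutation ", key,
         " (supported: ", paste(names(.mutation_edits), collapse = ", "),
         ", or an identity no-op)")
  structure(list(residue = residue, from = from, to = to,
                 edits = if (from == to) list() else .mutation_edits[[key]]),
            class = "qns_mutation")
}

.mutation_edits <- list(
  "LEU>ALA" = list(delete = c("CG", "CD1", "CD2")),
  "LEU>VAL" = list(delete = c("CD1", "CD2"), rename = c(CG = "CG1"),
                   methyl = list(attach = "CB", name = "CG2")),
  "LEU>ILE" = list(delete = c("CD2"), rename = c(CG = "CG1", CD1 = "CD1"),
                   methyl = list(attach = "CB", name = "CG2")),
  "SER>GLY" = list(delete = c("OG", "CB")),
  "SER>THR" = list(rename = c(OG = "OG1"),
                   methyl = list(attach = "CB", name = "CG2")),
  "ASN>SER" = list(delete = c("OD1", "ND2"), rename = c(CG = "OG"),
                   retype = c(OG = "O"))
)

#' Apply an in-silico point mutation
#'
#' Deletions remove the named terminal heavy atoms (hydrogens bonded to
#' them ride along); methyl additions place one carbon at 1.52 Angstrom
#' from the attachment atom in the staggered (anti to existing
#' substituents) direction. The residue is renamed to the target amino
#' acid. Original atom coordinates are never moved.
#'
#' @param s a \linkS4class{Structure}.
#' @param m a mutation spec from \code{\link{mutationSpec}}.
#' @return the mutated \linkS4class{Structure}.
#' @export
applyMutation <- function(s, m) {
  stopifnot(inherits(m, "qns_mutation"))
  at <- s@atoms
  rk <- .res_keys_of(at)
  rows <- which(rk == m$residue)
  if (!length(rows)) stop("residue not found: ", m$residue)
  if (at$resname[rows[1]] != m$from)
    stop("residue ", m$residue, " is ", at$resname[rows[1]], ", not ", m$from)
  if (!length(m$edits)) return(s)   # identity no-op
  ed <- m$edits
  drop_rows <- integer(0)
  if (!is.null(ed$delete)) {
    del <- rows[at$name[rows] %in% ed$delete]
    # hydrogens bonded to deleted heavies go too
    hyd <- rows[.is_hydrogen_el(at$element[rows])]
    if (length(hyd) && length(del)) {
      dh <- .cross_dist(.coords_of(at[hyd, , drop = FALSE]),
                        .coords_of(at[del, , drop = FALSE]))
      drop_rows <- c(del, hyd[apply(dh, 1, min) < 1.3])
    } else drop_rows <- del
  }
  if (length(drop_rows)) at <- at[-drop_rows, , drop = FALSE]
  rk <- .res_keys_of(at)
  rows <- which(rk == m$residue)
  if (!is.null(ed$rename)) {
    for (old in names(ed$rename)) {
      at$name[rows][at$name[rows] == old] <- ed$rename[[old]]
    }
  }
  if (!is.null(ed$retype)) {
    for (nm in names(ed$retype)) {
      at$element[rows][at$name[rows] == nm] <- ed$retype[[nm]]
    }
  }
  if (!is.null(ed$methyl)) {
    attach <- rows[at$name[rows] == ed$methyl$attach]
    if (!length(attach)) stop("methyl attachment atom ", ed$methyl$attach,
                              " missing in ", m$residue)
    attach <- attach[1]
    a_pos <- c(at$x[attach], at$y[attach], at$z[attach])
    heavy_rows <- rows[!.is_hydrogen_el(at$element[rows]) & rows != attach]
    nb <- heavy_rows[sqrt((at$x[heavy_rows] - a_pos[1])^2 +
                          (at$y[heavy_rows] - a_pos[2])^2 +
                          (at$z[heavy_rows] - a_pos[3])^2) < 1.8]
    dir <- if (length(nb)) {
      v <- -colSums(matrix(vapply(nb, function(j)
        .unit(c(at$x[j], at$y[j], at$z[j]) - a_pos), numeric(3)),
        ncol = 3, byrow = TRUE))
      if (sqrt(sum(v^2)) < 1e-8) .perp(c(at$x[nb[1]], at$y[nb[1]], at$z[nb[1]]) - a_pos)
      else .unit(v)
    } else c(0, 0, 1)
    pos <- a_pos + 1.52 * dir
    at <- rbind(at, data.frame(
      serial = max(at$serial) + 1L, name = ed$methyl$name,
      resname = at$resname[attach], chain = at$chain[attach],
      resno = at$resno[attach], insert = at$insert[attach],
      x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0, element = "C",
      record = at$record[attach], cap = FALSE, stringsAsFactors = FALSE))
    rows <- which(.res_keys_of(at) == m$residue)
  }
  at$resname[rows] <- m$to
  .structure(at, entryId = s@entryId, cell = s@cell,
             spaceGroup = s@spaceGroup, operators = s@operators)
}

#' Screen a mutation across reaction states
#'
#' For every state the wild-type and mutant contact areas of the mutated
#' residue are compared; the report flags states where the sign of the
#' area change differs from a neighbouring state (the transition-state
#' versus product clash logic).
#'
#' @param states named list of \linkS4class{Structure} reaction states.
#' @param m a mutation spec from \code{\link{mutationSpec}}.
#' @param substrate substrate residue key or residue name.
#' @param cutoff,probe,n surface parameters.
#' @return data.frame (state, area_wt, area_mut, delta, class_wt,
#'   class_mut, sign_change).
#' @export
screenMutation <- function(states, m, substrate, cutoff = 3.0, probe = 1.5,
                           n = 960) {
  if (is.null(names(states)) || any(names(states) == ""))
    names(states) <- paste0("state", seq_along(states))
  one_state <- function(s, lab) {
    sub <- .split_substrate(s, substrate, lab)
    surf <- sampleSurface(sub$ligand, probe = probe, n = n)
    wt <- residueContactAreas(surf, sub$receptor, cutoff = cutoff)
    area_wt <- if (m$residue %in% wt$residue) wt$area[wt$residue == m$residue] else 0
    mut_rec <- applyMutation(sub$receptor, m)
    mu <- residueContactAreas(surf, mut_rec, cutoff = cutoff)
    area_mut <- if (m$residue %in% mu$residue) mu$area[mu$residue == m$residue] else 0
    c(area_wt = area_wt, area_mut = area_mut)
  }
  vals <- t(vapply(names(states), function(lab) one_state(states[[lab]], lab),
                   numeric(2)))
  delta <- vals[, "area_mut"] - vals[, "area_wt"]
  sgn <- sign(round(delta, 10))
  sign_change <- vapply(seq_along(sgn), function(i) {
    nb <- sgn[setdiff(c(i - 1, i + 1), c(0, length(sgn) + 1))]
    sgn[i] != 0 && any(nb != 0 & nb != sgn[i])
  }, logical(1))
  data.frame(state = names(states),
             area_wt = vals[, "area_wt"], area_mut = vals[, "area_mut"],
             delta = delta,
             class_wt = classifyContact(vals[, "area_wt"]),
             class_mut = classifyContact(vals[, "area_mut"]),
             sign_change = sign_change,
             row.names = NULL, stringsAsFactors = FALSE)
}
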