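# Shared geometry helpers, atom/residue keys, element tables.

# Bondi-style van der Waals radii (Angstrom). Single table used by every
# surface computation so contact areas are reproducible across modules.
.vdw_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  B = 1.92, SI = 2.10, FE = 2.00, ZN = 1.39, MG = 1.73, "NA" = 2.27,
  K = 2.75, CA = 2.31, MN = 2.00, CU = 1.40, CD = 1.58
)

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdwRadius <- function(element) {
  el <- toupper(element)
  r <- .vdw_radii[el]
  if (anyNA(r)) {
    bad <- sort(unique(el[is.na(r)]))
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

.water_resnames <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

# residue key "chain/resno[insert]"
.res_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, "/", resno, ins)
}

# atom key "chain/resno[insert]/name"
.atom_key <- function(chain, resno, name, insert = "") {
  paste0(.res_key(chain, resno, insert), "/", name)
}

.atom_keys_of <- function(at) .atom_key(at$chain, at$resno, at$name, at$insert)
.res_keys_of  <- function(at) .res_key(at$chain, at$resno, at$insert)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

# any vector perpendicular to v
.perp <- function(v) {
  u <- .unit(v)
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(w - sum(w * u) * u)
}

# pairwise distances between rows of two n x 3 matrices (m x n result)
.cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.coords_of <- function(at) cbind(x = at$x, y = at$y, z = at$z)

# deterministic residue ordering: chain, then resno, then insertion code
.order_residues <- function(chain, resno, insert = NULL) {
  if (is.null(insert)) order(chain, resno) else order(chain, resno, insert)
}

.is_hydrogen_el <- function(element) toupper(element) %in% c("H", "D")
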