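# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; nothing is read from disk except
# files the tests themselves write.

# quick atom-table row(s)
fx_atoms <- function(name, resname, chain, resno, xyz, element = NULL,
                     record = "ATOM") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(serial = seq_len(length(name)), name = name, resname = resname,
             chain = chain, resno = resno,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = if (is.null(element)) substr(name, 1, 1) else element,
             record = record, stringsAsFactors = FALSE)
}

fx_structure <- function(...) buildStructure(fx_atoms(...))

# full-side-chain residue templates (idealised local geometry) for the
# mutagenesis tests; `origin` translates the whole residue
fx_residue <- function(resname, chain, resno, origin = c(0, 0, 0)) {
  tpl <- switch(resname,
    LEU = list(N  = c(-1.46, 0.90, 0.00), CA = c(0.00, 1.00, 0.00),
               C  = c(0.70, 1.10, 1.35),  O  = c(0.10, 1.30, 2.40),
               CB = c(0.60, -0.20, -0.75), CG = c(0.50, -1.55, -0.05),
               CD1 = c(1.20, -2.65, -0.85), CD2 = c(1.10, -1.55, 1.35)),
    SER = list(N  = c(-1.46, 0.90, 0.00), CA = c(0.00, 1.00, 0.00),
               C  = c(0.70, 1.10, 1.35),  O  = c(0.10, 1.30, 2.40),
               CB = c(0.60, -0.20, -0.75), OG = c(0.45, -1.40, -0.02)),
    ASN = list(N  = c(-1.46, 0.90, 0.00), CA = c(0.00, 1.00, 0.00),
               C  = c(0.70, 1.10, 1.35),  O  = c(0.10, 1.30, 2.40),
               CB = c(0.60, -0.20, -0.75), CG = c(0.50, -1.55, -0.05),
               OD1 = c(1.30, -2.45, -0.45), ND2 = c(-0.40, -1.85, 0.90)),
    VAL = list(N  = c(-1.46, 0.90, 0.00), CA = c(0.00, 1.00, 0.00),
               C  = c(0.70, 1.10, 1.35),  O  = c(0.10, 1.30, 2.40),
               CB = c(0.60, -0.20, -0.75), CG1 = c(0.50, -1.50, 0.05),
               CG2 = c(2.08, 0.05, -1.00)),
    GLY = list(N  = c(-1.46, 0.90, 0.00), CA = c(0.00, 1.00, 0.00),
               C  = c(0.70, 1.10, 1.35),  O  = c(0.10, 1.30, 2.40)),
    stop("no template for ", resname))
  nm <- names(tpl)
  xyz <- do.call(rbind, tpl)
  el <- substr(nm, 1, 1)
  data.frame(serial = seq_along(nm), name = nm, resname = resname,
             chain = chain, resno = resno,
             x = xyz[, 1] + origin[1], y = xyz[, 2] + origin[2],
             z = xyz[, 3] + origin[3],
             element = el, record = "ATOM", stringsAsFactors = FALSE)
}

fx_bind <- function(...) {
  parts <- list(...)
  at <- do.call(rbind, parts)
  at$serial <- seq_len(nrow(at))
  buildStructure(at)
}

# independent line-scan record counter for PDB files
fx_count_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sum(grepl("^(ATOM  |HETATM)", lines))
}

# closed-form adiabat of a scan-system manifest (independent of the
# scan driver: direct evaluation of the generator's stated energy law)
fx_adiabat <- function(d, pars) {
  e1 <- 0.5 * pars$kR * (d - pars$dR)^2
  e2 <- pars$De * (1 - exp(-pars$a * (d - pars$rc)))^2 - pars$De + pars$C
  0.5 * (e1 + e2) - sqrt(0.25 * (e1 - e2)^2 + pars$W^2)
}

# dense-grid barrier oracle (0.01 A grid, reference at the start distance)
fx_grid_barrier <- function(manifest, by = 0.01) {
  g <- seq(manifest$covalentTarget, manifest$startDistance, by = by)
  e <- fx_adiabat(g, manifest$pars)
  list(height = max(e) - e[length(e)], position = g[which.max(e)])
}

# brute-force point-assignment contact oracle: double loop over surface
# points and receptor atoms, nearest-in-range residue wins
fx_contact_oracle <- function(surface, receptor, cutoff = 3.0) {
  rat <- atoms(receptor)
  rk <- paste0(rat$chain, "/", rat$resno)
  areas <- list()
  pts <- surface@points
  for (p in seq_len(nrow(pts))) {
    best <- NULL
    bestd <- Inf
    for (a in seq_len(nrow(rat))) {
      d <- sqrt(sum((pts[p, ] - c(rat$x[a], rat$y[a], rat$z[a]))^2))
      if (d <= cutoff && d < bestd) { bestd <- d; best <- rk[a] }
    }
    if (!is.null(best))
      areas[[best]] <- (if (is.null(areas[[best]])) 0 else areas[[best]]) +
        surface@weights[p]
  }
  unlist(areas)
}

# brute-force cross-partition pair counter
fx_pair_count <- function(a, b, dmax, elements_a = NULL, elements_b = NULL,
                          drop_h = TRUE) {
  ata <- atoms(a); atb <- atoms(b)
  if (drop_h) {
    ata <- ata[!toupper(ata$element) %in% c("H", "D"), ]
    atb <- atb[!toupper(atb$element) %in% c("H", "D"), ]
  }
  if (!is.null(elements_a)) ata <- ata[ata$element %in% elements_a, ]
  if (!is.null(elements_b)) atb <- atb[atb$element %in% elements_b, ]
  n <- 0L
  for (i in seq_len(nrow(ata))) for (j in seq_len(nrow(atb))) {
    d <- sqrt((ata$x[i] - atb$x[j])^2 + (ata$y[i] - atb$y[j])^2 +
              (ata$z[i] - atb$z[j])^2)
    if (d <= dmax) n <- n + 1L
  }
  n
}
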