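## Synthetic planted complexes: desk-scale coordinate systems in which every
## interaction is built at known mid-criterion geometry (and every decoy just
## outside it), so detectors can be tested against exact ground truth.
##
## Fragments are idealized: pyranose rings are regular hexagons (bond
## ~1.45 Å) with radial substituents, water is rigid (O-H 0.957 Å, H-O-H
## 104.5 deg), and planted protein fragments carry only the atoms their
## interaction needs (e.g. a lysine site is just the NZ centre). Events are
## planted on a 20 Å grid so planted sites cannot interact with each other.

DEG <- pi / 180

ring_u <- function(angle_deg) c(cos(angle_deg * DEG), sin(angle_deg * DEG), 0)

## in-plane rotation of a direction about z
rot_z <- function(v, angle_deg) {
  c(cos(angle_deg * DEG) * v[1] - sin(angle_deg * DEG) * v[2],
    sin(angle_deg * DEG) * v[1] + cos(angle_deg * DEG) * v[2], v[3])
}

new_fragment <- function() {
  list(atoms = data.frame(name = character(), resname = character(),
                          element = character(), role = character(),
                          reskey = character(), stringsAsFactors = FALSE),
       xyz = matrix(numeric(0), 0, 3))
}

frag_add <- function(frag, name, resname, element, role, reskey, pos) {
  frag$atoms <- rbind(frag$atoms, data.frame(
    name = name, resname = resname, element = element, role = role,
    reskey = reskey, stringsAsFactors = FALSE))
  frag$xyz <- rbind(frag$xyz, matrix(pos, 1, 3))
  frag
}

frag_merge <- function(...) {
  fr <- list(...)
  list(atoms = do.call(rbind, lapply(fr, `[[`, "atoms")),
       xyz = do.call(rbind, lapply(fr, `[[`, "xyz")))
}

frag_transform <- function(frag, rotation = diag(3), translation = c(0, 0, 0)) {
  frag$xyz <- sweep(frag$xyz %*% t(rotation), 2, translation, `+`)
  frag
}

frag_atom_pos <- function(frag, resname, name) {
  i <- which(frag$atoms$resname == resname & frag$atoms$name == name)[1]
  frag$xyz[i, ]
}

#' Idealized hyaluronate disaccharide fragment (GCU-NAG)
#'
#' Builds a geometry-idealized repeat unit: a D-glucuronate ring (GCU) with
#' its carboxylate (formal charge -1), three hydroxyls and ring/glycosidic
#' oxygens, linked to an N-acetyl-D-glucosamine ring (NAG) with hydroxyls,
#' ring oxygen, N-acetyl group and methyl carbon. Heavy atoms plus polar
#' hydrogens are included; every N/O atom is covered by the shipped
#' oxygen-class map.
#'
#' @param rotation 3x3 rotation applied to the template.
#' @param translation 3-vector translation (Å).
#' @param reskey_prefix internal residue-key prefix.
#' @return A fragment list (`atoms`, `xyz`); see [make_planted_complex()] for
#'   assembly into a system, or wrap with [toy_disaccharide_system()].
#' @export
make_toy_disaccharide <- function(rotation = diag(3),
                                  translation = c(0, 0, 0),
                                  reskey_prefix = "L1") {
  f <- new_fragment()
  gk <- paste0(reskey_prefix, "_GCU")
  nk <- paste0(reskey_prefix, "_NAG")
  r <- 1.45; b <- 1.43; oh <- 0.96
  ## GCU ring: C1..C5 + ring O5 on a hexagon
  ang <- c(C1 = 0, C2 = 60, C3 = 120, C4 = 180, C5 = 240, O5 = 300)
  gpos <- lapply(ang, function(a) r * ring_u(a))
  for (nm in names(gpos))
    f <- frag_add(f, nm, "GCU", substr(nm, 1, 1), "ligand", gk, gpos[[nm]])
  ## glycosidic O1, hydroxyls O2-O4 (+H), carboxylate C6/O6A/O6B
  f <- frag_add(f, "O1", "GCU", "O", "ligand", gk, gpos$C1 + b * ring_u(0))
  for (nm in c("O2", "O3", "O4")) {
    a <- ang[[sub("O", "C", nm)]]
    z <- c(0, 0, ifelse(nm == "O3", 0.4, -0.4))
    op <- gpos[[sub("O", "C", nm)]] + b * ring_u(a) + z
    f <- frag_add(f, nm, "GCU", "O", "ligand", gk, op)
    f <- frag_add(f, paste0("H", nm), "GCU", "H", "ligand", gk,
                  op + oh * ring_u(a))
  }
  w <- ring_u(240)
  c6 <- gpos$C5 + 1.50 * w
  f <- frag_add(f, "C6", "GCU", "C", "ligand", gk, c6)
  f <- frag_add(f, "O6A", "GCU", "O", "ligand", gk, c6 + 1.25 * rot_z(w, 60))
  f <- frag_add(f, "O6B", "GCU", "O", "ligand", gk, c6 + 1.25 * rot_z(w, -60))
  ## NAG ring centred beyond the glycosidic oxygen
  n0 <- gpos$C1 + (2 * b + r) * ring_u(0)
  nang <- c(C1 = 60, C2 = 120, C3 = 180, C4 = 240, C5 = 300, O5 = 0)
  npos <- lapply(nang, function(a) n0 + r * ring_u(a))
  for (nm in names(npos))
    f <- frag_add(f, nm, "NAG", substr(nm, 1, 1), "ligand", nk, npos[[nm]])
  ## anomeric and C4 hydroxyls
  o1 <- npos$C1 + b * ring_u(60) + c(0, 0, 0.3)
  f <- frag_add(f, "O1", "NAG", "O", "ligand", nk, o1)
  f <- frag_add(f, "HO1", "NAG", "H", "ligand", nk, o1 + oh * ring_u(60))
  o4 <- npos$C4 + b * ring_u(240) + c(0, 0, -0.3)
  f <- frag_add(f, "O4", "NAG", "O", "ligand", nk, o4)
  f <- frag_add(f, "HO4", "NAG", "H", "ligand", nk, o4 + oh * ring_u(240))
  ## hydroxymethyl C6-O6
  c6n <- npos$C5 + 1.50 * unitv(ring_u(300) + c(0, 0, 0.8))
  f <- frag_add(f, "C6", "NAG", "C", "ligand", nk, c6n)
  o6 <- c6n + b * ring_u(300)
  f <- frag_add(f, "O6", "NAG", "O", "ligand", nk, o6)
  f <- frag_add(f, "HO6", "NAG", "H", "ligand", nk, o6 + oh * ring_u(300))
  ## N-acetyl group on C2
  d <- ring_u(120)
  n2 <- npos$C2 + b * d
  f <- frag_add(f, "N2", "NAG", "N", "ligand", nk, n2)
  f <- frag_add(f, "HN2", "NAG", "H", "ligand", nk,
                n2 + 1.01 * unitv(d + c(0, 0, 1.2)))
  c7 <- n2 + 1.35 * unitv(d - c(0, 0, 1.2))
  f <- frag_add(f, "C7", "NAG", "C", "ligand", nk, c7)
  f <- frag_add(f, "O7", "NAG", "O", "ligand", nk,
                c7 + 1.23 * unitv(c(0, 0, -1) + 0.3 * d))
  f <- frag_add(f, "C8", "NAG", "C", "ligand", nk,
                c7 + 1.50 * unitv(d + c(0, 0.2, -0.4)))
  frag_transform(f, rotation, translation)
}

#' A single toy disaccharide as a one-frame system
#' @param ... passed to [make_toy_disaccharide()].
#' @return A `molsys` with one GCU and one NAG residue.
#' @export
toy_disaccharide_system <- function(...) {
  assemble_system(make_toy_disaccharide(...))
}

## --- receptor / solvent fragments (minimal planted sites) ----------------

frag_single <- function(name, resname, element, role, reskey, pos) {
  frag_add(new_fragment(), name, resname, element, role, reskey, pos)
}

frag_water <- function(reskey, origin = c(0, 0, 0)) {
  h <- 52.25
  d1 <- c(-sin(h * DEG), 0, cos(h * DEG))
  d2 <- c(sin(h * DEG), 0, cos(h * DEG))
  f <- frag_single("O", "HOH", "O", "water", reskey, origin)
  f <- frag_add(f, "H1", "HOH", "H", "water", reskey, origin + 0.957 * d1)
  frag_add(f, "H2", "HOH", "H", "water", reskey, origin + 0.957 * d2)
}

## --- planted motifs -------------------------------------------------------
## Each motif returns a fragment in motif-local coordinates plus ground-truth
## records. Geometry is mid-criterion for planted events and outside the
## criterion (with a wide margin) for decoys.

motif_hbond <- function(reskey, dist = 2.2) {
  lig <- make_toy_disaccharide(reskey_prefix = reskey)
  a <- frag_atom_pos(lig, "NAG", "O5")
  x <- c(1, 0, 0)
  ser <- frag_single("OG", "SER", "O", "receptor", paste0(reskey, "_R"),
                     a + (dist + 0.96) * x)
  ser <- frag_add(ser, "HG", "SER", "H", "receptor", paste0(reskey, "_R"),
                  a + dist * x)
  frag_merge(lig, ser)
}

motif_water_bridge <- function(reskey, leg = 2.8) {
  lig <- make_toy_disaccharide(reskey_prefix = reskey)
  a <- frag_atom_pos(lig, "NAG", "O5")
  h <- 52.25
  d1 <- c(-sin(h * DEG), 0, cos(h * DEG))
  d2 <- c(sin(h * DEG), 0, cos(h * DEG))
  wpos <- a - (0.957 + leg) * d1
  wat <- frag_water(paste0(reskey, "_W"), wpos)
  ser <- frag_single("OG", "SER", "O", "receptor", paste0(reskey, "_R"),
                     wpos + (0.957 + leg) * d2)
  frag_merge(lig, wat, ser)
}

motif_ionic <- function(reskey, adjusted = 0.75, config = fp_config()) {
  lig <- make_toy_disaccharide(reskey_prefix = reskey)
  m <- (frag_atom_pos(lig, "GCU", "O6A") +
          frag_atom_pos(lig, "GCU", "O6B")) / 2
  w <- ring_u(240)
  raw <- adjusted + ionic_radius("N", config) + ionic_radius("O", config)
  lys <- frag_single("NZ", "LYS", "N", "receptor", paste0(reskey, "_R"),
                     m + raw * w)
  frag_merge(lig, lys)
}

motif_cation_bridge <- function(reskey, species = "CA", adjusted = 0.75,
                                adjusted_receptor = adjusted,
                                config = fp_config()) {
  lig <- make_toy_disaccharide(reskey_prefix = reskey)
  m <- (frag_atom_pos(lig, "GCU", "O6A") +
          frag_atom_pos(lig, "GCU", "O6B")) / 2
  w <- ring_u(240)
  r_ion <- ionic_radius(species, config)
  r_o <- ionic_radius("O", config)
  p <- m + (adjusted + r_ion + r_o) * w
  ion <- frag_single(species, species, species, "ion",
                     paste0(reskey, "_I"), p)
  g <- p + (adjusted_receptor + r_ion + r_o) * w
  glu <- frag_single("OE1", "GLU", "O", "receptor", paste0(reskey, "_R"),
                     g + c(0, 0, 1.082))
  glu <- frag_add(glu, "OE2", "GLU", "O", "receptor", paste0(reskey, "_R"),
                  g - c(0, 0, 1.082))
  frag_merge(lig, ion, glu)
}

motif_hydrophobic <- function(reskey, dist = 4.0) {
  lig <- make_toy_disaccharide(reskey_prefix = reskey)
  c8 <- frag_atom_pos(lig, "NAG", "C8")
  c7 <- frag_atom_pos(lig, "NAG", "C7")
  u <- unitv(c8 - c7)
  ala <- frag_single("CB", "ALA", "C", "receptor", paste0(reskey, "_R"),
                     c8 + dist * u)
  frag_merge(lig, ala)
}

## --- assembly -------------------------------------------------------------

## Turn a fragment into a one-frame molsys: receptor residues on chain A,
## ligand on B, waters on W, ions on I, sequential numbering per chain.
assemble_system <- function(frag, times = NULL) {
  a <- frag$atoms
  chain_of <- c(receptor = "A", ligand = "B", water = "W", ion = "I",
                other = "X")
  a$chain <- chain_of[a$role]
  a$resno <- NA_integer_
  for (ch in unique(a$chain)) {
    sel <- a$chain == ch
    keys <- unique(a$reskey[sel])
    a$resno[sel] <- match(a$reskey[sel], keys)
  }
  a$serial <- seq_len(nrow(a))
  atoms <- a[, c("serial", "name", "resname", "chain", "resno", "element",
                 "role")]
  xyz <- array(frag$xyz, c(nrow(a), 3, 1))
  molecular_system(atoms, xyz, times)
}

#' Build a planted complex with exactly known interactions
#'
#' Plants the requested number of events of each contact type, each at its
#' own site of a 20 Å grid so sites cannot interact, each at mid-criterion
#' geometry: hydrogen bonds at H-acceptor 2.2 Å and ideal angles (energy
#' 20 kJ/mol), water bridges with 2.8 Å legs, ionic contacts at adjusted
#' distance 0.75 Å, cation bridges with both adjusted legs 0.75 Å, and
#' hydrophobic methyl-methyl pairs at 4.0 Å. Decoys cycle through the same
#' motif types built well outside the criteria (2.9 Å hydrogen bonds, 3.5 Å
#' water legs, adjusted 2.0 Å ionic pairs, one-sided cation bridges, 5.5 Å
#' carbon pairs). Sites get deterministic seed-derived rigid rotations and
#' grid placements, so the whole construction is reproducible bit for bit.
#'
#' @param n_hbond,n_water_bridge,n_ionic,n_cation_bridge,n_hydrophobic
#'   planted event counts.
#' @param cation_species recycled over the cation-bridge sites.
#' @param n_decoys number of decoy sites.
#' @param seed integer seed controlling placement and orientation.
#' @param config an [fp_config()] (radii used in the ionic constructions).
#' @return Object of class `planted_complex`: list with `system` (one-frame
#'   `molsys`), `truth` (expected counts per detector plus participant
#'   table), and `params`.
#' @export
make_planted_complex <- function(n_hbond = 1, n_water_bridge = 1,
                                 n_ionic = 1, n_cation_bridge = 1,
                                 cation_species = "CA",
                                 n_hydrophobic = 1, n_decoys = 0,
                                 seed = 1, config = fp_config()) {
  counts <- c(n_hbond, n_water_bridge, n_ionic, n_cation_bridge,
              n_hydrophobic, n_decoys)
  if (any(counts < 0)) mf_stop("mf_domain_error", "counts must be >= 0")
  site_types <- c(rep("hbond", n_hbond),
                  rep("water_bridge", n_water_bridge),
                  rep("ionic", n_ionic),
                  rep("cation_bridge", n_cation_bridge),
                  rep("hydrophobic", n_hydrophobic),
                  rep("decoy", n_decoys))
  grid <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 20
  if (length(site_types) > nrow(grid))
    mf_stop("mf_packing_error",
            paste0("too many sites (", length(site_types), ") for the box (",
                   nrow(grid), " grid points)"))
  cation_species <- rep(cation_species, length.out = max(1, n_cation_bridge))
  decoy_cycle <- c("hbond", "water_bridge", "ionic", "cation_bridge",
                   "hydrophobic")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  place <- grid[sample(nrow(grid), length(site_types)), , drop = FALSE]

  frags <- list()
  truth_rows <- list()
  ncb <- 0
  for (k in seq_along(site_types)) {
    ty <- site_types[k]
    key <- sprintf("S%02d", k)
    decoy <- ty == "decoy"
    sub <- if (decoy) decoy_cycle[(k - 1) %% length(decoy_cycle) + 1] else ty
    f <- switch(sub,
      hbond = motif_hbond(key, dist = if (decoy) 2.9 else 2.2),
      water_bridge = motif_water_bridge(key, leg = if (decoy) 3.5 else 2.8),
      ionic = motif_ionic(key, adjusted = if (decoy) 2.0 else 0.75,
                          config = config),
      cation_bridge = {
        ncb <- ncb + !decoy
        sp <- if (decoy) "CA" else cation_species[ncb]
        motif_cation_bridge(key, species = sp, adjusted = 0.75,
                            adjusted_receptor = if (decoy) 2.5 else 0.75,
                            config = config)
      },
      hydrophobic = motif_hydrophobic(key, dist = if (decoy) 5.5 else 4.0)
    )
    f <- frag_transform(f, random_rotation(stats::runif(3)), place[k, ])
    frags[[k]] <- f
    if (!decoy)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        type = ty, site = key,
        species = if (ty == "cation_bridge") cation_species[ncb] else NA,
        stringsAsFactors = FALSE)
  }
  system <- assemble_system(do.call(frag_merge, frags))
  truth <- list(
    counts = c(hbond = n_hbond, water_bridge = n_water_bridge,
               ionic = n_ionic, cation_bridge = n_cation_bridge,
               hydrophobic = n_hydrophobic),
    events = if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
      data.frame(type = character(), site = character(),
                 species = character())
  )
  structure(list(system = system, truth = truth,
                 params = list(seed = seed, n_decoys = n_decoys,
                               cation_species = cation_species)),
            class = "planted_complex")
}

#' @export
print.planted_complex <- function(x, ...) {
  cat("Planted complex (seed", x$params$seed, "):",
      paste(sprintf("%s=%d", names(x$truth$counts), x$truth$counts),
            collapse = " "),
      "+", x$params$n_decoys, "decoy(s)\n")
  print(x$system)
  invisible(x)
}

#' Multi-frame pseudo-trajectory from a planted complex
#'
#' Replicates the base coordinates over `n_frames` frames and adds
#' independent Gaussian jitter per atom coordinate. With `jitter_sd` at most
#' a quarter of the smallest planted criterion margin (0.2 Å legs for water
#' bridges, so jitter_sd <= 0.05), planted counts are preserved in at least
#' 95% of frames.
#'
#' @param base a `planted_complex` or `molsys`.
#' @param n_frames number of frames.
#' @param jitter_sd per-coordinate Gaussian noise, Å.
#' @param seed integer seed.
#' @param dt frame spacing in ns.
#' @return A multi-frame `molsys`.
#' @export
make_trajectory <- function(base, n_frames = 10, jitter_sd = 0.0, seed = 1,
                            dt = 0.1) {
  system <- if (inherits(base, "planted_complex")) base$system else base
  nat <- nrow(system$atoms)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  xyz <- array(NA_real_, c(nat, 3, n_frames))
  base_xyz <- system$xyz[, , 1]
  for (f in seq_len(n_frames))
    xyz[, , f] <- base_xyz +
      matrix(stats::rnorm(nat * 3, 0, jitter_sd), nat, 3)
  molecular_system(system$atoms[, c("serial", "name", "resname", "chain",
                                    "resno", "element", "role")],
                   xyz, times = seq(0, by = dt, length.out = n_frames))
}

#' Random donor-hydrogen-acceptor geometries on a grid
#'
#' Builds one frame containing `n` isolated four-atom sites, each a donor
#' nitrogen with its hydrogen facing an acceptor oxygen carrying one attached
#' carbon. Per site the hydrogen-acceptor distance is drawn uniformly from
#' `dist_range` and the donor-hydrogen-acceptor and
#' hydrogen-acceptor-attached-atom angles uniformly from 0-180 degrees.
#' Sites sit on a 14 Å grid, so no cross-site pair can reach hydrogen-bond
#' range and each site's detection outcome is governed by its own sampled
#' (distance, angle, angle) triple -- which is returned alongside for
#' oracle checks.
#'
#' @param n number of sites.
#' @param seed integer seed.
#' @param dist_range hydrogen-acceptor distance range, Å.
#' @return List with `system` (one-frame `molsys`; donors are receptor ALA
#'   residues, acceptors ligand NAG residues) and `geometry` (data frame of
#'   sampled `dist`, `angle_dha`, `angle_hax` per site, with the donor and
#'   acceptor serials).
#' @export
make_random_hbond_frame <- function(n, seed = 1, dist_range = c(1.5, 3.5)) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  side <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side))) * 14
  grid <- grid[seq_len(n), , drop = FALSE]
  d <- stats::runif(n, dist_range[1], dist_range[2])
  a1 <- stats::runif(n, 0, 180)
  a2 <- stats::runif(n, 0, 180)
  rand_dirs <- function(m) {
    v <- matrix(stats::rnorm(3 * m), m, 3)
    v / sqrt(rowSums(v^2))
  }
  perp_to <- function(w) {
    v <- rand_dirs(nrow(w))
    v <- v - rowSums(v * w) * w
    v / sqrt(rowSums(v^2))
  }
  U <- rand_dirs(n)
  Dp <- grid
  Hp <- Dp + U
  W <- -U
  V <- perp_to(W)
  Ap <- Hp + d * (cos(a1 * DEG) * W + sin(a1 * DEG) * V)
  U2 <- (Hp - Ap) / d
  V2 <- perp_to(U2)
  Xp <- Ap + 1.4 * (cos(a2 * DEG) * U2 + sin(a2 * DEG) * V2)
  idx <- rep(seq_len(n), each = 4)
  frag <- list(
    atoms = data.frame(
      name = rep(c("N", "H", "O5", "C5"), n),
      resname = rep(c("ALA", "ALA", "NAG", "NAG"), n),
      element = rep(c("N", "H", "O", "C"), n),
      role = rep(c("receptor", "receptor", "ligand", "ligand"), n),
      reskey = paste0(rep(c("R", "R", "L", "L"), n), idx),
      stringsAsFactors = FALSE),
    xyz = NULL
  )
  ## interleave per site: D, H, A, X
  xyz <- matrix(NA_real_, 4 * n, 3)
  xyz[seq(1, 4 * n, 4), ] <- Dp
  xyz[seq(2, 4 * n, 4), ] <- Hp
  xyz[seq(3, 4 * n, 4), ] <- Ap
  xyz[seq(4, 4 * n, 4), ] <- Xp
  frag$xyz <- xyz
  system <- assemble_system(frag)
  a <- system$atoms
  geometry <- data.frame(
    site = seq_len(n), dist = d, angle_dha = a1, angle_hax = a2,
    donor_serial = a$serial[a$name == "N"],
    acceptor_serial = a$serial[a$name == "O5"]
  )
  list(system = system, geometry = geometry)
}

#' Single planted-event systems
#'
#' Thin wrappers assembling one motif into a one-frame system, parameterized
#' by the geometric quantity its detector thresholds on; used for boundary
#' scans (e.g. bisection on a water-bridge leg or an adjusted ionic
#' distance).
#'
#' @param dist hydrogen-acceptor distance (Å) of the planted hydrogen bond.
#' @return A one-frame `molsys`.
#' @export
plant_hbond_system <- function(dist = 2.2) {
  assemble_system(motif_hbond("S01", dist = dist))
}

#' @rdname plant_hbond_system
#' @param leg both water hydrogen-acceptor leg lengths (Å).
#' @export
plant_water_bridge_system <- function(leg = 2.8) {
  assemble_system(motif_water_bridge("S01", leg = leg))
}

#' @rdname plant_hbond_system
#' @param adjusted radii-subtracted lysine-carboxylate distance (Å).
#' @param config an [fp_config()] supplying the radii.
#' @export
plant_ionic_system <- function(adjusted = 0.75, config = fp_config()) {
  assemble_system(motif_ionic("S01", adjusted = adjusted, config = config))
}

#' @rdname plant_hbond_system
#' @param species cation residue name (CA, MG or NA).
#' @param adjusted_receptor adjusted distance of the ion-glutamate side (Å).
#' @export
plant_cation_bridge_system <- function(species = "CA", adjusted = 0.75,
                                       adjusted_receptor = adjusted,
                                       config = fp_config()) {
  assemble_system(motif_cation_bridge("S01", species = species,
                                      adjusted = adjusted,
                                      adjusted_receptor = adjusted_receptor,
                                      config = config))
}

#' @rdname plant_hbond_system
#' @export
plant_hydrophobic_system <- function(dist = 4.0) {
  assemble_system(motif_hydrophobic("S01", dist = dist))
}
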