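# Independent brute-force oracles: plain double/triple loops re-deriving
# every criterion from coordinates, sharing no code with the detectors.

oracle_ramp <- function(a, t1, t2) {
  if (a <= t1) return(0)
  if (a > t2) return(1)
  (a - t1) / (t2 - t1)
}

oracle_angle <- function(p, q, r) {
  u <- p - q
  v <- r - q
  cs <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(min(1, max(-1, cs))) * 180 / pi
}

oracle_dist <- function(p, q) sqrt(sum((p - q)^2))

oracle_hbonds <- function(system, groupA, groupB, frame = 1, thr = 6.25) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  res <- list()
  one_dir <- function(gd, ga) {
    for (d_i in gd) {
      if (!a$element[d_i] %in% c("N", "O")) next
      for (h_i in gd) {
        if (a$element[h_i] != "H" || a$resuid[h_i] != a$resuid[d_i]) next
        if (oracle_dist(xyz[h_i, ], xyz[d_i, ]) > 1.2) next
        for (acc in ga) {
          if (!a$element[acc] %in% c("N", "O")) next
          dha <- oracle_dist(xyz[h_i, ], xyz[acc, ])
          s1 <- oracle_ramp(oracle_angle(xyz[d_i, ], xyz[h_i, ], xyz[acc, ]),
                            75, 85)
          best <- 0
          found <- FALSE
          for (x_i in ga) {
            if (x_i == acc) next
            dx <- oracle_dist(xyz[x_i, ], xyz[acc, ])
            cut <- if (a$element[x_i] == "H") 1.2 else 1.8
            if (dx > cut) next
            found <- TRUE
            tt <- if (a$element[x_i] == "H") c(75, 85) else c(85, 95)
            best <- max(best, oracle_ramp(
              oracle_angle(xyz[h_i, ], xyz[acc, ], xyz[x_i, ]), tt[1], tt[2]))
          }
          s2 <- if (found) best else 1
          e <- max(0, 25 * (2.6 - max(dha, 2.1)) / 0.5) * s1 * s2
          if (e > thr)
            res[[length(res) + 1L]] <<- data.frame(
              donor = a$serial[d_i], acceptor = a$serial[acc], energy = e)
        }
      }
    }
  }
  one_dir(groupA, groupB)
  one_dir(groupB, groupA)
  if (length(res) == 0L)
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric()))
  out <- do.call(rbind, res)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

oracle_water_bridges <- function(system, frame = 1, thr = 3.0) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  racc <- which(a$role == "receptor" & a$element %in% c("N", "O"))
  lacc <- which(a$role == "ligand" & a$element %in% c("N", "O"))
  n <- 0
  for (uid in unique(a$resuid[a$role == "water"])) {
    hs <- which(a$resuid == uid & a$element == "H")
    for (i in racc) {
      for (j in lacc) {
        ok <- (oracle_dist(xyz[hs[1], ], xyz[i, ]) <= thr &&
                 oracle_dist(xyz[hs[2], ], xyz[j, ]) <= thr) ||
          (oracle_dist(xyz[hs[2], ], xyz[i, ]) <= thr &&
             oracle_dist(xyz[hs[1], ], xyz[j, ]) <= thr)
        if (ok) n <- n + 1
      }
    }
  }
  n
}

# Independent centre enumeration + adjusted-distance rule. Returns rows of
# (pairing, raw, adjusted).
oracle_ionic <- function(system, frame = 1, config = fp_config()) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  radius <- function(el) {
    key <- el
    key[key == "NA"] <- "NA."
    unname(config$hbond_radii[key])
  }
  centers <- list()
  for (uid in unique(a$resuid)) {
    sel <- which(a$resuid == uid)
    rn <- a$resname[sel[1]]
    role <- a$role[sel[1]]
    at <- function(nm) xyz[sel[match(nm, a$name[sel])], ]
    cen <- switch(rn,
      LYS = list(p = at("NZ"), q = 1, el = "N"),
      ARG = list(p = at("CZ"), q = 1, el = "C"),
      ASP = list(p = (at("OD1") + at("OD2")) / 2, q = -1, el = "O"),
      GLU = list(p = (at("OE1") + at("OE2")) / 2, q = -1, el = "O"),
      GCU = list(p = (at("O6A") + at("O6B")) / 2, q = -1, el = "O"),
      CA = if (role == "ion") list(p = xyz[sel, ], q = 2, el = "CA"),
      MG = if (role == "ion") list(p = xyz[sel, ], q = 2, el = "MG"),
      "NA" = if (role == "ion") list(p = xyz[sel, ], q = 1, el = "NA"),
      CL = if (role == "ion") list(p = xyz[sel, ], q = -1, el = "CL"),
      NULL)
    if (!is.null(cen)) {
      cen$role <- role
      centers[[length(centers) + 1L]] <- cen
    }
  }
  rows <- list()
  for (i in seq_along(centers)) {
    for (j in seq_along(centers)) {
      ci <- centers[[i]]; cj <- centers[[j]]
      if (!(ci$q > 0 && cj$q < 0)) next
      pairing <- paste(sort(c(ci$role, cj$role)), collapse = "-")
      if (!pairing %in% c("ligand-receptor", "ion-receptor", "ion-ligand"))
        next
      raw <- oracle_dist(ci$p, cj$p)
      adj <- raw - radius(ci$el) - radius(cj$el)
      if (adj >= config$ionic_range[1] && adj <= config$ionic_range[2])
        rows[[length(rows) + 1L]] <- data.frame(pairing = pairing, raw = raw,
                                                adjusted = adj)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(pairing = character(), raw = numeric(),
                      adjusted = numeric()))
  do.call(rbind, rows)
}

oracle_hydrophobic <- function(system, frame = 1, cutoff = 4.5) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  n <- 0
  rc <- which(a$role == "receptor" & a$element == "C")
  lc <- which(a$role == "ligand" & a$element == "C")
  for (i in rc) {
    ci <- classify_hydrophobic_carbons(a$resname[i], a$name[i])
    if (ci == "none") next
    for (j in lc) {
      cj <- classify_hydrophobic_carbons(a$resname[j], a$name[j])
      if (cj == "none") next
      if (oracle_dist(xyz[i, ], xyz[j, ]) <= cutoff) n <- n + 1
    }
  }
  n
}

# Build a bare system from explicit atom rows; used for exact-geometry cases.
tiny_system <- function(names, resnames, elements, roles, resnos, xyz,
                        chain = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(
    serial = seq_along(names), name = names, resname = resnames,
    chain = chain %||% ifelse(roles == "receptor", "A",
                              ifelse(roles == "ligand", "B", "W")),
    resno = resnos, element = elements, role = roles,
    stringsAsFactors = FALSE)
  mdfinger:::molecular_system(atoms, array(xyz, c(nrow(xyz), 3, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Counts recovered by all detectors, in ground-truth order.
detected_counts <- function(system, config = fp_config()) {
  cc <- detect_all_contacts(system, 1, config)
  c(hbond = nrow(cc$hbonds),
    water_bridge = nrow(cc$water_bridges),
    ionic = sum(cc$ionic$pairing == "ligand-receptor"),
    cation_bridge = nrow(cc$cation_bridges),
    hydrophobic = nrow(cc$hydrophobic))
}

# Bisection for the largest parameter value at which `hit(value)` is TRUE,
# given hit(lo) TRUE and hit(hi) FALSE.
bisect_boundary <- function(hit, lo, hi, tol = 1e-6) {
  stopifnot(hit(lo), !hit(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (hit(mid)) lo <- mid else hi <- mid
  }
  lo
}
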