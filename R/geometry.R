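# Ideal-geometry structure generators: alpha helix, antiparallel beta
# sheets, a parallel two-helix (coiled-coil-like) dimer, and a
# protein-DNA complex with a planted arginine-phosphate salt bridge.
# Backbones are built from ideal internal coordinates (N-CA 1.46,
# CA-C 1.52, C-N 1.33 A) by natural-extension-of-reference-frame
# chain growth.

BOND_N_CA <- 1.46
BOND_CA_C <- 1.52
BOND_C_N <- 1.33
BOND_C_O <- 1.23
ANGLE_N_CA_C <- 111
ANGLE_CA_C_N <- 117
ANGLE_C_N_CA <- 121
ANGLE_CA_C_O <- 121

#' Specification for an ideal-geometry structure fixture
#'
#' @param kind One of `"ideal_helix"`, `"beta_sheet"`,
#'   `"coiled_coil_dimer"`, `"protein_dna_complex"`.
#' @param n_residues Residues per chain/strand (minimum 6).
#' @param n_strands Strands for `beta_sheet` (2 or 3).
#' @param sequence Optional one-letter sequence recycled per chain.
#' @param strand_spacing Target inter-strand spacing (A) for sheets.
#' @param helix_separation Axis separation (A) for the dimer.
#' @param arg_phosphate_distance Planted Arg NH1 - phosphate OP1
#'   distance (A) for the protein-DNA complex.
#' @return A `geometry_spec` list.
#' @export
geometry_spec <- function(kind = c("ideal_helix", "beta_sheet",
                                   "coiled_coil_dimer",
                                   "protein_dna_complex"),
                          n_residues = 14L, n_strands = 2L,
                          sequence = NULL, strand_spacing = 4.8,
                          helix_separation = 9.8,
                          arg_phosphate_distance = 3.2,
                          tail_residues = 0L, connect = FALSE) {
  kind <- match.arg(kind)
  if (n_residues < 6L) stop("n_residues must be at least 6")
  structure(list(kind = kind, n_residues = as.integer(n_residues),
                 n_strands = as.integer(n_strands), sequence = sequence,
                 strand_spacing = strand_spacing,
                 helix_separation = helix_separation,
                 arg_phosphate_distance = arg_phosphate_distance,
                 tail_residues = as.integer(tail_residues),
                 connect = isTRUE(connect)),
            class = "geometry_spec")
}

# Place a new atom from three reference atoms plus internal
# coordinates (bond length, bond angle b-c-new in degrees, dihedral
# a-b-c-new in degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Build one chain backbone from phi/psi torsions. Returns a data frame
# of atoms (resno, resid, elety, x, y, z). Sequence is one-letter.
build_backbone <- function(sequence, phi, psi, omega = 180) {
  n <- nchar(sequence)
  aa1 <- strsplit(sequence, "")[[1]]
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  coords <- list()
  # seed residue frame
  Npos <- c(0, 0, 0)
  CApos <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  Cpos <- CApos + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- Npos; CA[1, ] <- CApos; C[1, ] <- Cpos
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND_N_CA, ANGLE_C_N_CA, omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    # carbonyl O in the peptide plane, trans to the next N
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, psi[i] + 180)
  }
  atoms <- list()
  three <- stats::setNames(names(AA_PDB_TO_ONE)[match(aa1, AA_PDB_TO_ONE)],
                           NULL)
  three[is.na(three)] <- "ALA"
  for (i in seq_len(n)) {
    res <- three[i]
    add <- function(name, xyz) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        resno = i, resid = res, elety = name,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    add("N", N[i, ]); add("CA", CA[i, ]); add("C", C[i, ]); add("O", O[i, ])
    if (res != "GLY") {
      cb <- nerf_place(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, -122.6)
      add("CB", cb)
      if (res == "LEU") {
        cg <- nerf_place(N[i, ], CA[i, ], cb, 1.53, 116, 180)
        add("CG", cg)
        add("CD1", nerf_place(CA[i, ], cb, cg, 1.52, 110, 60))
        add("CD2", nerf_place(CA[i, ], cb, cg, 1.52, 110, -60))
      } else if (res == "ARG") {
        cg <- nerf_place(N[i, ], CA[i, ], cb, 1.52, 114, 180)
        cd <- nerf_place(CA[i, ], cb, cg, 1.52, 111, 180)
        ne <- nerf_place(cb, cg, cd, 1.46, 112, 180)
        cz <- nerf_place(cg, cd, ne, 1.33, 124, 180)
        add("CG", cg); add("CD", cd); add("NE", ne); add("CZ", cz)
        add("NH1", nerf_place(cd, ne, cz, 1.33, 120, 0))
        add("NH2", nerf_place(cd, ne, cz, 1.33, 120, 180))
      } else if (res == "GLU") {
        cg <- nerf_place(N[i, ], CA[i, ], cb, 1.52, 114, 180)
        cd <- nerf_place(CA[i, ], cb, cg, 1.52, 113, 180)
        add("CG", cg); add("CD", cd)
        add("OE1", nerf_place(cb, cg, cd, 1.25, 118, 0))
        add("OE2", nerf_place(cb, cg, cd, 1.25, 118, 180))
      }
    }
  }
  do.call(rbind, atoms)
}

atoms_xyz <- function(at) as.matrix(at[, c("x", "y", "z")])

transform_atoms <- function(at, R = diag(3), t = c(0, 0, 0)) {
  xyz <- atoms_xyz(at) %*% t(R)
  at$x <- xyz[, 1] + t[1]; at$y <- xyz[, 2] + t[2]
  at$z <- xyz[, 3] + t[3]
  at
}

rot_about <- function(axis, theta_deg) {
  th <- theta_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * tcrossprod(u)
}

# Principal axis of a point cloud (unit vector, oriented from first to
# last point).
principal_axis <- function(xyz) {
  cen <- colMeans(xyz)
  v <- svd(sweep(xyz, 2L, cen))$v[, 1L]
  if (sum((xyz[nrow(xyz), ] - xyz[1L, ]) * v) < 0) v <- -v
  v
}

# Count Kabsch-Sander hydrogen bonds between two chains of a combined
# atom table (used to tune rigid placements deterministically).
count_cross_hbonds <- function(model) {
  bb <- backbone_table(model)
  hb <- ks_hbond_matrix(bb)
  ch <- bb$keys$chain
  cross <- outer(ch, ch, "!=")
  sum(hb & cross)
}

atoms_to_model <- function(chains) {
  # chains: named list of atom tables
  at <- do.call(rbind, lapply(names(chains), function(cn) {
    d <- chains[[cn]]
    data.frame(chain = cn, resno = d$resno, insert = "",
               resid = d$resid, elety = d$elety,
               elesy = substr(d$elety, 1L, 1L),
               x = d$x, y = d$y, z = d$z, stringsAsFactors = FALSE)
  }))
  cls <- vapply(chains, function(d) {
    if (mean(d$resid %in% names(AA_PDB_TO_ONE)) >= 0.5) "protein"
    else if (mean(d$resid %in% NUCLEIC_RESIDUES) >= 0.5) "nucleic"
    else "other"
  }, "")
  structure(list(atoms = at,
                 chains = data.frame(chain = names(chains), class = cls,
                                     stringsAsFactors = FALSE)),
            class = "structure_model")
}

#' Build an ideal-geometry structure as PDB text
#'
#' Deterministic constructions used as fixtures for every structural
#' operation: an ideal alpha helix (i -> i+4 carbonyl-amide distances
#' in the hydrogen-bonding range), antiparallel beta sheets of 2 or 3
#' strands (separate chains; strand placement is refined by maximizing
#' backbone hydrogen-bond counts over a deterministic grid), a parallel
#' two-helix dimer with leucine side chains packing the interface, and
#' a protein-DNA complex in which exactly one arginine NH1 sits at the
#' planted distance from a backbone phosphate OP1.
#'
#' @param spec A [geometry_spec()].
#' @return Character scalar: PDB-format text.
#' @export
build_geometry <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  model <- switch(spec$kind,
                  ideal_helix = geom_helix(spec),
                  beta_sheet = geom_sheet(spec),
                  coiled_coil_dimer = geom_dimer(spec),
                  protein_dna_complex = geom_protein_dna(spec),
                  stop("unknown geometry kind: ", spec$kind))
  write_pdb_text(model)
}

default_seq <- function(n) {
  paste(rep(c("A", "S", "L", "E", "G", "T", "V"), length.out = n),
        collapse = "")
}

geom_helix <- function(spec) {
  seqc <- spec$sequence %||% default_seq(spec$n_residues)
  at <- build_backbone(seqc, phi = -57, psi = -47)
  atoms_to_model(list(A = at))
}

geom_sheet <- function(spec) {
  n <- spec$n_residues
  # optional coil tail on the first strand: extra residues beyond the
  # paired region, used to exercise loop-adjacent-to-strand contexts
  nA <- n + (spec$tail_residues %||% 0L)
  seqA <- spec$sequence %||% paste(rep(c("V", "T"), length.out = nA),
                                   collapse = "")
  seqc <- substr(seqA, 1L, n)
  strandA <- build_backbone(seqA, phi = -139, psi = 135)
  strand <- build_backbone(seqc, phi = -139, psi = 135)
  axis <- principal_axis(atoms_xyz(strand[strand$elety == "CA", ]))
  cen <- colMeans(atoms_xyz(strand))
  # orthogonal frame: strand axis, sheet normal candidate, lateral
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  lat <- pracma_cross(axis, ref); lat <- lat / sqrt(sum(lat^2))
  nrm <- pracma_cross(axis, lat)

  place_next <- function(prev) {
    # antiparallel partner: rotate 180 deg about an axis perpendicular
    # to the strand (reversing the chain direction), then scan lateral
    # offset and register shift for the most cross-strand H-bonds
    pcen <- colMeans(atoms_xyz(prev))
    centred <- transform_atoms(prev, diag(3), -pcen)
    best <- NULL
    for (flip in list(lat, nrm)) {
      base <- transform_atoms(centred, rot_about(flip, 180), c(0, 0, 0))
      for (sep in seq(4.0, 5.6, by = 0.2)) {
        for (sh in seq(-3.4, 3.4, by = 0.2)) {
          cand <- transform_atoms(base, diag(3),
                                  pcen + sep * lat + sh * axis)
          m <- atoms_to_model(list(A = prev, B = cand))
          nh <- count_cross_hbonds(m)
          if (is.null(best) || nh > best$nh) {
            best <- list(nh = nh, sep = sep, sh = sh, base = base)
          }
        }
      }
    }
    # refine on a finer grid around the winner
    for (sep in seq(best$sep - 0.2, best$sep + 0.2, by = 0.05)) {
      for (sh in seq(best$sh - 0.2, best$sh + 0.2, by = 0.05)) {
        cand <- transform_atoms(best$base, diag(3),
                                pcen + sep * lat + sh * axis)
        m <- atoms_to_model(list(A = prev, B = cand))
        nh <- count_cross_hbonds(m)
        if (nh > best$nh) {
          best <- list(nh = nh, sep = sep, sh = sh, base = best$base)
        }
      }
    }
    transform_atoms(best$base, diag(3),
                    pcen + best$sep * lat + best$sh * axis)
  }
  chains <- list(A = strandA)
  for (k in seq_len(spec$n_strands - 1L)) {
    chains[[LETTERS[k + 1L]]] <- place_next(
      if (k == 1L) strand else chains[[k]])
  }
  if (!spec$connect) return(atoms_to_model(chains))
  # single-chain meander: join consecutive strands with 2-residue
  # glycine loops (monomeric sheet, as in a crystallin Greek key)
  up <- nrm / sqrt(sum(nrm^2))
  merged <- chains[[1L]]
  for (k in seq_len(length(chains) - 1L)) {
    nxt <- chains[[k + 1L]]
    prev_end <- merged[merged$resno == max(merged$resno), ]
    p0 <- as.numeric(prev_end[prev_end$elety == "C", c("x", "y", "z")])
    p3 <- as.numeric(nxt[nxt$resno == 1L & nxt$elety == "N",
                         c("x", "y", "z")])
    u <- (p3 - p0); u <- u / sqrt(sum(u^2))
    base_no <- max(merged$resno)
    loops <- list()
    for (g in 1:2) {
      tfrac <- g / 3
      ca <- p0 + tfrac * (p3 - p0) + 1.8 * sin(pi * tfrac) * up
      add <- function(name, xyz) {
        loops[[length(loops) + 1L]] <<- data.frame(
          resno = base_no + g, resid = "GLY", elety = name,
          x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
      }
      add("N", ca - 1.2 * u)
      add("CA", ca)
      add("C", ca + 1.2 * u)
      add("O", ca + 1.2 * u + 1.23 * up)
    }
    nxt$resno <- nxt$resno + base_no + 2L
    merged <- rbind(merged, do.call(rbind, loops), nxt)
  }
  atoms_to_model(list(A = merged))
}

geom_dimer <- function(spec) {
  n <- spec$n_residues
  seqc <- spec$sequence %||% {
    # heptad-like pattern with leucine at interface positions a and d
    paste(vapply(seq_len(n) - 1L, function(i) {
      p <- i %% 7L
      if (p == 0L || p == 3L) "L" else c("A", "E", "A", "A", "Q", "A",
                                         "K")[p]
    }, ""), collapse = "")
  }
  helA <- build_backbone(seqc, phi = -57, psi = -47)
  axis <- principal_axis(atoms_xyz(helA[helA$elety == "CA", ]))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  lat <- pracma_cross(axis, ref); lat <- lat / sqrt(sum(lat^2))
  cenA <- colMeans(atoms_xyz(helA))
  # rotate the copy about its own axis to pack leucines face to face
  best <- NULL
  for (rot in seq(0, 350, by = 10)) {
    cand <- transform_atoms(helA, diag(3), -cenA)
    cand <- transform_atoms(cand, rot_about(axis, rot), c(0, 0, 0))
    cand <- transform_atoms(cand, diag(3),
                            cenA + spec$helix_separation * lat)
    da <- helA[helA$resid == "LEU", ]
    db <- cand[cand$resid == "LEU", ]
    d <- sqrt(outer(rowSums(atoms_xyz(da)^2), rowSums(atoms_xyz(db)^2),
                    "+") - 2 * tcrossprod(atoms_xyz(da), atoms_xyz(db)))
    ncontact <- sum(d <= 4.5)
    mind <- min(d)
    score <- ncontact - as.numeric(mind < 2.8) * 100
    if (is.null(best) || score > best$score) {
      best <- list(score = score, rot = rot, cand = cand)
    }
  }
  atoms_to_model(list(A = helA, B = best$cand))
}

geom_protein_dna <- function(spec) {
  n <- spec$n_residues
  seqc <- spec$sequence %||% {
    s <- strsplit(default_seq(n), "")[[1]]
    s[ceiling(n / 2)] <- "R"
    paste(s, collapse = "")
  }
  # polyproline-II-like extended loop: no backbone hydrogen bonds
  prot <- build_backbone(seqc, phi = -75, psi = 145)
  argno <- which(strsplit(seqc, "")[[1]] == "R")[1L]
  nh1 <- prot[prot$resno == argno & prot$elety == "NH1", ]
  cz <- prot[prot$resno == argno & prot$elety == "CZ", ]
  dirv <- c(nh1$x - cz$x, nh1$y - cz$y, nh1$z - cz$z)
  dirv <- dirv / sqrt(sum(dirv^2))
  anchor <- c(nh1$x, nh1$y, nh1$z) + spec$arg_phosphate_distance * dirv

  dna <- build_dna_strand(4L)
  # move nucleotide 2's OP1 onto the anchor, DNA axis along dirv's
  # orthogonal so the strand points away from the protein
  op1 <- as.numeric(dna[dna$resno == 2L & dna$elety == "OP1",
                        c("x", "y", "z")])
  dna_axis <- principal_axis(atoms_xyz(dna[dna$elety == "P", ]))
  tgt_axis <- pracma_cross(dirv, c(0, 0, 1))
  if (sqrt(sum(tgt_axis^2)) < 1e-6) tgt_axis <- pracma_cross(dirv, c(0, 1, 0))
  tgt_axis <- tgt_axis / sqrt(sum(tgt_axis^2))
  R <- rotation_between(dna_axis, tgt_axis)
  dna <- transform_atoms(dna, R, c(0, 0, 0))
  op1 <- as.numeric(R %*% op1)
  dna <- transform_atoms(dna, diag(3), anchor - op1)
  atoms_to_model(list(A = prot, B = dna))
}

rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  w <- pracma_cross(u, v)
  s <- sqrt(sum(w^2)); c0 <- sum(u * v)
  if (s < 1e-9) return(if (c0 > 0) diag(3) else rot_about(
    if (abs(u[1]) < 0.9) pracma_cross(u, c(1, 0, 0)) else
      pracma_cross(u, c(0, 1, 0)), 180))
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + wx + wx %*% wx * ((1 - c0) / s^2)
}

# Minimal single-stranded DNA: phosphate group plus a sugar-carbon
# trace, enough for parsing, occlusion and phosphate contacts.
build_dna_strand <- function(n_nt) {
  bases <- rep(c("DA", "DT"), length.out = n_nt)
  atoms <- list()
  for (i in seq_len(n_nt)) {
    z <- (i - 1L) * 6.5
    add <- function(name, xyz) {
      atoms[[length(atoms) + 1L]] <<- data.frame(
        resno = i, resid = bases[i], elety = name,
        x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
    }
    add("P", c(0, 0, z))
    add("OP1", c(1.35, 0.6, z + 0.4))
    add("OP2", c(-1.35, 0.6, z + 0.4))
    add("O5'", c(0, -1.2, z + 0.9))
    add("C5'", c(0.8, -2.2, z + 1.4))
    add("C4'", c(0.4, -3.5, z + 2.0))
    add("C3'", c(-0.9, -3.9, z + 2.6))
    add("O3'", c(-0.9, -4.2, z + 4.0))
    add("C1'", c(1.4, -4.5, z + 2.2))
    add("N1", c(2.7, -4.2, z + 2.6))
  }
  do.call(rbind, atoms)
}

#' Serialize a structure model to PDB text
#'
#' Fixed-width PDB v3.3 ATOM records with TER between chains;
#' coordinates to 3 decimals.
#'
#' @param model A `structure_model`.
#' @return Character scalar of PDB text.
#' @export
write_pdb_text <- function(model) {
  at <- model$atoms
  lines <- character(0)
  serial <- 0L
  for (cn in unique(at$chain)) {
    d <- at[at$chain == cn, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      serial <- serial + 1L
      name <- d$elety[i]
      namef <- if (nchar(name) >= 4L) substr(name, 1L, 4L) else
        sprintf(" %-3s", name)
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namef, d$resid[i], cn, d$resno[i],
        d$x[i], d$y[i], d$z[i], 1.00, 0.00, d$elesy[i]))
    }
    serial <- serial + 1L
    lines <- c(lines,
               sprintf("TER   %5d      %-3s %1s%4d", serial,
                       d$resid[nrow(d)], cn, d$resno[nrow(d)]))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}
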