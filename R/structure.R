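# Structural annotation: PDB parsing into a light-weight model,
# secondary-structure assignment from backbone hydrogen-bond patterns,
# solvent accessibility by numerical sphere integration, sheet
# topology, and inter-chain contact / salt-bridge geometry.

#' Geometric thresholds for structural annotation
#'
#' All cutoffs used by the structural rules, exposed as named
#' constants: the backbone hydrogen-bond energy cutoff, the salt-bridge
#' and generic interface heavy-atom distance cutoffs, the relative
#' accessibility above which a residue counts as surface, the sequence
#' separation from the nearest helix/strand element for a loop to count
#' as remote, and the helix register shift regarded as disruptive.
#'
#' @param hbond_energy_cutoff Kabsch-Sander energy (kcal/mol) below
#'   which an N-H...O=C pair is a hydrogen bond.
#' @param salt_bridge_cutoff Maximum donor-acceptor distance (A) for a
#'   salt bridge.
#' @param interface_cutoff Maximum heavy-atom distance (A) for an
#'   inter-chain interface contact.
#' @param surface_rsa Relative accessibility at or above which a
#'   residue is surface.
#' @param loop_element_distance Minimum sequence distance (residues)
#'   from any helix/strand element for a loop to count as remote.
#' @param register_shift_cutoff Helix register shift (degrees) at or
#'   above which the shift is disruptive.
#' @param probe_radius Solvent probe radius (A).
#' @param n_sphere_points Sphere quadrature points per atom.
#' @return A `structure_thresholds` list.
#' @export
structure_thresholds <- function(hbond_energy_cutoff = -0.5,
                                 salt_bridge_cutoff = 4.0,
                                 interface_cutoff = 4.5,
                                 surface_rsa = 0.25,
                                 loop_element_distance = 3L,
                                 register_shift_cutoff = 60,
                                 probe_radius = 1.4,
                                 n_sphere_points = 960L) {
  structure(as.list(environment()), class = "structure_thresholds")
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records into a flat atom table with chains
#' classified as protein, nucleic or other by residue names. Waters are
#' dropped; alternate locations are resolved to a single conformer
#' (highest occupancy, ties to altLoc `A`).
#'
#' @param pdb Path to a PDB file, or a character vector/string of PDB
#'   text.
#' @return A `structure_model`: list with `atoms` (data frame `chain`,
#'   `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`) and
#'   `chains` (data frame `chain`, `class`).
#' @export
parse_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb, fixed = TRUE) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL)", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb) > 1L) pdb else
      strsplit(pdb, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  }
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM records in PDB input")
  bad <- which(rec &
                 is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))))
  if (length(bad)) {
    stop(sprintf("malformed coordinate field at line %d", bad[1L]))
  }
  pdb_obj <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb_obj$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(at) == 0L) stop("no non-water atoms in PDB input")
  # drop hydrogens; annotation operates on heavy atoms
  elesy <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                  substr(trimws(at$elety), 1L, 1L), trimws(at$elesy))
  at$elesy <- toupper(elesy)
  at <- at[at$elesy != "H" & at$elesy != "D", , drop = FALSE]
  # altLoc: keep highest occupancy, ties towards 'A'/first
  alt <- ifelse(is.na(at$alt) | !nzchar(at$alt), "", at$alt)
  if (any(nzchar(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      ix <- ix[order(-occ[ix], alt[ix])]
      ix[1L]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = at$insert, resid = at$resid,
                      elety = trimws(at$elety), elesy = at$elesy,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  chains <- do.call(rbind, lapply(split(atoms, atoms$chain), function(d) {
    res <- unique(d$resid)
    n_prot <- sum(unique(paste(d$resno, d$resid)) %in%
                    paste(d$resno, d$resid)[d$resid %in% names(AA_PDB_TO_ONE)])
    cls <- if (mean(d$resid %in% names(AA_PDB_TO_ONE)) >= 0.5) "protein"
    else if (mean(d$resid %in% NUCLEIC_RESIDUES) >= 0.5) "nucleic"
    else "other"
    data.frame(chain = d$chain[1L], class = cls, stringsAsFactors = FALSE)
  }))
  rownames(chains) <- NULL
  structure(list(atoms = atoms, chains = chains),
            class = "structure_model")
}

#' Read a structure from a PDB file
#' @param path PDB file path.
#' @return A `structure_model`; see [parse_structure()].
#' @export
read_structure <- function(path) parse_structure(path)

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, chains: %s\n",
              nrow(x$atoms),
              paste(sprintf("%s(%s)", x$chains$chain, x$chains$class),
                    collapse = ", ")))
  invisible(x)
}

# Ordered residue table for one protein chain: resno, resid, one-letter.
chain_residues <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no such chain: ", chain)
  key <- !duplicated(paste(a$resno, a$insert))
  d <- a[key, c("resno", "insert", "resid")]
  d <- d[order(d$resno, d$insert), ]
  d$one <- unname(AA_PDB_TO_ONE[d$resid])
  d$one[is.na(d$one)] <- "X"
  rownames(d) <- NULL
  d
}

# Residue-level backbone coordinate table across protein chains.
backbone_table <- function(s) {
  prot <- s$chains$chain[s$chains$class == "protein"]
  a <- s$atoms[s$atoms$chain %in% prot, , drop = FALSE]
  keys <- unique(a[, c("chain", "resno", "insert", "resid")])
  keys <- keys[order(keys$chain, keys$resno, keys$insert), ]
  rownames(keys) <- NULL
  get_xyz <- function(name) {
    m <- matrix(NA_real_, nrow(keys), 3L)
    sel <- a[a$elety == name, , drop = FALSE]
    idx <- match(paste(keys$chain, keys$resno, keys$insert),
                 paste(sel$chain, sel$resno, sel$insert))
    ok <- !is.na(idx)
    m[ok, ] <- as.matrix(sel[idx[ok], c("x", "y", "z")])
    m
  }
  list(keys = keys, N = get_xyz("N"), CA = get_xyz("CA"),
       C = get_xyz("C"), O = get_xyz("O"))
}

# Kabsch-Sander hydrogen-bond matrix: hb[i, j] is TRUE when the C=O of
# residue i accepts a hydrogen bond from the N-H of residue j.
ks_hbond_matrix <- function(bb, cutoff = -0.5) {
  n <- nrow(bb$keys)
  ch <- bb$keys$chain
  # impute amide H: 1.0 A from N opposite the preceding carbonyl
  H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)[-1]) {
    if (ch[i] != ch[i - 1L]) next
    if (anyNA(bb$C[i - 1L, ]) || anyNA(bb$O[i - 1L, ]) ||
        anyNA(bb$N[i, ])) next
    d <- bb$C[i - 1L, ] - bb$O[i - 1L, ]
    H[i, ] <- bb$N[i, ] + d / sqrt(sum(d^2))
  }
  H[bb$keys$resid == "PRO", ] <- NA_real_  # proline cannot donate
  dmat <- function(A, B) {
    sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
  }
  safe <- function(M) { M[is.na(M)] <- Inf; M }
  rON <- safe(dmat(bb$O, bb$N))
  rCH <- safe(dmat(bb$C, H))
  rOH <- safe(dmat(bb$O, H))
  rCN <- safe(dmat(bb$C, bb$N))
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[!is.finite(E)] <- 0
  E[, is.na(H[, 1L])] <- 0  # residues without a donatable N-H
  diag(E) <- 0
  # exclude chain-adjacent donors (covalently constrained geometry)
  for (i in seq_len(n - 1L)) {
    if (ch[i] == ch[i + 1L]) { E[i, i + 1L] <- 0; E[i + 1L, i] <- 0 }
  }
  E < cutoff
}

#' Assign secondary structure from backbone geometry
#'
#' Hydrogen bonds are identified by the Kabsch-Sander electrostatic
#' energy `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol
#' with a bond when `E < -0.5`; amide hydrogens are imputed 1.0 A from
#' N opposite the preceding carbonyl. Helix (`H`) requires two
#' consecutive i -> i+4 turns; strand (`E`) comes from parallel or
#' antiparallel bridge patterns (minimum sequence separation 3, chains
#' may differ); everything else is coil (`C`). Residues with missing
#' backbone atoms are annotated `C` with a warning flag.
#'
#' @param s A `structure_model`.
#' @param th A [structure_thresholds()].
#' @return Data frame per protein residue: `chain`, `resno`, `insert`,
#'   `resid`, `ss` (one of `H`, `E`, `C`), `incomplete_backbone`, and
#'   `bridge_partners` (list column of partner residue row indices).
#' @export
assign_secondary_structure <- function(s, th = structure_thresholds()) {
  bb <- backbone_table(s)
  n <- nrow(bb$keys)
  miss <- apply(cbind(bb$N, bb$CA, bb$C, bb$O), 1L, anyNA)
  hb <- ks_hbond_matrix(bb, th$hbond_energy_cutoff)
  ch <- bb$keys$chain
  same_chain_step <- function(i, k) {
    j <- i + k
    j >= 1L & j <= n & ch[pmin(pmax(j, 1L), n)] == ch[i]
  }
  hbs <- function(i, j) {
    ok <- i >= 1L & i <= n & j >= 1L & j <= n
    out <- logical(length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  idx <- seq_len(n)
  # n-turns: CO(i) <- NH(i+4) within one chain
  turn4 <- hbs(idx, idx + 4L) & same_chain_step(idx, 4L)
  ss <- rep("C", n)
  for (i in idx) {
    if (i >= 2L && turn4[i - 1L] && turn4[i] &&
        same_chain_step(i - 1L, 4L)) {
      ss[i:min(i + 3L, n)] <- "H"
    }
  }
  # bridges
  partners <- vector("list", n)
  for (i in idx) {
    for (j in idx) {
      if (j <= i) next
      if (ch[i] == ch[j] && abs(i - j) < 3L) next
      par <- (hbs(i - 1L, j) && hbs(j, i + 1L) &&
                same_chain_step(i, -1L) && same_chain_step(i, 1L)) ||
        (hbs(j - 1L, i) && hbs(i, j + 1L) &&
           same_chain_step(j, -1L) && same_chain_step(j, 1L))
      anti <- (hbs(i, j) && hbs(j, i)) ||
        (hbs(i - 1L, j + 1L) && hbs(j - 1L, i + 1L) &&
           same_chain_step(i, -1L) && same_chain_step(i, 1L) &&
           same_chain_step(j, -1L) && same_chain_step(j, 1L))
      if (par || anti) {
        partners[[i]] <- c(partners[[i]], j)
        partners[[j]] <- c(partners[[j]], i)
      }
    }
  }
  bridged <- vapply(partners, function(p) length(p) > 0L, logical(1L))
  ss[bridged & ss != "H"] <- "E"
  ss[miss] <- "C"
  out <- bb$keys
  out$ss <- ss
  out$incomplete_backbone <- miss
  out$bridge_partners <- partners
  rownames(out) <- NULL
  out
}

# Deterministic golden-spiral quadrature points on the unit sphere.
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area and relative accessibility
#'
#' Shrake-Rupley numerical integration: each heavy atom's solvent
#' sphere (van der Waals radius + probe) is sampled at `n_sphere_points`
#' quadrature points and the exposed fraction retained. Residue ASA is
#' the sum over its atoms; relative accessibility divides by the
#' theoretical maximum per residue type and is clipped to `[0, 1]`.
#' All chains, including nucleic ones, occlude.
#'
#' @param s A `structure_model`.
#' @param th A [structure_thresholds()].
#' @return List with `atom_sasa` (numeric per atom row of `s$atoms`)
#'   and `residues`: data frame `chain`, `resno`, `insert`, `resid`,
#'   `asa`, `rsa`, `is_surface`.
#' @export
compute_rsa <- function(s, th = structure_thresholds()) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- VDW_RADII[a$elesy]
  rad[is.na(rad)] <- VDW_DEFAULT
  pr <- th$probe_radius
  pts <- sphere_points(th$n_sphere_points)
  n <- nrow(a)
  sasa <- numeric(n)
  ext <- rad + pr
  for (i in seq_len(n)) {
    ri <- ext[i]
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (ri + ext)^2 & seq_len(n) != i)
    p <- sweep(pts * ri, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(exposed)) break
      dj <- rowSums(sweep(p[exposed, , drop = FALSE], 2L, xyz[j, ])^2)
      exposed[exposed] <- dj >= ext[j]^2
    }
    sasa[i] <- 4 * pi * ri^2 * mean(exposed)
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  res <- a[first, c("chain", "resno", "insert", "resid")]
  res$asa <- as.numeric(tapply(sasa, factor(key, levels = key[first]), sum))
  res$rsa <- pmin(1, pmax(0, res$asa / MAX_ASA[res$resid]))
  res$is_surface <- !is.na(res$rsa) & res$rsa >= th$surface_rsa
  rownames(res) <- NULL
  list(atom_sasa = sasa, residues = res)
}

#' Classify a strand residue as edge or central
#'
#' Strands are maximal runs of `E` residues within a chain; a strand is
#' central when its residues have bridge partners in at least two
#' distinct neighbouring strands (one on each side of the sheet), edge
#' when only one, and residues outside sheets are `not_in_sheet`.
#'
#' @param ss Data frame from [assign_secondary_structure()].
#' @param chain,resno Residue to classify.
#' @return `"edge"`, `"central"` or `"not_in_sheet"`.
#' @export
classify_strand_position <- function(ss, chain, resno) {
  strands <- strand_segments(ss)
  row <- which(ss$chain == chain & ss$resno == resno)
  if (length(row) != 1L || ss$ss[row] != "E") return("not_in_sheet")
  sid <- strands$id[row]
  members <- which(strands$id == sid)
  partner_rows <- unique(unlist(ss$bridge_partners[members]))
  partner_strands <- setdiff(unique(strands$id[partner_rows]),
                             c(sid, NA))
  if (length(partner_strands) >= 2L) "central"
  else if (length(partner_strands) == 1L) "edge"
  else "edge"  # isolated bridge: bonded on one side only
}

# Label every residue with a strand segment id (NA outside strands).
strand_segments <- function(ss) {
  id <- rep(NA_integer_, nrow(ss))
  cur <- 0L
  for (i in seq_len(nrow(ss))) {
    if (ss$ss[i] != "E") next
    new_seg <- i == 1L || ss$ss[i - 1L] != "E" ||
      ss$chain[i - 1L] != ss$chain[i]
    if (new_seg) cur <- cur + 1L
    id[i] <- cur
  }
  list(id = id)
}

#' Inter-chain contacts and salt bridges of one residue
#'
#' An interface contact is any heavy-atom pair across chains within the
#' interface cutoff. A salt bridge requires a charged side-chain atom
#' (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2, Asp OD1/OD2, Glu OE1/OE2) of
#' the residue within the salt-bridge cutoff of an opposite-charge
#' atom on another chain, DNA phosphate OP1/OP2 included as negative.
#'
#' @param s A `structure_model`.
#' @param chain,resno Residue to examine.
#' @param th A [structure_thresholds()].
#' @return List with `interface_partner_chains` (character vector) and
#'   `salt_bridges` (data frame `own_atom`, `partner_chain`,
#'   `partner_resno`, `partner_atom`, `distance`).
#' @export
detect_interchain_contacts <- function(s, chain, resno,
                                       th = structure_thresholds()) {
  a <- s$atoms
  own <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  other <- a[a$chain != chain, , drop = FALSE]
  empty <- data.frame(own_atom = character(0), partner_chain = character(0),
                      partner_resno = integer(0), partner_atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(own) == 0L || nrow(other) == 0L) {
    return(list(interface_partner_chains = character(0),
                salt_bridges = empty))
  }
  xo <- as.matrix(own[, c("x", "y", "z")])
  xt <- as.matrix(other[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(xo^2), rowSums(xt^2), "+") - 2 * tcrossprod(xo, xt))
  contact <- which(d <= th$interface_cutoff, arr.ind = TRUE)
  partners <- sort(unique(other$chain[contact[, 2L]]))

  resid <- own$resid[1L]
  pos_atoms <- POSITIVE_ATOMS[[resid]]
  neg_atoms <- NEGATIVE_ATOMS[[resid]]
  sb <- empty
  charged_rows <- function(df, sign) {
    hits <- logical(nrow(df))
    for (rn in names(if (sign > 0) POSITIVE_ATOMS else NEGATIVE_ATOMS)) {
      atoms <- if (sign > 0) POSITIVE_ATOMS[[rn]] else NEGATIVE_ATOMS[[rn]]
      hits <- hits | (df$resid == rn & df$elety %in% atoms)
    }
    if (sign < 0) {
      hits <- hits | (df$resid %in% NUCLEIC_RESIDUES &
                        df$elety %in% DNA_PHOSPHATE_ATOMS)
    }
    hits
  }
  own_sign <- if (!is.null(pos_atoms)) 1L else if (!is.null(neg_atoms)) -1L else 0L
  if (own_sign != 0L) {
    oi <- which(charged_rows(own, own_sign))
    ti <- which(charged_rows(other, -own_sign))
    if (length(oi) && length(ti)) {
      dd <- d[oi, ti, drop = FALSE]
      hit <- which(dd <= th$salt_bridge_cutoff, arr.ind = TRUE)
      if (nrow(hit)) {
        sb <- data.frame(
          own_atom = own$elety[oi[hit[, 1L]]],
          partner_chain = other$chain[ti[hit[, 2L]]],
          partner_resno = other$resno[ti[hit[, 2L]]],
          partner_atom = other$elety[ti[hit[, 2L]]],
          distance = dd[hit], stringsAsFactors = FALSE)
        sb <- sb[order(sb$distance), ]
        rownames(sb) <- NULL
      }
    }
  }
  list(interface_partner_chains = partners, salt_bridges = sb)
}
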