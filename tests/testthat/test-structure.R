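test_that("PDB parsing classifies chains and resolves altLocs", {
  m <- cached_models("protein_dna")
  expect_setequal(m$chains$class, c("protein", "nucleic"))
  expect_equal(m$chains$class[m$chains$chain == "B"], "nucleic")

  # altLoc: highest occupancy wins, waters are dropped
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.460   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       1.500   0.100   0.000  0.60  0.00           C",
    "HETATM    4  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END")
  m2 <- parse_structure(paste(pdb, collapse = "\n"))
  ca <- m2$atoms[m2$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.5)
  expect_false(any(m2$atoms$resid == "HOH"))

  expect_error(parse_structure("REMARK nothing here\nEND"), "no ATOM")
  bad <- sub("1.460", "1.4x6", pdb[2], fixed = TRUE)
  expect_error(parse_structure(paste(c(pdb[1], bad, "END"), collapse = "\n")),
               "line 2")
})

test_that("generated structures re-parse losslessly to 3 decimals", {
  for (name in c("helix", "sheet2", "coil_dimer")) {
    m <- cached_models(name)
    rt <- parse_structure(write_pdb_text(m))
    expect_equal(nrow(rt$atoms), nrow(m$atoms))
    expect_equal(rt$atoms$x, round(m$atoms$x, 3))
    expect_equal(rt$atoms$resno, m$atoms$resno)
  }
})

test_that("secondary structure matches the reference implementation on ideal fixtures", {
  for (name in c("helix", "sheet2", "meander")) {
    pdb <- cached_suite()[[name]]$pdb
    mine <- assign_secondary_structure(parse_structure(pdb))$ss
    ref <- strsplit(mdtraj_dssp(pdb), "")[[1]]
    ref[!ref %in% c("H", "E")] <- "C"
    n <- length(mine)
    interior <- 3:(n - 2)
    agree <- mean(mine[interior] == ref[interior])
    expect_gte(agree, 0.95)
  }
  # an ideal helix has hydrogen-bond-range i -> i+4 carbonyl-amide pairs
  bb <- indelstruct:::backbone_table(cached_models("helix"))
  d <- vapply(1:(nrow(bb$keys) - 4), function(i)
    sqrt(sum((bb$O[i, ] - bb$N[i + 4, ])^2)), numeric(1))
  expect_true(all(d > 2.7 & d < 3.2))
})

test_that("an isolated extended chain is entirely coil", {
  pdb <- build_geometry(geometry_spec("beta_sheet", n_residues = 12,
                                      n_strands = 1))
  ss <- assign_secondary_structure(parse_structure(pdb))
  expect_true(all(ss$ss == "C"))
})

test_that("SASA of an isolated atom equals the analytic sphere area", {
  one <- structure(list(
    atoms = data.frame(chain = "A", resno = 1L, insert = "",
                       resid = "GLY", elety = "CA", elesy = "C",
                       x = 0, y = 0, z = 0),
    chains = data.frame(chain = "A", class = "protein")),
    class = "structure_model")
  r <- compute_rsa(one)
  expect_equal(r$atom_sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
})

test_that("SASA is non-increasing as atoms are added and zero when buried", {
  set.seed(21)
  base <- data.frame(chain = "A", resno = 1L, insert = "", resid = "GLY",
                     elety = "CA", elesy = "C",
                     x = c(0, 2.5), y = c(0, 0), z = c(0, 0))
  mk <- function(at) structure(list(
    atoms = at, chains = data.frame(chain = "A", class = "protein")),
    class = "structure_model")
  s2 <- compute_rsa(mk(base))$atom_sasa
  more <- rbind(base, within(base[1, ], { x <- 1.2; y <- 2.2 }))
  s3 <- compute_rsa(mk(more))$atom_sasa
  expect_lte(s3[1], s2[1] + 1e-9)
  expect_lte(s3[2], s2[2] + 1e-9)

  # an atom caged by a tight shell has zero accessible surface
  dirs <- indelstruct:::sphere_points(60) * 2.6
  cage <- data.frame(chain = "A", resno = 1L, insert = "", resid = "GLY",
                     elety = "CA", elesy = "C",
                     x = c(0, dirs[, 1]), y = c(0, dirs[, 2]),
                     z = c(0, dirs[, 3]))
  sc <- compute_rsa(mk(cage))$atom_sasa
  expect_equal(sc[1], 0)
})

test_that("per-atom SASA tracks an independent implementation within 3%", {
  pdb <- cached_suite()$helix$pdb
  mine <- compute_rsa(parse_structure(pdb))$atom_sasa
  ref <- mdtraj_sasa(pdb)
  expect_equal(length(mine), length(ref))
  expect_lt(abs(sum(mine) - sum(ref)) / sum(ref), 0.03)
})

test_that("strand topology separates edge, central and non-sheet residues", {
  m <- cached_models("meander")
  ss <- assign_secondary_structure(m)
  # strands: 2-10 (edge), 13-21 (central), 26-33 (edge)
  expect_equal(classify_strand_position(ss, "A", 15), "central")
  expect_equal(classify_strand_position(ss, "A", 5), "edge")
  expect_equal(classify_strand_position(ss, "A", 28), "edge")
  expect_equal(classify_strand_position(ss, "A", 11), "not_in_sheet")
  h <- cached_models("helix")
  ssh <- assign_secondary_structure(h)
  expect_equal(classify_strand_position(ssh, "A", 10), "not_in_sheet")
})

test_that("salt bridges and interface contacts follow the distance cutoffs", {
  mk_pair <- function(d) {
    atoms <- rbind(
      data.frame(chain = "A", resno = 1L, insert = "", resid = "ARG",
                 elety = c("CZ", "NH1"), elesy = "N",
                 x = c(-1.33, 0), y = 0, z = 0),
      data.frame(chain = "B", resno = 1L, insert = "", resid = "DA",
                 elety = c("P", "OP1"), elesy = c("P", "O"),
                 x = c(d + 1.5, d), y = 0, z = 0))
    atoms$elesy <- c("C", "N", "P", "O")
    structure(list(atoms = atoms,
                   chains = data.frame(chain = c("A", "B"),
                                       class = c("protein", "nucleic"))),
              class = "structure_model")
  }
  ct <- detect_interchain_contacts(mk_pair(3.2), "A", 1)
  expect_equal(nrow(ct$salt_bridges), 1L)
  expect_equal(ct$salt_bridges$distance, 3.2)
  expect_equal(ct$salt_bridges$partner_atom, "OP1")

  # 4.3 A: interface contact but no salt bridge
  ct43 <- detect_interchain_contacts(mk_pair(4.3), "A", 1)
  expect_equal(nrow(ct43$salt_bridges), 0L)
  expect_equal(ct43$interface_partner_chains, "B")

  # 10 A: nothing
  ct10 <- detect_interchain_contacts(mk_pair(10), "A", 1)
  expect_equal(nrow(ct10$salt_bridges), 0L)
  expect_length(ct10$interface_partner_chains, 0L)
})

test_that("the salt-bridge relation is symmetric across chains", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1L, insert = "", resid = "ARG",
               elety = "NH1", elesy = "N", x = 0, y = 0, z = 0),
    data.frame(chain = "B", resno = 7L, insert = "", resid = "GLU",
               elety = "OE1", elesy = "O", x = 3.5, y = 0, z = 0))
  m <- structure(list(atoms = atoms,
                      chains = data.frame(chain = c("A", "B"),
                                          class = "protein")),
                 class = "structure_model")
  a <- detect_interchain_contacts(m, "A", 1)
  b <- detect_interchain_contacts(m, "B", 7)
  expect_equal(nrow(a$salt_bridges), 1L)
  expect_equal(nrow(b$salt_bridges), 1L)
  expect_equal(a$salt_bridges$distance, b$salt_bridges$distance)
})

test_that("the planted protein-DNA complex has exactly one close arginine-phosphate pair", {
  m <- cached_models("protein_dna")
  arg <- m$atoms[m$atoms$resid == "ARG" &
                   m$atoms$elety %in% c("NH1", "NH2", "NE"), ]
  ops <- m$atoms[m$atoms$elety %in% c("OP1", "OP2"), ]
  d <- sqrt(outer(rowSums(as.matrix(arg[, c("x", "y", "z")])^2),
                  rowSums(as.matrix(ops[, c("x", "y", "z")])^2), "+") -
              2 * tcrossprod(as.matrix(arg[, c("x", "y", "z")]),
                             as.matrix(ops[, c("x", "y", "z")])))
  expect_equal(sum(d <= 3.5), 1L)
})
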