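# Independent oracles used by the property tests. These deliberately
# re-derive results by brute force (or via an unrelated library) and
# must stay independent of the package implementations they check.

# Apply a variant to a reference string (1-based coordinates).
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt,
         substr(seq, pos + nchar(ref), nchar(seq)))
}

# Brute-force left-most representation: enumerate every anchored indel
# of the same net change that reproduces the same mutated sequence and
# return the left-most one.
oracle_leftmost <- function(seq, pos, ref, alt) {
  mutated <- apply_variant(seq, pos, ref, alt)
  d <- nchar(ref) - nchar(alt)
  n <- nchar(seq)
  if (d > 0) {  # deletion of d bases with a 1-base anchor
    for (p in 1:(n - d)) {
      cand_ref <- substr(seq, p, p + d)
      cand_alt <- substr(seq, p, p)
      if (apply_variant(seq, p, cand_ref, cand_alt) == mutated) {
        return(list(position = p, ref = cand_ref, alt = cand_alt))
      }
    }
  } else {      # insertion of -d bases after a 1-base anchor
    k <- -d
    for (p in 1:n) {
      for (ins in unique(substring(mutated, p + 1L, p + k))) {
        cand_alt <- paste0(substr(seq, p, p), ins)
        if (nchar(cand_alt) == k + 1L &&
            apply_variant(seq, p, substr(seq, p, p), cand_alt) == mutated) {
          return(list(position = p, ref = substr(seq, p, p),
                      alt = cand_alt))
        }
      }
    }
  }
  stop("oracle found no representation")
}

# Brute-force tandem-repeat oracle: enumerate every substring unit and
# anchor; check for >= 2 consecutive copies containing the altered
# bases, with the net change a multiple of the unit length or the
# indel sequence a rotation of whole unit copies.
oracle_tr <- function(flank, lo, hi, indel_seq, net, type,
                      max_unit = 21L) {
  n <- nchar(flank)
  rot_copies <- function(s, u) {
    L <- nchar(u)
    if (!nzchar(s) || nchar(s) %% L != 0L) return(FALSE)
    any(vapply(0:(L - 1L), function(r) {
      ru <- paste0(substr(u, r + 1L, L), substr(u, 1L, r))
      identical(s, strrep(ru, nchar(s) %/% L))
    }, logical(1L)))
  }
  for (L in 1:max_unit) {
    for (s in 1:(n - 2L * L + 1L)) {
      u <- substr(flank, s, s + L - 1L)
      copies <- 1L
      while (substr(flank, s + copies * L, s + (copies + 1L) * L - 1L) == u &&
             s + (copies + 1L) * L - 1L <= n) {
        copies <- copies + 1L
      }
      if (copies < 2L) next
      seg_end <- s + copies * L - 1L
      inside <- lo >= s && hi <= seg_end
      hit <- if (type == "ins") {
        at_edge <- (lo >= s && lo <= seg_end) || (hi >= s && hi <= seg_end)
        inside || (at_edge && rot_copies(indel_seq, u))
      } else inside
      if (hit && (abs(net) %% L == 0L || rot_copies(indel_seq, u))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Exhaustive recursive local-alignment oracle with affine gaps
# (open 11, extend 1): maximum over all substring pairs of the best
# global alignment score of the pair, floored at 0.
oracle_local_align <- function(a, b, S) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i1, i2, j1, j2, state) {
    # best score aligning av[i1..i2] with bv[j1..j2]
    if (i1 > i2 && j1 > j2) return(0)
    best <- -Inf
    if (i1 <= i2 && j1 <= j2) {
      best <- max(best, S[av[i1], bv[j1]] +
                    rec(i1 + 1L, i2, j1 + 1L, j2, "M"))
    }
    if (i1 <= i2) {
      best <- max(best, -(if (state == "GA") 1 else 12) +
                    rec(i1 + 1L, i2, j1, j2, "GA"))
    }
    if (j1 <= j2) {
      best <- max(best, -(if (state == "GB") 1 else 12) +
                    rec(i1, i2, j1 + 1L, j2, "GB"))
    }
    best
  }
  best <- 0
  n <- length(av); m <- length(bv)
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      best <- max(best, rec(i1, i2, j1, j2, "M"))
    }
  }
  best
}

# Confusion-matrix recount oracle: per-record loop, no vectorization.
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(pred)) {
    if (is.na(pred[k]) || is.na(truth[k])) next
    if (pred[k] && truth[k]) tp <- tp + 1L
    else if (pred[k] && !truth[k]) fp <- fp + 1L
    else if (!pred[k] && !truth[k]) tn <- tn + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# Reference DSSP assignment via the mdtraj library (independent
# implementation of the same backbone hydrogen-bond convention).
mdtraj_dssp <- function(pdb_text) {
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".txt")
  writeLines(pdb_text, pdb)
  on.exit(unlink(c(pdb, out)))
  code <- sprintf(paste0(
    "import mdtraj as md\n",
    "t = md.load_pdb(%s)\n",
    "open(%s, 'w').write(''.join(md.compute_dssp(t, simplified=True)[0]))\n"),
    deparse(pdb), deparse(out))
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  res <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) stop("mdtraj oracle failed: ",
                              paste(res, collapse = "\n"))
  readLines(out, warn = FALSE)
}

# Reference solvent-accessible surface areas via mdtraj (A^2).
mdtraj_sasa <- function(pdb_text) {
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".txt")
  writeLines(pdb_text, pdb)
  on.exit(unlink(c(pdb, out)))
  code <- sprintf(paste0(
    "import mdtraj as md\n",
    "t = md.load_pdb(%s)\n",
    "s = md.shrake_rupley(t, probe_radius=0.14, n_sphere_points=960)[0]\n",
    "open(%s, 'w').write('\\n'.join(str(x*100) for x in s))\n"),
    deparse(pdb), deparse(out))
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  res <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) stop("mdtraj oracle failed: ",
                              paste(res, collapse = "\n"))
  as.numeric(readLines(out, warn = FALSE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small plus- and minus-strand transcript pair used across tests.
toy_transcript <- function(strand = "+", cds = "ATGGCCGCCAAATTTGGCTAA",
                           exon_break = NULL) {
  n <- nchar(cds)
  genomic <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  left <- strrep("G", 100)
  if (is.null(exon_break)) {
    chrom <- paste0(left, genomic, strrep("C", 100))
    ex <- cbind(101L, 100L + n)
  } else {
    # split genomic CDS into two exons with a 50-nt intron
    p1 <- substr(genomic, 1L, exon_break)
    p2 <- substr(genomic, exon_break + 1L, n)
    intron <- strrep("T", 50)
    chrom <- paste0(left, p1, intron, p2, strrep("C", 100))
    ex <- rbind(c(101L, 100L + exon_break),
                c(151L + exon_break, 150L + n))
  }
  t <- transcript_model("TOY", "chrT", strand, ex, ex,
                        cds_sequence = cds)
  list(t = t, chrom = chrom)
}
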