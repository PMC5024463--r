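# Disruption-mechanism rules: combine per-residue structural
# annotations of the affected residues into a
# probably / unclear / unlikely verdict with machine-readable evidence.

#' Helix register shift caused by an in-frame indel
#'
#' An alpha helix has 3.6 residues per turn, so each inserted or
#' deleted residue rotates all downstream side chains by 100 degrees
#' around the helix axis. The shift is reported modulo 360 and flagged
#' disruptive at or beyond the cutoff (default 60 degrees), the point
#' where interface side chains rotate well out of their packing
#' positions.
#'
#' @param n_deleted_or_inserted Number of residues gained or lost
#'   (non-negative).
#' @param cutoff Disruptive threshold in degrees.
#' @return List with `shift_degrees` in `[0, 360)` and `disruptive`.
#' @export
helix_register_shift <- function(n_deleted_or_inserted, cutoff = 60) {
  n <- n_deleted_or_inserted
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("n_deleted_or_inserted must be a single non-negative integer")
  }
  shift <- (n * 100) %% 360
  list(shift_degrees = shift, disruptive = shift >= cutoff)
}

#' Annotate every protein residue of a structure
#'
#' Runs secondary-structure assignment, accessibility, sheet topology
#' and inter-chain contact detection, and derives per-residue features
#' the mechanism rules consume: the helix segment a residue belongs to,
#' whether that segment contains interface residues, and the sequence
#' distance to the nearest helix/strand element.
#'
#' @param s A `structure_model`.
#' @param th A [structure_thresholds()].
#' @return Data frame, one row per protein residue: `chain`, `resno`,
#'   `insert`, `resid`, `ss`, `strand_position`, `rsa`, `is_surface`,
#'   `interface_chains` (comma-joined), `n_salt_bridges`,
#'   `min_salt_bridge_distance`, `helix_segment`,
#'   `helix_has_interface`, `dist_to_element`.
#' @export
annotate_structure <- function(s, th = structure_thresholds()) {
  ss <- assign_secondary_structure(s, th)
  rsa <- compute_rsa(s, th)$residues
  key <- function(d) paste(d$chain, d$resno, d$insert, sep = "\r")
  m <- match(key(ss), key(rsa))
  out <- ss[, c("chain", "resno", "insert", "resid", "ss")]
  out$strand_position <- vapply(seq_len(nrow(out)), function(i) {
    if (ss$ss[i] != "E") "not_in_sheet" else
      classify_strand_position(ss, ss$chain[i], ss$resno[i])
  }, "")
  out$rsa <- rsa$rsa[m]
  out$is_surface <- rsa$is_surface[m]

  contacts <- lapply(seq_len(nrow(out)), function(i) {
    detect_interchain_contacts(s, out$chain[i], out$resno[i], th)
  })
  out$interface_chains <- vapply(contacts, function(ct) {
    paste(ct$interface_partner_chains, collapse = ",")
  }, "")
  out$n_salt_bridges <- vapply(contacts, function(ct) {
    nrow(ct$salt_bridges)
  }, integer(1L))
  out$min_salt_bridge_distance <- vapply(contacts, function(ct) {
    if (nrow(ct$salt_bridges)) min(ct$salt_bridges$distance) else NA_real_
  }, numeric(1L))

  # helix segments and whether each contains interface residues
  seg <- rep(NA_integer_, nrow(out)); cur <- 0L
  for (i in seq_len(nrow(out))) {
    if (out$ss[i] != "H") next
    if (i == 1L || out$ss[i - 1L] != "H" ||
        out$chain[i - 1L] != out$chain[i]) cur <- cur + 1L
    seg[i] <- cur
  }
  out$helix_segment <- seg
  has_if <- tapply(nzchar(out$interface_chains), seg, any)
  out$helix_has_interface <- ifelse(is.na(seg), FALSE,
                                    unname(has_if[as.character(seg)]))

  # sequence distance (same chain) to the nearest H/E residue
  out$dist_to_element <- NA_real_
  for (chn in unique(out$chain)) {
    i <- which(out$chain == chn)
    el <- which(out$ss[i] %in% c("H", "E"))
    out$dist_to_element[i] <- if (length(el) == 0L) Inf else
      vapply(seq_along(i), function(k) min(abs(k - el)), numeric(1L))
  }
  out
}

#' Classify the likely disruption mechanism of an indel
#'
#' Applies the mechanism rules to the structural annotations of the
#' affected residues, in fixed order, returning the first match:
#'
#' 1. any affected residue in a beta strand -> `probably`,
#'    `beta_sheet_disruption` (evidence records edge/central topology);
#' 2. any affected residue in a helix whose segment packs against
#'    another chain, with a disruptive register shift -> `probably`,
#'    `helix_register_shift`;
#' 3. any affected residue forming a salt bridge or interface contact
#'    with another chain -> `probably`, `binding_site_disruption`;
#' 4. all affected residues in surface coil, with no interface
#'    contacts, at least `loop_element_distance` residues from the
#'    nearest helix/strand -> `unlikely` (no mechanism);
#' 5. otherwise -> `unclear`, `packing_loss`.
#'
#' @param annotations Data frame from [annotate_structure()].
#' @param affected Data frame with columns `chain` and `resno` naming
#'   the affected (mapped) residues; rows absent from `annotations`
#'   make the variant unassessable.
#' @param n_changed_residues Residues gained or lost (drives the helix
#'   register shift).
#' @param th A [structure_thresholds()].
#' @return A `mechanism_verdict`: list with `category`
#'   (`probably`/`unclear`/`unlikely`/`unassessable`), `mechanisms`
#'   (character vector; `"none"` for unlikely) and `evidence`.
#' @export
classify_mechanism <- function(annotations, affected, n_changed_residues,
                               th = structure_thresholds()) {
  stopifnot(is.data.frame(affected),
            all(c("chain", "resno") %in% names(affected)))
  rows <- match(paste(affected$chain, affected$resno),
                paste(annotations$chain, annotations$resno))
  if (nrow(affected) == 0L || anyNA(rows)) {
    return(structure(list(category = "unassessable",
                          mechanisms = character(0),
                          evidence = list(
                            unmapped = affected[is.na(rows), , drop = FALSE])),
                     class = "mechanism_verdict"))
  }
  ann <- annotations[rows, , drop = FALSE]
  verdict <- function(category, mechanisms, evidence) {
    structure(list(category = category, mechanisms = mechanisms,
                   evidence = evidence), class = "mechanism_verdict")
  }
  # rule 1: beta-sheet disruption
  if (any(ann$ss == "E")) {
    e <- ann[ann$ss == "E", , drop = FALSE]
    return(verdict("probably", "beta_sheet_disruption",
                   list(strand_position = e$strand_position,
                        residues = paste0(e$chain, e$resno))))
  }
  # rule 2: helix register shift at an interface
  shift <- helix_register_shift(n_changed_residues,
                                th$register_shift_cutoff)
  helix_if <- ann$ss == "H" & ann$helix_has_interface
  if (any(helix_if) && shift$disruptive) {
    return(verdict("probably", "helix_register_shift",
                   list(shift_degrees = shift$shift_degrees,
                        residues = paste0(ann$chain[helix_if],
                                          ann$resno[helix_if]))))
  }
  # rule 3: binding-site disruption
  bound <- ann$n_salt_bridges > 0L | nzchar(ann$interface_chains)
  if (any(bound)) {
    return(verdict("probably", "binding_site_disruption",
                   list(salt_bridge_distance =
                          suppressWarnings(min(ann$min_salt_bridge_distance,
                                               na.rm = TRUE)),
                        partner_chains =
                          unique(unlist(strsplit(
                            ann$interface_chains[bound], ","))))))
  }
  # rule 4: remote surface loop
  if (all(ann$ss == "C") && all(ann$is_surface, na.rm = FALSE) &&
      !anyNA(ann$is_surface) &&
      all(ann$dist_to_element >= th$loop_element_distance)) {
    return(verdict("unlikely", "none", list()))
  }
  # rule 5: default
  verdict("unclear", "packing_loss",
          list(dist_to_element = min(ann$dist_to_element),
               min_rsa = suppressWarnings(min(ann$rsa, na.rm = TRUE))))
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat(sprintf("<mechanism_verdict> %s [%s]\n", x$category,
              paste(x$mechanisms, collapse = ", ")))
  invisible(x)
}
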