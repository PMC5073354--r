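#' Graft a ligand from a reference complex onto an ensemble frame
#'
#' The receptor atoms shared between the frame and the reference complex are
#' Kabsch-superposed (reference onto frame) and the resulting rigid transform
#' is applied to the reference ligand, so the ligand's internal geometry is
#' untouched and it lands where the crystallographic pose predicts on that
#' frame's receptor conformation.
#'
#' @param frame `Structure` (one receptor conformation).
#' @param reference_complex `Structure` holding receptor + ligand.
#' @param receptor_sel `Selection` for receptor atoms used in the fit
#'   (default: whole receptor backbone; the atoms must match by identity keys).
#' @param ligand_sel `Selection` for the ligand in `reference_complex`.
#' @return `Structure`: the ligand atoms with transformed coordinates.
#' @export
graft_ligand <- function(frame, reference_complex,
                         receptor_sel = sel_backbone(), ligand_sel) {
  m <- match_atoms(reference_complex, frame, receptor_sel,
                   on_unmatched = "exclude")
  if (nrow(m) < 3L) stop("fewer than 3 matched receptor atoms")
  fit <- kabsch_superpose(coords(reference_complex)[m$ia, , drop = FALSE],
                          coords(frame)[m$ib, , drop = FALSE])
  lig <- subset_structure(reference_complex, ligand_sel)
  set_coords(lig, apply_transform(coords(lig), fit))
}

#' Detect steric clashes between two atom sets
#'
#' A receptor-ligand atom pair clashes when its distance is smaller than the
#' sum of van der Waals radii minus `overlap_min` (default 0.4 angstrom, the
#' standard steric-clash convention). Pairs on the `whitelist` -- typically
#' the crystallographic interface contacts, which must not self-report -- are
#' skipped.
#'
#' @param receptor,ligand `Structure`s.
#' @param overlap_min minimum vdW overlap to call a clash, angstrom.
#' @param whitelist data.frame with columns `receptor_key`, `ligand_key`
#'   (values `chain|resseq|icode|atom`), or NULL.
#' @return data.frame of class `ClashReport`: receptor/ligand chain, resseq,
#'   resname, atom, `distance`, `overlap`.
#' @export
detect_clashes <- function(receptor, ligand, overlap_min = 0.4, whitelist = NULL) {
  rx <- coords(receptor); lx <- coords(ligand)
  rr <- vdw_radius(receptor$atoms$element)
  rl <- vdw_radius(ligand$atoms$element)
  # brute-force O(N*M) distance evaluation, vectorised per ligand atom
  out <- list()
  rkeys <- atom_keys(receptor); lkeys <- atom_keys(ligand)
  wl <- if (is.null(whitelist)) character(0)
        else paste(whitelist$receptor_key, whitelist$ligand_key)
  for (j in seq_len(nrow(lx))) {
    dv <- rx - matrix(lx[j, ], nrow(rx), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dv^2))
    lim <- rr + rl[j] - overlap_min
    hit <- which(dist < lim)
    if (length(hit) == 0L) next
    hit <- hit[!(paste(rkeys[hit], lkeys[j]) %in% wl)]
    for (i in hit) {
      out[[length(out) + 1L]] <- data.frame(
        receptor_chain = receptor$atoms$chain[i],
        receptor_resseq = receptor$atoms$resseq[i],
        receptor_resname = receptor$atoms$resname[i],
        receptor_atom = receptor$atoms$atom[i],
        ligand_chain = ligand$atoms$chain[j],
        ligand_resseq = ligand$atoms$resseq[j],
        ligand_resname = ligand$atoms$resname[j],
        ligand_atom = ligand$atoms$atom[j],
        distance = dist[i], overlap = rr[i] + rl[j] - dist[i],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) == 0L)
    data.frame(receptor_chain = character(0), receptor_resseq = integer(0),
               receptor_resname = character(0), receptor_atom = character(0),
               ligand_chain = character(0), ligand_resseq = integer(0),
               ligand_resname = character(0), ligand_atom = character(0),
               distance = numeric(0), overlap = numeric(0))
  else do.call(rbind, out)
  class(res) <- c("ClashReport", class(res))
  res
}

atom_keys <- function(s) paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode,
                               s$atoms$atom, sep = "|")

# reference-complex contact pairs within vdW sum + margin -> whitelist
native_contact_whitelist <- function(receptor, ligand, margin = 0.5) {
  rx <- coords(receptor); lx <- coords(ligand)
  rr <- vdw_radius(receptor$atoms$element)
  rl <- vdw_radius(ligand$atoms$element)
  rkeys <- atom_keys(receptor); lkeys <- atom_keys(ligand)
  out <- list()
  for (j in seq_len(nrow(lx))) {
    dv <- rx - matrix(lx[j, ], nrow(rx), 3, byrow = TRUE)
    hit <- which(sqrt(rowSums(dv^2)) < rr + rl[j] + margin)
    if (length(hit) > 0L)
      out[[length(out) + 1L]] <- data.frame(receptor_key = rkeys[hit],
                                            ligand_key = lkeys[j],
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(receptor_key = character(0), ligand_key = character(0)))
  do.call(rbind, out)
}

#' Time-resolved clash screening of a grafted ligand over an ensemble
#'
#' For each ensemble frame the reference ligand is grafted by receptor
#' superposition ([graft_ligand()]) and clashes are detected
#' ([detect_clashes()]). The whitelist of native contacts is built once from
#' the reference complex (pairs within vdW sum + `whitelist_margin`), so an
#' unperturbed copy of the reference receptor is clash-free by construction.
#'
#' @param e receptor `Ensemble`.
#' @param reference_complex `Structure` with receptor + ligand.
#' @param receptor_sel fit selection (default whole receptor backbone).
#' @param ligand_sel ligand selection in the reference complex.
#' @param overlap_min clash threshold, angstrom.
#' @param whitelist_margin native-contact margin, angstrom.
#' @param position_labels optional named character vector mapping ligand
#'   residue numbers to substrate position labels (P4...P2').
#' @return list of class `ClashTimecourse`: `frames` (list of `ClashReport`s),
#'   `per_frame_counts`, `summary` (receptor residue x ligand residue counts
#'   with first/last clashing frame).
#' @export
clash_timecourse <- function(e, reference_complex,
                             receptor_sel = sel_backbone(), ligand_sel,
                             overlap_min = 0.4, whitelist_margin = 0.5,
                             position_labels = NULL) {
  stopifnot(inherits(e, "Ensemble"))
  lig_ref <- subset_structure(reference_complex, ligand_sel)
  # receptor side of the reference = everything not in the ligand selection
  lig_rows <- atom_select(reference_complex, ligand_sel)
  rec_ref <- Structure(reference_complex$atoms[-lig_rows, , drop = FALSE],
                       reference_complex$metadata)
  wl <- native_contact_whitelist(rec_ref, lig_ref, whitelist_margin)
  reports <- vector("list", length(e$frames))
  counts <- integer(length(e$frames))
  for (f in seq_along(e$frames)) {
    frame <- set_coords(e$topology, e$frames[[f]])
    lig <- graft_ligand(frame, reference_complex, receptor_sel, ligand_sel)
    rep_f <- detect_clashes(frame, lig, overlap_min, wl)
    reports[[f]] <- rep_f
    counts[f] <- nrow(rep_f)
  }
  pairs <- do.call(rbind, lapply(seq_along(reports), function(f) {
    r <- reports[[f]]
    if (nrow(r) == 0L) return(NULL)
    data.frame(frame = f, receptor_resseq = r$receptor_resseq,
               receptor_resname = r$receptor_resname,
               ligand_resseq = r$ligand_resseq,
               ligand_resname = r$ligand_resname, stringsAsFactors = FALSE)
  }))
  summary <- NULL
  if (!is.null(pairs)) {
    key <- paste(pairs$receptor_resseq, pairs$ligand_resseq)
    agg <- lapply(split(pairs, key), function(g) data.frame(
      receptor_resseq = g$receptor_resseq[1],
      receptor_resname = g$receptor_resname[1],
      ligand_resseq = g$ligand_resseq[1], ligand_resname = g$ligand_resname[1],
      position = if (!is.null(position_labels))
        position_labels[as.character(g$ligand_resseq[1])] else NA_character_,
      n_frames = length(unique(g$frame)),
      first_frame = min(g$frame), last_frame = max(g$frame),
      stringsAsFactors = FALSE))
    summary <- do.call(rbind, agg)
    rownames(summary) <- NULL
    summary <- summary[order(summary$first_frame), , drop = FALSE]
  }
  structure(list(frames = reports, per_frame_counts = counts, summary = summary,
                 overlap_min = overlap_min),
            class = "ClashTimecourse")
}
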