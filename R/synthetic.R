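#' Ideal alpha-helix structure
#'
#' Backbone (N, CA, C, O) plus Cbeta pseudo-atoms on per-atom-type helices
#' with 100 degrees twist per residue and 1.5 angstrom rise -- ideal-helix
#' geometry, so consecutive Calpha-Calpha distances are exactly equal
#' (about 3.8 angstrom). Coordinates are deterministic; `jitter_sd` adds
#' seeded isotropic Gaussian noise when a noisy copy is wanted.
#'
#' @param n_res number of residues (>= 8).
#' @param seed RNG seed (used only when `jitter_sd > 0`).
#' @param sequence 3-letter residue codes, recycled to `n_res` (default ALA).
#' @param chain chain identifier.
#' @param jitter_sd per-axis Gaussian noise, angstrom.
#' @return a `Structure`.
#' @export
make_helix <- function(n_res, seed = 1L, sequence = "ALA", chain = "A",
                       jitter_sd = 0) {
  if (n_res < 8L) stop("n_res must be >= 8")
  sequence <- rep(sequence, length.out = n_res)
  twist <- 100 * pi / 180; rise <- 1.5
  # (radius, phase offset rad, z offset) per atom type: ideal-helix placement
  params <- list(N = c(1.58, -0.48, -0.85), CA = c(2.30, 0, 0),
                 C = c(1.65, 0.42, 0.90), O = c(1.95, 0.47, 2.08),
                 CB = c(3.22, -0.25, -0.66))
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  rows <- list()
  for (i in seq_len(n_res)) {
    atoms_i <- c("N", "CA", "C", "O", if (sequence[i] != "GLY") "CB")
    for (a in atoms_i) {
      p <- params[[a]]
      phi <- (i - 1) * twist + p[2]
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resseq = i, icode = "", resname = sequence[i], atom = a,
        altloc = "", x = p[1] * cos(phi), y = p[1] * sin(phi),
        z = (i - 1) * rise + p[3], occ = 1, b = 10, element = elements[[a]],
        het = FALSE, stringsAsFactors = FALSE)
    }
  }
  s <- Structure(do.call(rbind, rows), metadata = list(generator = "make_helix"))
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- set_coords(s, coords(s) +
                      matrix(stats::rnorm(3 * n_atoms(s), 0, jitter_sd), ncol = 3))
  }
  s
}

#' Reference / ligand-displaced / control structure triple
#'
#' Emulates the crystal-structure comparison that calls ligand-associated
#' conformational change: `query` is the reference with the atoms of a
#' residue segment rigidly displaced by `shift` angstrom perpendicular to the
#' helix axis; `third` (the unliganded control) is the reference plus
#' isotropic noise of sd `control_noise_sd`. The planted truth travels with
#' the data so recovery tests never hand-code it twice.
#'
#' @param n_res chain length.
#' @param segment integer residue numbers to displace.
#' @param shift displacement, angstrom.
#' @param seed RNG seed (control noise).
#' @param control_noise_sd per-axis noise of the control structure, angstrom.
#' @return list: `reference`, `query`, `third` (`Structure`s), `truth`
#'   (list with `segment`, `shift`).
#' @export
make_deviation_triple <- function(n_res = 60L, segment = 20:24, shift = 1.0,
                                  seed = 1L, control_noise_sd = 0.1) {
  if (length(segment) < 1L) stop("segment must contain at least one residue")
  if (any(segment < 1L | segment > n_res)) stop("segment outside the chain")
  reference <- make_helix(n_res, seed)
  query <- reference
  if (shift != 0) {
    rows <- which(query$atoms$resseq %in% segment)
    direction <- c(1, 0, 0) # perpendicular to the helix (z) axis
    xyz <- coords(query)
    xyz[rows, ] <- xyz[rows, ] + matrix(direction * shift, length(rows), 3,
                                        byrow = TRUE)
    query <- set_coords(query, xyz)
  }
  set.seed(seed)
  third <- set_coords(reference, coords(reference) +
                        matrix(stats::rnorm(3 * n_atoms(reference), 0,
                                            control_noise_sd), ncol = 3))
  list(reference = reference, query = query, third = third,
       truth = list(segment = segment, shift = shift))
}

#' Ensemble displaced along a known elastic-network mode
#'
#' Frames are the base structure's Calpha coordinates plus a_f * v_mode plus
#' isotropic Gaussian noise, with a_f ~ Normal(amplitude_mean, amplitude_sd).
#' Emulates an MD snapshot set whose equilibrium population is shifted along
#' one collective mode. The topology of the returned ensemble is the Calpha
#' trace of `base`.
#'
#' @param base `Structure` the modes are computed from.
#' @param mode_index global mode number (> 6; rigid-body modes are an error).
#' @param amplitude_mean,amplitude_sd Gaussian amplitude parameters,
#'   angstrom * mode units.
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @param noise_sd per-axis Gaussian noise, angstrom.
#' @param cutoff elastic-network cutoff, angstrom.
#' @return list: `ensemble` (`Ensemble`), `modes` (`ModeSet`), `truth`
#'   (list with `mode_index`, `amplitudes`, `noise_sd`).
#' @export
make_mode_ensemble <- function(base, mode_index = 8L, amplitude_mean = 2,
                               amplitude_sd = 0.5, n_frames = 200L, seed = 1L,
                               noise_sd = 0.05, cutoff = 15) {
  h <- build_enm(base, cutoff = cutoff)
  m <- enm_modes(h, n_modes = min(100L, 3L * nrow(attr(h, "nodes")) - 6L))
  if (any(mode_index <= m$n_zero))
    stop("mode_index must exceed ", m$n_zero, " (rigid-body modes)")
  topo <- subset_structure(base, sel_calpha())
  ca <- coords(topo)
  v <- matrix(m$vectors[, mode_index], ncol = 3, byrow = TRUE)
  set.seed(seed)
  amplitudes <- stats::rnorm(n_frames, amplitude_mean, amplitude_sd)
  frames <- lapply(seq_len(n_frames), function(f) {
    ca + amplitudes[f] * v +
      matrix(stats::rnorm(length(ca), 0, noise_sd), ncol = 3)
  })
  list(ensemble = Ensemble(topo, frames),
       modes = m,
       truth = list(mode_index = mode_index, amplitudes = amplitudes,
                    noise_sd = noise_sd))
}

#' Two-chain complex with planted interface bonds
#'
#' A hand-placed two-chain fixture (chain A protease side, chain I inhibitor
#' side) in which exactly three donor-acceptor pairs satisfy the hydrogen-bond
#' geometry (2.9-3.2 angstrom, angle >= 90 degrees) -- two backbone bonds and
#' one Lys NZ - Asp OD1 pair at 3.2 angstrom that is simultaneously the single
#' planted salt bridge. All other cross-chain polar pairs are kept outside
#' the cutoffs. `separation` pulls chain I away along -z to switch the
#' interface off.
#'
#' @param seed unused (the fixture is fully deterministic); kept so every
#'   generator shares one signature.
#' @param separation extra chain separation, angstrom.
#' @return list: `complex` (`Structure`), `truth` (`hbonds` and
#'   `salt_bridges` data.frames naming the planted pairs).
#' @export
make_interface_complex <- function(seed = 1L, separation = 0) {
  at <- function(chain, resseq, resname, atom, x, y, z, element)
    data.frame(chain = chain, resseq = resseq, icode = "", resname = resname,
               atom = atom, altloc = "", x = x, y = y, z = z, occ = 1, b = 10,
               element = element, het = FALSE, stringsAsFactors = FALSE)
  a <- rbind(
    # slot x=0: chain A residue 1 backbone O is an acceptor
    at("A", 1, "GLY", "O", 0, 0, 0, "O"),
    at("A", 1, "GLY", "C", 0, 1.23, 0, "C"),
    at("A", 1, "GLY", "CA", 0, 2.40, 0.5, "C"),
    at("A", 1, "GLY", "N", 0, 3.60, 0, "N"),
    # slot x=6: chain A residue 2 backbone N is a donor
    at("A", 2, "GLY", "N", 6, 0, 0, "N"),
    at("A", 2, "GLY", "CA", 6.8, 0.8, 0.8, "C"),
    at("A", 2, "GLY", "C", 7.5, 1.5, 0.2, "C"),
    at("A", 2, "GLY", "O", 8.5, 2.0, 0.5, "O"),
    # slot x=12: chain A residue 3 lysine side chain
    at("A", 3, "LYS", "NZ", 12, 0, 0, "N"),
    at("A", 3, "LYS", "CE", 12.7, 0.7, 0.7, "C"),
    at("A", 3, "LYS", "CD", 13.4, 1.4, 1.4, "C"),
    at("A", 3, "LYS", "CA", 14, 2.0, 2.0, "C"),
    at("A", 3, "LYS", "N", 14.5, 3.0, 2.2, "N"),
    at("A", 3, "LYS", "C", 15, 2.0, 1.5, "C"),
    at("A", 3, "LYS", "O", 15.5, 2.5, 0.8, "O"),
    # residue 4 sits clear of the interface (> 4.5 A from every chain-I atom):
    # it is the designated intruder for planted clash trajectories
    at("A", 4, "ALA", "N", 6, 7.0, 2.3, "N"),
    at("A", 4, "ALA", "CA", 6, 6.0, 1.5, "C"),
    at("A", 4, "ALA", "C", 7, 6.3, 0.7, "C"),
    at("A", 4, "ALA", "O", 7.2, 7.0, -0.2, "O"),
    at("A", 4, "ALA", "CB", 5, 6.3, 0.7, "C"))
  i <- rbind(
    at("I", 1, "GLY", "N", 0, 0, -2.9, "N"),
    at("I", 1, "GLY", "CA", 1.0, 0.5, -3.9, "C"),
    at("I", 1, "GLY", "C", 2.0, 1.0, -4.3, "C"),
    at("I", 1, "GLY", "O", 3.0, 1.5, -4.0, "O"),
    at("I", 2, "GLY", "O", 6, 0, -2.9, "O"),
    at("I", 2, "GLY", "C", 6, 1.23, -2.9, "C"),
    at("I", 2, "GLY", "CA", 6, 2.40, -3.4, "C"),
    at("I", 2, "GLY", "N", 6, 3.60, -3.0, "N"),
    at("I", 3, "ASP", "OD1", 12, 0, -3.2, "O"),
    at("I", 3, "ASP", "CG", 12, 1.23, -3.5, "C"),
    at("I", 3, "ASP", "OD2", 12, 2.40, -3.0, "O"),
    at("I", 3, "ASP", "CB", 13, 1.5, -4.3, "C"),
    at("I", 3, "ASP", "CA", 14, 2.0, -4.8, "C"),
    at("I", 3, "ASP", "N", 15, 2.5, -4.4, "N"),
    at("I", 3, "ASP", "C", 14, 3.2, -5.6, "C"),
    at("I", 3, "ASP", "O", 13.5, 4.2, -5.5, "O"))
  # rigid anchor domain (20-residue helix, residues 10-29) kept > 7 A from
  # chain I: stabilises whole-receptor superpositions the way the bulk of a
  # real protease does, without touching the planted interface geometry
  anchor <- make_helix(20, chain = "A")$atoms
  anchor$resseq <- anchor$resseq + 9L
  xyz <- as.matrix(anchor[, c("x", "y", "z")])
  anchor[, c("x", "y", "z")] <- cbind(xyz[, 3], xyz[, 2] + 14, xyz[, 1] + 4)
  i$z <- i$z - separation
  cx <- Structure(rbind(a, anchor, i),
                  metadata = list(generator = "make_interface_complex"))
  truth <- list(
    hbonds = data.frame(
      donor_chain = c("I", "A", "A"), donor_resseq = c(1L, 2L, 3L),
      donor_atom = c("N", "N", "NZ"),
      acceptor_chain = c("A", "I", "I"), acceptor_resseq = c(1L, 2L, 3L),
      acceptor_atom = c("O", "O", "OD1"), stringsAsFactors = FALSE),
    salt_bridges = data.frame(
      basic_chain = "A", basic_resseq = 3L, basic_atom = "NZ",
      acidic_chain = "I", acidic_resseq = 3L, acidic_atom = "OD1",
      stringsAsFactors = FALSE))
  list(complex = cx, truth = truth)
}

#' Receptor ensemble with a planted clash window
#'
#' Copies of the reference receptor conformation in which one named residue
#' translates toward the ligand centroid by `depth` angstrom during the given
#' frame range only. Outside the window frames equal the reference, so with
#' the native-contact whitelist they are clash-free by construction.
#'
#' @param base_complex `Structure` with receptor and ligand (see
#'   [make_interface_complex()]).
#' @param intruding_residue receptor residue number that moves.
#' @param clash_frames integer frame numbers of the intrusion window (may be
#'   empty for a clash-free trajectory).
#' @param n_frames total frame count.
#' @param depth intrusion distance, angstrom.
#' @param ligand_chain chain id of the ligand within `base_complex`.
#' @param seed unused; deterministic fixture, signature symmetry.
#' @return list: `ensemble` (receptor `Ensemble`), `truth` (list with
#'   `clash_frames`, `residue`, `depth`).
#' @export
make_clash_trajectory <- function(base_complex, intruding_residue = 4L,
                                  clash_frames = 10:20, n_frames = 30L,
                                  depth = 3.0, ligand_chain = "I", seed = 1L) {
  lig_rows <- atom_select(base_complex, sel(chain = ligand_chain))
  rec <- Structure(base_complex$atoms[-lig_rows, , drop = FALSE],
                   base_complex$metadata)
  res_rows <- which(rec$atoms$resseq == intruding_residue)
  if (length(res_rows) == 0L)
    stop("residue ", intruding_residue, " not found in receptor")
  # intrusion direction: from the residue's closest atom straight at the
  # nearest ligand atom, so a modest depth reliably enters the ligand volume
  lig_xyz <- coords(base_complex)[lig_rows, , drop = FALSE]
  res_xyz <- coords(rec)[res_rows, , drop = FALSE]
  cd <- matrix(0, nrow(res_xyz), nrow(lig_xyz))
  for (j in seq_len(nrow(lig_xyz)))
    cd[, j] <- sqrt(rowSums((res_xyz - matrix(lig_xyz[j, ], nrow(res_xyz), 3,
                                              byrow = TRUE))^2))
  nearest <- which(cd == min(cd), arr.ind = TRUE)[1, ]
  dir <- lig_xyz[nearest[2], ] - res_xyz[nearest[1], ]
  dir <- dir / sqrt(sum(dir^2))
  base_xyz <- coords(rec)
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- base_xyz
    if (f %in% clash_frames)
      xyz[res_rows, ] <- xyz[res_rows, ] +
        matrix(dir * depth, length(res_rows), 3, byrow = TRUE)
    xyz
  })
  list(ensemble = Ensemble(rec, frames),
       truth = list(clash_frames = intersect(clash_frames, seq_len(n_frames)),
                    residue = intruding_residue, depth = depth))
}
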