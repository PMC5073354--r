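#' Van der Waals radii
#'
#' Fixed element radius table (angstrom) used by SASA and clash screening;
#' a single published set is shipped so results are bit-reproducible.
#' @param elements character vector of element symbols.
#' @return numeric vector of radii; unknown elements are an error.
#' @export
vdw_radius <- function(elements) {
  tab <- c("H" = 1.20, "C" = 1.70, "N" = 1.55, "O" = 1.52, "S" = 1.80,
           "P" = 1.80, "F" = 1.47, "CL" = 1.75, "BR" = 1.85, "I" = 1.98,
           "SE" = 1.90, "NI" = 1.63, "ZN" = 1.39, "CU" = 1.40, "FE" = 1.47,
           "MN" = 1.61, "MG" = 1.73, "CA" = 2.31, "NA" = 2.27, "K" = 2.75,
           "B" = 1.92)
  r <- tab[toupper(elements)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

# deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each atom's sphere of radius r_vdw + probe is sampled at
#' `n_points` quasi-uniform points; the accessible fraction (points not inside
#' any neighbour's inflated sphere) times the sphere area gives the atom area.
#'
#' @param s a `Structure`.
#' @param selection atoms to include (default: protein atoms; waters and
#'   heteroatoms excluded).
#' @param probe_radius solvent probe radius, angstrom (1.4 = water).
#' @param n_points sphere sample count (>= 24; 960 gives ~1-2% accuracy).
#' @return list of class `SASAResult`: `per_atom_area`, `per_residue_area`
#'   (named by residue key), `total`, `probe_radius`, `n_sphere_points`,
#'   `atom_index` (rows of `s$atoms` used).
#' @export
sasa <- function(s, selection = sel_protein(), probe_radius = 1.4, n_points = 960L) {
  if (n_points < 24L) stop("n_points must be >= 24")
  idx <- atom_select(s, selection)
  xyz <- coords(s)[idx, , drop = FALSE]
  radii <- vdw_radius(s$atoms$element[idx]) + probe_radius
  n <- length(idx)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  # neighbour lists from the full pairwise distance matrix (desk-scale n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    Ri <- radii[i]
    nb <- which(d2[i, ] < (Ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0L) { area[i] <- 4 * pi * Ri^2; next }
    p <- sweep(pts * Ri, 2, xyz[i, ], `+`)
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      dj <- p - matrix(xyz[j, ], n_points, 3, byrow = TRUE)
      buried <- buried | (rowSums(dj * dj) < radii[j]^2)
      if (all(buried)) break
    }
    area[i] <- 4 * pi * Ri^2 * sum(!buried) / n_points
  }
  keys <- residue_keys(s)[idx]
  per_res <- tapply(area, factor(keys, levels = unique(keys)), sum)
  structure(list(per_atom_area = area,
                 per_residue_area = per_res,
                 total = sum(area),
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_points),
                 atom_index = idx),
            class = "SASAResult")
}

#' Interface burial upon complexation
#'
#' Per-residue buried area dASA = ASA(isolated side) - ASA(in complex),
#' percent burial relative to the isolated side, and each residue's share of
#' its side's total buried area. Small negative numerical noise is clamped
#' to zero. Waters and heteroatoms are excluded.
#'
#' @param complex `Structure` holding both sides.
#' @param side_a,side_b `Selection`s partitioning the polymer atoms
#'   (overlap is an error).
#' @param probe_radius,n_points passed to [sasa()].
#' @return list of class `InterfaceReport` with a per-residue data.frame
#'   (`side`, `chain`, `resseq`, `resname`, `asa_isolated`, `asa_complex`,
#'   `buried`, `percent_burial`, `contribution`) and per-side totals.
#' @export
buried_interface <- function(complex, side_a, side_b, probe_radius = 1.4,
                             n_points = 960L) {
  pa <- sel_and_protein(side_a); pb <- sel_and_protein(side_b)
  ia <- atom_select(complex, pa); ib <- atom_select(complex, pb)
  if (length(intersect(ia, ib)) > 0L) stop("side selections overlap")
  both <- subset_structure(complex, NULL)
  both$atoms <- complex$atoms[sort(c(ia, ib)), , drop = FALSE]
  both <- Structure(both$atoms, complex$metadata)
  sa_cx <- sasa(both, sel_protein(), probe_radius, n_points)
  iso_a <- sasa(Structure(complex$atoms[ia, , drop = FALSE]), sel_protein(),
                probe_radius, n_points)
  iso_b <- sasa(Structure(complex$atoms[ib, , drop = FALSE]), sel_protein(),
                probe_radius, n_points)

  one_side <- function(iso, side_label) {
    res_iso <- iso$per_residue_area
    res_cx <- sa_cx$per_residue_area[names(res_iso)]
    res_cx[is.na(res_cx)] <- 0
    buried <- pmax(res_iso - res_cx, 0)
    parts <- strsplit(names(res_iso), "|", fixed = TRUE)
    data.frame(side = side_label,
               chain = vapply(parts, `[`, "", 1),
               resseq = as.integer(vapply(parts, `[`, "", 2)),
               resname = NA_character_,
               asa_isolated = as.numeric(res_iso),
               asa_complex = as.numeric(res_cx),
               buried = as.numeric(buried),
               percent_burial = ifelse(res_iso > 0, 100 * buried / res_iso, 0),
               stringsAsFactors = FALSE)
  }
  ta <- one_side(iso_a, "A"); tb <- one_side(iso_b, "B")
  ta$contribution <- if (sum(ta$buried) > 0) ta$buried / sum(ta$buried) else 0
  tb$contribution <- if (sum(tb$buried) > 0) tb$buried / sum(tb$buried) else 0
  tab <- rbind(ta, tb)
  # recover residue names from the complex
  rk <- residue_keys(complex)
  rn <- complex$atoms$resname[!duplicated(rk)]
  names(rn) <- rk[!duplicated(rk)]
  tab$resname <- rn[paste(tab$chain, tab$resseq, "", sep = "|")]
  structure(list(residues = tab,
                 total_buried_a = sum(ta$buried),
                 total_buried_b = sum(tb$buried),
                 asa_isolated_a = sum(ta$asa_isolated),
                 asa_isolated_b = sum(tb$asa_isolated),
                 asa_complex = sa_cx$total,
                 probe_radius = probe_radius),
            class = "InterfaceReport")
}

sel_and_protein <- function(selection) {
  if (is.null(selection$het)) selection$het <- FALSE
  selection
}

# donor/acceptor typing for standard residues; heavy-atom criteria
# (crystal structures carry no hydrogens). antecedent = bonded heavy atom
# used for the angle test.
hbond_table <- function() {
  d <- function(res, atom, ante) data.frame(res = res, atom = atom, ante = ante,
                                            stringsAsFactors = FALSE)
  donors <- rbind(
    d("*", "N", "CA"),     # backbone amide (proline excluded in match_role)
    d("ARG", "NE", "CD"), d("ARG", "NH1", "CZ"), d("ARG", "NH2", "CZ"),
    d("LYS", "NZ", "CE"), d("HIS", "ND1", "CG"), d("HIS", "NE2", "CE1"),
    d("ASN", "ND2", "CG"), d("GLN", "NE2", "CD"),
    d("SER", "OG", "CB"), d("THR", "OG1", "CB"), d("TYR", "OH", "CZ"),
    d("TRP", "NE1", "CE2"), d("CYS", "SG", "CB"), d("HOH", "O", NA))
  acceptors <- rbind(
    d("*", "O", NA), d("*", "OXT", NA),
    d("ASP", "OD1", NA), d("ASP", "OD2", NA),
    d("GLU", "OE1", NA), d("GLU", "OE2", NA),
    d("ASN", "OD1", NA), d("GLN", "OE1", NA),
    d("SER", "OG", NA), d("THR", "OG1", NA), d("TYR", "OH", NA),
    d("HIS", "ND1", NA), d("HIS", "NE2", NA), d("MET", "SD", NA),
    d("HOH", "O", NA))
  list(donors = donors, acceptors = acceptors)
}

match_role <- function(s, idx, table) {
  res <- s$atoms$resname[idx]; atm <- s$atoms$atom[idx]
  hit <- rep(FALSE, length(idx)); ante <- rep(NA_character_, length(idx))
  for (k in seq_len(nrow(table))) {
    sel_k <- (table$res[k] == "*" | res == table$res[k]) & atm == table$atom[k]
    # backbone N of proline has no H
    if (table$res[k] == "*" && table$atom[k] == "N") sel_k <- sel_k & res != "PRO"
    ante[sel_k & !hit] <- table$ante[k]
    hit <- hit | sel_k
  }
  list(hit = hit, ante = ante)
}

#' Geometric hydrogen-bond detection across an interface
#'
#' Heavy-atom criteria (no hydrogens in crystal structures): a donor N/O/S
#' bearing an implicit hydrogen and an acceptor N/O/S within `d_max`, and,
#' when the donor's bonded antecedent atom is present, an
#' antecedent-donor-acceptor angle of at least `angle_min` degrees. Both
#' directions across the interface are searched; output is sorted by distance.
#'
#' @param s `Structure` containing both sides.
#' @param side_a,side_b `Selection`s for the two sides.
#' @param d_max donor-acceptor distance cutoff, angstrom.
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees.
#' @param include_waters include water O as donor/acceptor (bridging waters).
#' @return data.frame: donor/acceptor chain, resseq, resname, atom, distance,
#'   angle (NA when no antecedent is defined), donor_side.
#' @export
find_hbonds <- function(s, side_a, side_b, d_max = 3.5, angle_min = 90,
                        include_waters = FALSE) {
  tabs <- hbond_table()
  pick <- function(selection) {
    if (!include_waters) selection <- sel_and_protein(selection)
    atom_select(s, selection, allow_empty = TRUE)
  }
  ia <- pick(side_a); ib <- pick(side_b)
  xyz <- coords(s)
  res <- list()
  one_direction <- function(idon, iacc, donor_side) {
    dn <- match_role(s, idon, tabs$donors)
    ac <- match_role(s, iacc, tabs$acceptors)
    di <- idon[dn$hit]; ante <- dn$ante[dn$hit]; aj <- iacc[ac$hit]
    if (length(di) == 0L || length(aj) == 0L) return(NULL)
    out <- list()
    for (k in seq_along(di)) {
      dvec <- xyz[aj, , drop = FALSE] -
        matrix(xyz[di[k], ], length(aj), 3, byrow = TRUE)
      dist <- sqrt(rowSums(dvec^2))
      ok <- which(dist <= d_max & dist > 0.5)
      if (length(ok) == 0L) next
      ang <- rep(NA_real_, length(ok))
      if (!is.na(ante[k])) {
        # antecedent: same residue, named atom
        arow <- which(residue_keys(s) == residue_keys(s)[di[k]] &
                        s$atoms$atom == ante[k])
        if (length(arow) == 1L) {
          v1 <- xyz[arow, ] - xyz[di[k], ]
          for (q in seq_along(ok)) {
            v2 <- xyz[aj[ok[q]], ] - xyz[di[k], ]
            ang[q] <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
              (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
          }
        }
      }
      pass <- is.na(ang) | ang >= angle_min
      for (q in which(pass)) {
        j <- aj[ok[q]]
        out[[length(out) + 1L]] <- data.frame(
          donor_chain = s$atoms$chain[di[k]], donor_resseq = s$atoms$resseq[di[k]],
          donor_resname = s$atoms$resname[di[k]], donor_atom = s$atoms$atom[di[k]],
          acceptor_chain = s$atoms$chain[j], acceptor_resseq = s$atoms$resseq[j],
          acceptor_resname = s$atoms$resname[j], acceptor_atom = s$atoms$atom[j],
          distance = dist[ok[q]], angle = ang[q], donor_side = donor_side,
          stringsAsFactors = FALSE)
      }
    }
    if (length(out) > 0L) do.call(rbind, out) else NULL
  }
  res <- rbind(one_direction(ia, ib, "A"), one_direction(ib, ia, "B"))
  if (is.null(res))
    return(data.frame(donor_chain = character(0), donor_resseq = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_resseq = integer(0),
                      acceptor_resname = character(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      donor_side = character(0)))
  res[order(res$distance), , drop = FALSE]
}

#' Salt-bridge detection across an interface
#'
#' Inter-side pairs of basic nitrogen (Lys NZ; Arg NH1/NH2/NE; optionally
#' His ND1/NE2) and acidic oxygen (Asp OD1/OD2; Glu OE1/OE2; C-terminal OXT)
#' within `d_max`, deduplicated to one bridge per residue pair (the closest
#' atom pair is reported).
#'
#' @inheritParams find_hbonds
#' @param d_max N-O distance cutoff, angstrom.
#' @param include_his count His imidazole nitrogens as basic.
#' @return data.frame: basic/acidic chain, resseq, resname, atom, distance.
#' @export
find_salt_bridges <- function(s, side_a, side_b, d_max = 4.0, include_his = FALSE) {
  basic <- data.frame(res = c("LYS", "ARG", "ARG", "ARG"),
                      atom = c("NZ", "NH1", "NH2", "NE"), stringsAsFactors = FALSE)
  if (include_his)
    basic <- rbind(basic, data.frame(res = c("HIS", "HIS"), atom = c("ND1", "NE2")))
  acidic <- data.frame(res = c("ASP", "ASP", "GLU", "GLU", "*"),
                       atom = c("OD1", "OD2", "OE1", "OE2", "OXT"),
                       stringsAsFactors = FALSE)
  ia <- atom_select(s, sel_and_protein(side_a), allow_empty = TRUE)
  ib <- atom_select(s, sel_and_protein(side_b), allow_empty = TRUE)
  pick <- function(idx, tab) {
    keep <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(tab)))
      keep <- keep | ((tab$res[k] == "*" | s$atoms$resname[idx] == tab$res[k]) &
                        s$atoms$atom[idx] == tab$atom[k])
    idx[keep]
  }
  xyz <- coords(s)
  pairs <- list()
  add_pairs <- function(ibase, iacid) {
    for (i in ibase) {
      dv <- xyz[iacid, , drop = FALSE] - matrix(xyz[i, ], length(iacid), 3, byrow = TRUE)
      dist <- sqrt(rowSums(dv^2))
      for (q in which(dist <= d_max))
        pairs[[length(pairs) + 1L]] <<- data.frame(
          basic_chain = s$atoms$chain[i], basic_resseq = s$atoms$resseq[i],
          basic_resname = s$atoms$resname[i], basic_atom = s$atoms$atom[i],
          acidic_chain = s$atoms$chain[iacid[q]],
          acidic_resseq = s$atoms$resseq[iacid[q]],
          acidic_resname = s$atoms$resname[iacid[q]],
          acidic_atom = s$atoms$atom[iacid[q]],
          distance = dist[q], stringsAsFactors = FALSE)
    }
  }
  add_pairs(pick(ia, basic), pick(ib, acidic))
  add_pairs(pick(ib, basic), pick(ia, acidic))
  if (length(pairs) == 0L)
    return(data.frame(basic_chain = character(0), basic_resseq = integer(0),
                      basic_resname = character(0), basic_atom = character(0),
                      acidic_chain = character(0), acidic_resseq = integer(0),
                      acidic_resname = character(0), acidic_atom = character(0),
                      distance = numeric(0)))
  tab <- do.call(rbind, pairs)
  key <- paste(tab$basic_chain, tab$basic_resseq, tab$acidic_chain, tab$acidic_resseq)
  tab <- tab[order(key, tab$distance), , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$basic_chain, tab$basic_resseq,
                               tab$acidic_chain, tab$acidic_resseq)), , drop = FALSE]
  tab[order(tab$distance), , drop = FALSE]
}
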