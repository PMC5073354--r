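AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# Kyte-Doolittle hydropathy (scaled to [-1,1]) and formal charge per residue
kd_scaled <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
               GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
               LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
               SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2) / 4.5
res_charge <- c(ARG = 1, LYS = 1, HIS = 0.5, ASP = -1, GLU = -1)

#' The 20 x 20 residue-pair contact potential
#'
#' Simplified pairwise statistical potential (model units, more negative =
#' more favourable): a hydrophobic-burial term, minus the product of the
#' residues' positive hydropathies, plus an electrostatic term, the product of
#' formal charges. Hydrophobic pairs and opposite charges are favourable, like
#' charges unfavourable, everything else near zero. It is symmetric and is
#' shipped as code, not fitted, so frustration indices are bit-reproducible.
#' The decoy z-score machinery defined on top of it is independent of the
#' particular table.
#'
#' @return named symmetric 20 x 20 matrix over the standard amino acids.
#' @export
contact_potential <- function() {
  h <- pmax(kd_scaled, 0)
  q <- ifelse(AA3 %in% names(res_charge), res_charge[AA3], 0)
  names(q) <- AA3
  M <- -outer(h, h) + outer(q, q)
  dimnames(M) <- list(AA3, AA3)
  M
}

# smooth distance switch: full weight inside r_on, cosine roll-off to 0 at r_off
distance_switch <- function(d, r_on = 6.5, r_off = 9.5) {
  w <- numeric(length(d))
  w[d <= r_on] <- 1
  mid <- d > r_on & d < r_off
  w[mid] <- 0.5 * (1 + cos(pi * (d[mid] - r_on) / (r_off - r_on)))
  w
}

#' Pairwise contact energy
#'
#' Table value from [contact_potential()] modulated by a smooth distance well:
#' full weight up to `r_on`, cosine switch to zero at `r_off`, zero beyond.
#'
#' @param res_i,res_j 3-letter residue codes.
#' @param distance centre-centre distance, angstrom.
#' @param r_on,r_off switch-on/off distances, angstrom.
#' @return energy in model units.
#' @export
contact_energy <- function(res_i, res_j, distance, r_on = 6.5, r_off = 9.5) {
  M <- contact_potential()
  if (!all(res_i %in% AA3) || !all(res_j %in% AA3))
    stop("unknown residue type: ",
         paste(setdiff(c(res_i, res_j), AA3), collapse = ", "))
  M[cbind(res_i, res_j)] * distance_switch(distance, r_on, r_off)
}

#' Residue contact list
#'
#' One interaction centre per residue (Cbeta; Calpha for glycine or when no
#' Cbeta is present). All residue pairs with centre distance <= `cutoff` and
#' sequence separation >= `min_seq_sep` (pairs on different chains always
#' qualify on separation).
#'
#' @param s a `Structure`.
#' @param cutoff centre distance cutoff, angstrom.
#' @param min_seq_sep minimum |i - j| in residue order along a chain.
#' @return data.frame: `i`, `j` (residue ordinals, i < j), `chain_i`,
#'   `resseq_i`, `resname_i`, likewise for j, `distance`.
#' @export
build_contacts <- function(s, cutoff = 9.5, min_seq_sep = 3L) {
  prot <- atom_select(s, sel_protein())
  keys <- residue_keys(s)[prot]
  ukeys <- unique(keys)
  centers <- matrix(NA_real_, length(ukeys), 3)
  info <- data.frame(chain = character(length(ukeys)),
                     resseq = integer(length(ukeys)),
                     resname = character(length(ukeys)), stringsAsFactors = FALSE)
  xyz <- coords(s)
  for (r in seq_along(ukeys)) {
    rows <- prot[keys == ukeys[r]]
    info$chain[r] <- s$atoms$chain[rows[1]]
    info$resseq[r] <- s$atoms$resseq[rows[1]]
    info$resname[r] <- s$atoms$resname[rows[1]]
    cb <- rows[s$atoms$atom[rows] == "CB"]
    ca <- rows[s$atoms$atom[rows] == "CA"]
    pick <- if (info$resname[r] != "GLY" && length(cb) == 1L) cb
            else if (length(ca) == 1L) ca else rows[1]
    centers[r, ] <- xyz[pick, ]
  }
  n <- length(ukeys)
  d <- as.matrix(stats::dist(centers))
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (d[i, j] > cutoff) next
    if (info$chain[i] == info$chain[j] && (j - i) < min_seq_sep) next
    out[[length(out) + 1L]] <- data.frame(
      i = i, j = j, chain_i = info$chain[i], resseq_i = info$resseq[i],
      resname_i = info$resname[i], chain_j = info$chain[j],
      resseq_j = info$resseq[j], resname_j = info$resname[j],
      distance = d[i, j], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(i = integer(0), j = integer(0), chain_i = character(0),
                      resseq_i = integer(0), resname_i = character(0),
                      chain_j = character(0), resseq_j = integer(0),
                      resname_j = character(0), distance = numeric(0)))
  do.call(rbind, out)
}

#' Mutational frustration index of contacts
#'
#' For each contact the two residue identities are mutated to decoys drawn
#' uniformly over the 20 amino-acid types, energies recomputed at fixed
#' geometry, and the native energy compared with the decoy distribution:
#' F_ij = (mean(E_decoy) - E_native) / sd(E_decoy). Sign convention: larger F
#' means the native pair is more favourable than typical decoys (minimal
#' frustration); strongly negative F marks an unfavourable, highly frustrated
#' native contact. With `exhaustive = TRUE` all 400 identity pairs are
#' enumerated instead of sampled (no randomness). If the decoy energies are
#' degenerate (sd = 0) F is undefined and reported as NA with a warning; such
#' contacts classify as neutral.
#'
#' @param contacts data.frame from [build_contacts()].
#' @param n_decoys decoy count per contact (>= 100) when sampling.
#' @param seed RNG seed (sampling mode; required for reproducibility).
#' @param exhaustive enumerate all 400 decoy identity pairs.
#' @param r_on,r_off passed to [contact_energy()].
#' @return `contacts` with columns `native_energy` and `frustration` added.
#' @export
mutational_frustration <- function(contacts, n_decoys = 1000L, seed = 1L,
                                   exhaustive = FALSE, r_on = 6.5, r_off = 9.5) {
  if (!exhaustive && n_decoys < 100L) stop("n_decoys must be >= 100")
  M <- contact_potential()
  ener <- as.numeric(M)            # all 400 ordered pairs
  contacts$native_energy <- contact_energy(contacts$resname_i, contacts$resname_j,
                                           contacts$distance, r_on, r_off)
  F <- numeric(nrow(contacts))
  warned <- FALSE
  if (!exhaustive) set.seed(seed)
  for (k in seq_len(nrow(contacts))) {
    w <- distance_switch(contacts$distance[k], r_on, r_off)
    ed <- if (exhaustive) ener * w
          else M[cbind(sample(AA3, n_decoys, TRUE), sample(AA3, n_decoys, TRUE))] * w
    sdv <- stats::sd(ed)
    if (!is.finite(sdv) || sdv == 0) {
      F[k] <- NA_real_; warned <- TRUE
    } else {
      F[k] <- (mean(ed) - contacts$native_energy[k]) / sdv
    }
  }
  if (warned)
    warning("degenerate decoy energies for some contacts; F undefined, treated as neutral")
  contacts$frustration <- F
  contacts
}

#' Classify frustration indices
#'
#' `minimal` when F >= `minimal_threshold` (native clearly more favourable
#' than decoys), `high` when F <= `high_threshold`, otherwise `neutral`
#' (undefined F is neutral). Thresholds default to the published
#' frustratometer convention (+0.78 / -1).
#'
#' @param F numeric frustration indices.
#' @param minimal_threshold,high_threshold class boundaries.
#' @return character vector in {"minimal", "neutral", "high"}.
#' @export
classify_frustration <- function(F, minimal_threshold = 0.78, high_threshold = -1) {
  out <- rep("neutral", length(F))
  out[!is.na(F) & F >= minimal_threshold] <- "minimal"
  out[!is.na(F) & F <= high_threshold] <- "high"
  out
}

#' Build the full frustration network of a structure
#'
#' Contacts, frustration indices, classes and class fractions in one object.
#'
#' @param s a `Structure`.
#' @inheritParams build_contacts
#' @inheritParams mutational_frustration
#' @inheritParams classify_frustration
#' @return list of class `FrustrationNetwork`: `contacts` (with `frustration`
#'   and `class` columns), `fractions`, `thresholds`, `n_decoys`, `seed`.
#' @export
frustration_network <- function(s, cutoff = 9.5, min_seq_sep = 3L,
                                n_decoys = 1000L, seed = 1L, exhaustive = FALSE,
                                minimal_threshold = 0.78, high_threshold = -1) {
  ct <- build_contacts(s, cutoff, min_seq_sep)
  ct <- mutational_frustration(ct, n_decoys, seed, exhaustive)
  ct$class <- classify_frustration(ct$frustration, minimal_threshold, high_threshold)
  fr <- table(factor(ct$class, levels = c("minimal", "neutral", "high"))) / max(nrow(ct), 1L)
  structure(list(contacts = ct, fractions = as.numeric(fr),
                 thresholds = c(minimal = minimal_threshold, high = high_threshold),
                 n_decoys = if (exhaustive) 400L else as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "FrustrationNetwork")
}

#' @export
print.FrustrationNetwork <- function(x, ...) {
  cat("FrustrationNetwork:", nrow(x$contacts), "contacts; fractions",
      sprintf("minimal %.2f neutral %.2f high %.2f", x$fractions[1],
              x$fractions[2], x$fractions[3]), "\n")
  invisible(x)
}

#' Path through highly frustrated contacts between two sites
#'
#' Builds a graph whose nodes are residues and whose edges are the contacts
#' classified `high`, then finds the shortest path (fewest edges) between any
#' residue of `site_a` and any residue of `site_b`; ties are broken in favour
#' of the largest summed |F| (the most strongly frustrated route). Traces
#' candidate exosite-to-active-site communication routes.
#'
#' @param net a `FrustrationNetwork`.
#' @param site_a,site_b integer residue numbers (non-empty).
#' @return list: `found` (logical), `path` (residue numbers along the route,
#'   or NULL), `n_edges`, `sum_absF`.
#' @export
frustration_path <- function(net, site_a, site_b) {
  if (length(site_a) == 0L || length(site_b) == 0L)
    stop("site sets must be non-empty")
  hc <- net$contacts[net$contacts$class == "high", , drop = FALSE]
  no_path <- list(found = FALSE, path = NULL, n_edges = NA_integer_,
                  sum_absF = NA_real_)
  if (nrow(hc) == 0L) return(no_path)
  verts <- as.character(sort(unique(c(hc$resseq_i, hc$resseq_j))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(hc$resseq_i), to = as.character(hc$resseq_j)),
    directed = FALSE, vertices = verts)
  absF <- abs(hc$frustration)
  # edge-count primary, summed |F| secondary (maximised):
  # weight = 1 - |F|/K with K large enough that total |F| can never buy an edge
  K <- (max(absF) + 1) * (nrow(hc) + 1)
  igraph::E(g)$weight <- 1 - absF / K
  sa <- intersect(as.character(site_a), verts)
  sb <- intersect(as.character(site_b), verts)
  if (length(sa) == 0L || length(sb) == 0L) return(no_path)
  best <- NULL
  for (u in sa) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = u, to = sb, output = "both"))
    for (k in seq_along(sp$vpath)) {
      vp <- sp$vpath[[k]]
      if (length(vp) == 0L) next
      wsum <- sum(igraph::E(g)$weight[as.integer(sp$epath[[k]])])
      if (is.null(best) || wsum < best$wsum)
        best <- list(vpath = vp, wsum = wsum,
                     sum_absF = sum(absF[as.integer(sp$epath[[k]])]))
    }
  }
  if (is.null(best)) return(no_path)
  path <- as.integer(igraph::as_ids(best$vpath))
  list(found = TRUE, path = path, n_edges = length(path) - 1L,
       sum_absF = best$sum_absF)
}
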