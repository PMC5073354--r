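# shared helpers: tiny structures, rigid transforms, independent oracles

atom_row <- function(chain, resseq, resname, atom, x, y, z, element,
                     b = 10, occ = 1, het = FALSE, altloc = "") {
  data.frame(chain = chain, resseq = resseq, icode = "", resname = resname,
             atom = atom, altloc = altloc, x = x, y = y, z = z, occ = occ,
             b = b, element = element, het = het, stringsAsFactors = FALSE)
}

structure_from_coords <- function(xyz, element = "C", atom = "CA",
                                  resname = "ALA", chain = "A") {
  n <- nrow(xyz)
  Structure(do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(chain, i, resname, atom, xyz[i, 1], xyz[i, 2], xyz[i, 3], element))))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, byrow = TRUE)
}

apply_random_rigid <- function(s) {
  R <- random_rotation(); t <- stats::rnorm(3, 0, 10)
  set_coords(s, sweep(coords(s) %*% R, 2, t, `+`))
}

# independent superposition oracle: minimise RMSD over Euler angles by
# multi-start Nelder-Mead (never calls the SVD path)
brute_force_rmsd <- function(P, Q, n_starts = 24) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  best <- Inf
  set.seed(99)
  for (k in seq_len(n_starts)) {
    a0 <- stats::runif(3, -pi, pi)
    o <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 5000))
    best <- min(best, o$value)
  }
  best
}

# exhaustive-run oracle for segment detection: residues in qualifying runs
segment_residues_oracle <- function(resseq, dev, threshold, min_len) {
  qual <- dev > threshold
  out <- integer(0)
  i <- 1
  n <- length(resseq)
  while (i <= n) {
    if (!qual[i]) { i <- i + 1; next }
    j <- i
    while (j < n && qual[j + 1] && resseq[j + 1] == resseq[j] + 1) j <- j + 1
    if (j - i + 1 >= min_len) out <- c(out, resseq[i:j])
    i <- j + 1
  }
  out
}

# plain breadth-first search oracle for unweighted shortest path length
bfs_path_length <- function(edges, from_set, to_set) {
  nodes <- unique(c(edges$a, edges$b))
  adj <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  from_set <- intersect(from_set, nodes); to_set <- intersect(to_set, nodes)
  if (length(from_set) == 0 || length(to_set) == 0) return(NA_integer_)
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  queue <- as.character(from_set); dist[queue] <- 0L
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    if (u %in% as.character(to_set)) return(dist[[u]])
    for (v in adj[[u]]) {
      v <- as.character(v)
      if (is.na(dist[[v]])) { dist[[v]] <- dist[[u]] + 1L; queue <- c(queue, v) }
    }
  }
  NA_integer_
}

# naive O(N*M) clash oracle, independent double loop
clash_count_oracle <- function(receptor, ligand, overlap_min, whitelist = NULL) {
  rx <- coords(receptor); lx <- coords(ligand)
  rr <- allopath::vdw_radius(receptor$atoms$element)
  rl <- allopath::vdw_radius(ligand$atoms$element)
  rk <- paste(receptor$atoms$chain, receptor$atoms$resseq, receptor$atoms$icode,
              receptor$atoms$atom, sep = "|")
  lk <- paste(ligand$atoms$chain, ligand$atoms$resseq, ligand$atoms$icode,
              ligand$atoms$atom, sep = "|")
  wl <- if (is.null(whitelist)) character(0)
        else paste(whitelist$receptor_key, whitelist$ligand_key)
  n <- 0L
  for (i in seq_len(nrow(rx))) for (j in seq_len(nrow(lx))) {
    d <- sqrt(sum((rx[i, ] - lx[j, ])^2))
    if (d < rr[i] + rl[j] - overlap_min && !(paste(rk[i], lk[j]) %in% wl))
      n <- n + 1L
  }
  n
}

# all pairwise distances between two coordinate sets (rows x rows)
proxy_crossdist <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(nrow(B)))
    out[, j] <- sqrt(rowSums((A - matrix(B[j, ], nrow(A), 3, byrow = TRUE))^2))
  out
}
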