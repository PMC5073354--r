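#' Build an anisotropic elastic-network Hessian
#'
#' Calpha anisotropic network model (ANM): every Calpha pair within `cutoff`
#' is joined by a Hookean spring of stiffness `gamma`. The 3N x 3N Hessian has
#' off-diagonal 3x3 superelements -gamma (r_ij x r_ij^T)/|r_ij|^2 and diagonal
#' superelements equal to minus the sum of the row's off-diagonals, so rigid
#' translations are exact zero modes. This coarse-grained surrogate stands in
#' for all-atom force-field normal modes: the low-frequency subspaces of the
#' two are known to overlap strongly, and every downstream quantity
#' (variance fractions, projections, cross-correlations) is model-generic.
#'
#' @param s a `Structure` (>= 7 Calpha nodes) or an n x 3 matrix of node
#'   coordinates.
#' @param cutoff pair cutoff, angstrom (default 15, a standard ANM choice).
#' @param gamma uniform spring constant, model units.
#' @return 3N x 3N symmetric matrix with attributes `nodes` (data.frame:
#'   chain, resseq), `cutoff`, `gamma`, `xyz`.
#' @export
build_enm <- function(s, cutoff = 15, gamma = 1) {
  if (inherits(s, "Structure")) {
    idx <- atom_select(s, sel_calpha())
    xyz <- coords(s)[idx, , drop = FALSE]
    nodes <- data.frame(chain = s$atoms$chain[idx], resseq = s$atoms$resseq[idx],
                        stringsAsFactors = FALSE)
  } else {
    xyz <- as.matrix(s)
    nodes <- data.frame(chain = "A", resseq = seq_len(nrow(xyz)))
  }
  n <- nrow(xyz)
  if (n < 4L) stop("need at least 4 non-degenerate nodes")
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= cutoff & d > 0
  # connectivity check with component listing
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))
  if (comp$no > 1L) {
    sizes <- table(comp$membership)
    stop("elastic network is disconnected at cutoff ", cutoff, " A: ",
         comp$no, " components of sizes ", paste(sizes, collapse = ", "))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1L)) {
    for (j in which(adj[i, ] & seq_len(n) > i)) {
      rij <- xyz[j, ] - xyz[i, ]
      block <- -gamma * tcrossprod(rij) / sum(rij^2)
      bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
      H[bi, bj] <- block; H[bj, bi] <- block
      H[bi, bi] <- H[bi, bi] - block; H[bj, bj] <- H[bj, bj] - block
    }
  }
  attr(H, "nodes") <- nodes; attr(H, "cutoff") <- cutoff
  attr(H, "gamma") <- gamma; attr(H, "xyz") <- xyz
  H
}

#' Diagonalize an elastic-network Hessian
#'
#' Eigenvalues are returned ascending. Modes are numbered including the six
#' rigid-body (near-zero) modes, so the first internal mode is mode 7 and
#' "mode 8" is the second internal mode. A connected network must yield
#' exactly six near-zero eigenvalues; anything else is an error.
#'
#' @param h Hessian from [build_enm()].
#' @param n_modes number of internal modes to retain (default 100, capped at
#'   3N - 6).
#' @param zero_tol relative tolerance for classifying zero modes.
#' @return list of class `ModeSet`: `values` (ascending, all computed),
#'   `vectors` (3N x kept columns, orthonormal), `mode_numbers` (global mode
#'   indices of kept columns, starting at 7), `n_zero`, `nodes`, `cutoff`,
#'   `gamma`, `xyz`.
#' @export
enm_modes <- function(h, n_modes = 100L, zero_tol = 1e-8) {
  eig <- eigen(h, symmetric = TRUE)
  values <- rev(eig$values); vectors <- eig$vectors[, rev(seq_len(ncol(eig$vectors)))]
  n3 <- length(values)
  if (n_modes > n3) stop("n_modes exceeds 3N = ", n3)
  scale_ref <- max(abs(values))
  n_zero <- sum(abs(values) < zero_tol * scale_ref)
  if (n_zero != 6L)
    stop("expected exactly 6 near-zero modes for a connected network, found ",
         n_zero)
  if (any(values < -zero_tol * scale_ref))
    stop("Hessian is not positive semi-definite")
  keep <- seq(n_zero + 1L, min(n_zero + n_modes, n3))
  structure(list(values = values,
                 vectors = vectors,
                 mode_numbers = keep,
                 internal_values = values[keep],
                 internal_vectors = vectors[, keep, drop = FALSE],
                 n_zero = n_zero,
                 nodes = attr(h, "nodes"), cutoff = attr(h, "cutoff"),
                 gamma = attr(h, "gamma"), xyz = attr(h, "xyz")),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat("ModeSet:", nrow(x$nodes), "nodes,", length(x$internal_values),
      "internal modes kept (numbered from 7),", x$n_zero, "rigid-body modes\n")
  invisible(x)
}

# columns of the full eigenvector matrix for global mode numbers
mode_columns <- function(m, mode_index) {
  if (any(mode_index <= m$n_zero))
    stop("mode index <= ", m$n_zero, " refers to a rigid-body mode")
  if (any(mode_index > length(m$values)))
    stop("mode index exceeds 3N")
  mode_index
}

#' Fraction of thermal variance carried by the first k internal modes
#'
#' With thermal-amplitude weighting each internal mode contributes variance
#' proportional to 1/lambda. The fraction is
#' sum(1/lambda, modes 7..6+k) / sum(1/lambda, all internal modes). Set
#' `weighting = "equal"` to count modes without amplitude weighting.
#'
#' @param m a `ModeSet`.
#' @param k number of low-frequency internal modes.
#' @param weighting `"thermal"` (1/lambda, default) or `"equal"`.
#' @return fraction in [0, 1].
#' @export
variance_fraction <- function(m, k, weighting = c("thermal", "equal")) {
  weighting <- match.arg(weighting)
  internal <- m$values[-seq_len(m$n_zero)]
  if (k > length(internal)) stop("k exceeds the number of internal modes")
  if (k == 0L) return(0)
  w <- if (weighting == "thermal") 1 / internal else rep(1, length(internal))
  sum(w[seq_len(k)]) / sum(w)
}

#' Per-node mean-square fluctuations from normal modes
#'
#' MSF_i = sum over the first `n_modes` internal modes of |v_k(i)|^2 / lambda_k
#' (the classical thermal amplitude, uniform masses). Rigid-body modes never
#' contribute.
#'
#' @param m a `ModeSet`.
#' @param n_modes internal mode count (default: all kept).
#' @return numeric vector, one value per node, model units.
#' @export
mode_fluctuations <- function(m, n_modes = length(m$internal_values)) {
  if (n_modes < 1L) stop("n_modes must be >= 1")
  if (n_modes > length(m$internal_values))
    stop("n_modes exceeds the ", length(m$internal_values), " kept internal modes")
  n <- nrow(m$nodes)
  msf <- numeric(n)
  for (k in seq_len(n_modes)) {
    v <- matrix(m$internal_vectors[, k], ncol = 3, byrow = TRUE)
    msf <- msf + rowSums(v^2) / m$internal_values[k]
  }
  msf
}

#' Project ensemble conformations onto normal modes
#'
#' Each frame is Kabsch-superposed onto the reference on the mode nodes
#' (removing rigid-body degrees of freedom), then the displacement from the
#' reference is projected onto each requested eigenvector. Projecting the
#' reference conformation itself gives zero on every mode.
#'
#' @param e an `Ensemble` whose topology contains the mode nodes' Calphas.
#' @param m a `ModeSet`.
#' @param modes global mode numbers (>= 7; e.g. `7:11` for the first five
#'   internal modes).
#' @param reference `Structure` providing reference node coordinates
#'   (default: the conformation the modes were built from).
#' @return matrix frames x modes of class `ProjectionSet` (columns named
#'   `mode7`, ...), projection coordinates in angstrom * mode units.
#' @export
project_ensemble <- function(e, m, modes = 7:11, reference = NULL) {
  cols <- mode_columns(m, modes)
  ref_xyz <- if (is.null(reference)) m$xyz else {
    idx <- atom_select(reference, sel_calpha())
    coords(reference)[idx, , drop = FALSE]
  }
  idx_e <- atom_select(e$topology, sel_calpha())
  if (length(idx_e) != nrow(ref_xyz) || length(idx_e) != nrow(m$nodes))
    stop("node mismatch: ensemble Calphas do not map onto mode nodes")
  V <- m$vectors[, cols, drop = FALSE]
  out <- matrix(NA_real_, length(e$frames), length(cols),
                dimnames = list(NULL, paste0("mode", modes)))
  for (f in seq_along(e$frames)) {
    xyz <- e$frames[[f]][idx_e, , drop = FALSE]
    fit <- kabsch_superpose(xyz, ref_xyz)
    disp <- as.numeric(t(apply_transform(xyz, fit) - ref_xyz))
    out[f, ] <- as.numeric(crossprod(V, disp))
  }
  class(out) <- c("ProjectionSet", class(out))
  out
}

#' Population shift between two projected ensembles
#'
#' Per mode: difference of means, pooled-standard-deviation effect size
#' (Cohen's d) and a two-sample Welch t-test p-value; modes ranked by absolute
#' effect size. Detects an equilibrium-population shift along a collective
#' mode between two conditions (e.g. apo vs metal-bound).
#'
#' @param p_a,p_b `ProjectionSet`s over the same modes.
#' @return data.frame sorted by |effect|: `mode`, `mean_a`, `mean_b`,
#'   `mean_shift`, `effect_size`, `p_value`.
#' @export
population_shift <- function(p_a, p_b) {
  if (!identical(colnames(p_a), colnames(p_b)))
    stop("projection sets cover different modes")
  if (nrow(p_a) < 10L || nrow(p_b) < 10L)
    warning("fewer than 10 frames in a set: shift estimates are unstable")
  out <- lapply(colnames(p_a), function(cn) {
    x <- p_a[, cn]; y <- p_b[, cn]
    sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    es <- if (sp > 0) (mean(y) - mean(x)) / sp else 0
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else stats::t.test(x, y)$p.value
    data.frame(mode = as.integer(sub("mode", "", cn)), mean_a = mean(x),
               mean_b = mean(y), mean_shift = mean(y) - mean(x),
               effect_size = es, p_value = p)
  })
  out <- do.call(rbind, out)
  out[order(-abs(out$effect_size)), , drop = FALSE]
}

#' Mode-based dynamical cross-correlation matrix
#'
#' C(i,j) = sum_k v_k(i) . v_k(j) / lambda_k over the first `n_modes` internal
#' modes, normalised by sqrt(MSF_i * MSF_j), so the diagonal is exactly 1 and
#' entries lie in [-1, 1]. Invariant to a uniform spring-constant rescaling.
#'
#' @param m a `ModeSet`.
#' @param n_modes internal modes used (default: all kept; 100 and 40 are the
#'   conventional choices for whole-protein maps).
#' @return N x N symmetric matrix of class `DCCMatrix` with attribute
#'   `n_modes`; row/col names are node residue numbers.
#' @export
dcc <- function(m, n_modes = length(m$internal_values)) {
  if (n_modes < 1L || n_modes > length(m$internal_values))
    stop("n_modes out of range")
  n <- nrow(m$nodes)
  C <- matrix(0, n, n)
  for (k in seq_len(n_modes)) {
    v <- matrix(m$internal_vectors[, k], ncol = 3, byrow = TRUE)
    C <- C + tcrossprod(v) / m$internal_values[k]
  }
  d <- sqrt(diag(C))
  C <- C / tcrossprod(d)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(m$nodes$resseq, m$nodes$resseq)
  attr(C, "n_modes") <- as.integer(n_modes)
  class(C) <- c("DCCMatrix", class(C))
  C
}
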