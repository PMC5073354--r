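#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `target` via singular value
#' decomposition, constrained to a proper rotation (determinant +1;
#' reflections are disallowed, as required for chiral molecules).
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param target n x 3 coordinate matrix to fit onto.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3x3, applied on the right: `x %*% rotation`),
#'   `translation` (length-3), and `rmsd` (angstrom, weighted). The fitted
#'   coordinates are `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3L || ncol(target) != 3L)
    stop("point-count mismatch: ", nrow(mobile), " vs ", nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 points for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); ct <- colSums(target * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  # guard against degenerate (all-collinear) inputs: two near-zero singular values
  if (sv$d[2] <= 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate point set (collinear): rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # right-multiplication convention: P %*% R ~ Q
  fitted <- P %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(ct - cm %*% R), rmsd = rmsd)
}

#' Apply a rigid transform
#' @param xyz n x 3 matrix.
#' @param fit result of [kabsch_superpose()].
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, `+`)
}

#' Match atoms of two structures by identity keys
#'
#' Atoms are paired on (chain, residue number, insertion code, atom name).
#' Mismatches are never dropped silently: by default unmatched atoms raise an
#' error carrying a pairing report; set `on_unmatched = "exclude"` to proceed
#' with the common subset (the exclusions are attached as an attribute).
#'
#' @param a,b `Structure`s.
#' @param selection optional `Selection` applied to both.
#' @param on_unmatched `"error"` (default) or `"exclude"`.
#' @return data.frame with columns `ia`, `ib` (row indices into the atom
#'   tables), attribute `unmatched` listing keys present on one side only.
#' @export
match_atoms <- function(a, b, selection = NULL, on_unmatched = c("error", "exclude")) {
  on_unmatched <- match.arg(on_unmatched)
  ia <- atom_select(a, selection); ib <- atom_select(b, selection)
  key <- function(s, i) paste(s$atoms$chain[i], s$atoms$resseq[i],
                              s$atoms$icode[i], s$atoms$atom[i], sep = "|")
  ka <- key(a, ia); kb <- key(b, ib)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("duplicate atom keys (unresolved altlocs?); resolve altlocs first")
  common <- intersect(ka, kb)
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  if ((length(only_a) > 0L || length(only_b) > 0L) && on_unmatched == "error") {
    stop("unmatched atoms between structures: ",
         length(only_a), " only in first (e.g. ",
         paste(utils::head(only_a, 3), collapse = ", "), "), ",
         length(only_b), " only in second (e.g. ",
         paste(utils::head(only_b, 3), collapse = ", "),
         "); pass on_unmatched = \"exclude\" to drop them explicitly")
  }
  pos_a <- ia[match(common, ka)]; pos_b <- ib[match(common, kb)]
  ord <- order(pos_a)
  out <- data.frame(ia = pos_a[ord], ib = pos_b[ord])
  attr(out, "unmatched") <- list(only_a = only_a, only_b = only_b)
  out
}

#' RMSD between two structures
#'
#' @param a,b `Structure`s with atoms matchable by identity keys.
#' @param selection `Selection` (default: backbone N, CA, C, O).
#' @param superpose if `TRUE` (default) Kabsch-fit `a` onto `b` first; if
#'   `FALSE` compute the raw coordinate RMSD.
#' @param on_unmatched see [match_atoms()].
#' @return RMSD in angstrom.
#' @export
rmsd_between <- function(a, b, selection = sel_backbone(), superpose = TRUE,
                         on_unmatched = "error") {
  m <- match_atoms(a, b, selection, on_unmatched)
  pa <- coords(a)[m$ia, , drop = FALSE]; pb <- coords(b)[m$ib, , drop = FALSE]
  if (superpose) {
    kabsch_superpose(pa, pb)$rmsd
  } else {
    sqrt(mean(rowSums((pa - pb)^2)))
  }
}

#' Per-residue and mean B-factors
#'
#' `normalize = TRUE` z-scores atom B-factors within the structure
#' ((B - mean)/sd over the selection), the within-structure normalisation used
#' when comparing flexibility across crystal structures refined at different
#' resolutions.
#'
#' @param s a `Structure`.
#' @param selection `Selection` (default: protein atoms, i.e. ATOM records,
#'   excluding waters and heteroatoms).
#' @param normalize z-score within the structure.
#' @return list with `per_atom` (named by atom row), `per_residue` (mean over
#'   each residue's selected atoms), and `mean` (arithmetic mean of atom B over
#'   the selection; on the raw scale even when `normalize = TRUE`).
#' @export
bfactor_stats <- function(s, selection = sel_protein(), normalize = FALSE) {
  idx <- atom_select(s, selection)
  bv <- s$atoms$b[idx]
  m <- mean(bv)
  vals <- bv
  if (normalize) {
    sdv <- sqrt(mean((bv - m)^2))   # population sd: z-scores have sd exactly 1
    if (!is.finite(sdv) || sdv == 0)
      stop("cannot normalize: B-factor standard deviation is zero")
    vals <- (bv - m) / sdv
  }
  keys <- residue_keys(s)[idx]
  per_res <- tapply(vals, factor(keys, levels = unique(keys)), mean)
  list(per_atom = vals, per_residue = per_res, mean = m)
}
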