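#' Per-residue Calpha deviation profile
#'
#' One global backbone (N, CA, C, O) Kabsch superposition over all shared
#' residues, then the Calpha-Calpha distance per shared residue. The fit never
#' uses a subset of residues, so segment calls downstream are not circular.
#'
#' @param query,reference `Structure`s sharing residues with Calpha atoms.
#' @return data.frame of class `DeviationProfile`: `chain`, `resseq`, `icode`,
#'   `deviation` (angstrom), ordered along the chain.
#' @export
deviation_profile <- function(query, reference) {
  m_bb <- match_atoms(query, reference, sel_backbone(), on_unmatched = "exclude")
  n_res_shared <- length(unique(residue_keys(query)[m_bb$ia]))
  if (n_res_shared < 10L)
    stop("fewer than 10 shared residues: global alignment would be unstable")
  fit <- kabsch_superpose(coords(query)[m_bb$ia, ], coords(reference)[m_bb$ib, ])
  m_ca <- match_atoms(query, reference, sel_calpha(), on_unmatched = "exclude")
  qa <- apply_transform(coords(query)[m_ca$ia, , drop = FALSE], fit)
  ra <- coords(reference)[m_ca$ib, , drop = FALSE]
  dev <- sqrt(rowSums((qa - ra)^2))
  out <- data.frame(chain = query$atoms$chain[m_ca$ia],
                    resseq = query$atoms$resseq[m_ca$ia],
                    icode = query$atoms$icode[m_ca$ia],
                    deviation = dev, stringsAsFactors = FALSE)
  class(out) <- c("DeviationProfile", class(out))
  out
}

#' Find segments of consecutive deviating residues
#'
#' Maximal runs of consecutive residues (adjacent in chain, no numbering gap;
#' chain breaks and missing residues terminate runs) whose deviation is
#' strictly greater than `threshold`, of length at least `min_len`. Defaults
#' are the 0.5 angstrom / 3 residue rule used for calling ligand-associated
#' conformational change.
#'
#' @param profile a `DeviationProfile`.
#' @param threshold deviation threshold, angstrom.
#' @param min_len minimum run length, residues.
#' @return data.frame: `chain`, `start`, `end`, `length`, `mean_dev`, `max_dev`.
#' @export
find_segments <- function(profile, threshold = 0.5, min_len = 3L) {
  if (nrow(profile) == 0L) stop("empty deviation profile")
  out <- list()
  ord <- order(profile$chain, profile$resseq)
  p <- profile[ord, , drop = FALSE]
  run_start <- NULL
  flush <- function(i_end) {
    if (is.null(run_start)) return()
    len <- i_end - run_start + 1L
    if (len >= min_len) {
      seg <- p[run_start:i_end, ]
      out[[length(out) + 1L]] <<- data.frame(
        chain = seg$chain[1], start = seg$resseq[1], end = seg$resseq[len],
        length = len, mean_dev = mean(seg$deviation), max_dev = max(seg$deviation),
        stringsAsFactors = FALSE)
    }
    run_start <<- NULL
  }
  for (i in seq_len(nrow(p))) {
    qualifies <- p$deviation[i] > threshold
    contiguous <- i > 1L && p$chain[i] == p$chain[i - 1L] &&
      p$resseq[i] == p$resseq[i - 1L] + 1L
    if (qualifies) {
      if (is.null(run_start)) run_start <- i
      else if (!contiguous) { flush(i - 1L); run_start <- i }
    } else flush(i - 1L)
  }
  flush(nrow(p))
  if (length(out) == 0L)
    return(data.frame(chain = character(0), start = integer(0), end = integer(0),
                      length = integer(0), mean_dev = numeric(0), max_dev = numeric(0)))
  do.call(rbind, out)
}

#' Classify deviating segments as ligand-associated, shared, or indeterminate
#'
#' For each segment found in the query-vs-reference profile, the same
#' residues' deviations in a third structure (unliganded active site) vs the
#' reference are taken as control, and a two-tailed Welch t-test compares the
#' two sets. Verdicts: `shared` when the third structure also exceeds
#' `threshold` on average over the segment; `ligand-associated` when
#' p < `alpha` and the query segment deviates more than the control; otherwise
#' `indeterminate`.
#'
#' @param segments output of [find_segments()] on `query_vs_ref`.
#' @param query_vs_ref,third_vs_ref `DeviationProfile`s against one reference.
#' @param alpha significance level.
#' @param threshold deviation threshold (for the `shared` verdict), angstrom.
#' @param p_adjust `"none"` (default: one t-test per segment) or
#'   `"bonferroni"` (multiply p-values by the segment count) for
#'   multi-segment scans.
#' @return data.frame of class `SegmentCall`: segment columns plus
#'   `mean_dev_third`, `p_value`, `verdict`.
#' @export
classify_segments <- function(segments, query_vs_ref, third_vs_ref,
                              alpha = 0.05, threshold = 0.5,
                              p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(segments) == 0L)
    return(cbind(segments, mean_dev_third = numeric(0), p_value = numeric(0),
                 verdict = character(0)))
  calls <- segments
  calls$mean_dev_third <- NA_real_; calls$p_value <- NA_real_
  calls$verdict <- "indeterminate"
  for (k in seq_len(nrow(segments))) {
    rr <- seq(segments$start[k], segments$end[k])
    ch <- segments$chain[k]
    x <- query_vs_ref$deviation[query_vs_ref$chain == ch &
                                  query_vs_ref$resseq %in% rr]
    y <- third_vs_ref$deviation[third_vs_ref$chain == ch &
                                  third_vs_ref$resseq %in% rr]
    if (length(x) < 3L || length(y) < 3L)
      stop("segment ", ch, " ", segments$start[k], "-", segments$end[k],
           " has fewer than 3 matched residues in a profile")
    p <- if (isTRUE(all.equal(x, y)) ||
             (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))) 1
      else tryCatch(stats::t.test(x, y, alternative = "two.sided")$p.value,
                    error = function(e) NA_real_)
    if (p_adjust == "bonferroni") p <- min(1, p * nrow(segments))
    calls$mean_dev_third[k] <- mean(y)
    calls$p_value[k] <- p
    calls$verdict[k] <-
      if (mean(y) > threshold) "shared"
      else if (!is.na(p) && p < alpha && mean(x) > mean(y)) "ligand-associated"
      else "indeterminate"
  }
  class(calls) <- c("SegmentCall", class(calls))
  calls
}

#' Compare a liganded structure against reference and control in one call
#'
#' Convenience wrapper: deviation profile of query vs reference, segment
#' detection, classification against the third (unliganded) structure.
#'
#' @param query liganded `Structure`.
#' @param reference comparison `Structure` (e.g. a differently-liganded form).
#' @param third control `Structure` with an unliganded active site.
#' @inheritParams find_segments
#' @inheritParams classify_segments
#' @return list: `profile`, `segments`, `calls`.
#' @export
compare_structures <- function(query, reference, third, threshold = 0.5,
                               min_len = 3L, alpha = 0.05) {
  qp <- deviation_profile(query, reference)
  tp <- deviation_profile(third, reference)
  segs <- find_segments(qp, threshold, min_len)
  calls <- classify_segments(segs, qp, tp, alpha, threshold)
  list(profile = qp, segments = segs, calls = calls)
}

#' Per-residue root-mean-square fluctuation of an ensemble
#'
#' RMSF of each selected Calpha about its ensemble-mean position. Frames are
#' expected to be pre-superposed (see [superpose_ensemble()]).
#'
#' @param e an `Ensemble` (>= 2 frames).
#' @param selection atoms to report (default Calpha).
#' @return data.frame: `chain`, `resseq`, `rmsf` (angstrom).
#' @export
ensemble_rmsf <- function(e, selection = sel_calpha()) {
  stopifnot(inherits(e, "Ensemble"))
  if (length(e$frames) < 2L) stop("RMSF needs at least 2 frames")
  idx <- atom_select(e$topology, selection)
  nf <- length(e$frames)
  arr <- vapply(e$frames, function(f) f[idx, , drop = FALSE],
                matrix(0, length(idx), 3))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(k) rowSums((arr[, , k] - mean_pos)^2),
                 numeric(length(idx)))
  data.frame(chain = e$topology$atoms$chain[idx],
             resseq = e$topology$atoms$resseq[idx],
             rmsf = sqrt(rowMeans(dev2)), stringsAsFactors = FALSE)
}

#' Superpose every frame of an ensemble onto a reference conformation
#'
#' Removes rigid-body (rotational and translational) degrees of freedom by
#' Kabsch-fitting each frame's selected atoms onto the reference.
#'
#' @param e an `Ensemble`.
#' @param reference `Structure` to fit onto (default: topology of `e` with
#'   frame-1 coordinates).
#' @param selection atoms used for the fit (default backbone).
#' @return the `Ensemble` with transformed frames.
#' @export
superpose_ensemble <- function(e, reference = NULL, selection = sel_backbone()) {
  stopifnot(inherits(e, "Ensemble"))
  if (is.null(reference)) reference <- set_coords(e$topology, e$frames[[1]])
  m <- match_atoms(e$topology, reference, selection, on_unmatched = "exclude")
  ref_xyz <- coords(reference)[m$ib, , drop = FALSE]
  e$frames <- lapply(e$frames, function(f) {
    fit <- kabsch_superpose(f[m$ia, , drop = FALSE], ref_xyz)
    apply_transform(f, fit)
  })
  e
}
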