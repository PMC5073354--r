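#' Atomic structure and conformational ensemble containers
#'
#' A `Structure` is an ordered table of atom records (chain, residue number,
#' insertion code, residue name, atom name, altloc, coordinates, occupancy,
#' B-factor, element, HETATM flag) plus free-form metadata. An `Ensemble` is
#' one `Structure` used as topology together with a list of coordinate
#' matrices, one per conformation -- the in-memory stand-in for a set of MD
#' snapshots read from a multi-model PDB file.
#'
#' @param atoms data.frame with columns `chain`, `resseq`, `icode`, `resname`,
#'   `atom`, `altloc`, `x`, `y`, `z`, `occ`, `b`, `element`, `het`.
#' @param metadata named list carried along unmodified (source path, model no.).
#' @return An object of class `Structure`.
#' @export
Structure <- function(atoms, metadata = list()) {
  required <- c("chain", "resseq", "icode", "resname", "atom", "altloc",
                "x", "y", "z", "occ", "b", "element", "het")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: zero atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (any(atoms$b < 0, na.rm = TRUE)) stop("negative B-factor")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @param topology `Structure` providing atom identities (its own coordinates
#'   are ignored by ensemble operations).
#' @param frames list of numeric n_atoms x 3 matrices, one per conformation.
#' @rdname Structure
#' @export
Ensemble <- function(topology, frames, metadata = list()) {
  stopifnot(inherits(topology, "Structure"))
  if (length(frames) < 1L) stop("ensemble needs at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != na)
      stop("frame ", i, " does not match topology (", na, " atoms expected)")
    if (!all(is.finite(f))) stop("non-finite coordinates in frame ", i)
  }
  structure(list(topology = topology, frames = frames, metadata = metadata),
            class = "Ensemble")
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat("Structure:", nrow(a), "atoms,",
      length(unique(residue_keys(x))), "residues, chains",
      paste(unique(a$chain), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", length(x$frames), "frames x", n_atoms(x$topology), "atoms\n")
  invisible(x)
}

#' Basic accessors
#'
#' @param s a `Structure`.
#' @return `coords` returns an n x 3 numeric matrix (angstrom); `n_atoms` the
#'   atom count; `residue_keys` a character vector `chain|resseq|icode`, one
#'   entry per atom, that identifies residues uniquely.
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "Structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @rdname coords
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' @rdname coords
#' @export
residue_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode, sep = "|")
}

#' Replace coordinates of a structure
#' @param s a `Structure`.
#' @param xyz n x 3 matrix.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "Structure"), nrow(xyz) == n_atoms(s), ncol(xyz) == 3L)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Atom selections
#'
#' A `Selection` is a conjunction of simple predicates over atom records.
#' Applying a selection preserves atom order. Fields left `NULL` do not
#' constrain. `het = FALSE` restricts to ATOM (polymer) records, which also
#' excludes waters and metals; this is the "protein atoms" convention used for
#' average B-factors.
#'
#' @param chain chain identifier(s).
#' @param resseq residue numbers (vector; use `seq` for ranges).
#' @param atoms atom name(s), e.g. `c("N","CA","C","O")`.
#' @param elements element symbol(s).
#' @param resname residue name(s).
#' @param het `TRUE`/`FALSE` to require/exclude HETATM records, `NULL` for both.
#' @return object of class `Selection`.
#' @export
sel <- function(chain = NULL, resseq = NULL, atoms = NULL, elements = NULL,
                resname = NULL, het = NULL) {
  structure(list(chain = chain, resseq = resseq, atoms = atoms,
                 elements = elements, resname = resname, het = het),
            class = "Selection")
}

#' @rdname sel
#' @export
sel_backbone <- function(chain = NULL)
  sel(chain = chain, atoms = c("N", "CA", "C", "O"), het = FALSE)

#' @rdname sel
#' @export
sel_calpha <- function(chain = NULL) sel(chain = chain, atoms = "CA", het = FALSE)

#' @rdname sel
#' @export
sel_protein <- function(chain = NULL) sel(chain = chain, het = FALSE)

#' Resolve a selection to atom indices
#'
#' @param s a `Structure`.
#' @param selection a `Selection` (or `NULL` for all atoms).
#' @param allow_empty if `FALSE` (default) an empty selection is an error, so
#'   typos in chain ids or atom names fail loudly instead of propagating.
#' @return integer vector of row indices into `s$atoms`, in original order.
#' @export
atom_select <- function(s, selection = NULL, allow_empty = FALSE) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "Selection"))
    if (!is.null(selection$chain))    keep <- keep & a$chain %in% selection$chain
    if (!is.null(selection$resseq))   keep <- keep & a$resseq %in% selection$resseq
    if (!is.null(selection$atoms))    keep <- keep & a$atom %in% selection$atoms
    if (!is.null(selection$elements)) keep <- keep & a$element %in% selection$elements
    if (!is.null(selection$resname))  keep <- keep & a$resname %in% selection$resname
    if (!is.null(selection$het))      keep <- keep & a$het == selection$het
  }
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty)
    stop("selection matched zero atoms")
  idx
}

#' Subset a structure by selection
#' @inheritParams atom_select
#' @export
subset_structure <- function(s, selection = NULL, allow_empty = FALSE) {
  idx <- atom_select(s, selection, allow_empty)
  Structure(s$atoms[idx, , drop = FALSE], s$metadata)
}

#' Parse a compact selection phrase
#'
#' Understands phrases used on the command line: `"chain A"`, `"backbone"`,
#' `"calpha"`, `"protein"`, `"resid 10-20"`, `"name CA CB"` joined by
#' `" and "`, e.g. `"chain I and backbone"`.
#' @param text selection phrase.
#' @return a `Selection`.
#' @export
parse_selection <- function(text) {
  out <- sel()
  for (tok in strsplit(trimws(text), "\\s+and\\s+")[[1]]) {
    w <- strsplit(trimws(tok), "\\s+")[[1]]
    if (length(w) == 0L || w[1] == "") next
    head <- tolower(w[1])
    if (head == "chain" && length(w) >= 2) out$chain <- w[-1]
    else if (head == "backbone") { out$atoms <- c("N", "CA", "C", "O"); out$het <- FALSE }
    else if (head == "calpha")   { out$atoms <- "CA"; out$het <- FALSE }
    else if (head == "protein")  out$het <- FALSE
    else if (head == "resid" && length(w) >= 2) {
      rr <- unlist(lapply(w[-1], function(r) {
        if (grepl("-", r)) { ab <- as.integer(strsplit(r, "-")[[1]]); seq(ab[1], ab[2]) }
        else as.integer(r)
      }))
      out$resseq <- rr
    }
    else if (head == "name" && length(w) >= 2) out$atoms <- w[-1]
    else stop("cannot parse selection token: '", tok, "'")
  }
  out
}

# per-residue table: first atom row index of each residue, in atom order
residue_table <- function(s, idx = seq_len(n_atoms(s))) {
  keys <- residue_keys(s)[idx]
  first <- !duplicated(keys)
  data.frame(key = keys[first],
             chain = s$atoms$chain[idx][first],
             resseq = s$atoms$resseq[idx][first],
             icode = s$atoms$icode[idx][first],
             resname = s$atoms$resname[idx][first],
             stringsAsFactors = FALSE)
}
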