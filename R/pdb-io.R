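#' Read a PDB file
#'
#' Fixed-column parser for ATOM/HETATM/MODEL/ENDMDL/TER records. A file with
#' several MODEL blocks is returned as an [Ensemble] (topology from the first
#' model); otherwise a [Structure]. HETATM records are retained with
#' `het = TRUE` so bound metals survive parsing.
#'
#' Alternate locations are resolved according to `altloc_policy`:
#' \describe{
#'   \item{highest-occupancy}{keep, per (residue, atom name), the altloc with
#'     the highest occupancy; ties broken by altloc label order ('A' first).}
#'   \item{keep-all}{keep every altloc record.}
#'   \item{any single letter}{keep blank-altloc records plus that label.}
#' }
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest-occupancy"` (default), `"keep-all"`, or a
#'   single altloc letter.
#' @return a `Structure`, or an `Ensemble` when multiple MODELs are present.
#' @export
read_pdb <- function(path, altloc_policy = "highest-occupancy") {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  model_ends <- which(startsWith(lines, "ENDMDL"))

  parse_block <- function(line_idx) {
    ln <- lines[line_idx]
    if (length(ln) == 0L) stop("empty input: zero atoms in ", path)
    num <- function(txt, what, i) {
      v <- suppressWarnings(as.numeric(txt))
      bad <- which(is.na(v) & trimws(txt) != "")
      bad2 <- which(trimws(txt) == "" & what %in% c("x", "y", "z"))
      if (length(bad) > 0L || length(bad2) > 0L) {
        b <- c(bad, bad2)[1]
        stop("malformed ATOM record (bad ", what, ") at line ", i[b], " of ", path)
      }
      v
    }
    field <- function(a, b) substr(ln, a, b)
    x <- num(field(31, 38), "x", line_idx)
    y <- num(field(39, 46), "y", line_idx)
    z <- num(field(47, 54), "z", line_idx)
    occ <- num(field(55, 60), "occupancy", line_idx); occ[is.na(occ)] <- 1
    b <- num(field(61, 66), "b-factor", line_idx); b[is.na(b)] <- 0
    elem <- trimws(field(77, 78))
    name <- trimws(field(13, 16))
    no_elem <- elem == ""
    if (any(no_elem))  # fall back to the first letter of the atom name
      elem[no_elem] <- sub("^[0-9]*", "", name[no_elem]) |> substr(1, 1)
    data.frame(
      chain = trimws(field(22, 22)),
      resseq = as.integer(num(field(23, 26), "residue number", line_idx)),
      icode = trimws(field(27, 27)),
      resname = trimws(field(18, 20)),
      atom = name,
      altloc = trimws(field(17, 17)),
      x = x, y = y, z = z, occ = occ, b = b,
      element = toupper(elem),
      het = startsWith(ln, "HETATM"),
      stringsAsFactors = FALSE)
  }

  if (length(model_starts) >= 2L) {
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines))
    blocks <- lapply(seq_along(model_starts), function(k) {
      span <- seq(model_starts[k] + 1L, model_ends[k] - 1L)
      idx <- span[is_atom[span]]
      resolve_altloc(parse_block(idx), altloc_policy)
    })
    topo <- Structure(blocks[[1]], metadata = list(source = path))
    frames <- lapply(blocks, function(bl) unname(as.matrix(bl[, c("x", "y", "z")])))
    return(Ensemble(topo, frames, metadata = list(source = path)))
  }

  idx <- which(is_atom)
  if (length(idx) == 0L) stop("empty input: zero atoms in ", path)
  atoms <- resolve_altloc(parse_block(idx), altloc_policy)
  Structure(atoms, metadata = list(source = path))
}

resolve_altloc <- function(atoms, policy) {
  if (identical(policy, "keep-all")) return(atoms)
  if (identical(policy, "highest-occupancy")) {
    key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$atom, sep = "|")
    # stable: order by occupancy desc then altloc label asc, keep first per key
    ord <- order(key, -atoms$occ, atoms$altloc)
    keep_rows <- ord[!duplicated(key[ord])]
    return(atoms[sort(keep_rows), , drop = FALSE])
  }
  if (is.character(policy) && nchar(policy) == 1L) {
    return(atoms[atoms$altloc %in% c("", policy), , drop = FALSE])
  }
  stop("unknown altloc policy: ", policy)
}

#' Write a structure or ensemble as PDB
#'
#' Coordinates are written with 3 decimals (the PDB fixed-column precision);
#' ensembles are written as MODEL/ENDMDL blocks sharing the topology's
#' identity fields.
#'
#' @param x a `Structure` or `Ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_atoms <- function(atoms) {
    name <- ifelse(nchar(atoms$atom) < 4L, paste0(" ", atoms$atom), atoms$atom)
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(atoms$het, "HETATM", "ATOM"), seq_len(nrow(atoms)), name,
            substr(paste0(atoms$altloc, " "), 1, 1), atoms$resname, atoms$chain,
            atoms$resseq, substr(paste0(atoms$icode, " "), 1, 1),
            atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
            formatC(atoms$element, width = 2, flag = " "))
  }
  if (inherits(x, "Structure")) {
    writeLines(c(fmt_atoms(x$atoms), "END"), path)
  } else if (inherits(x, "Ensemble")) {
    out <- character(0)
    a <- x$topology$atoms
    for (k in seq_along(x$frames)) {
      a$x <- x$frames[[k]][, 1]; a$y <- x$frames[[k]][, 2]; a$z <- x$frames[[k]][, 3]
      out <- c(out, sprintf("MODEL %8d", k), fmt_atoms(a), "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else stop("x must be a Structure or Ensemble")
  invisible(path)
}
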