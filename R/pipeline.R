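run_config_defaults <- function() list(
  # inputs (paths; stages whose inputs are absent are skipped)
  complex_pdb = NA_character_,       # protease-inhibitor complex
  query_pdb = NA_character_,         # liganded structure for segment calling
  ref_pdb = NA_character_,           # comparison structure
  third_pdb = NA_character_,         # unliganded-active-site control
  modes_pdb = NA_character_,         # structure for ENM / DCC / frustration
  apo_ensemble_pdb = NA_character_,  # multi-model PDB, condition A
  holo_ensemble_pdb = NA_character_, # multi-model PDB, condition B
  clash_ensemble_pdb = NA_character_,
  # selections / sites
  side_a = "chain A", side_b = "chain I",
  site_a = "", site_b = "",          # residue number lists, comma separated
  # stage parameters (paper-default values)
  interface.probe = 1.4, interface.n_points = 960,
  interface.hbond_dmax = 3.5, interface.hbond_angle_min = 90,
  interface.salt_dmax = 4.0,
  compare.threshold = 0.5, compare.min_len = 3, compare.alpha = 0.05,
  enm.cutoff = 15, modes.n = 100, project.modes = "7-11",
  dcc.n_modes = 100,
  frustration.cutoff = 9.5, frustration.min_seq_sep = 3,
  frustration.n_decoys = 1000,
  frustration.minimal_threshold = 0.78, frustration.high_threshold = -1,
  clash.overlap = 0.4, clash.whitelist_margin = 0.5,
  seed = 1)

#' Read a flat key = value run configuration
#'
#' One `key = value` per line; `#` starts a comment. Unknown keys are rejected
#' before any computation. Defaults are materialised so the resolved config
#' echoed into reports is complete.
#'
#' @param path config file path, or NULL for pure defaults.
#' @param overrides named list applied after the file.
#' @return named list of class `RunConfig` with every key resolved.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  entries <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[lines != ""]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
      entries[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  entries <- utils::modifyList(entries, overrides)
  unknown <- setdiff(names(entries), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(entries)) {
    v <- entries[[k]]
    cfg[[k]] <- if (is.character(cfg[[k]])) as.character(v) else as.numeric(v)
  }
  class(cfg) <- "RunConfig"
  cfg
}

parse_mode_range <- function(txt) {
  parts <- strsplit(txt, ",")[[1]]
  unlist(lapply(trimws(parts), function(p) {
    if (grepl("-", p)) { ab <- as.integer(strsplit(p, "-")[[1]]); seq(ab[1], ab[2]) }
    else as.integer(p)
  }))
}

parse_residue_list <- function(txt) {
  if (is.na(txt) || txt == "") return(integer(0))
  as.integer(trimws(strsplit(txt, ",")[[1]]))
}

#' Minimum or centroid distance between two atom sets
#'
#' @param s a `Structure`.
#' @param site_a,site_b `Selection`s (or integer residue-number vectors).
#' @param mode `"min"` (closest atom pair) or `"centroid"`.
#' @return distance, angstrom.
#' @export
site_distance <- function(s, site_a, site_b, mode = c("min", "centroid")) {
  mode <- match.arg(mode)
  as_sel <- function(x) if (inherits(x, "Selection")) x else sel(resseq = x)
  ia <- atom_select(s, as_sel(site_a)); ib <- atom_select(s, as_sel(site_b))
  xa <- coords(s)[ia, , drop = FALSE]; xb <- coords(s)[ib, , drop = FALSE]
  if (mode == "centroid")
    return(sqrt(sum((colMeans(xa) - colMeans(xb))^2)))
  min(vapply(seq_len(nrow(xb)), function(j)
    min(sqrt(rowSums((xa - matrix(xb[j, ], nrow(xa), 3, byrow = TRUE))^2))),
    numeric(1)))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order, every stage whose inputs the config names:
#' interface characterisation, ligand-associated segment calling, elastic
#' network modes with ensemble projection, population shift and DCC,
#' frustration network with site-to-site path, and ensemble clash screening.
#' A failing stage is recorded as an error entry; independent stages still
#' run. Stochastic stages are seeded from `cfg$seed`, so identical
#' config + inputs reproduce the report exactly.
#'
#' @param cfg a `RunConfig` from [read_run_config()].
#' @return list of class `AnalysisReport`: one entry per executed stage
#'   (value or condition object), plus `config` (the resolved echo) and
#'   `seed`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  report <- list()
  has <- function(key) !is.na(cfg[[key]]) && nzchar(cfg[[key]])
  stage <- function(name, expr) {
    report[[name]] <<- tryCatch(expr, error = function(e) {
      message("stage '", name, "' failed: ", conditionMessage(e)); e
    })
  }

  if (has("complex_pdb")) {
    cx <- read_pdb(cfg$complex_pdb)
    sa <- parse_selection(cfg$side_a); sb <- parse_selection(cfg$side_b)
    stage("interface", {
      burial <- buried_interface(cx, sa, sb, cfg$interface.probe,
                                 cfg$interface.n_points)
      list(burial = burial,
           hbonds = find_hbonds(cx, sa, sb, cfg$interface.hbond_dmax,
                                cfg$interface.hbond_angle_min),
           salt_bridges = find_salt_bridges(cx, sa, sb, cfg$interface.salt_dmax))
    })
  }

  if (has("query_pdb") && has("ref_pdb") && has("third_pdb")) {
    stage("compare", {
      compare_structures(read_pdb(cfg$query_pdb), read_pdb(cfg$ref_pdb),
                         read_pdb(cfg$third_pdb), cfg$compare.threshold,
                         as.integer(cfg$compare.min_len), cfg$compare.alpha)
    })
  }

  modes_obj <- NULL
  if (has("modes_pdb")) {
    stage("modes", {
      s <- read_pdb(cfg$modes_pdb)
      h <- build_enm(s, cfg$enm.cutoff)
      m <- enm_modes(h, min(as.integer(cfg$modes.n),
                            3L * nrow(attr(h, "nodes")) - 6L))
      list(modes = m,
           variance_fraction_5 = variance_fraction(m, 5L),
           msf = mode_fluctuations(m),
           dcc = dcc(m, min(as.integer(cfg$dcc.n_modes),
                            length(m$internal_values))))
    })
    if (!inherits(report$modes, "error")) modes_obj <- report$modes$modes
    if (!is.null(modes_obj) && has("apo_ensemble_pdb") && has("holo_ensemble_pdb")) {
      stage("population_shift", {
        mode_idx <- parse_mode_range(cfg$project.modes)
        ref <- read_pdb(cfg$modes_pdb)
        pa <- project_ensemble(read_pdb(cfg$apo_ensemble_pdb), modes_obj,
                               mode_idx, ref)
        pb <- project_ensemble(read_pdb(cfg$holo_ensemble_pdb), modes_obj,
                               mode_idx, ref)
        list(projection_apo = pa, projection_holo = pb,
             shift = population_shift(pa, pb))
      })
    }
    stage("frustration", {
      s <- read_pdb(cfg$modes_pdb)
      net <- frustration_network(
        s, cfg$frustration.cutoff, as.integer(cfg$frustration.min_seq_sep),
        as.integer(cfg$frustration.n_decoys), as.integer(cfg$seed),
        minimal_threshold = cfg$frustration.minimal_threshold,
        high_threshold = cfg$frustration.high_threshold)
      out <- list(network = net)
      site_a <- parse_residue_list(cfg$site_a)
      site_b <- parse_residue_list(cfg$site_b)
      if (length(site_a) > 0L && length(site_b) > 0L)
        out$path <- frustration_path(net, site_a, site_b)
      out
    })
  }

  if (has("clash_ensemble_pdb") && has("complex_pdb")) {
    stage("clash", {
      clash_timecourse(read_pdb(cfg$clash_ensemble_pdb), read_pdb(cfg$complex_pdb),
                       ligand_sel = parse_selection(cfg$side_b),
                       overlap_min = cfg$clash.overlap,
                       whitelist_margin = cfg$clash.whitelist_margin)
    })
  }

  report$config <- unclass(cfg)
  report$seed <- as.integer(cfg$seed)
  class(report) <- "AnalysisReport"
  report
}
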