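# Batch analysis driven by a YAML manifest, plus configuration validation.
# The manifest lists coordinate files (pre-downloaded; no network access is
# ever attempted) and the analyses to run on each; results are written as
# JSON and TSV with a provenance block.

.default_config <- function() {
  list(
    max_da_dist = 3.5,           # A, Watson-Crick donor-acceptor cutoff
    min_normal_angle = 140,      # degrees, base-normal antiparallelism
    max_origin_dist = 2.5,       # A, flipped frame origin coincidence
    ideal_twist_per_step = 36.0, # degrees, ideal B-form reference
    extrapolation_steps = 19,    # steps the mean h-twist is extrapolated over
    probe = 1.4,                 # A, SASA probe radius
    n_points = 960,              # SASA sphere points per atom
    partition = NULL,            # kink partition, NULL = automatic
    kink_policy = "frame",       # kink block-centroid policy
    length_policy = "all")       # spacer-length centroid policy
}

#' Validate and normalize a configuration
#'
#' Fills documented defaults, rejects unknown keys, and type-checks values.
#'
#' @param config path to a YAML file, a list, or NULL for all defaults.
#' @return named list of normalized options.
#' @export
validate_config <- function(config = NULL) {
  defaults <- .default_config()
  if (is.null(config)) return(defaults)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) return(defaults)
  }
  if (!is.list(config)) stop("config must be a file path, a list, or NULL")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  numeric_keys <- c("max_da_dist", "min_normal_angle", "max_origin_dist",
                    "ideal_twist_per_step", "extrapolation_steps", "probe",
                    "n_points")
  for (k in names(config)) {
    v <- config[[k]]
    if (k %in% numeric_keys) {
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
        stop("config key '", k, "' must be a single finite number")
    } else if (k == "partition") {
      if (!is.null(v) && (!is.numeric(v) || length(v) != 3))
        stop("config key 'partition' must be three block sizes or null")
    } else if (k %in% c("kink_policy", "length_policy")) {
      if (!is.character(v) || !v %in% c("frame", "all", "base"))
        stop("config key '", k, "' must be one of frame/all/base")
    }
    defaults[[k]] <- v
  }
  defaults
}

config_criteria <- function(cfg) {
  pair_criteria(max_da_dist = cfg$max_da_dist,
                min_normal_angle = cfg$min_normal_angle,
                max_origin_dist = cfg$max_origin_dist)
}

# Run one manifest entry; returns a result list or signals an error.
run_entry <- function(entry, cfg, out_dir) {
  if (is.null(entry$id)) stop("manifest entry lacks an 'id'")
  analysis <- entry$analysis %||% "spacer"
  if (!is.null(entry$options))
    cfg <- validate_config(utils::modifyList(cfg, entry$options))
  result <- switch(
    analysis,
    spacer = {
      model <- read_structure(entry$structure)
      part <- entry$partition %||% cfg$partition
      rep <- spacer_report(model, entry$t_strand, entry$nt_strand,
                           partition = part,
                           extrapolation_steps = cfg$extrapolation_steps,
                           ideal_twist_per_step = cfg$ideal_twist_per_step,
                           criteria = config_criteria(cfg),
                           kink_policy = cfg$kink_policy,
                           length_policy = cfg$length_policy)
      write_report_json(rep, file.path(out_dir, paste0(entry$id, ".json")))
      write_report_tsv(rep, file.path(out_dir, paste0(entry$id, ".tsv")))
      report_values(rep)
    },
    motion = {
      s1 <- read_structure(entry$state1)
      s2 <- read_structure(entry$state2)
      dm <- domain_motion(s1, s2, entry$reference, entry$domain)
      out <- list(rotation_angle = dm$rotation_angle,
                  centroid_displacement = dm$centroid_displacement,
                  n_atoms = dm$n_atoms, reference_rmsd = dm$reference_rmsd)
      jsonlite::write_json(out, file.path(out_dir, paste0(entry$id, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    },
    interface = {
      model <- read_structure(entry$structure)
      bsa <- buried_area(model, entry$sel_a, entry$sel_b,
                         probe = cfg$probe, n_points = cfg$n_points)
      out <- list(buried_total = bsa$buried_total,
                  buried_a = unname(bsa$buried_per_side["A"]),
                  buried_b = unname(bsa$buried_per_side["B"]),
                  interface_area = bsa$interface_area)
      jsonlite::write_json(out, file.path(out_dir, paste0(entry$id, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out
    },
    stop("unknown analysis kind '", analysis, "'"))
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a batch analysis manifest
#'
#' The manifest (YAML file or list) has optional `config` (see
#' [validate_config()]) and `entries`, each with an `id`, an `analysis` kind
#' (`spacer`, `motion`, `interface`), the structure path(s) and the
#' selections that analysis needs.  Every referenced file must exist before
#' any computation starts; per-entry failures are isolated and reported in
#' the bundle.  Re-running with identical inputs reproduces identical
#' values (no timestamps in data files).
#'
#' @param manifest path to a YAML manifest or an equivalent list.
#' @param out_dir output directory for per-entry JSON/TSV (created if
#'   needed).
#' @return a `report_bundle`: per-entry results (or error messages), the
#'   normalized config, and a provenance block.
#' @export
run_manifest <- function(manifest, out_dir = ".") {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  cfg <- validate_config(manifest$config)
  entries <- manifest$entries %||% list()
  # validate inputs up front: a missing file aborts before any computation
  for (e in entries) {
    for (key in c("structure", "state1", "state2")) {
      if (!is.null(e[[key]]) && !file.exists(e[[key]]))
        stop("manifest references a missing file: ", e[[key]],
             " (entry '", e$id %||% "?", "')")
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  errors <- character(0)
  for (e in entries) {
    res <- tryCatch(run_entry(e, cfg, out_dir), error = function(err) {
      message("entry '", e$id %||% "?", "' failed: ", conditionMessage(err))
      structure(list(error = conditionMessage(err)), class = "entry_error")
    })
    if (inherits(res, "entry_error")) errors <- c(errors, e$id %||% "?")
    results[[e$id %||% paste0("entry", length(results) + 1)]] <- res
  }
  checksums <- vapply(entries, function(e) {
    f <- e$structure %||% e$state1
    if (is.null(f)) "" else as.character(tools::md5sum(f))
  }, character(1))
  structure(list(results = results, failed = errors, config = cfg,
                 provenance = list(
                   package = "spacergeom",
                   version = as.character(utils::packageVersion("spacergeom")),
                   input_checksums = checksums)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", length(x$results), " entr",
      if (length(x$results) == 1) "y" else "ies", sep = "")
  if (length(x$failed)) cat(" (", length(x$failed), " failed)", sep = "")
  cat("\n")
  invisible(x)
}

#' Batch measurement over locally mirrored deposited structures
#'
#' Recomputes the promoter-spacer remodeling table (spacer length, kink
#' angle, under-twist) for coordinate entries mirrored in a local directory
#' (files named `<id>.pdb` or `<id>.cif`).  No download is ever attempted:
#' entries whose files are absent are reported as missing.
#'
#' @param mirror_dir directory holding pre-downloaded coordinate files.
#' @param entries data.frame with columns id, t_strand, nt_strand (selection
#'   expressions for the spacer strands) and optionally partition.
#' @param ... passed to [spacer_report()].
#' @return list with `reports` (per present entry) and `missing` (ids whose
#'   files were not found).
#' @export
measure_mirrored_spacers <- function(mirror_dir, entries, ...) {
  reports <- list()
  missing <- character(0)
  for (i in seq_len(nrow(entries))) {
    id <- entries$id[i]
    path <- NULL
    for (ext in c(".pdb", ".cif")) {
      cand <- file.path(mirror_dir, paste0(id, ext))
      if (file.exists(cand)) { path <- cand; break }
    }
    if (is.null(path)) { missing <- c(missing, id); next }
    model <- read_structure(path)
    reports[[id]] <- spacer_report(model, entries$t_strand[i],
                                   entries$nt_strand[i], ...)
  }
  list(reports = reports, missing = missing)
}
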