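# Configuration files, outputs and provenance. The run configuration is one
# canonical YAML document; tabular outputs are CSV, frames are standard XYZ,
# acceptance and provenance are JSON. Every output carries the config hash.

config_defaults <- function() {
  list(
    dp = 100L, dd = 1.0, pattern = "random", block_size = 2L,
    ph = 4.5, cs = 0.1, temperature = 298,
    seed = 1L, n_sweeps = 10000L, log_stride = 10L,
    titration_moves_per_sweep = NA_integer_,
    cutoff_kbt = 7, pk_i = 6.6, sigma_lj_nm = 0.65, eps_lj_kjmol = 0.6276,
    electrostatics = TRUE, titration = TRUE, map_swapping = TRUE,
    include_bonded_in_titration = FALSE,
    include_ph_in_ionic_strength = TRUE,
    static_map_key = NA_character_,
    burn_in = 0.2, collect_frames = FALSE, collect_dihedrals = FALSE,
    maps = "synthetic"
  )
}

#' Validate a run-configuration list
#'
#' Applies defaults, rejects unknown keys, checks ranges.
#'
#' @param x Named list of configuration values.
#' @return A validated `run_config` (full list of canonical keys).
#' @export
validate_config <- function(x) {
  defs <- config_defaults()
  unknown <- setdiff(names(x), names(defs))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defs, x)
  # canonical types, so configs compare identical across YAML/JSON round trips
  for (f in c("dd", "ph", "cs", "temperature", "cutoff_kbt", "pk_i",
              "sigma_lj_nm", "eps_lj_kjmol", "burn_in")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  for (f in c("dp", "seed", "n_sweeps", "log_stride", "block_size")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  tms <- suppressWarnings(as.integer(cfg$titration_moves_per_sweep))
  cfg$titration_moves_per_sweep <- if (length(tms) == 0) NA_integer_ else tms
  smk <- as.character(cfg$static_map_key)
  cfg$static_map_key <- if (length(smk) == 0 || identical(smk, "NA")) NA_character_ else smk
  for (f in c("electrostatics", "titration", "map_swapping",
              "include_bonded_in_titration", "include_ph_in_ionic_strength",
              "collect_frames", "collect_dihedrals")) {
    cfg[[f]] <- isTRUE(as.logical(cfg[[f]]))
  }
  stopifnot(cfg$dp >= 2, cfg$dd >= 0, cfg$dd <= 1, cfg$cs >= 0,
            cfg$n_sweeps >= 1, cfg$cutoff_kbt > 0, cfg$sigma_lj_nm > 0,
            cfg$burn_in >= 0, cfg$burn_in < 1)
  structure(cfg, class = "run_config")
}

#' Parse a YAML run configuration
#'
#' @param path Path to a YAML file with any subset of the canonical keys.
#' @return A validated `run_config` with defaults applied.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  validate_config(x)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$titration_moves_per_sweep <-
    if (is.na(out$titration_moves_per_sweep)) NULL else out$titration_moves_per_sweep
  if (is.na(out$static_map_key)) out$static_map_key <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialization; stored in every output file so a
#' result can be traced to its exact configuration.
#'
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Build a simulation from a run configuration
#'
#' @param config A `run_config`.
#' @param manifest_dir Directory against which a map-manifest path in
#'   `config$maps` is resolved.
#' @return A [simulation_config()].
#' @export
config_to_simulation <- function(config, manifest_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  params <- forcefield_params(
    sigma_lj = config$sigma_lj_nm, eps_lj_kjmol = config$eps_lj_kjmol,
    pk_i = config$pk_i, cutoff = config$cutoff_kbt,
    temperature = config$temperature,
    include_bonded_in_titration = config$include_bonded_in_titration
  )
  conditions <- solution_conditions(
    ph = config$ph, cs = config$cs, temperature = config$temperature,
    include_ph_in_ionic_strength = config$include_ph_in_ionic_strength
  )
  library <- if (identical(config$maps, "synthetic")) {
    default_map_library(cutoff = config$cutoff_kbt)
  } else {
    path <- config$maps
    if (!file.exists(path)) path <- file.path(manifest_dir, config$maps)
    load_map_manifest(path, cutoff = config$cutoff_kbt)
  }
  simulation_config(
    dp = config$dp, dd = config$dd, pattern = config$pattern,
    ph = config$ph, cs = config$cs,
    n_sweeps = config$n_sweeps, seed = config$seed,
    library = library, params = params, conditions = conditions,
    titration_moves_per_sweep =
      if (is.na(config$titration_moves_per_sweep)) NULL else config$titration_moves_per_sweep,
    log_stride = config$log_stride,
    electrostatics = config$electrostatics, titration = config$titration,
    map_swapping = config$map_swapping,
    static_map_key = if (is.na(config$static_map_key)) NULL else config$static_map_key,
    burn_in = config$burn_in,
    collect_frames = config$collect_frames,
    collect_dihedrals = config$collect_dihedrals
  )
}

#' Load a map library from a manifest
#'
#' The manifest is a YAML mapping of link keys to map-file paths (relative
#' paths are resolved against the manifest's directory).
#'
#' @param path Manifest path.
#' @param cutoff Restriction energy in k_BT.
#' @param grid_spec Target grid shape for the loaded maps.
#' @return A `map_library`.
#' @export
load_map_manifest <- function(path, cutoff = 7, grid_spec = c(200, 200)) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  dir <- dirname(path)
  maps <- lapply(names(man), function(key) {
    f <- man[[key]]
    if (!file.exists(f)) f <- file.path(dir, man[[key]])
    load_map(f, link_key = key, grid_spec = grid_spec)
  })
  names(maps) <- names(man)
  map_library(maps, cutoff = cutoff)
}

#' Write the standard outputs of a run
#'
#' Observables CSV, acceptance JSON, provenance JSON and (if frames were
#' collected) an XYZ trajectory of the ring-center sites.
#'
#' @param run An `mc_run`.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` recorded in the provenance; without it
#'   the provenance is reconstructed from the run.
#' @return Named list of written paths, invisibly.
#' @export
write_outputs <- function(run, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- run_config_from_run(run)
  hash <- config_hash(config)
  paths <- list(
    observables = file.path(dir, "observables.csv"),
    acceptance = file.path(dir, "acceptance.json"),
    provenance = file.path(dir, "provenance.json")
  )
  log <- run$log
  con <- file(paths$observables, "w")
  writeLines(sprintf("# config_hash %s", hash), con)
  utils::write.csv(log, con, row.names = FALSE)
  close(con)
  acc <- acceptance_report(run)
  jsonlite::write_json(list(config_hash = hash, rates = acc),
                       paths$acceptance, auto_unbox = TRUE, digits = NA)
  cfg_list <- unclass(config)
  cfg_list <- cfg_list[!vapply(cfg_list, function(v) length(v) == 1 && is.na(v), TRUE)]
  prov <- list(
    config_hash = hash,
    config = cfg_list,
    seed = run$config$seed,
    package_version = as.character(utils::packageVersion("chitomc")),
    map_checksums = map_checksums(run$config$library),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA)
  if (!is.null(run$frames)) {
    paths$frames <- file.path(dir, "frames.xyz")
    write_xyz(run$frames, paths$frames,
              comments = sprintf("step %d config %s", run$log$step, hash))
  }
  invisible(paths)
}

# Canonical run_config reconstructed from a simulation's settings.
run_config_from_run <- function(run) {
  cfg <- run$config
  validate_config(list(
    dp = cfg$sequence$dp, dd = cfg$sequence$dd,
    pattern = if (cfg$sequence$pattern %in% c("random", "alternating", "explicit"))
      cfg$sequence$pattern else "block",
    ph = cfg$conditions$ph, cs = cfg$conditions$cs,
    temperature = cfg$conditions$temperature,
    seed = cfg$seed, n_sweeps = cfg$n_sweeps, log_stride = cfg$log_stride,
    titration_moves_per_sweep = cfg$titration_moves_per_sweep,
    cutoff_kbt = cfg$params$cutoff, pk_i = cfg$params$pk_i,
    sigma_lj_nm = cfg$params$sigma_lj, eps_lj_kjmol = cfg$params$eps_lj_kjmol,
    electrostatics = cfg$electrostatics, titration = cfg$titration,
    map_swapping = cfg$map_swapping,
    include_bonded_in_titration = cfg$params$include_bonded_in_titration,
    include_ph_in_ionic_strength = cfg$conditions$include_ph_in_ionic_strength,
    static_map_key = if (is.null(cfg$static_map_key)) NA_character_ else cfg$static_map_key,
    burn_in = cfg$burn_in,
    collect_frames = cfg$collect_frames, collect_dihedrals = cfg$collect_dihedrals
  ))
}

map_checksums <- function(library) {
  out <- lapply(library$maps, function(m) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(sprintf("%.10e", as.vector(m$grid)), tf)
    unname(tools::md5sum(tf))
  })
  out
}

#' Re-run a simulation from a provenance record
#'
#' @param path Path to a `provenance.json` written by [write_outputs()].
#' @return The reproduced `mc_run`.
#' @export
rerun_from_provenance <- function(path) {
  prov <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- validate_config(prov$config[!vapply(prov$config, is.null, TRUE)])
  run_simulation(config_to_simulation(cfg, manifest_dir = dirname(path)))
}

#' Write site frames as an XYZ trajectory
#'
#' Standard XYZ: atom count, comment line, then one `S x y z` row per
#' ring-center site (pseudo-element "S").
#'
#' @param frames `n_frames x dp x 3` array (or a single matrix).
#' @param path Output path.
#' @param comments Per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comments = NULL) {
  fl <- as_frame_list(frames)
  if (is.null(comments)) comments <- sprintf("frame %d", seq_along(fl))
  comments <- rep_len(comments, length(fl))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(fl)) {
    s <- fl[[i]]
    writeLines(c(
      as.character(nrow(s)), comments[i],
      sprintf("S %.6f %.6f %.6f", s[, 1], s[, 2], s[, 3])
    ), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file written by [write_xyz()].
#' @return A `n_frames x n_sites x 3` array.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    rows <- lines[(i + 2):(i + 1 + n)]
    m <- do.call(rbind, lapply(strsplit(rows, "[[:blank:]]+"), function(f) {
      as.numeric(f[2:4])
    }))
    frames[[length(frames) + 1]] <- m
    i <- i + 2 + n
  }
  out <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (k in seq_along(frames)) out[k, , ] <- frames[[k]]
  out
}

#' Read an observables CSV
#'
#' @param path File written by [write_outputs()].
#' @return A tibble; the config hash is attached as attribute `config_hash`.
#' @export
read_observables <- function(path) {
  first <- readLines(path, n = 1)
  hash <- if (startsWith(first, "# config_hash")) {
    sub("# config_hash ", "", first)
  } else NA_character_
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(df, "config_hash") <- hash
  df
}

#' Write a map-library manifest plus map files
#'
#' Writes each map of a library as a three-column text file together with the
#' YAML manifest pointing at them.
#'
#' @param library A `map_library`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_map_manifest <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (key in names(library$maps)) {
    fname <- paste0(gsub("[^A-Za-z0-9]+", "_", key), ".map")
    write_map(library$maps[[key]], file.path(dir, fname), dialect = "matrix")
    files[[key]] <- fname
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(files, manifest)
  invisible(manifest)
}
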