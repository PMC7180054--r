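CONFIG_KEYS <- c("region_length", "region_width", "synapses", "n_receptors",
                 "dt", "D_out", "D_in", "D_trap", "p_crossing",
                 "crossing_mode", "bound_edge", "t_burn_in", "t_baseline",
                 "t_post", "sample_interval", "seed")
PROTOCOL_KEYS <- c("name", "k_on_base", "k_off_base", "k_off_potentiated",
                   "k_on_potentiated", "t_induction")

#' Load a simulation configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose top-level keys
#' match the [sim_config()] argument names (units: um, s, 1/s), plus an
#' optional `protocol` block with the [protocol()] argument names. Omitted
#' keys take the reference defaults, so an empty file yields the full default
#' configuration. Unknown keys and invariant violations are rejected with an
#' error naming the offending key.
#'
#' @param path file path.
#' @return list with elements `config` (a `sim_config`) and `protocol` (a
#'   `protocol_spec`, or `NULL` when the file has no protocol block).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c(CONFIG_KEYS, "protocol"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  proto <- NULL
  if (!is.null(raw$protocol)) {
    p <- raw$protocol
    bad <- setdiff(names(p), PROTOCOL_KEYS)
    if (length(bad)) {
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(p$name)) stop("protocol block needs a 'name'", call. = FALSE)
    proto <- do.call(protocol, p)
    raw$protocol <- NULL
  }
  if (!is.null(raw$synapses)) {
    raw$synapses <- as.data.frame(raw$synapses)
  }
  cfg <- tryCatch(do.call(sim_config, raw), error = function(e) {
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE)
  })
  list(config = cfg, protocol = proto)
}

#' Write a time-averaged occupancy grid as plain text
#'
#' One comment header line records the bin size and accumulation window;
#' the matrix follows, rows spanning the region width (y) and columns the
#' region length (x).
#'
#' @param occ an `occupancy_grid` (see [run_simulation()]).
#' @param path output path.
#' @export
write_occupancy <- function(occ, path) {
  stopifnot(inherits(occ, "occupancy_grid"))
  header <- sprintf("# bin_size_um=%g window_s=%g,%g", occ$bin_size,
                    occ$window[1], occ$window[2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(occ$grid, con, row.names = FALSE, col.names = FALSE)
}

#' Read an occupancy grid written by [write_occupancy()]
#' @param path file path.
#' @return an `occupancy_grid`.
#' @export
read_occupancy <- function(path) {
  header <- readLines(path, n = 1)
  bin <- as.numeric(sub(".*bin_size_um=([0-9.eE+-]+).*", "\\1", header))
  win <- as.numeric(strsplit(sub(".*window_s=", "", header), ",")[[1]])
  grid <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(grid) <- NULL
  structure(list(grid = grid, bin_size = bin, window = win),
            class = "occupancy_grid")
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$synapses <- as.list(as.data.frame(cfg$synapses))
  out
}

#' Write run outputs and a reproducibility manifest
#'
#' Serializes a replicate set (per-replicate counts and the cross-replicate
#' summary), optional analysis results and optional occupancy grids into a
#' directory, and writes a JSON manifest holding the configuration snapshot,
#' protocol, seeds, package version and MD5 hashes of every file. Re-running
#' the same configuration and seeds reproduces byte-identical count files.
#'
#' @param rep_set a [replicate_set][run_replicates()].
#' @param analysis optional named list of results; `plateau_result` entries
#'   go into `plateau.csv`, a `sweep_result` entry into `sweep.csv`.
#' @param out_dir output directory (created if missing).
#' @param occupancy optional `occupancy_grid`.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(rep_set, analysis = NULL, out_dir,
                          occupancy = NULL) {
  stopifnot(inherits(rep_set, "replicate_set"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  counts_path <- file.path(out_dir, "counts.csv")
  utils::write.csv(as.data.frame(rep_set), counts_path, row.names = FALSE)
  files <- c(files, counts_path)

  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_table(rep_set), summary_path, row.names = FALSE)
  files <- c(files, summary_path)

  if (!is.null(analysis)) {
    plateaus <- Filter(function(z) inherits(z, "plateau_result"), analysis)
    if (length(plateaus)) {
      tab <- do.call(rbind, lapply(names(plateaus), function(nm) {
        p <- plateaus[[nm]]
        data.frame(condition = nm, baseline_mean = p$baseline_mean,
                   plateau_mean = p$plateau_mean,
                   plateau_percent = p$plateau_percent,
                   plateau_percent_sem = p$plateau_percent_sem)
      }))
      plateau_path <- file.path(out_dir, "plateau.csv")
      utils::write.csv(tab, plateau_path, row.names = FALSE)
      files <- c(files, plateau_path)
    }
    sweeps <- Filter(function(z) inherits(z, "sweep_result"), analysis)
    if (length(sweeps)) {
      sweep_path <- file.path(out_dir, "sweep.csv")
      utils::write.csv(as.data.frame(sweeps[[1]]), sweep_path,
                       row.names = FALSE)
      files <- c(files, sweep_path)
    }
  }
  if (!is.null(occupancy)) {
    occ_path <- file.path(out_dir, "occupancy.txt")
    write_occupancy(occupancy, occ_path)
    files <- c(files, occ_path)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ampartrap")),
    config = config_to_list(rep_set$config),
    protocol = if (!is.null(rep_set$spec)) unclass(rep_set$spec) else NULL,
    seeds = rep_set$seeds,
    phases = list(burn_in_s = rep_set$config$t_burn_in,
                  baseline_s = c(0, rep_set$config$t_baseline),
                  post_s = c(rep_set$config$t_baseline,
                             rep_set$config$t_baseline + rep_set$config$t_post)),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
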