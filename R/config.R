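#' Default run configuration
#'
#' The fully-resolved default configuration: reference parameter values for
#' the dynamics (Cr = 1.1, Ca = 1, lr = 1, la = 7.5, k = 25, m = 1, eta = 1,
#' gamma = 0.01, tau = 1), the environment (M = 2 peaks, lambda0 = 10,
#' lambda1 = 20, alpha = (1, 0), beta = 0.1, tau_p = 1500, u = 0, edge
#' length 346), and the evolutionary loop. The caption-level density
#' parameter rho = 0.16 is carried as metadata only; the domain is configured
#' directly by `edge_length`.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    seed = 1L,
    output_dir = "runs",
    dynamics = list(Cr = 1.1, Ca = 1, lr = 1, la = 7.5, k = 25L, m = 1,
                    eta = 1, gamma = 0.01, tau = 1, n_sub = 10L),
    environment = list(n_peaks = 2L, lambda0 = 10, lambda1 = 20,
                       alpha = c(1, 0), beta = 0.1, tau_p = 1500,
                       u = 0, edge_length = 346, rho = 0.16,
                       centroids = "uniform"),
    evolution = list(n_agents = 500L, generations = 100L,
                     steps_per_generation = 1500L,
                     mutation_sd = list(psi0 = 0.05, psi1 = 0.05, lmax = 0.5),
                     lmax_cap = 30, asocial = FALSE, lmax_asocial = 2,
                     init_psi0 = c(0, 1), init_psi1 = c(0, 1),
                     init_lmax = c(0, 30)),
    analysis = list(n_neighbors = 10L, kl_bins = 30L,
                    state_thresholds = c(0, 2.95))),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified values from
#' [default_config()], and validates it. Unknown keys (top-level or within a
#' block) are rejected; every failing key is listed in the error.
#'
#' @param path path to a YAML file, or `NULL` for the pure defaults.
#' @return validated `run_config` with all defaults resolved explicitly.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      bad <- character(0)
      unknown_top <- setdiff(names(user), names(cfg))
      bad <- c(bad, unknown_top)
      for (blk in intersect(names(user), names(cfg))) {
        if (is.list(cfg[[blk]]) && is.list(user[[blk]])) {
          unk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
          if (length(unk)) bad <- c(bad, paste0(blk, "$", unk))
        }
      }
      if (length(bad))
        stop("unknown config keys: ", paste(bad, collapse = ", "))
      cfg <- utils::modifyList(cfg, user)
      class(cfg) <- "run_config"
    }
  }
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Collects every violated constraint and reports them all at once.
#'
#' @param cfg a `run_config`.
#' @return the config, invisibly, or an error listing every failing key.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  d <- cfg$dynamics
  chk(d$Cr > 0 && d$Ca > 0 && d$lr > 0 && d$la > 0,
      "dynamics: strengths and lengths must be positive")
  chk(d$lr < d$la, "dynamics$lr: must be < dynamics$la")
  chk(d$Cr / d$lr > d$Ca / d$la,
      "dynamics: Cr/lr must exceed Ca/la (repulsive at contact)")
  chk(d$k >= 0, "dynamics$k: must be >= 0")
  chk(d$gamma >= 0, "dynamics$gamma: must be >= 0")
  chk(d$tau > 0, "dynamics$tau: must be > 0")
  e <- cfg$environment
  chk(e$n_peaks >= 0, "environment$n_peaks: must be >= 0")
  chk(e$lambda0 >= 0, "environment$lambda0: must be >= 0")
  chk(e$lambda1 > 0, "environment$lambda1: must be > 0")
  chk(e$tau_p > 0, "environment$tau_p: must be > 0")
  chk(e$u >= 0, "environment$u: must be >= 0")
  chk(e$edge_length > 0, "environment$edge_length: must be > 0")
  v <- cfg$evolution
  chk(v$n_agents >= 2, "evolution$n_agents: must be >= 2")
  chk(v$generations >= 1, "evolution$generations: must be >= 1")
  chk(v$steps_per_generation >= 1,
      "evolution$steps_per_generation: must be >= 1")
  chk(all(unlist(v$mutation_sd) >= 0),
      "evolution$mutation_sd: must be >= 0")
  chk(v$lmax_cap > 0, "evolution$lmax_cap: must be > 0")
  if (isTRUE(v$asocial))
    chk(v$lmax_asocial > d$lr && v$lmax_asocial < d$la,
        "evolution$lmax_asocial: must lie in (lr, la)")
  a <- cfg$analysis
  chk(a$n_neighbors >= 1, "analysis$n_neighbors: must be >= 1")
  chk(length(a$state_thresholds) == 2 &&
        a$state_thresholds[1] < a$state_thresholds[2],
      "analysis$state_thresholds: must be two increasing values")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  invisible(cfg)
}

# config -> module objects
config_params <- function(cfg) {
  d <- cfg$dynamics
  social_params(d$Cr, d$Ca, d$lr, d$la, d$k, d$m, d$eta, d$gamma, d$tau,
                d$n_sub)
}

config_field <- function(cfg) {
  e <- cfg$environment
  make_resource_field(e$n_peaks, e$lambda0, e$lambda1, e$centroids,
                      e$alpha, e$beta, e$tau_p, e$u,
                      torus_geometry(e$edge_length))
}

config_evolution <- function(cfg) {
  v <- cfg$evolution
  evolution_config(v$n_agents, v$generations, v$steps_per_generation,
                   unlist(v$mutation_sd), v$lmax_cap,
                   asocial = isTRUE(v$asocial),
                   lmax_asocial = v$lmax_asocial,
                   init_psi0 = v$init_psi0, init_psi1 = v$init_psi1,
                   init_lmax = v$init_lmax)
}

#' Derive an independent sub-stream seed
#'
#' Expands one global seed into per-module seeds through a fixed integer hash
#' of (seed, key), so adding an analysis stage never perturbs the randomness
#' of another. All arithmetic stays below 2^31.
#'
#' @param seed integer global seed.
#' @param key character stream name (e.g. `"dynamics"`, `"evolution"`).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647
  h <- seed %% m
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Persist a run directory
#'
#' Writes each table as CSV together with the resolved configuration (YAML),
#' and a metadata sidecar (JSON) carrying the seed, package version, and MD5
#' content hashes of every table. A run directory is reloadable and
#' re-verifiable from its contents alone. Writes go to a temporary directory
#' first and are moved into place, so a failed write leaves a
#' `*.incomplete` directory rather than a partial run.
#'
#' @param dir target directory (created; must not already exist).
#' @param tables named list of data frames.
#' @param config a `run_config`.
#' @param seed the integer seed the run used.
#' @param format `"csv"` (plain text, default) or `"parquet"` (chunked
#'   binary columnar; requires the arrow package) for the tables.
#' @return `dir`, invisibly.
#' @export
write_run <- function(dir, tables, config, seed,
                      format = c("csv", "parquet")) {
  format <- match.arg(format)
  if (format == "parquet" && !requireNamespace("arrow", quietly = TRUE))
    stop("format = 'parquet' requires the arrow package")
  stopifnot(length(names(tables)) == length(tables), !file.exists(dir))
  tmp <- paste0(dir, ".incomplete")
  if (file.exists(tmp)) unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) NULL else NULL, add = TRUE)
  ext <- if (format == "csv") ".csv" else ".parquet"
  for (nm in names(tables)) {
    if (format == "csv")
      write.csv(tables[[nm]], file.path(tmp, paste0(nm, ".csv")),
                row.names = FALSE)
    else
      arrow::write_parquet(tables[[nm]], file.path(tmp, paste0(nm, ".parquet")))
  }
  yaml::write_yaml(unclass(config), file.path(tmp, "config.yaml"))
  files <- list.files(tmp, pattern = paste0("\\", ext, "$"))
  hashes <- as.list(tools::md5sum(file.path(tmp, files)))
  names(hashes) <- files
  meta <- list(seed = seed,
               format = format,
               package = "swarmevol",
               version = as.character(utils::packageVersion("swarmevol")),
               tables = names(tables),
               hashes = hashes)
  jsonlite::write_json(meta, file.path(tmp, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, dir)
  ok <- TRUE
  invisible(dir)
}

#' Reload a persisted run
#'
#' @param dir a directory written by [write_run()].
#' @return list with `tables` (named data frames), `config`, `metadata`.
#' @export
read_run <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  fmt <- if (is.null(meta$format)) "csv" else meta$format
  tables <- lapply(setNames(meta$tables, meta$tables), function(nm) {
    if (fmt == "csv") read.csv(file.path(dir, paste0(nm, ".csv")))
    else as.data.frame(arrow::read_parquet(file.path(dir,
                                                     paste0(nm, ".parquet"))))
  })
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  class(cfg) <- "run_config"
  list(tables = tables, config = cfg, metadata = meta)
}

#' Verify the content hashes of a persisted run
#'
#' @param dir a directory written by [write_run()].
#' @return `TRUE` if every table matches its recorded MD5 hash, otherwise
#'   `FALSE` (with a warning naming the mismatching files).
#' @export
verify_run <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- names(meta$hashes)
  now <- unname(tools::md5sum(file.path(dir, files)))
  bad <- files[now != unlist(meta$hashes)]
  if (length(bad)) {
    warning("hash mismatch: ", paste(bad, collapse = ", "))
    return(FALSE)
  }
  TRUE
}
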