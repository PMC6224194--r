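## Configuration files (YAML), run manifests and plain-text outputs.

config_schema <- list(
  network = c("N", "tau", "alpha", "wI", "wmax", "w_init", "dt"),
  input = c("I0", "IPF", "Itheta", "f", "place_field_on"),
  motion = c("kind", "v_const", "v0", "sigma_v", "tau_v", "sigma_scaling"),
  depression = c("tau_x", "U0"),
  plasticity = c("rule", "A_plus", "tau_plus", "A_minus", "tau_minus",
                 "A3_plus", "tau_y", "A3_minus", "tau_x3", "scale")
)

#' Load and validate a simulation configuration
#'
#' Reads a YAML file with optional `network`, `input`, `motion`, `depression`
#' and `plasticity` sections mirroring [network_params()], [input_config()],
#' [motion_model()], [depression_params()] and the plasticity-rule
#' constructors. Unknown sections or keys are rejected; missing keys take the
#' package defaults; all type invariants are enforced by the constructors.
#' The `plasticity` section may name a preset via `rule` (`"pair"`,
#' `"triplet"`, `"antisymmetric"`, `"depression_dominant"`, or `"none"`) with
#' optional parameter overrides and an amplitude `scale`.
#'
#' @param path YAML file path.
#' @return list with validated `params`, `input`, `motion`, `dep`, `rule`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  ## YAML 1.1 parses a bare `N` key as the boolean FALSE; map it back
  if (!is.null(raw$network) && "FALSE" %in% names(raw$network)) {
    names(raw$network)[names(raw$network) == "FALSE"] <- "N"
  }
  bad_sec <- setdiff(names(raw), names(config_schema))
  if (length(bad_sec)) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    }
  }
  build <- function(sec, ctor) do.call(ctor, raw[[sec]] %||% list())
  pl <- raw$plasticity %||% list()
  preset <- pl$rule %||% "pair"
  pl$rule <- NULL
  scale <- pl$scale %||% 1
  pl$scale <- NULL
  rule <- if (identical(preset, "none")) NULL else {
    base <- plasticity_preset(preset)
    if (length(pl)) {
      args <- as.list(base)[intersect(names(base), c(
        "A_plus", "tau_plus", "A_minus", "tau_minus"))]
      args[names(pl)] <- pl
      base <- if (inherits(base, "triplet_rule")) {
        full <- as.list(base)
        full[names(pl)] <- pl
        do.call(triplet_rule, list(A2_plus = full$A_plus,
                                   tau_plus = full$tau_plus,
                                   A2_minus = full$A_minus,
                                   tau_minus = full$tau_minus,
                                   A3_plus = full$A3_plus,
                                   tau_y = full$tau_y,
                                   A3_minus = full$A3_minus,
                                   tau_x3 = full$tau_x3))
      } else {
        do.call(pair_rule, args)
      }
    }
    scale_rule(base, scale)
  }
  list(params = build("network", network_params),
       input = build("input", input_config),
       motion = build("motion", motion_model),
       dep = build("depression", depression_params),
       rule = rule)
}

#' Run manifest
#'
#' Reproducibility record written alongside every output set: configuration
#' snapshot, seed, package version, timestamp, chosen conventions (OU noise
#' scaling, offset sign) and the registry of output files.
#'
#' @param config list as returned by [load_config()] (or equivalent).
#' @param seed integer seed used for the run.
#' @param files named character vector of output paths.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, files = character()) {
  structure(list(
    package_version = as.character(utils::packageVersion("thetaring")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    conventions = list(
      ou_sigma_scaling = tryCatch(config$motion$sigma_scaling,
                                  error = function(e) NULL),
      offset_sign = "post_minus_pre",
      position_interval = "[-pi, pi)"),
    config = config,
    files = as.list(files)
  ), class = "run_manifest")
}

#' Write simulation outputs to plain-text files
#'
#' Writes the recorded state trajectory (`<stem>_trajectory.csv`: time_s,
#' position, velocity, lfp, then per-neuron rate and depression columns),
#' spike events (`<stem>_spikes.csv`: neuron_id, time_s), the final weight
#' matrix (`<stem>_W.csv`) and the JSON manifest (`<stem>_manifest.json`).
#'
#' @param sim a `ring_sim` object.
#' @param stem output path stem.
#' @param seed seed recorded in the manifest.
#' @return (invisibly) the manifest.
#' @export
write_run_outputs <- function(sim, stem, seed = sim$seed) {
  stopifnot(inherits(sim, "ring_sim"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  N <- sim$params$N
  traj <- data.frame(time_s = sim$time, position = sim$position,
                     velocity = sim$velocity, lfp = sim$lfp)
  rates <- as.data.frame(sim$rates)
  names(rates) <- paste0("r", seq_len(N))
  depr <- as.data.frame(sim$depression)
  names(depr) <- paste0("x", seq_len(N))
  files <- c(trajectory = paste0(stem, "_trajectory.csv"),
             spikes = paste0(stem, "_spikes.csv"),
             weights = paste0(stem, "_W.csv"),
             manifest = paste0(stem, "_manifest.json"))
  write.csv(cbind(traj, rates, depr), files[["trajectory"]],
            row.names = FALSE)
  write.csv(sim$spikes, files[["spikes"]], row.names = FALSE)
  write.csv(as.data.frame(sim$W), files[["weights"]], row.names = FALSE)
  man <- run_manifest(list(params = sim$params, input = sim$input,
                           motion = sim$motion, dep = sim$dep,
                           rule = sim$rule),
                      seed = seed, files = files)
  jsonlite::write_json(man, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(man)
}

#' Read a weight matrix written by [write_run_outputs()]
#'
#' @param path CSV path.
#' @return numeric matrix.
#' @export
read_weight_matrix <- function(path) {
  as.matrix(read.csv(path))
}
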