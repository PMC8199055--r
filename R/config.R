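# Pipeline configuration: YAML-backed, strictly validated, hashable.

#' Default pipeline configuration
#'
#' Every tunable parameter of the simulate -> fit -> reference -> detect ->
#' dice pipeline with its default value.  A YAML config file may override
#' any subset; unknown keys are rejected.
#'
#' @return a nested list (class `pipeline_config`).
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    n_reference = 3L,
    phantom = list(
      grid_shape = c(64L, 64L, 24L),
      voxel_size = c(2, 2, 5),
      anat_voxel_size = c(1, 1, 3),
      snr = 40
    ),
    scheme = list(
      b_values = c(0, 500, 1000, 1500, 2000, 2500),
      n_directions = 30L
    ),
    fit = list(sigma = 1.25, k_max = 3, d_max = 5, weighted = FALSE),
    histogram = list(md_max = 3.5, md_step = 0.05,
                     mk_max = 3.0, mk_step = 0.02),
    signature = list(tau = 1e-5, dilate = 1L, min_cluster = 10L,
                     bounds = list(md = c(0.2, 3.0), mk = c(0.1, 2.0))),
    evaluation = list(grid = "dki")
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file, overlays it on [default_pipeline_config()], rejects
#' unknown keys and validates parameter ranges.
#'
#' @param path YAML file path; `NULL` returns the validated defaults.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  config <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config <- merge_config(config, user, keypath = "")
  }
  validate_pipeline_config(config)
  config
}

merge_config <- function(base, user, keypath) {
  if (is.null(user)) return(base)
  if (!is.list(user)) stop("config entry '", keypath, "' must be a mapping",
                           call. = FALSE)
  for (key in names(user)) {
    full <- if (nzchar(keypath)) paste0(keypath, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: '", full, "'", call. = FALSE)
    if (is.list(base[[key]]) && !is.null(names(base[[key]])))
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    else
      base[[key]] <- user[[key]]
  }
  base
}

validate_pipeline_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg,
                                             call. = FALSE)
  chk(is.numeric(config$seed) && length(config$seed) == 1L, "seed")
  chk(config$n_reference >= 1, "n_reference must be >= 1")
  chk(all(config$phantom$grid_shape >= 4), "phantom.grid_shape")
  chk(all(config$phantom$voxel_size > 0), "phantom.voxel_size")
  chk(all(config$phantom$anat_voxel_size > 0), "phantom.anat_voxel_size")
  chk(config$phantom$snr > 0, "phantom.snr must be > 0")
  chk(any(config$scheme$b_values == 0), "scheme.b_values must include 0")
  chk(config$scheme$n_directions >= 6, "scheme.n_directions >= 6")
  chk(config$fit$sigma >= 0, "fit.sigma must be >= 0")
  chk(config$fit$k_max > 0, "fit.k_max must be > 0")
  chk(config$fit$d_max > 0, "fit.d_max must be > 0")
  chk(config$histogram$md_step > 0 && config$histogram$mk_step > 0,
      "histogram steps must be > 0")
  chk(config$signature$tau >= 0, "signature.tau must be >= 0")
  chk(config$signature$dilate >= 0, "signature.dilate must be >= 0")
  chk(config$signature$min_cluster >= 0, "signature.min_cluster must be >= 0")
  chk(config$evaluation$grid %in% c("dki", "anat"),
      "evaluation.grid must be 'dki' or 'anat'")
  invisible(config)
}

# 32-bit FNV-1a hash of the canonical deparse of an R object; used to stamp
# artifacts with the configuration that produced them.
config_hash <- function(config) {
  s <- paste(deparse(config, control = c("keepNA", "niceNames")),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2_32(h, b)
    h <- mul_mod_2_32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor2_32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through two 16-bit halves
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

mul_mod_2_32 <- function(a, m) {
  lo <- (a %% 65536) * m
  hi <- ((a %/% 65536) * m) %% 65536
  (lo + hi * 65536) %% 4294967296
}

#' Derive a stage-local RNG seed from the global seed
#'
#' Stable string hashing keeps stages independent while fully determined by
#' the one global seed; results stay below 2^31.
#'
#' @param seed global integer seed.
#' @param tag stage name.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  s <- paste0(seed, "/", tag)
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2_32(h, b)
    h <- mul_mod_2_32(h, 16777619)
  }
  as.integer(h %% 2147483646) + 1L
}
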