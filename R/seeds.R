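#' Derive a child seed from a global seed and a stage label
#'
#' Every stochastic stage of a pipeline draws its own seed from the single
#' global seed plus a fixed stage label, so adding or reordering stages does
#' not shift another stage's random stream.
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. `"bootstrap"`, `"simulator"`).
#' @return An integer seed in `[1, 2^31 - 2]`, deterministic in both inputs.
#' @examples
#' derive_seed(1L, "bootstrap")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483629  # largest prime < 2^31, keeps everything in integer range
  h <- as.double(seed) %% m
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% m
  as.integer(h %% (m - 1L) + 1)
}

#' Read a run configuration from YAML
#'
#' A run configuration is a plain list with a mandatory integer `seed` and
#' optional per-module parameter blocks (`simulator`, `fst`, `rarefaction`,
#' `hotspots`, `bootstrap`, `synth`). Unknown blocks are kept as-is.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must contain a 'seed' field")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (seed ", x$seed, ")\n", sep = "")
  blocks <- setdiff(names(x), "seed")
  if (length(blocks)) cat("  blocks:", paste(blocks, collapse = ", "), "\n")
  invisible(x)
}
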