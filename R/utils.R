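# Shared helpers: seeded evaluation, deterministic per-library seeds,
# run manifests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a deterministic per-library seed
#'
#' Hashes a library identifier together with a root seed into a 31-bit
#' integer, so that every simulated library gets its own reproducible RNG
#' stream while the whole experiment is governed by one root seed.
#'
#' @param library_id character identifier.
#' @param root_seed integer root seed of the experiment.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(library_id, root_seed) {
  stopifnot(length(library_id) == 1L, length(root_seed) == 1L)
  mod <- 2147483629  # prime below 2^31
  h <- as.numeric(root_seed) %% mod
  for (b in utf8ToInt(as.character(library_id))) {
    h <- (h * 131 + b) %% mod
  }
  as.integer(h)
}

#' Write a run manifest
#'
#' Records, as JSON, the parameters, seeds, match mode and input file
#' checksums of a command-line run, so any output can be regenerated.
#'
#' @param path output JSON path.
#' @param command subcommand name.
#' @param params named list of parameter values.
#' @param inputs character vector of input file paths (checksummed).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, params = list(),
                           inputs = character(0)) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    tool = "primercov",
    version = as.character(utils::packageVersion("primercov")),
    command = command,
    params = params,
    input_md5 = as.list(tools::md5sum(inputs)),
    coordinate_convention = "reports 1-based inclusive; BED 0-based half-open")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
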