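TRAJ_SCHEMA <- "scemsort-trajectory v1"

#' Write a trajectory to a plain-text file
#'
#' Serialises the snapshots, contact graphs, division events and the final
#' element/cell tables of a growth run into a single sectioned CSV file
#' with a versioned schema header. The round trip through
#' [read_trajectory()] is lossless for all tables.
#'
#' @param traj An `sce_trajectory` (or a compatible list of tibbles with
#'   elements `snapshots`, `contacts`, `events`, and optionally
#'   `aggregate`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", TRAJ_SCHEMA), con)
  sections <- list(snapshots = traj$snapshots, contacts = traj$contacts,
                   events = traj$events)
  if (!is.null(traj$aggregate)) {
    sections$elements <- element_table(update_structure(traj$aggregate))
    sections$cells <- traj$aggregate$cells
    writeLines(sprintf("#time %.12g", traj$aggregate$time), con)
  }
  for (nm in names(sections)) {
    tab <- sections[[nm]]
    if (is.null(tab)) tab <- tibble::tibble()
    writeLines(sprintf("#section %s %d", nm, nrow(tab)), con)
    if (nrow(tab)) {
      write.csv(tab, con, row.names = FALSE)
    } else {
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a trajectory file
#'
#' @param path A file written by [write_trajectory()].
#' @return A named list of tibbles (one per stored section) plus the stored
#'   final `time` if present.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != paste0("#", TRAJ_SCHEMA))
    stop("schema mismatch: expected header '#", TRAJ_SCHEMA, "'")
  out <- list()
  i <- 2L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#time ")) {
      out$time <- as.numeric(sub("#time ", "", ln))
      i <- i + 1L
    } else if (startsWith(ln, "#section ")) {
      hdr <- strsplit(ln, " ")[[1]]
      nm <- hdr[2]
      n <- as.integer(hdr[3])
      if (n > 0) {
        blk <- lines[(i + 1):(i + 1 + n)]  # header row + n data rows
        out[[nm]] <- tibble::as_tibble(
          read.csv(text = paste(blk, collapse = "\n")))
        i <- i + 2L + n
      } else {
        out[[nm]] <- tibble::tibble()
        i <- i + 2L
      }
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Read a run configuration from YAML
#'
#' The configuration mirrors [sim_params()] and [lifecycle_params()]
#' argument names under `params:` and `lifecycle:` blocks, with optional
#' top-level `seed` and `scale` (`"test"` or `"production"`). Unknown keys
#' are rejected. The fully resolved configuration (all defaults filled in)
#' is attached so it can be echoed to a run log.
#'
#' @param path Path to a YAML file.
#' @return A list with `params`, `lifecycle`, `seed`, `scale`, and
#'   `resolved` (the full parameter echo).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  scale <- cfg$scale %||% "test"
  preset <- scale_preset(scale)
  pargs <- cfg$params %||% list()
  largs <- cfg$lifecycle %||% list()
  bad <- setdiff(names(pargs), names(formals(sim_params)))
  if (length(bad)) stop("unknown params keys: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(largs), names(formals(lifecycle_params)))
  if (length(bad)) stop("unknown lifecycle keys: ", paste(bad, collapse = ", "))
  params <- do.call(sim_params, pargs)
  lifecycle <- do.call(lifecycle_params, largs)
  res <- list(seed = cfg$seed, scale = scale,
              params = unclass(params), lifecycle = unclass(lifecycle),
              preset = preset)
  list(params = params, lifecycle = lifecycle, seed = cfg$seed,
       scale = scale, preset = preset, resolved = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale presets
#'
#' `"test"`: desk-scale runs (24 elements per cell, 1e3 shuffles);
#' `"production"`: the full-resolution settings (128 elements per cell,
#' 1e4 shuffles).
#'
#' @param scale `"test"` or `"production"`.
#' @return A list with `elements_per_cell` and `n_shuffles`.
#' @export
scale_preset <- function(scale = c("test", "production")) {
  scale <- match.arg(scale)
  switch(scale,
         test = list(elements_per_cell = 24L, n_shuffles = 1e3L),
         production = list(elements_per_cell = 128L, n_shuffles = 1e4L))
}

#' Echo a resolved configuration as YAML
#'
#' @param config A list from [read_run_config()] (its `resolved` element is
#'   written), or any list.
#' @param con A connection or file path (default: standard error).
#' @return The YAML text, invisibly.
#' @export
echo_config <- function(config, con = stderr()) {
  x <- config$resolved %||% config
  x <- rapply(x, function(v) if (is.matrix(v)) as.vector(v) else v, how = "replace")
  txt <- yaml::as.yaml(x)
  writeLines(txt, con)
  invisible(txt)
}
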