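#' Export / import a tissue and its contact graph as CSV + JSON metadata
#'
#' Writes \code{positions.csv} (id, x, y, radius), \code{edges.csv}
#' (id_i, id_j) and \code{tissue_meta.json} (seed if known, package
#' version). Re-importing rebuilds the identical graph and hop distances.
#'
#' @param tissue a [Tissue-class] object.
#' @param graph the matching [CellGraph-class] object.
#' @param dir output directory (created if missing).
#' @param seed optional seed recorded in the metadata.
#' @return invisibly, the written file paths.
#' @export
exportTissue <- function(tissue, graph, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pos <- data.frame(id = seq_len(nCells(tissue)),
                    x = tissue@positions[, 1], y = tissue@positions[, 2],
                    radius = tissue@radius)
  ed <- which(graph@adjacency & upper.tri(graph@adjacency), arr.ind = TRUE)
  edges <- data.frame(id_i = ed[, 1], id_j = ed[, 2])
  files <- file.path(dir, c("positions.csv", "edges.csv", "tissue_meta.json"))
  utils::write.csv(pos, files[1], row.names = FALSE)
  utils::write.csv(edges, files[2], row.names = FALSE)
  meta <- list(seed = seed, n = nCells(tissue),
               generator = paste0("fatepattern ",
                                  as.character(utils::packageVersion("fatepattern"))))
  jsonlite::write_json(meta, files[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' @rdname exportTissue
#' @return for `importTissue`, a list with \code{tissue} and \code{graph}.
#' @export
importTissue <- function(dir) {
  pos <- utils::read.csv(file.path(dir, "positions.csv"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  tissue <- new("Tissue", positions = cbind(pos$x, pos$y),
                radius = pos$radius[1])
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  idx <- cbind(edges$id_i, edges$id_j)
  adj[idx] <- TRUE
  adj[idx[, c(2, 1), drop = FALSE]] <- TRUE
  list(tissue = tissue, graph = .cellGraphFromAdjacency(adj))
}

#' Write a per-cell state table
#'
#' Columns: id, x, y, u, v, s, label.
#'
#' @param state a [TissueState-class] object.
#' @param tissue the matching [Tissue-class] object (for coordinates).
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeStateCSV <- function(state, tissue, path) {
  stopifnot(nCells(state) == nCells(tissue))
  df <- data.frame(id = seq_len(nCells(state)),
                   x = tissue@positions[, 1], y = tissue@positions[, 2],
                   u = state@u, v = state@v, s = state@s,
                   label = state@labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a signal kernel as dense CSV
#'
#' @param kernel a [SignalKernel-class] object.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeKernelCSV <- function(kernel, path) {
  utils::write.table(kernel@weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

.config_schema <- list(
  params = c("r_u", "r_v", "gamma_u", "gamma_v", "eta_u", "eta_v", "eta_s",
             "eta_vs", "delta_eps_u", "delta_eps_v", "delta_eps_s",
             "delta_eps_vs", "eta_uv", "eta_us", "eta_uvs"),
  tissue = c("kind", "n", "rows", "cols", "periodic", "seed"),
  signal = c("kind", "q"),
  integration = c("dt", "tol", "max_steps"),
  experiment = c("kind", "n_grid", "target_counts", "ratio_threshold"),
  seed = NULL, out = NULL
)

#' Read and validate a run configuration
#'
#' YAML with sections \code{params} (flat model-parameter keys), \code{tissue}
#' (kind: disc|hex|line, n or rows/cols, periodic, seed), \code{signal}
#' (kind: neighbor-mean|dispersion, q), \code{integration} (dt, tol,
#' max_steps), \code{experiment} (kind: simulate|sweep|bisect|pcf, n_grid,
#' target_counts), plus top-level \code{seed} and \code{out}. Unknown keys
#' anywhere are rejected with a report naming each one.
#'
#' @param path path to the YAML config.
#' @return a validated config list (class "fatepattern_config").
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 implicitly types the bare key "n" as a boolean; undo it
  nm <- names(cfg$tissue)
  nm[nm == "FALSE"] <- "n"
  names(cfg$tissue) <- nm
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config a config list (as from YAML) to validate.
#' @export
validateRunConfig <- function(config) {
  errs <- character()
  bad_top <- setdiff(names(config), names(.config_schema))
  if (length(bad_top)) errs <- c(errs, paste0("unknown key: ", bad_top))
  for (sec in intersect(names(config), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) errs <- c(errs, paste0("unknown key: ", sec, ".", bad))
  }
  if (is.null(config$params)) errs <- c(errs, "missing section: params")
  tk <- config$tissue$kind
  if (!is.null(tk) && !tk %in% c("disc", "hex", "line"))
    errs <- c(errs, paste0("tissue.kind must be disc|hex|line, got: ", tk))
  sk <- config$signal$kind
  if (!is.null(sk) && !sk %in% c("neighbor-mean", "dispersion"))
    errs <- c(errs, paste0("signal.kind must be neighbor-mean|dispersion, got: ", sk))
  ek <- config$experiment$kind
  if (!is.null(ek) && !ek %in% c("tissue", "simulate", "sweep", "bisect", "pcf"))
    errs <- c(errs, paste0("experiment.kind must be tissue|simulate|sweep|bisect|pcf, got: ", ek))
  if (length(errs))
    stop("invalid run config:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(config, class = c("fatepattern_config", "list"))
}

# fill defaults without mutating validated keys
.configWithDefaults <- function(config) {
  defaults <- list(
    tissue = list(kind = "disc", n = 177, rows = 6, cols = 6,
                  periodic = FALSE, seed = NULL),
    signal = list(kind = "neighbor-mean", q = 0.5),
    integration = list(dt = NULL, tol = 1e-8, max_steps = 1e7),
    experiment = list(kind = "simulate", n_grid = 20, target_counts = NULL,
                      ratio_threshold = 1),
    seed = 1, out = "fatepattern_out")
  for (sec in c("tissue", "signal", "integration", "experiment")) {
    for (key in names(defaults[[sec]]))
      if (is.null(config[[sec]][[key]]))
        config[[sec]][[key]] <- defaults[[sec]][[key]]
  }
  if (is.null(config$seed)) config$seed <- defaults$seed
  if (is.null(config$out)) config$out <- defaults$out
  config
}

#' Run a configured experiment end to end
#'
#' Orchestrates tissue generation, kernel construction, dynamics and (for
#' experiment kind "pcf") pattern quantification, and writes all artifact
#' files plus a metadata record (config echo, seeds, package version)
#' sufficient to reproduce the run bit-for-bit.
#'
#' Experiment kind "tissue" writes only the tissue/graph files.
#'
#' @param config a config list from [readRunConfig()]/[validateRunConfig()].
#' @param out optional output directory overriding the config.
#' @return invisibly, a list with \code{status} ("ok" or "not-converged"),
#'   \code{files} written, and the main result object.
#' @export
runExperiment <- function(config, out = NULL) {
  config <- validateRunConfig(unclass(config))
  config <- .configWithDefaults(config)
  if (!is.null(out)) config$out <- out
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  params <- paramsFromList(config$params)
  seed <- config$seed
  tseed <- if (is.null(config$tissue$seed)) .subSeed(seed, "tissue") else config$tissue$seed

  tg <- switch(config$tissue$kind,
    disc = { t <- discTissue(config$tissue$n, seed = tseed)
             list(tissue = t, graph = contactGraph(t)) },
    hex = hexLattice(config$tissue$rows, config$tissue$cols,
                     config$tissue$periodic),
    line = list(tissue = .lineTissue(config$tissue$n),
                graph = lineGraph(config$tissue$n)))
  kernel <- switch(config$signal$kind,
    "neighbor-mean" = neighborMeanKernel(tg$graph),
    "dispersion" = dispersionKernel(tg$graph, config$signal$q))

  it <- config$integration
  files <- exportTissue(tg$tissue, tg$graph, config$out, seed = tseed)
  status <- "ok"
  kind <- config$experiment$kind
  result <- NULL
  if (kind == "tissue") {
    result <- tg
  } else if (kind %in% c("simulate", "pcf")) {
    st <- simulateTissue(tg$graph, kernel, params, dt = it$dt, tol = it$tol,
                         max_steps = it$max_steps, seed = seed)
    if (!st@converged) status <- "not-converged"
    else st <- classifyFates(st, config$experiment$ratio_threshold)
    f <- writeStateCSV(st, tg$tissue, file.path(config$out, "state.csv"))
    files <- c(files, f)
    result <- st
    if (kind == "pcf" && st@converged) {
      pc <- pairCorrelation(st@labels, tg$graph@distances)
      f <- file.path(config$out, "pcf.csv")
      utils::write.csv(as.data.frame(pc), f, row.names = FALSE)
      files <- c(files, f)
      result <- pc
    }
  } else if (kind == "sweep") {
    sw <- proportionSweep(tg$graph, kernel, params,
                          n_grid = config$experiment$n_grid, seed = seed,
                          dt = it$dt, tol = it$tol, max_steps = it$max_steps)
    if (!all(sw@converged)) status <- "not-converged"
    f <- file.path(config$out, "sweep.csv")
    utils::write.csv(as.data.frame(sw), f, row.names = FALSE)
    files <- c(files, f)
    result <- sw
  } else if (kind == "bisect") {
    tc <- config$experiment$target_counts
    if (is.null(tc)) {
      n <- nCells(tg$graph)
      tc <- c(ceiling(n / 2), floor(n / 2))
    }
    bi <- bisectRatio(tg$graph, kernel, params, target_counts = tc,
                      seed = seed, dt = it$dt, tol = it$tol,
                      max_steps = it$max_steps)
    if (!bi$achieved) status <- "not-converged"
    f <- writeStateCSV(bi$state, tg$tissue, file.path(config$out, "state.csv"))
    f2 <- file.path(config$out, "bisect.json")
    jsonlite::write_json(list(neg_delta_eps = bi$neg_delta_eps,
                              counts = as.list(bi$counts),
                              achieved = bi$achieved),
                         f2, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, f, f2)
    result <- bi
  }

  meta <- list(config = unclass(config), seed = seed, tissue_seed = tseed,
               package_version = as.character(utils::packageVersion("fatepattern")),
               r_version = R.version.string, status = status)
  mf <- file.path(config$out, "run_meta.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, mf)
  invisible(list(status = status, files = files, result = result))
}
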