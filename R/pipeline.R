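#' Default run configuration
#'
#' All analysis constants are defaulted, overridable keys: the leaflet and
#' cluster linkage cutoffs (1.2 nm), the onset persistence (1 ns), the
#' post-fusion analysis window (1500-2000 ns) and snapshot stride (200 ps),
#' and the RDF binning (0.02 nm up to 3 nm).
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    stages = c("onset", "migration", "rdf", "clusters", "order"),
    input = list(coords = NULL, trajectory = NULL, topology = NULL),
    synthetic = NULL,
    window_ps = c(1.5e6, 2e6),
    stride_ps = 200,
    leaflet_cutoff = 1.2,
    cluster_cutoff = 1.2,
    persistence_ns = 1.0,
    rdf = list(r_max = 3.0, bin_width = 0.02),
    design = list(grid_step = 10, replicas = 3),
    out_dir = NULL,
    seed = 1L
  )
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file keep their [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), y)
  if (!is.null(cfg$window_ps)) cfg$window_ps <- as.numeric(unlist(cfg$window_ps))
  if (!is.null(cfg$synthetic)) {
    cfg$synthetic <- do.call(synthetic_params, cfg$synthetic)
  }
  cfg
}

.log_info <- function(...) {
  message(sprintf("[%s] INFO %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

#' Run the full fusion-analysis pipeline
#'
#' Validates the configuration, loads (or generates) the trajectory, and
#' executes the requested stages in dependency order: fusion-onset
#' detection first (the later stages presume the post-fusion window),
#' then leaflet migration, head-group RDFs, maximum-cluster tracking and
#' segmental order parameters. The protonation design matrix is always
#' attached. When `cfg$out_dir` is set, every table is written as CSV
#' alongside a JSON provenance block (config hash, package version, seed).
#'
#' @param cfg configuration list (see [default_run_config()] /
#'   [read_run_config()]), or a path to a YAML file.
#' @return object of class `fusion_report`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- utils::modifyList(default_run_config(), cfg)
  t0 <- Sys.time()
  if (!is.null(cfg$synthetic)) {
    .log_info("generating synthetic run (seed %d)", cfg$synthetic$seed)
    run <- generate_fusion_trajectory(cfg$synthetic)
    traj <- run$trajectory
    topology <- run$topology
    provenance_input <- list(synthetic_seed = cfg$synthetic$seed)
  } else {
    inp <- cfg$input
    if (is.null(inp$coords) || is.null(inp$topology)) {
      stop("config needs input$coords and input$topology (or a synthetic block)",
           call. = FALSE)
    }
    topology <- read_topology(inp$topology)
    traj <- read_trajectory(inp$coords, inp$trajectory, topology)
    provenance_input <- list(coords = inp$coords, trajectory = inp$trajectory,
                             checksums = as.list(tools::md5sum(
                               unlist(inp[c("coords", "trajectory", "topology")]))))
    .log_info("loaded trajectory: %d beads x %d frames", nrow(traj$atoms), n_frames(traj))
  }
  # validate the window before any computation
  if (any(c("migration", "rdf", "order") %in% cfg$stages)) {
    if (cfg$window_ps[1] >= cfg$window_ps[2]) {
      stop("window start must precede window end", call. = FALSE)
    }
    tspan <- range(traj$times_ps)
    if (cfg$window_ps[1] < tspan[1] || cfg$window_ps[2] > tspan[2]) {
      stop(sprintf("analysis window %g-%g ps outside trajectory span %g-%g ps",
                   cfg$window_ps[1], cfg$window_ps[2], tspan[1], tspan[2]),
           call. = FALSE)
    }
  }
  report <- list(config = cfg,
                 design = build_design_matrix(grid_step = cfg$design$grid_step,
                                              replicas = cfg$design$replicas))
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- expr
    .log_info("stage %-9s done in %.2f s", name,
              as.numeric(difftime(Sys.time(), ts, units = "secs")))
    out
  }
  if ("onset" %in% cfg$stages) {
    report$onset <- stage("onset", fusion_onset(traj, topology, cfg$persistence_ns))
  }
  if ("migration" %in% cfg$stages) {
    ref <- build_leaflet_reference(traj, topology, cfg$leaflet_cutoff)
    report$migration <- stage("migration",
      migration_fractions(traj, ref, topology, cfg$window_ps, cfg$stride_ps))
  }
  if ("rdf" %in% cfg$stages) {
    frames <- window_frames(traj, cfg$window_ps, cfg$stride_ps)
    report$rdf <- stage("rdf",
      headgroup_rdfs(traj, topology, cfg$rdf$r_max, cfg$rdf$bin_width, frames))
  }
  if ("clusters" %in% cfg$stages) {
    report$clusters <- stage("clusters",
      max_cluster_timeseries(traj, topology, stride_ps = cfg$stride_ps,
                             cutoff = cfg$cluster_cutoff))
  }
  if ("order" %in% cfg$stages) {
    report$order <- stage("order",
      segmental_order_profile(traj, topology, cfg$window_ps, cfg$stride_ps))
  }
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("lndfusion")),
    config_hash = .config_hash(cfg), seed = cfg$seed, input = provenance_input,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "fusion_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("<fusion_report> stages:", paste(intersect(
    c("onset", "migration", "rdf", "clusters", "order"), names(x)), collapse = ", "), "\n")
  cat("  design:", attr(x$design, "n_complexes"), "complexes /",
      attr(x$design, "n_runs"), "runs\n")
  if (!is.null(x$onset)) print(x$onset)
  invisible(x)
}

#' Write every table of a report as CSV plus a provenance JSON
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    f <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), f, row.names = FALSE)
    files <<- c(files, f)
  }
  put(report$design, "design_matrix")
  if (!is.null(report$onset)) {
    put(report$onset$series, "delta_z")
    o <- report$onset
    jsonlite::write_json(
      list(onset_ps = o$onset_time_ps, onset_frame = o$onset_frame,
           first_entrant = o$first_entrant, il_rank = o$il_rank,
           censored = o$censored),
      file.path(dir, "onset.json"), auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, file.path(dir, "onset.json"))
  }
  if (!is.null(report$migration)) put(report$migration, "migration_fractions")
  if (!is.null(report$rdf)) {
    for (s in names(report$rdf)) {
      if (!is.null(report$rdf[[s]])) put(report$rdf[[s]], paste0("rdf_", tolower(s)))
    }
  }
  if (!is.null(report$clusters)) put(report$clusters, "max_cluster")
  if (!is.null(report$order)) put(report$order, "order_parameters")
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(dir, "provenance.json"))
  invisible(files)
}

#' Aggregate replicate pipeline reports
#'
#' Checks that the reports describe the same design entry (same synthetic
#' parameters apart from the seed, or user-asserted identity) and
#' aggregates their migration fractions into replica mean and sample SD;
#' per-replica values are retained alongside. A single report passes
#' through flagged as such.
#'
#' @param reports list of [run_pipeline()] results (or of
#'   [migration_fractions()] tables).
#' @return list of class `replica_summary` with `migration`
#'   (a [replica_mean_sd()] table) and `per_replica`.
#' @export
summarize_replicas <- function(reports) {
  stopifnot(length(reports) >= 1L)
  mig <- lapply(reports, function(r) {
    if (inherits(r, "fusion_report")) r$migration else r
  })
  if (any(vapply(mig, is.null, TRUE))) {
    stop("all reports must contain a migration stage", call. = FALSE)
  }
  ident <- lapply(reports, function(r) {
    if (!inherits(r, "fusion_report") || is.null(r$config$synthetic)) return(NULL)
    s <- r$config$synthetic
    list(il = s$il, membrane = s$membrane, percent = s$protonated_percent)
  })
  ident <- Filter(Negate(is.null), ident)
  if (length(ident) > 1L && !all(vapply(ident[-1], identical, TRUE, y = ident[[1]]))) {
    stop("reports mix different design entries; refusing to aggregate", call. = FALSE)
  }
  out <- list(migration = replica_mean_sd(mig), per_replica = mig,
              n_replicas = length(mig))
  class(out) <- "replica_summary"
  out
}

#' @export
print.replica_summary <- function(x, ...) {
  print(x$migration)
  invisible(x)
}
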