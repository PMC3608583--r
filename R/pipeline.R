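# Configuration-driven orchestration: per-system RMSD, groove compartments,
# interaction networks, entropy and SIE/IC50, with provenance and
# multi-system comparison.

# recursively overlay user config onto the defaults profile
.mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(over[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML run configuration (or accepts an equivalent list) and
#' overlays it on the packaged defaults profile, which encodes the standard
#' analysis settings: binding-site ranges alpha 5-76 / beta 5-90, the D1-D4
#' compartments, the 3.1 Angstrom / 130 degree hydrogen-bond criteria, the
#' 30 degree / 5 Angstrom stacking criteria, 20% persistence, 310 K and the
#' 20 ps SIE stride.
#'
#' @param config path to a YAML file, or a named list.
#' @return merged configuration list.
#' @export
loadRunConfig <- function(config) {
  defaults <- yaml::read_yaml(system.file("extdata", "paper_defaults.yaml",
                                          package = "pmhcdyn"))
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .mergeConfig(defaults, user)
  if (is.null(cfg$systems) || !length(cfg$systems))
    stop("configuration error: no systems defined")
  labels <- vapply(cfg$systems, function(s) s$label %||% "", character(1))
  if (any(labels == "")) stop("configuration error: every system needs a label")
  if (anyDuplicated(labels)) stop("configuration error: duplicate system labels")
  cfg
}

.compartmentTableFromConfig <- function(cfg) {
  lapply(cfg$compartments, function(cp)
    list(alpha = cp$alpha[1]:cp$alpha[2], beta = cp$beta[1]:cp$beta[2]))
}

# materialize one configured system: either read from disk or synthesize
.loadConfiguredSystem <- function(scfg, cfg) {
  if (!is.null(scfg$synth)) {
    sy <- scfg$synth
    system <- makeToyComplex(sy$n_alpha %||% 80, sy$n_beta %||% 95,
                             sy$n_pep %||% 14, sy$waters %||% 0,
                             seed = sy$seed %||% cfg$seed %||% 1)
    spec <- fluctuationSpec(mode = sy$mode %||% "isotropic_gaussian",
                            amplitude = sy$amplitude %||% 0,
                            state_means = sy$state_means,
                            state_occupancy = sy$state_occupancy %||% 0.5,
                            compartment = sy$compartment %||% "D1",
                            seed = sy$seed %||% cfg$seed %||% 1)
    traj <- sampleTrajectory(system, spec, sy$n_frames %||% 60,
                             frame_interval = cfg$frame_interval %||% 200)
    return(list(system = system, traj = traj))
  }
  for (f in c("structure", "trajectory")) {
    if (is.null(scfg[[f]]))
      stop("configuration error: system '", scfg$label, "' lacks a ", f, " path")
    if (!file.exists(scfg[[f]]))
      stop("system '", scfg$label, "': ", f, " file not found: ", scfg[[f]])
  }
  system <- readStructure(scfg$structure)
  traj <- readTrajectory(system, scfg$trajectory,
                         frame_interval = cfg$frame_interval %||% 200)
  list(system = system, traj = traj)
}

# run every analysis stage on one system
.analyzeSystem <- function(system, traj, cfg) {
  bs <- bindingSiteSelection(system,
    alpha_range = cfg$selections$binding_site$alpha[1]:cfg$selections$binding_site$alpha[2],
    beta_range = cfg$selections$binding_site$beta[1]:cfg$selections$binding_site$beta[2])
  cmap <- compartmentSelections(system, .compartmentTableFromConfig(cfg))
  rmsd <- rmsdSeries(traj, bs)
  rmsd_dist <- distributionSummary(rmsd, cfg$histogram$rmsd_bin_width %||% 0.1)
  widths <- compartmentDistanceSeries(traj, cmap)
  width_dists <- lapply(widths, distributionSummary,
                        bin_width = cfg$histogram$width_bin_width %||% 0.25)
  a <- system@atoms
  betaSel <- makeSelection("beta_site",
                           rep("B", sum(members(bs)$chain == "B")),
                           members(bs)$resno[members(bs)$chain == "B"])
  pepRes <- sort(unique(a$residue_index[a$chain_id == "P"]))
  network <- NULL; hb <- st <- hp <- NULL
  if (length(pepRes)) {
    pepSel <- makeSelection("peptide", rep("P", length(pepRes)), pepRes)
    hb <- detectHbonds(traj, betaSel, pepSel,
                       do.call(hbondCriteria, cfg$criteria$hbond))
    st <- detectStacking(traj, betaSel, pepSel,
                         do.call(stackCriteria, cfg$criteria$stacking))
    hp <- detectHydrophobic(traj, betaSel, pepSel,
                            do.call(hydrophobicCriteria, cfg$criteria$hydrophobic))
    network <- networkSummary(hb, st, hp)
  } else {
    network <- networkSummary()
  }
  entropy <- quasiharmonicEntropy(traj, bs,
                                  temperature = cfg$entropy$temperature %||% 310)
  binding <- NULL
  if (isTRUE(cfg$sie$enabled) && length(pepRes)) {
    pepSel <- makeSelection("peptide", rep("P", length(pepRes)), pepRes)
    pars <- sieParams(alpha = cfg$sie$alpha %||% 0.1048,
                      d_in = cfg$sie$d_in %||% 2.25,
                      gamma = cfg$sie$gamma %||% 0.0129,
                      constant = cfg$sie$constant %||% -2.89,
                      temperature = cfg$sie$temperature %||% 310)
    binding <- sieTrajectory(traj, bs, pepSel, pars,
                             stride_ps = max(cfg$sie$stride_ps %||% 20,
                                             traj@frameInterval))
  }
  list(binding_site = bs, compartments = cmap, rmsd = rmsd,
       rmsd_dist = rmsd_dist, widths = widths, width_dists = width_dists,
       network = network, entropy = entropy, binding = binding)
}

.writeSystemOutputs <- function(label, res, dir) {
  d <- file.path(dir, label)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(seriesAsDataFrame(res$rmsd),
                   file.path(d, "rmsd.csv"), row.names = FALSE)
  for (nm in names(res$widths))
    utils::write.csv(seriesAsDataFrame(res$widths[[nm]]),
                     file.path(d, paste0("width_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(res$network, file.path(d, "network.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(rmsd_modes = res$rmsd_dist@modes,
         width_modes = lapply(res$width_dists, function(x) x@modes),
         TS_kcal_mol = res$entropy@TS),
    file.path(d, "summary.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$binding))
    jsonlite::write_json(
      list(dg_mean = res$binding@dgMean, dg_sd = res$binding@dgSd,
           ic50_nM = res$binding@ic50nM, stride_ps = res$binding@stridePs,
           per_frame = res$binding@perFrame),
      file.path(d, "binding.json"), auto_unbox = TRUE, digits = NA)
  invisible(d)
}

#' Run the full analysis pipeline
#'
#' Executes every analysis stage (binding-site RMSD and its distribution,
#' compartment groove widths and their distributions, the three interaction
#' detectors, quasi-harmonic entropy, SIE/IC50) for every configured
#' system, optionally writing CSV/JSON artifacts, and returns an in-memory
#' report. Deterministic given the configuration and inputs.
#'
#' @param config YAML path or configuration list (see [loadRunConfig()]).
#' @param write_outputs write per-system CSV/JSON artifacts to the
#'   configured `output_dir`.
#' @param quiet suppress per-stage progress messages.
#' @return a `RunReport` list: `systems` (per-label result bundles),
#'   `config`, and `provenance` (config hash, package version, seed).
#' @export
runPipeline <- function(config, write_outputs = !is.null(cfg$output_dir),
                        quiet = FALSE) {
  cfg <- loadRunConfig(config)
  force(write_outputs)
  results <- list()
  for (scfg in cfg$systems) {
    t0 <- Sys.time()
    loaded <- tryCatch(.loadConfiguredSystem(scfg, cfg), error = function(e)
      stop("system '", scfg$label, "': ", conditionMessage(e), call. = FALSE))
    res <- tryCatch(.analyzeSystem(loaded$system, loaded$traj, cfg),
                    error = function(e)
      stop("system '", scfg$label, "': ", conditionMessage(e), call. = FALSE))
    res$system <- loaded$system
    res$traj_frames <- nFrames(loaded$traj)
    results[[scfg$label]] <- res
    if (!quiet)
      message(sprintf("[%s] %d frames, %d network records, TS=%.2f kcal/mol (%.1f s)",
                      scfg$label, res$traj_frames, nrow(res$network),
                      res$entropy@TS,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  cfg_for_hash <- cfg
  cfg_for_hash$output_dir <- NULL
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                              null = "null"), tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  report <- list(systems = results, config = cfg,
                 provenance = list(config_md5 = hash,
                                   package_version = as.character(
                                     utils::packageVersion("pmhcdyn")),
                                   seed = cfg$seed %||% 1))
  class(report) <- "RunReport"
  if (write_outputs && !is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(results))
      .writeSystemOutputs(lab, results[[lab]], cfg$output_dir)
    jsonlite::write_json(report$provenance,
                         file.path(cfg$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' Compare pipeline systems against a reference
#'
#' Produces IC50 ratios relative to the reference system, pairwise
#' free-energy differences, per-compartment primary-mode location
#' differences, and interaction-network set differences (records unique to
#' each system vs shared with the reference).
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param reference_label label of the reference system.
#' @return list with `ic50_ratio`, `ddg`, `mode_shift` (data.frame), and
#'   `network_diff` (per-system list of `shared`, `unique_to_system`,
#'   `unique_to_reference` keys).
#' @export
compareSystems <- function(report, reference_label) {
  stopifnot(inherits(report, "RunReport"))
  labs <- names(report$systems)
  if (!reference_label %in% labs)
    stop("unknown reference label '", reference_label, "'")
  ref <- report$systems[[reference_label]]
  haveBinding <- !vapply(report$systems, function(s) is.null(s$binding), logical(1))
  ic50 <- ddg <- NULL
  if (all(haveBinding)) {
    v <- vapply(report$systems, function(s) s$binding@ic50nM, numeric(1))
    ic50 <- ic50Ratio(v, reference_label)
    dg <- vapply(report$systems, function(s) s$binding@dgMean, numeric(1))
    ddg <- dg - dg[[reference_label]]
  }
  primaryMode <- function(dist) {
    md <- modes(dist)
    if (!nrow(md)) return(NA_real_)
    md$location[which.max(md$mass)]
  }
  ms <- do.call(rbind, lapply(labs, function(lab) {
    s <- report$systems[[lab]]
    data.frame(system = lab, compartment = names(s$width_dists),
      mode_shift = vapply(names(s$width_dists), function(nm)
        primaryMode(s$width_dists[[nm]]) - primaryMode(ref$width_dists[[nm]]),
        numeric(1)), row.names = NULL)
  }))
  netKey <- function(tab)
    if (nrow(tab)) paste(tab$kind, tab$chain_a, tab$res_a, tab$chain_b, tab$res_b)
    else character(0)
  refKeys <- netKey(ref$network)
  nd <- lapply(report$systems, function(s) {
    k <- netKey(s$network)
    list(shared = sort(intersect(k, refKeys)),
         unique_to_system = sort(setdiff(k, refKeys)),
         unique_to_reference = sort(setdiff(refKeys, k)))
  })
  list(ic50_ratio = ic50, ddg = ddg, mode_shift = ms, network_diff = nd)
}
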