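#' Pipeline run configuration
#'
#' A single document (JSON-serializable list) driving [runPipeline()]:
#' stage toggles, numeric parameters and a master seed from which each
#' stage derives its own child seed, so any stage is reproducible
#' independently of which other stages are enabled.
#'
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("synth", "ifr", "group", "assort", "concnet")`.
#' @param n_per_group participants per group for the connectivity
#'   cohort.
#' @param n_samples samples per synthetic participant.
#' @param group_gain concussed-like off-diagonal drift gain.
#' @param dt sampling interval of the ROI series.
#' @param threshold active-connection threshold on mean \eqn{|\tau|}.
#' @param n_perm permutations per connection.
#' @param subsample_k,subsample_reps subsample shape-feature settings.
#' @param eeg_n_per_class,eeg_duration,eeg_effect raw-EEG cohort
#'   settings for the classifier stage.
#' @param classifier a [concNetConfig()].
#' @param repeats,folds classifier cross-validation structure.
#' @param seed master seed.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(out_dir,
                      stages = c("synth", "ifr", "group", "assort"),
                      n_per_group = 15L, n_samples = 75000L,
                      group_gain = 1.5, dt = 1 / 250, threshold = 0.05,
                      n_perm = 100L, subsample_k = 6L,
                      subsample_reps = 100000L,
                      eeg_n_per_class = 13L, eeg_duration = 60,
                      eeg_effect = 1.0,
                      classifier = concNetConfig(),
                      repeats = 5L, folds = 6L, seed = 1L) {
  stopifnot(threshold > 0, n_perm >= 1, subsample_k >= 1)
  stages <- match.arg(stages, c("synth", "ifr", "group", "assort", "concnet"),
                      several.ok = TRUE)
  structure(list(out_dir = out_dir, stages = stages,
                 n_per_group = as.integer(n_per_group),
                 n_samples = as.integer(n_samples),
                 group_gain = group_gain, dt = dt, threshold = threshold,
                 n_perm = as.integer(n_perm),
                 subsample_k = as.integer(subsample_k),
                 subsample_reps = as.integer(subsample_reps),
                 eeg_n_per_class = as.integer(eeg_n_per_class),
                 eeg_duration = eeg_duration, eeg_effect = eeg_effect,
                 classifier = classifier,
                 repeats = as.integer(repeats), folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

stageSeed <- function(master, stage) {
  # deterministic child seed per stage, independent of stage toggles
  offs <- c(synth = 101L, ifr = 202L, group = 303L, assort = 404L,
            concnet = 505L)
  (as.integer(master) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order (synth -> ifr ->
#' group/assort; synth -> concnet), writes per-stage CSV/JSON outputs
#' under `config$out_dir` and a provenance manifest (config snapshot,
#' child seeds, package version, timestamps). Rerunning with an
#' identical config reproduces every stochastic output.
#'
#' @param config a [runConfig()].
#' @return list of class `"ResultBundle"`: per-stage results plus
#'   `manifest` (paths of files written) and `provenance`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  res <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest[[stage]] <<- c(manifest[[stage]], path)
    path
  }

  want <- function(s) s %in% config$stages
  need_cohort <- want("ifr") || want("group") || want("assort")

  if (want("synth") || need_cohort) {
    cohort <- genVarCohort(config$n_per_group, dt = config$dt,
                           n_samples = config$n_samples,
                           group_gain = config$group_gain,
                           seed = stageSeed(config$seed, "synth"))
    res$cohort <- cohort
    if (want("synth")) {
      emit("synth", "cohort_labels.csv", function(p)
        utils::write.csv(data.frame(
          participant = vapply(participants(cohort), participantId,
                               character(1)),
          group = groupLabels(cohort)), p, row.names = FALSE))
    }
  }

  if (want("ifr")) {
    res$flow <- lapply(participants(res$cohort), ifrMatrix)
    emit("ifr", "tau_matrices.csv", function(p) {
      rows <- do.call(rbind, lapply(res$flow, function(m) {
        e <- flowEdges(m)
        cbind(participant = participantId(m), e)
      }))
      utils::write.csv(rows, p, row.names = FALSE)
    })
  }

  if (want("group")) {
    grp <- split(res$flow, groupLabels(res$cohort))
    ts_grp <- split(participants(res$cohort), groupLabels(res$cohort))
    res$group <- lapply(names(grp), function(g) {
      mm <- meanGroupMatrix(grp[[g]], g)
      pooled <- poolGroupValues(grp[[g]], g)
      null <- permutationNull(ts_grp[[g]], n_perm = config$n_perm,
                              seed = stageSeed(config$seed, "group"))
      sub <- subsampleShapeFeatures(grp[[g]], k = config$subsample_k,
                                    reps = config$subsample_reps,
                                    seed = stageSeed(config$seed, "group"))
      list(name = g, mean_matrix = mm,
           top = topConnections(mm),
           active = activeConnections(mm, config$threshold),
           pooled = pooled, null = null, subsample = sub)
    })
    names(res$group) <- names(grp)
    res$comparison <- compareGroups(res$group[[1]]$pooled,
                                    res$group[[2]]$pooled)
    emit("group", "group_stats.csv", function(p)
      utils::write.csv(do.call(rbind, lapply(res$group, function(g)
        data.frame(group = g$name, t(g$pooled$stats),
                   p95_null = g$null$p95, p5_null = g$null$p5))),
        p, row.names = FALSE))
    emit("group", "top_connections.csv", function(p)
      utils::write.csv(do.call(rbind, lapply(res$group, function(g)
        cbind(group = g$name, g$top))), p, row.names = FALSE))
    emit("group", "comparison.json", function(p)
      jsonlite::write_json(unclass(res$comparison), p, auto_unbox = TRUE,
                           digits = NA))
  }

  if (want("assort")) {
    rw <- lapply(res$flow, degreeAssortativity)
    grp_rw <- split(rw, groupLabels(res$cohort))
    res$assortativity <- list(
      per_participant = data.frame(
        participant = vapply(rw, `[[`, character(1), "participant_id"),
        group = groupLabels(res$cohort),
        r_w = vapply(rw, `[[`, numeric(1), "r_w")),
      comparison = compareAssortativity(grp_rw[[1]], grp_rw[[2]]))
    emit("assort", "assortativity.csv", function(p)
      utils::write.csv(res$assortativity$per_participant, p,
                       row.names = FALSE))
    emit("assort", "assortativity_comparison.json", function(p)
      jsonlite::write_json(unclass(res$assortativity$comparison), p,
                           auto_unbox = TRUE, digits = NA))
  }

  if (want("concnet")) {
    eeg <- genRawEEGCohort(config$eeg_n_per_class,
                           duration = config$eeg_duration,
                           class_effect_size = config$eeg_effect,
                           seed = stageSeed(config$seed, "synth"))
    cfg <- config$classifier
    cfg$seed <- stageSeed(config$seed, "concnet")
    res$ensemble <- runEnsemble(eeg, config = cfg,
                                repeats = config$repeats,
                                folds = config$folds,
                                seed = stageSeed(config$seed, "concnet"))
    emit("concnet", "classifier_metrics.csv", function(p)
      utils::write.csv(cbind(metric = rownames(res$ensemble$summary),
                             res$ensemble$summary), p, row.names = FALSE))
    emit("concnet", "misclassification.csv", function(p)
      utils::write.csv(res$ensemble$misclassification, p, row.names = FALSE))
  }

  prov <- list(config = unclass(config),
               classifier = unclass(config$classifier),
               seeds = lapply(stats::setNames(nm = config$stages),
                              function(s) stageSeed(config$seed, s)),
               package_version = as.character(utils::packageVersion("flowconn")),
               timestamp = format(Sys.time(), tz = "UTC"))
  prov$config$classifier <- NULL
  path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest$provenance <- path
  res$manifest <- manifest
  res$provenance <- prov
  class(res) <- "ResultBundle"
  res
}
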