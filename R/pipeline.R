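#' Default pipeline configuration
#'
#' All defaults follow the high-TR public-cohort settings: 55-TR windows at
#' TR 0.720 s (39.60 s), cosine k-means with k = 2, 5000 bootstrap
#' resamples, FD exclusion at more than 7.5% of frames >= 0.5 mm. The
#' `simulate` block mirrors [cohort_spec()] / [mediation_spec()].
#'
#' @param seed global seed recorded in every stage's provenance.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    window_trs = 55L,
    tr_seconds = 0.720,
    qc = list(fd_threshold_mm = 0.5, max_fraction = 0.075),
    kmeans = list(n_init = 100L, max_iter = 300L, tol = 1e-6),
    graph = list(gamma = 1, n_repeats = 20L),
    stats = list(
      variant = "auto",
      ## directional hypotheses, males minus females
      one_sided = c(modularity = "less", global_efficiency = "greater",
                    prev_s = "less", mdt_s = "less", var_i = "greater")
    ),
    mediation = list(n_boot = 5000L, m = 66L, alpha = 0.05,
                     mediator = "prev_i"),
    simulate = list(
      n_subjects = 80L, n_rois = 20L, n_modules = 4L, n_frames = 1200L,
      within_r = 0.6, between_r_segregated = 0.10,
      between_r_integrated = 0.45,
      a_effect = 0.4, b_effect = 0.3, c_prime = 0.2,
      n_fd_fail = 0L
    )
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file.
#' @param seed fallback seed when the file does not set one.
#' @return `run_config` list.
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  config <- default_run_config(seed)
  merge_lists <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(base[[nm]]) && is.list(new[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  structure(merge_lists(unclass(config), user), class = "run_config")
}

write_provenance <- function(out_dir, stage, info) {
  dir.create(file.path(out_dir, "provenance"), recursive = TRUE,
             showWarnings = FALSE)
  info$stage <- stage
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  info$package_version <- as.character(utils::packageVersion("dfcstates"))
  jsonlite::write_json(info,
                       file.path(out_dir, "provenance", paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the end-to-end analysis pipeline
#'
#' Stage order: `simulate` (optional) -> `qc` -> `fc` (static + windowed)
#' -> `states` -> `dynamics` -> `graphs` -> `compare` -> `mediate` ->
#' `report`. Each stage writes its tabular artifact as delimited text under
#' `out_dir` plus a JSON provenance record (settings, seed, counts).
#' Subjects failing FD QC are excluded before clustering and listed with
#' their offending fraction. Rerunning with an identical config and seed
#' reproduces all outputs.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all). Later
#'   stages require the in-memory products of earlier ones within the same
#'   call, so partial runs must be prefixes of the stage order.
#' @param cohort optionally, a pre-built `synthetic_cohort` (skips
#'   simulation even if `"simulate"` is listed).
#' @return invisible list with the main products (`cohort`, `qc`,
#'   `dynamics`, `static_metrics`, `comparisons`, `mediation`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir,
                         stages = c("simulate", "qc", "fc", "states",
                                    "dynamics", "graphs", "compare",
                                    "mediate", "report"),
                         cohort = NULL) {
  all_stages <- c("simulate", "qc", "fc", "states", "dynamics", "graphs",
                  "compare", "mediate", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list()

  if ("simulate" %in% stages || !is.null(cohort)) {
    if (is.null(cohort)) {
      sim <- config$simulate
      n <- sim$n_subjects
      spec <- cohort_spec(
        n_subjects = n, n_rois = sim$n_rois, n_modules = sim$n_modules,
        n_frames = sim$n_frames, tr_seconds = config$tr_seconds,
        within_r = sim$within_r,
        between_r_segregated = sim$between_r_segregated,
        between_r_integrated = sim$between_r_integrated,
        seed = config$seed
      )
      mspec <- mediation_spec(sim$a_effect, sim$b_effect, sim$c_prime,
                              seed = config$seed + 1L)
      fd_fail <- if (sim$n_fd_fail > 0) seq_len(sim$n_fd_fail) else integer()
      cohort <- simulate_cohort(spec, mspec, fd_fail_subjects = fd_fail)
      write_cohort(cohort, file.path(out_dir, "cohort"))
    }
    state$cohort <- cohort
    write_provenance(out_dir, "simulate",
                     list(seed = config$seed,
                          n_subjects = nrow(cohort$manifest)))
    message("simulate: ", nrow(cohort$manifest), " subjects")
  }
  if (identical(stages, "simulate") || !any(stages != "simulate")) {
    return(invisible(state))
  }
  if (is.null(state$cohort)) {
    stop("missing upstream artifact: run the 'simulate' stage ",
         "(or pass a cohort)")
  }

  cohort <- state$cohort
  manifest <- cohort$manifest
  keep <- rep(TRUE, nrow(manifest))

  if ("qc" %in% stages) {
    qc_rows <- lapply(seq_along(cohort$subjects), function(i) {
      q <- qc_fd(cohort$subjects[[i]]$fd,
                 config$qc$fd_threshold_mm, config$qc$max_fraction)
      data.frame(subject_id = manifest$subject_id[i], pass = q$pass,
                 spike_fraction = q$fraction, median_fd = q$median_fd)
    })
    qc_table <- do.call(rbind, qc_rows)
    keep <- qc_table$pass
    utils::write.table(qc_table, file.path(out_dir, "qc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "qc",
                     list(threshold_mm = config$qc$fd_threshold_mm,
                          max_fraction = config$qc$max_fraction,
                          n_in = nrow(qc_table), n_pass = sum(keep)))
    state$qc <- qc_table
    message("qc: ", sum(keep), "/", nrow(qc_table), " subjects pass")
  }

  idx <- which(keep)
  if (length(idx) < 4) stop("too few subjects pass QC to continue")

  if (any(c("fc", "states", "dynamics", "graphs") %in% stages)) {
    static <- lapply(idx, function(i) static_fc(cohort$subjects[[i]]$ts))
    windowed <- lapply(idx, function(i) {
      sliding_window_fc(cohort$subjects[[i]]$ts, config$window_trs)
    })
    state$static <- static
    state$windowed <- windowed
    write_provenance(out_dir, "fc",
                     list(window_trs = config$window_trs,
                          window_seconds = window_seconds(config$window_trs,
                                                          config$tr_seconds),
                          n_windows_per_subject = nrow(windowed[[1]]$vectors)))
    message("fc: ", length(windowed), " subjects, ",
            nrow(windowed[[1]]$vectors), " windows each")
  }

  if (any(c("states", "dynamics") %in% stages)) {
    pool <- build_state_pool(state$windowed)
    model <- fit_states(pool, n_init = config$kmeans$n_init,
                        max_iter = config$kmeans$max_iter,
                        tol = config$kmeans$tol, seed = config$seed)
    state$model <- model
    utils::write.table(
      cbind(state = model$state_of_centroid, as.data.frame(model$centroids)),
      file.path(out_dir, "state_centroids.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "states",
                     list(seed = config$seed, k = 2,
                          n_init = config$kmeans$n_init,
                          inertia = model$inertia,
                          label_metrics = model$label_metrics))
    message("states: centroids labeled ",
            paste(model$state_of_centroid, collapse = "/"))
  }

  if ("dynamics" %in% stages) {
    sequences <- lapply(state$windowed, function(w) {
      assign_windows(state$model, w)
    })
    dyn <- do.call(rbind, lapply(seq_along(sequences), function(j) {
      dynamics_summary(sequences[[j]], state$windowed[[j]])
    }))
    dyn <- cbind(dyn, sex = manifest$sex[idx])
    state$sequences <- sequences
    state$dynamics <- dyn
    utils::write.table(dyn, file.path(out_dir, "dynamics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "dynamics",
                     list(n_subjects = nrow(dyn),
                          step_seconds = config$tr_seconds))
    message("dynamics: ", nrow(dyn), " subject summaries")
  }

  if ("graphs" %in% stages) {
    gm <- do.call(rbind, lapply(seq_along(idx), function(j) {
      w <- to_graph(state$static[[j]])
      data.frame(
        subject_id = manifest$subject_id[idx[j]],
        global_efficiency = global_efficiency(w),
        modularity = modularity(w, gamma = config$graph$gamma,
                                n_repeats = config$graph$n_repeats,
                                seed = config$seed)$q
      )
    }))
    gm$sex <- manifest$sex[idx]
    state$static_metrics <- gm
    utils::write.table(gm, file.path(out_dir, "static_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "graphs",
                     list(gamma = config$graph$gamma,
                          n_repeats = config$graph$n_repeats,
                          seed = config$seed))
    message("graphs: ", nrow(gm), " subjects")
  }

  if ("compare" %in% stages) {
    if (is.null(state$dynamics)) stop("missing upstream artifact: dynamics")
    tables <- list(
      dynamics = compare_table(
        state$dynamics,
        c("prev_s", "prev_i", "mdt_s", "mdt_i", "iti", "var_s", "var_i"),
        one_sided = config$stats$one_sided, variant = config$stats$variant
      )
    )
    if (!is.null(state$static_metrics)) {
      tables$static <- compare_table(
        state$static_metrics, c("global_efficiency", "modularity"),
        one_sided = config$stats$one_sided, variant = config$stats$variant
      )
    }
    comparisons <- do.call(rbind, tables)
    state$comparisons <- comparisons
    utils::write.table(comparisons, file.path(out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "compare",
                     list(variant = config$stats$variant,
                          one_sided = as.list(config$stats$one_sided)))
    message("compare: ", nrow(comparisons), " parameters")
  }

  if ("mediate" %in% stages && !is.null(cohort$behavior)) {
    beh <- cohort$behavior[idx, , drop = FALSE]
    mediator <- if (config$mediation$mediator == "prev_i" &&
                    !is.null(state$dynamics)) {
      state$dynamics$prev_i
    } else {
      beh$mediator
    }
    med <- mediate_table(
      beh[, "outcome", drop = FALSE], beh$sex, mediator,
      m = config$mediation$m, alpha = config$mediation$alpha,
      n_boot = config$mediation$n_boot, seed = config$seed
    )
    state$mediation <- med
    if (!is.null(med$results)) {
      utils::write.table(med$results, file.path(out_dir, "mediation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(med$screen, file.path(out_dir, "mediation_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(out_dir, "mediate",
                     list(n_boot = config$mediation$n_boot,
                          m = config$mediation$m,
                          mediator = config$mediation$mediator,
                          n_candidates = sum(med$screen$candidate)))
    message("mediate: ", sum(med$screen$candidate), " candidate variable(s)")
  }

  if ("report" %in% stages) {
    report <- list(
      seed = config$seed,
      n_subjects_in = nrow(manifest),
      n_subjects_analyzed = length(idx),
      window_trs = config$window_trs,
      window_seconds = window_seconds(config$window_trs, config$tr_seconds)
    )
    write_provenance(out_dir, "report", report)
  }

  invisible(state)
}
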