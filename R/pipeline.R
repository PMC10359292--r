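#' Study configuration
#'
#' Bundles every analysis constant of the pipeline with its standard
#' default: 1000 permutations for the licking test, 200-pair subsamples and
#' 1000 repetitions with a 10-bin minimum cluster for the coherence test,
#' FDR level 0.05 and a 1-250 ms window for the causality analysis, and the
#' animal-specific 500-ms stimulus epoch. Generator specifications control
#' the synthetic study the pipeline runs on. Overrides are recorded in the
#' run manifest.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_perm Licking permutation count. Default 1000.
#' @param n_sub,n_rep,min_cluster Coherence subsampling-null parameters.
#'   Defaults 200, 1000, 10. `n_sub` is capped at the number of available
#'   maps at run time (logged).
#' @param fdr_q FDR level for the causality tests. Default 0.05.
#' @param gc_window_ms Post-stimulus causality window, ms. Default
#'   `c(1, 250)`.
#' @param gc_max_order AIC search bound, samples. Default 20.
#' @param epoch_stim Animal-specific stimulus epoch, ms after onset.
#'   Default `c(501, 1000)`.
#' @param task,licks,coupling,gaze Generator specifications.
#' @param conditions Condition labels, control first.
#' @return A `study_config` object.
#' @export
study_config <- function(seed = 1, n_perm = 1000, n_sub = 200, n_rep = 1000,
                         min_cluster = 10, fdr_q = 0.05,
                         gc_window_ms = c(1, 250), gc_max_order = 20,
                         epoch_stim = c(501, 1000),
                         task = task_config(n_sessions = 2),
                         licks = lick_effect_spec(epoch_stim = epoch_stim),
                         coupling = coupling_spec(),
                         gaze = gaze_spec(),
                         conditions = c("vehicle", "DCZ")) {
  structure(
    list(
      seed = seed, n_perm = n_perm, n_sub = n_sub, n_rep = n_rep,
      min_cluster = min_cluster, fdr_q = fdr_q,
      gc_window_ms = gc_window_ms, gc_max_order = gc_max_order,
      epoch_stim = epoch_stim, task = task, licks = licks,
      coupling = coupling, gaze = gaze, conditions = conditions
    ),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Flat YAML keys override [study_config()] defaults; nested sections
#' `task`, `licks`, `coupling`, `gaze` override the generator
#' specifications field-by-field.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec_args <- list(
    task = task_config, licks = lick_effect_spec,
    coupling = coupling_spec, gaze = gaze_spec
  )
  args <- list()
  for (nm in names(raw)) {
    if (nm %in% names(spec_args)) {
      args[[nm]] <- do.call(spec_args[[nm]], raw[[nm]])
    } else {
      args[[nm]] <- if (is.list(raw[[nm]])) unlist(raw[[nm]]) else raw[[nm]]
    }
  }
  do.call(study_config, args)
}

#' Run the full synthetic study pipeline
#'
#' Simulates a study from the configuration's generators, then runs every
#' analysis stage: licking quantification (z-scored frequencies, MAD
#' screening, Spearman association, modulation and permutation test per
#' block), gaze ROI occupancy comparisons, baseline-normalised wavelet
#' coherence with the subsampling cluster test (per block, pooling pairs
#' across sessions), and session-level Granger causality (when at least two
#' sessions are configured). Progress is logged to stderr; the returned
#' report carries a manifest (config hash, seed, package version).
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory; when given, the trial CSV, signal
#'   containers, permutation distributions, cluster table and report JSON
#'   are written there.
#' @return A `study_report` list with one element per stage.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  log_stage <- function(...) message("[dyadflow] ", sprintf(...))
  stage <- function(name, expr) {
    log_stage("stage: %s", name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  trials <- stage("simulate", simulate_trials(config$task, seed = config$seed))
  licks <- stage("licks", simulate_licks(trials, config$licks,
                                         seed = config$seed))
  gaze <- stage("gaze-samples", simulate_gaze(trials, config$gaze,
                                              seed = config$seed))
  lfp <- stage("lfp", simulate_lfp(trials, config$coupling,
                                   seed = config$seed))

  behavior <- stage("behavior", {
    z <- lick_zscores(licks)
    z <- dplyr::group_by(z, .data$block, .data$condition)
    z <- dplyr::filter(z, mad_keep(.data$lick_z))
    z <- dplyr::ungroup(z)
    purrr::map(split(z, z$block), function(zb) {
      varying <- if (grepl("self", zb$block[1])) zb$p_self else zb$p_partner
      assoc <- purrr::imap(
        split(seq_len(nrow(zb)), zb$condition),
        function(idx, cond) {
          s <- spearman_association(zb$lick_z[idx], varying[idx])
          list(condition = cond, rho = s$rho, p = s$p_value, n = s$n)
        }
      )
      pt <- lick_permutation_test(zb, n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, "behavior"),
                                  conditions = config$conditions)
      list(spearman = assoc, permutation = as.list(glance(pt)),
           perm_distribution = pt$perm)
    })
  })

  gaze_stage <- stage("gaze", {
    props <- roi_proportions(gaze)
    as.list(compare_roi_occupancy(props, config$conditions))
  })

  coherence <- stage("coherence", {
    purrr::map(setNames(nm = config$task$blocks), function(blk) {
      per_cond <- purrr::map(setNames(nm = config$conditions), function(cond) {
        sel <- lfp$trials$block == blk & lfp$trials$condition == cond
        maps_by_session <- purrr::map(
          unique(lfp$trials$session[sel]), function(s) {
            sub <- lfp_subset(lfp, sel & lfp$trials$session == s)
            sub <- lfp_subset(sub, lfp_trial_filter(sub))
            baseline_normalize(wavelet_coherence_maps(sub))
          }
        )
        do.call(stack_bind, maps_by_session)
      })
      modul <- coherence_modulation(per_cond[[1]], per_cond[[2]])
      pooled <- stack_bind(per_cond[[1]], per_cond[[2]])
      n_sub <- min(config$n_sub, 2 * (dim(pooled$values)[3] %/% 2))
      if (n_sub < config$n_sub) {
        log_stage("coherence: n_sub capped at %d (available maps)", n_sub)
      }
      null <- subsample_null(pooled, n_sub = n_sub, n_rep = config$n_rep,
                             seed = derive_seed(config$seed, "coherence"))
      ct <- threshold_and_cluster(modul$observed, null,
                                  min_cluster = config$min_cluster,
                                  time = pooled$time, freqs = pooled$freqs)
      list(glance = as.list(glance(ct)), clusters = tidy(ct),
           observed = modul$observed)
    })
  })

  granger <- if (config$task$n_sessions >= 2) {
    stage("granger", {
      res <- granger_pair_tests(
        lfp_subset(lfp, lfp$trials$block == config$task$blocks[2]),
        window_ms = config$gc_window_ms, max_order = config$gc_max_order,
        q = config$fdr_q
      )
      summ <- session_gc_summary(res, config$conditions)
      list(pairs = res$pairs, freq_tests = summ$freq_tests)
    })
  } else {
    log_stage("granger skipped: fewer than 2 sessions")
    NULL
  }

  manifest <- list(
    package = "dyadflow",
    version = as.character(utils::packageVersion("dyadflow")),
    seed = config$seed,
    config_hash = rlang::hash(config)
  )
  report <- structure(
    list(
      manifest = manifest,
      behavior = purrr::map(behavior, function(b) {
        b[c("spearman", "permutation")]
      }),
      gaze = gaze_stage,
      coherence = purrr::map(coherence, function(cc) {
        c(cc["glance"], list(clusters = as.list(cc$clusters)))
      }),
      granger = if (!is.null(granger)) {
        list(freq_tests = as.list(granger$freq_tests))
      }
    ),
    class = "study_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_csv(trials, file.path(out_dir, "trials.csv"))
    write_signals(licks, file.path(out_dir, "licks.rds"))
    write_signals(lfp, file.path(out_dir, "lfp.rds"))
    write_signals(gaze, file.path(out_dir, "gaze.rds"))
    for (blk in names(behavior)) {
      readr::write_csv(
        tibble(simulated_effect = behavior[[blk]]$perm_distribution),
        file.path(out_dir, sprintf("perm_%s.csv", gsub("[^a-z]+", "_", blk)))
      )
    }
    cl <- dplyr::bind_rows(
      purrr::imap(coherence, function(cc, blk) {
        dplyr::mutate(cc$clusters, block = blk)
      })
    )
    readr::write_csv(cl, file.path(out_dir, "clusters.csv"))
    if (!is.null(granger)) {
      readr::write_csv(granger$pairs, file.path(out_dir, "gc_pairs.csv"))
      readr::write_csv(granger$freq_tests,
                       file.path(out_dir, "gc_freq_tests.csv"))
    }
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}
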