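#' Experiment configuration
#'
#' Bundles every stage's settings: the synthetic session designs (main four-
#' condition MID session and the two-condition static-disparity control),
#' preprocessing, bootstrap-SVM decoding, the comparison list and the group
#' statistics. All stage seeds are derived from one master seed.
#'
#' @param session Main [session_spec()] (CD/IOVD x TOWARD/AWAY).
#' @param static_session Static-disparity control [session_spec()]; `NULL`
#'   to skip the static comparison.
#' @param preproc A [preproc_config()].
#' @param decode A [decode_config()].
#' @param comparisons Character vector drawn from
#'   `names(comparison_table())`.
#' @param n_permutations,alpha_forming,cluster_alpha Group-statistics
#'   settings.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param master_seed Master seed; session and decoding seeds derive from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(session = session_spec(),
                              static_session = session_spec(
                                n_blocks = 3,
                                condition_set = c("STATIC_NEAR", "STATIC_FAR"),
                                components = default_components(
                                  c("STATIC_NEAR", "STATIC_FAR")),
                                n_participants = session$n_participants),
                              preproc = preproc_config(),
                              decode = decode_config(),
                              comparisons = names(comparison_table()),
                              n_permutations = 5000,
                              alpha_forming = 0.05,
                              cluster_alpha = 0.05,
                              out_dir = NULL,
                              master_seed = 1L) {
  unknown <- setdiff(comparisons, names(comparison_table()))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown comparison(s): %s", paste(unknown, collapse = ", ")))
  }
  session$master_seed <- derive_seed(master_seed, "session")
  if (!is.null(static_session)) {
    static_session$master_seed <- derive_seed(master_seed, "static-session")
  }
  structure(
    list(session = session, static_session = static_session,
         preproc = preproc, decode = decode, comparisons = comparisons,
         n_permutations = n_permutations, alpha_forming = alpha_forming,
         cluster_alpha = cluster_alpha, out_dir = out_dir,
         master_seed = as.integer(master_seed)),
    class = "experiment_config"
  )
}

#' The comparison matrix
#'
#' The nine binary comparisons the pipeline runs: direction pooled over cue,
#' cue pooled over direction, direction within each cue, cue within each
#' direction, near vs far static disparity, and the two cross-trained
#' transfers.
#'
#' @return Named list describing each comparison.
#' @export
comparison_table <- function() {
  list(
    pooled_direction = list(type = "pooled", scheme = "direction_pooled",
                            pair = c("TOWARD", "AWAY")),
    pooled_cue = list(type = "pooled", scheme = "cue_pooled",
                      pair = c("CD", "IOVD")),
    cd_direction = list(type = "within", pair = c("CD_TOWARD", "CD_AWAY")),
    iovd_direction = list(type = "within",
                          pair = c("IOVD_TOWARD", "IOVD_AWAY")),
    cue_within_toward = list(type = "within",
                             pair = c("CD_TOWARD", "IOVD_TOWARD")),
    cue_within_away = list(type = "within",
                           pair = c("CD_AWAY", "IOVD_AWAY")),
    static_disparity = list(type = "static",
                            pair = c("STATIC_NEAR", "STATIC_FAR")),
    cross_cd_to_iovd = list(type = "cross",
                            train = c("CD_TOWARD", "CD_AWAY"),
                            test = c("IOVD_TOWARD", "IOVD_AWAY")),
    cross_iovd_to_cd = list(type = "cross",
                            train = c("IOVD_TOWARD", "IOVD_AWAY"),
                            test = c("CD_TOWARD", "CD_AWAY"))
  )
}

run_one_comparison <- function(name, spec, pool, decode_cfg, participant_no,
                               master_seed) {
  decode_cfg$base_seed <- derive_seed(master_seed, paste0("decode-", name),
                                      participant_no)
  switch(spec$type,
    within = decode_timecourse(pool, spec$pair, decode_cfg),
    static = decode_timecourse(pool, spec$pair, decode_cfg),
    pooled = decode_timecourse(pool_conditions(pool, spec$scheme),
                               spec$pair, decode_cfg),
    cross = cross_decode_timecourse(pool, spec$train, spec$test, decode_cfg)
  )
}

#' Run the full synthetic experiment
#'
#' Simulates the configured sessions, preprocesses every participant's
#' epochs, runs every configured comparison per participant, and applies the
#' cluster-corrected group test per comparison. With `out_dir` set, writes a
#' tidy accuracy CSV, a clusters CSV, a summary CSV and a JSON run manifest
#' (seeds and configuration echo); reruns with the same configuration are
#' byte-identical.
#'
#' @param cfg An [experiment_config()].
#' @return List with `timecourses` (tidy tibble), `clusters` (named list of
#'   `cluster_result`), `summary` (tibble, see [summarize_decoding()]),
#'   `ground_truth` and `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  specs <- comparison_table()[cfg$comparisons]
  need_static <- any(vapply(specs, function(s) s$type == "static", TRUE))
  need_main <- any(vapply(specs, function(s) s$type != "static", TRUE))

  main <- if (need_main) simulate_preprocessed(cfg$session, cfg$preproc)
          else NULL
  static <- if (need_static) {
    if (is.null(cfg$static_session)) {
      abort("static comparison requested but `static_session` is NULL")
    }
    simulate_preprocessed(cfg$static_session, cfg$preproc)
  } else NULL

  tcs <- list()
  clusters <- list()
  for (name in names(specs)) {
    spec <- specs[[name]]
    sess <- if (spec$type == "static") static else main
    per_part <- vector("list", length(sess$epochs))
    for (p in seq_along(sess$epochs)) {
      pool <- build_pool(sess$epochs[[p]])
      per_part[[p]] <- run_one_comparison(name, spec, pool, cfg$decode, p,
                                          cfg$master_seed)
    }
    tcs[[name]] <- per_part
    mat <- group_accuracy_matrix(per_part)
    clusters[[name]] <- cluster_test(
      mat, n_permutations = cfg$n_permutations,
      seed = derive_seed(cfg$master_seed, paste0("perm-", name)),
      alpha_forming = cfg$alpha_forming, cluster_alpha = cfg$cluster_alpha)
  }

  tidy_tc <- purrr::map_dfr(names(tcs), function(name) {
    purrr::map_dfr(tcs[[name]], tidy) |>
      dplyr::mutate(comparison = name, .before = 1)
  })
  summary <- summarize_decoding(tidy_tc, clusters)
  manifest <- list(
    package_version = as.character(utils::packageVersion("middecode")),
    master_seed = cfg$master_seed,
    comparisons = cfg$comparisons,
    n_participants = if (need_main) cfg$session$n_participants
                     else cfg$static_session$n_participants,
    decode = unclass(cfg$decode),
    stats = list(n_permutations = cfg$n_permutations,
                 alpha_forming = cfg$alpha_forming,
                 cluster_alpha = cfg$cluster_alpha)
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tidy_tc, file.path(cfg$out_dir, "decoding_timecourses.csv"),
              row.names = FALSE)
    cl_tab <- purrr::map_dfr(names(clusters), function(name) {
      tidy(clusters[[name]]) |> dplyr::mutate(comparison = name, .before = 1)
    })
    write.csv(cl_tab, file.path(cfg$out_dir, "clusters.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(cfg$out_dir, "summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(timecourses = tidy_tc, per_participant = tcs, clusters = clusters,
       summary = summary,
       ground_truth = list(main = main$ground_truth,
                           static = static$ground_truth),
       manifest = manifest)
}

#' Summarise decoding results per comparison
#'
#' Reports, for every comparison, the peak of the group-mean accuracy
#' timecourse, its latency (earliest timepoint on ties), the onset of the
#' first significant cluster and the significant-cluster extents.
#'
#' @param timecourses Tidy tibble with `comparison`, `participant`,
#'   `time_ms`, `accuracy` columns.
#' @param clusters Named list of `cluster_result`s keyed by comparison.
#' @return A tibble, one row per comparison.
#' @export
summarize_decoding <- function(timecourses, clusters = list()) {
  timecourses |>
    dplyr::group_by(.data$comparison, .data$time_ms) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop_last") |>
    dplyr::summarise(
      peak_accuracy = max(.data$accuracy),
      peak_latency_ms = .data$time_ms[which.max(.data$accuracy)],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      first_sig_onset_ms = vapply(.data$comparison, function(name) {
        cl <- clusters[[name]]
        if (is.null(cl)) return(NA_real_)
        sig <- cl[cl$significant, , drop = FALSE]
        if (nrow(sig) == 0L) NA_real_ else min(sig$start_ms)
      }, 0, USE.NAMES = FALSE),
      sig_extents = vapply(.data$comparison, function(name) {
        cl <- clusters[[name]]
        if (is.null(cl)) return("")
        sig <- cl[cl$significant, , drop = FALSE]
        if (nrow(sig) == 0L) return("")
        paste(sprintf("%g-%g ms", sig$start_ms, sig$end_ms), collapse = "; ")
      }, "", USE.NAMES = FALSE)
    )
}
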