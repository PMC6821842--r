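#' Pipeline configuration
#'
#' Assembles the stage toggles, seeds, thresholds and scale parameters of
#' the end-to-end analysis into one list that round-trips through JSON
#' unchanged. Every stochastic stage derives its own seed from the single
#' base seed by a fixed counter scheme, so a config fully determines the
#' run.
#'
#' @param seed Base integer seed.
#' @param set_id Task version to simulate.
#' @param n_channels Simulated channels.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "signal", "contacts", "decode", "rsa", "units")`.
#' @param n_perm Permutations for inference stages.
#' @param n_iter_decode Decoding iterations.
#' @param alpha FDR level for screening.
#' @param delta_min Glass' delta gate.
#' @param planted_layer Layer name carrying the planted geometry.
#' @param alpha_match Match level of the planted layer.
#' @param k Latent dimension.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(seed = 1L, set_id = 2L, n_channels = 8L,
                            stages = c("simulate", "signal", "contacts",
                                       "decode", "rsa", "units"),
                            n_perm = 200L, n_iter_decode = 200L,
                            alpha = 0.05, delta_min = 1,
                            planted_layer = "conv5_3", alpha_match = 0.95,
                            k = 8L) {
  structure(list(seed = as.integer(seed), set_id = as.integer(set_id),
                 n_channels = as.integer(n_channels), stages = stages,
                 n_perm = as.integer(n_perm),
                 n_iter_decode = as.integer(n_iter_decode), alpha = alpha,
                 delta_min = delta_min, planted_layer = planted_layer,
                 alpha_match = alpha_match, k = as.integer(k)),
            class = "pipeline_config")
}

#' Run the simulation-to-inference pipeline
#'
#' Executes the toggled stages in order - simulate (protocol, latent space,
#' recording, layer stack), signal (CAR, HFA, epoching), contacts
#' (visual/face screening, grand matrix), decode (template matching +
#' permutation), rsa (layer profile), units (model-unit scan in the top
#' layer) - and writes TSV/JSON results plus a provenance log to `out_dir`.
#' Deterministic given the config: re-running writes identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Named list of stage results (also serialized under `out_dir`),
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("facespace_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  res <- list()
  stage_seed <- function(i) derive_seed(config$seed, i)
  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    logline("stage %s: start (seed %d)", name, config$seed)
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logline("stage %s: done", name)
    out
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("facespace pipeline, base seed %d\n", config$seed),
      file = log_path)

  sim <- run_stage("simulate", {
    protocol <- generate_protocol(config$set_id, stage_seed(1))
    space <- latent_face_space(10, config$k, stage_seed(2))
    cfg <- contacts_config(config$n_channels, k = config$k,
                           seed = stage_seed(3))
    rec <- simulate_recording(protocol, cfg, space, stage_seed(4))
    nm <- enumerate_layers(vgg_architecture())
    mp <- stats::setNames(rep(0.1, length(nm)), nm)
    mp[config$planted_layer] <- config$alpha_match
    stack <- simulate_layer_stack(space, mp, dims = 50,
                                  seed = stage_seed(5))
    write_events_tsv(protocol, file.path(out_dir, "events.tsv"))
    list(protocol = protocol, space = space, rec = rec, stack = stack)
  })
  res$simulate <- sim

  sig <- run_stage("signal", {
    car <- common_average_reference(sim$rec)
    hfa <- estimate_hfa(car)
    ep <- epoch_and_normalize(hfa, sim$protocol)
    list(ep = ep)
  })
  res$signal <- sig

  con <- run_stage("contacts", {
    ct <- detect_visual_contacts(sig$ep, alpha = config$alpha,
                                 delta_min = config$delta_min)
    comp <- intersect(c("places", "houses"),
                      unique(attr(sig$ep, "trials")$category))[1]
    ct <- detect_face_contacts(ct, sig$ep,
                               comparison_categories = c(comp, "patterns"))
    utils::write.table(ct, file.path(out_dir, "contacts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    G <- build_response_matrix(sig$ep, ct, smoothing_ms = 50)
    list(table = ct, G = G)
  })
  res$contacts <- con

  res$decode <- run_stage("decode", {
    dec <- decode_exemplars(con$G, n_iter = config$n_iter_decode,
                            seed = stage_seed(6))
    pt <- decoding_permutation_test(con$G, n_perm = min(config$n_perm, 100),
                                    n_iter = max(20L,
                                                 config$n_iter_decode %/% 10L),
                                    seed = stage_seed(7),
                                    observed = dec$accuracy)
    out <- list(accuracy = dec$accuracy, permutation_p = pt$p,
                n_iterations = dec$n_iterations)
    jsonlite::write_json(out, file.path(out_dir, "decoding.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  res$rsa <- run_stage("rsa", {
    Gr <- build_response_matrix(sig$ep, con$table, smoothing_ms = 0)
    prof <- correlate_profile(pairwise_distances(neural_patterns(Gr)),
                              sim$stack, n_perm = config$n_perm,
                              seed = stage_seed(8))
    write_profile_tsv(prof, file.path(out_dir, "layer_profile.tsv"))
    prof
  })

  res$units <- run_stage("units", {
    resp <- neural_patterns(con$G, time_average = TRUE)
    sig_layers <- if (!is.null(res$rsa) && any(res$rsa$significant))
      res$rsa$layer[res$rsa$significant] else config$planted_layer
    scans <- lapply(sig_layers, function(ly)
      model_unit_scan(resp, sim$stack$layers[[ly]]$activations,
                      alpha = config$alpha, n_perm_fit = 100,
                      n_perm_cluster = max(20L, config$n_perm %/% 4L),
                      seed = stage_seed(9)))
    names(scans) <- sig_layers
    counts <- vapply(scans, `[[`, numeric(1), "observed_count")
    jsonlite::write_json(as.list(counts), file.path(out_dir, "units.json"),
                         auto_unbox = TRUE, digits = NA)
    scans
  })

  summary <- list(
    seed = config$seed,
    n_face_contacts = if (!is.null(con)) sum(con$table$face_flag) else NA,
    decoding_accuracy = if (!is.null(res$decode)) res$decode$accuracy
                        else NA,
    top_layer = if (!is.null(res$rsa))
      res$rsa$layer[which.max(res$rsa$rho)] else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
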