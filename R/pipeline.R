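#' Pipeline run configuration
#'
#' Bundles the simulation parameters with the analysis settings of a full
#' run: which conditions and hemifields to decode, cross-validation folds,
#' the RSA delay grid and averaging window, the behavioral simulation, the
#' permutation count of the commonality test, and the Bayes-factor spec.
#' Unknown arguments are rejected; a config serializes losslessly to JSON
#' ([save_run_config()] / [load_run_config()]).
#'
#' @param simulation a [simulation_config()].
#' @param conditions conditions to analyze ("single", "dual").
#' @param hemifields hemifields to decode.
#' @param n_folds decoding folds for the full split (odd/even halves use
#'   `n_folds / 2`).
#' @param n_keep_words word presentations retained per hemifield/condition
#'   (NULL = no balancing).
#' @param time_window optional ms pair restricting decoding.
#' @param delay_range ms pair for the RSA delay grid.
#' @param rsa_window ms pair for delay-profile averaging.
#' @param n_behavior_trials triplet trials per simulated rater.
#' @param n_behavior_participants simulated raters per task.
#' @param decision_noise triplet softmax temperature.
#' @param n_permutations commonality permutations.
#' @param bf a [bf_spec()] for decoding onsets (mu0 is overridden per use).
#' @param stages stages to run (subset of "decode", "rsa", "behavior",
#'   "commonality").
#' @param out_dir output directory root (NULL = no files written).
#' @param seed analysis-level seed (balancing, behavior, permutations).
#' @return list of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       conditions = "single",
                       hemifields = c("LVF", "RVF"),
                       n_folds = 12,
                       n_keep_words = 48,
                       time_window = NULL,
                       delay_range = c(-100, 100),
                       rsa_window = c(0, 500),
                       n_behavior_trials = 400,
                       n_behavior_participants = 21,
                       decision_noise = 0.1,
                       n_permutations = 1000,
                       bf = bf_spec(mu0 = 0.5),
                       stages = c("decode", "rsa", "behavior", "commonality"),
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(simulation, "simulation_config"),
            all(conditions %in% c("single", "dual")),
            all(hemifields %in% c("LVF", "RVF")),
            all(stages %in% c("decode", "rsa", "behavior", "commonality")))
  structure(list(simulation = simulation, conditions = conditions,
                 hemifields = hemifields, n_folds = n_folds,
                 n_keep_words = n_keep_words, time_window = time_window,
                 delay_range = as.numeric(delay_range),
                 rsa_window = as.numeric(rsa_window),
                 n_behavior_trials = n_behavior_trials,
                 n_behavior_participants = n_behavior_participants,
                 decision_noise = decision_noise,
                 n_permutations = n_permutations,
                 bf = bf, stages = stages, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  x <- unclass(config)
  x$simulation <- unclass(x$simulation)
  x$bf <- unclass(x$bf)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim <- do.call(simulation_config, x$simulation[setdiff(names(x$simulation), character())])
  bf <- do.call(bf_spec, x$bf)
  args <- x[setdiff(names(x), c("simulation", "bf"))]
  args$simulation <- sim
  args$bf <- bf
  if (!is.null(args$time_window)) args$time_window <- as.numeric(args$time_window)
  do.call(run_config, args)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  save_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Run the full simulate / decode / RSA / behavior / commonality pipeline
#'
#' End-to-end driver: generates the design and epochs, balances word trials,
#' decodes every requested hemisphere x hemifield x condition (x odd/even
#' split when RSA is requested) per participant, and runs the requested
#' downstream stages. Returns a manifest with provenance (config hash,
#' seeds, stage outputs); when `config$out_dir` is set, stage tables are
#' written as CSV under a hash-stamped run directory, so a changed config
#' never overwrites a previous run.
#'
#' @param config a [run_config()].
#' @param stimuli the [stimulus_set()] to simulate.
#' @return list of class `run_manifest`; see elements `decode`, `rsa`,
#'   `behavior`, `commonality`, and `n_pair_contrasts`.
#' @export
run_pipeline <- function(config, stimuli = stimulus_set()) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  hash <- config_hash(config)
  run_dir <- NULL
  if (!is.null(config$out_dir)) {
    run_dir <- file.path(config$out_dir, paste0("run-", substr(hash, 1, 12)))
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    save_run_config(config, file.path(run_dir, "config.json"))
  }
  manifest <- list(config_hash = hash, seed = config$seed,
                   sim_seed = sim$seed, run_dir = run_dir,
                   n_pair_contrasts = NA_integer_, stages = config$stages)

  design <- generate_design(sim, stimuli)
  if (!is.null(config$n_keep_words))
    design <- balance_word_trials(design, stimuli, n_keep = config$n_keep_words,
                                  seed = derive_seed(config$seed, 11L))
  need_dual <- "dual" %in% config$conditions
  if (need_dual && sim$n_dual_sequences == 0)
    stop("stage decode: dual condition requested but the design has no dual sequences")
  if ("single" %in% config$conditions && sim$n_single_sequences == 0)
    stop("stage decode: single condition requested but the design has no single sequences")

  splits <- if ("rsa" %in% config$stages) c("odd", "even") else "all"
  participants <- sort(unique(design$participant))
  rdms <- list()
  for (p in participants) {
    epochs <- generate_epochs(sim, design[design$participant == p, ], stimuli)
    for (cond in config$conditions) {
      for (hemi in c("left", "right")) {
        for (hf in config$hemifields) {
          for (sp in splits) {
            nf <- if (sp == "all") config$n_folds else config$n_folds / 2
            key <- paste(cond, hemi, hf, sp, sep = "_")
            rdms[[key]][[as.character(p)]] <- pairwise_decode(
              epochs, cluster = hemi, condition = cond, hemifield = hf,
              n_folds = nf, split = sp, time_window = config$time_window)
          }
        }
      }
    }
  }
  first <- rdms[[1]][[1]]
  manifest$n_pair_contrasts <- choose(length(first$stimuli), 2)
  time <- first$time

  # group accuracy time courses and onsets per condition cell
  decode_out <- list()
  for (key in names(rdms)) {
    acc <- do.call(rbind, lapply(rdms[[key]], function(r) mean_accuracy(r)$values))
    decode_out[[key]] <- acc
  }
  manifest$decode <- list(accuracy = decode_out, time = time)
  if (length(participants) >= 2) {
    spec_acc <- config$bf
    spec_acc$mu0 <- 0.5
    manifest$decode$onsets <- lapply(decode_out, function(acc) {
      # a zero-variance time point (possible with very few participants)
      # leaves the onset undefined rather than aborting the run
      tryCatch({
        bf <- bf_timecourse(acc, spec_acc, time = time)
        detect_onset(bf)
      }, error = function(e) NA_real_)
    })
  }

  if ("rsa" %in% config$stages) {
    delays <- seq(config$delay_range[1], config$delay_range[2])
    rsa_out <- list()
    for (cond in config$conditions) {
      for (hf in config$hemifields) {
        contra <- if (hf == "LVF") "right" else "left"
        ipsi <- setdiff(c("left", "right"), contra)
        k <- function(h, s) paste(cond, h, hf, s, sep = "_")
        profiles <- lapply(as.character(participants), function(p) {
          tg <- crosscorrelate_timegen(rdms[[k(contra, "odd")]][[p]],
                                       rdms[[k(ipsi, "even")]][[p]],
                                       rdms[[k(contra, "even")]][[p]],
                                       rdms[[k(ipsi, "odd")]][[p]])
          delay_profile(tg, delays = delays, window = config$rsa_window)
        })
        mat <- do.call(rbind, lapply(profiles, `[[`, "values"))
        colnames(mat) <- delays
        cell <- list(profiles = mat, delays = delays)
        if (length(participants) >= 2)
          cell$asymmetry <- asymmetry_test(profiles)
        rsa_out[[paste(cond, hf, sep = "_")]] <- cell
      }
    }
    manifest$rsa <- rsa_out
  }

  models <- build_model_rdms(stimuli)
  if ("behavior" %in% config$stages) {
    beh <- list()
    for (task in c("image", "concept")) {
      w <- if (task == "image") c(1, 0.3) else c(0.3, 1)
      resp <- generate_triplet_responses(
        list(models$image_model$values, models$concept_model$values),
        weights = w, n_participants = config$n_behavior_participants,
        n_trials = config$n_behavior_trials,
        decision_noise = config$decision_noise,
        seed = derive_seed(config$seed, if (task == "image") 21L else 22L))
      beh[[task]] <- build_rdm_from_triplets(resp, n_stimuli = nrow(stimuli))
    }
    beh$model_cor <- list(
      image_task_image_model = correlate_rdms(beh$image, models$image_model)$rho,
      concept_task_concept_model = correlate_rdms(beh$concept, models$concept_model)$rho)
    manifest$behavior <- beh
  }

  if ("commonality" %in% config$stages) {
    key <- paste(config$conditions[1], "left",
                 config$hemifields[length(config$hemifields)], splits[1], sep = "_")
    group <- Reduce(`+`, lapply(rdms[[key]], `[[`, "values")) / length(participants)
    beh_models <- if ("behavior" %in% config$stages)
      list(image = manifest$behavior$image, concept = manifest$behavior$concept)
    else list(image = models$image_model, concept = models$concept_model)
    manifest$commonality <- commonality_permutation_test(
      group, beh_models$image, beh_models$concept,
      n_permutations = config$n_permutations,
      seed = derive_seed(config$seed, 31L))
    manifest$commonality$time <- time
  }

  if (!is.null(run_dir)) {
    for (key in names(decode_out)) {
      df <- data.frame(participant = rep(participants, length(time)),
                       time_ms = rep(time, each = length(participants)),
                       accuracy = as.vector(decode_out[[key]]))
      write.csv(df, file.path(run_dir, paste0("accuracy_", key, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(manifest$rsa)) {
      for (key in names(manifest$rsa)) {
        m <- manifest$rsa[[key]]$profiles
        df <- data.frame(participant = rep(participants, ncol(m)),
                         delay_ms = rep(as.integer(colnames(m)), each = nrow(m)),
                         correlation = as.vector(m))
        write.csv(df, file.path(run_dir, paste0("delay_profile_", key, ".csv")),
                  row.names = FALSE)
      }
    }
    if (!is.null(manifest$commonality)) {
      cm <- manifest$commonality
      df <- data.frame(time_ms = cm$time, t(cm$observed), t(cm$p))
      names(df) <- c("time_ms", rownames(cm$observed),
                     paste0("p_", rownames(cm$observed)))
      write.csv(df, file.path(run_dir, "commonality.csv"), row.names = FALSE)
    }
  }
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> config %s; %d pair contrasts per decoding cell\n",
              substr(x$config_hash, 1, 12), x$n_pair_contrasts))
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$run_dir)) cat("  outputs:", x$run_dir, "\n")
  invisible(x)
}
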