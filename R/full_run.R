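# End-to-end orchestration on a synthetic cohort: generate -> predict
# (age + cognitive metrics) -> interpret -> overlap -> stability ->
# mediation -> transfer, writing every artifact plus a checksum manifest.

#' Default configuration for [full_run()]
#'
#' Every stochastic stage has an explicit seed derived from `seed`; the
#' resolved configuration is echoed into the output directory as
#' `config.json` so runs are self-describing. The default sizes are desk
#' scale (60 nodes, 200 subjects, 20 CV repetitions).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed.
#' @param n_subjects,n_nodes Cohort and parcellation size.
#' @param targets Targets to model: `"age"` plus cognitive metric names.
#' @param folds,reps,n_components CV settings.
#' @param n_perm Permutations for prediction significance.
#' @param overlap_perm Permutations for weight-map overlap.
#' @param n_boot Bootstrap resamples for the stability map.
#' @param max_pairs Map pairs sampled for the inter-correlation.
#' @param restricted_reps CV repetitions per network-restricted run.
#' @param mediation_k,mediation_boot Top-k edges and bootstrap iterations
#'   for the mediation stage.
#' @return Named list, the run configuration.
#' @export
default_run_config <- function(out_dir, seed = 1L, n_subjects = 200L,
                               n_nodes = 60L, targets = c("age", "gF"),
                               folds = 10L, reps = 20L, n_components = 5L,
                               n_perm = 200L, overlap_perm = 1000L,
                               n_boot = 100L, max_pairs = 2000L,
                               restricted_reps = 2L, mediation_k = 20L,
                               mediation_boot = 200L) {
  list(out_dir = out_dir, seed = as.integer(seed),
       n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
       targets = targets, folds = as.integer(folds), reps = as.integer(reps),
       n_components = as.integer(n_components), n_perm = as.integer(n_perm),
       overlap_perm = as.integer(overlap_perm), n_boot = as.integer(n_boot),
       max_pairs = as.integer(max_pairs),
       restricted_reps = as.integer(restricted_reps),
       mediation_k = as.integer(mediation_k),
       mediation_boot = as.integer(mediation_boot))
}

# Atlas with 8 canonical networks whose sizes are scaled down from the
# 246-node default in proportion.
.scaled_atlas <- function(n_nodes) {
  ref <- c(VIS = 30, SMN = 38, DAN = 26, VAN = 24, LIM = 22, FPN = 28,
           DMN = 42, SUB = 36)
  sizes <- pmax(1L, round(ref / sum(ref) * n_nodes))
  while (sum(sizes) != n_nodes) {
    i <- if (sum(sizes) > n_nodes) which.max(sizes) else which.min(sizes)
    sizes[i] <- sizes[i] + sign(n_nodes - sum(sizes))
  }
  make_atlas(sizes, names(ref))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage on a generated cohort and writes all artifacts into
#' `config$out_dir`: atlas, phenotypes and connectomes (discovery and
#' external cohorts), per-target CV metrics, predictions, permutation
#' nulls, weight maps at all three levels, frozen models, age-cognition
#' overlap, the stability report, mediation of the age-cognition
#' association by the top positively weighted edges, transfer validation,
#' the resolved configuration, and a `manifest.tsv` of MD5 checksums. A
#' failing stage aborts with its name after writing the partial manifest.
#'
#' @param config List from [default_run_config()].
#' @return Data.frame manifest (file, md5), invisibly.
#' @export
full_run <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) written[[length(written) + 1L]] <<- path
  finish_manifest <- function() {
    man <- data.frame(file = basename(written),
                      md5 = unname(tools::md5sum(written)))
    data.table::fwrite(man, file.path(out, "manifest.tsv"), sep = "\t")
    man
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      finish_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  jsonlite::write_json(config, file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  emit(file.path(out, "config.json"))

  atlas <- NULL; spec <- NULL; coh <- NULL; ext <- NULL
  stage("synth", {
    atlas <- .scaled_atlas(config$n_nodes)
    spec <- synthetic_spec(atlas, n_subjects = config$n_subjects,
                            seed = config$seed)
    coh <- simulate_cohort(spec, seed = config$seed)
    ext <- simulate_cohort(spec, seed = config$seed + 1L)
    emit(write_atlas(atlas, file.path(out, "atlas.tsv")))
    emit(write_phenotypes(coh$cohort, file.path(out, "phenotypes.tsv")))
    emit(write_edge_matrix(coh$connectomes, file.path(out, "connectomes.tsv")))
    emit(write_phenotypes(ext$cohort, file.path(out, "phenotypes_external.tsv")))
    emit(write_edge_matrix(ext$connectomes,
                           file.path(out, "connectomes_external.tsv")))
  })

  X <- coh$connectomes
  conn_maps <- list()
  models <- list()
  cv_results <- list()
  stage("predict", {
    for (tg in config$targets) {
      y <- if (tg == "age") coh$cohort$age else coh$cohort[[tg]]
      if (is.null(y)) stop("unknown target '", tg, "'")
      cv <- repeated_cv(X, y, folds = config$folds, reps = config$reps,
                        n_components = config$n_components,
                        seed = config$seed)
      pt <- permutation_test(X, y, folds = config$folds, reps = config$reps,
                             n_components = config$n_components,
                             n_perm = config$n_perm, seed = config$seed)
      cv_results[[tg]] <- cv
      preds <- data.frame(subject_id = coh$cohort$subject_id, actual = y,
                          predicted = cv$predicted)
      data.table::fwrite(preds, file.path(out, paste0("predictions_", tg, ".tsv")),
                         sep = "\t")
      emit(file.path(out, paste0("predictions_", tg, ".tsv")))
      jsonlite::write_json(
        c(cv$summary, list(p_perm = pt$p_value, n_perm = pt$n_perm,
                           reps_per_perm = pt$reps_per_perm,
                           n_fold_maps = ncol(cv$fold_weight_maps),
                           n_components = config$n_components)),
        file.path(out, paste0("metrics_", tg, ".json")),
        auto_unbox = TRUE, digits = NA)
      emit(file.path(out, paste0("metrics_", tg, ".json")))
      data.table::fwrite(data.frame(null_r = pt$null_values),
                         file.path(out, paste0("perm_null_", tg, ".tsv")),
                         sep = "\t")
      emit(file.path(out, paste0("perm_null_", tg, ".tsv")))
      cmap <- average_maps(cv$fold_weight_maps, source = tg)
      conn_maps[[tg]] <- cmap
      emit(write_weight_map(cmap, atlas,
                            file.path(out, paste0("weights_connection_", tg, ".tsv"))))
      emit(write_weight_map(node_summary(cmap, atlas), atlas,
                            file.path(out, paste0("weights_node_", tg, ".tsv"))))
      ns <- network_summary(cmap, atlas)
      data.table::fwrite(ns$cells,
                         file.path(out, paste0("weights_network_", tg, ".tsv")),
                         sep = "\t")
      emit(file.path(out, paste0("weights_network_", tg, ".tsv")))
      full_model <- fit_plsr(X, y, n_components = config$n_components,
                             target_name = tg, atlas = atlas)
      models[[tg]] <- full_model
      emit(save_model(full_model, file.path(out, paste0("model_", tg, ".json"))))
    }
  })

  stage("overlap", {
    cogs <- setdiff(config$targets, "age")
    res <- list()
    for (tg in cogs) {
      for (lv in c("connection", "node", "network")) {
        ma <- switch(lv, connection = conn_maps[["age"]],
                     node = node_summary(conn_maps[["age"]], atlas),
                     network = network_summary(conn_maps[["age"]], atlas)$map)
        mb <- switch(lv, connection = conn_maps[[tg]],
                     node = node_summary(conn_maps[[tg]], atlas),
                     network = network_summary(conn_maps[[tg]], atlas)$map)
        ov <- overlap(ma, mb, n_perm = config$overlap_perm, seed = config$seed)
        res[[paste0("age_vs_", tg, "_", lv)]] <-
          list(r = ov$r, p = ov$p, n_perm = ov$n_perm)
      }
    }
    jsonlite::write_json(res, file.path(out, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out, "overlap.json"))
  })

  stage("stability", {
    y_age <- coh$cohort$age
    ic <- weight_intercorrelation(cv_results[["age"]]$fold_weight_maps,
                                  max_pairs = config$max_pairs,
                                  seed = config$seed)
    bw <- bootstrap_weights(X, y_age, n_boot = config$n_boot,
                            n_components = config$n_components,
                            seed = config$seed)
    nr <- network_restricted_cv(X, y_age, atlas, folds = config$folds,
                                reps = config$restricted_reps,
                                n_components = config$n_components,
                                seed = config$seed)
    boot_vs_cv <- overlap(network_summary(bw$map, atlas)$map,
                          network_summary(conn_maps[["age"]], atlas)$map,
                          n_perm = config$overlap_perm, seed = config$seed)
    jsonlite::write_json(
      list(intercorrelation_mean = ic$mean, intercorrelation_sd = ic$sd,
           n_pairs = ic$n_pairs, bootstrap_n = config$n_boot,
           bootstrap_vs_cv_network_r = boot_vs_cv$r,
           whole_brain_r = nr$whole_brain$r_mean,
           max_restricted_r = max(nr$per_pair$r_mean, na.rm = TRUE),
           size_accuracy_spearman = nr$size_accuracy_spearman),
      file.path(out, "stability.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(out, "stability.json"))
    data.table::fwrite(nr$per_pair, file.path(out, "network_restricted.tsv"),
                       sep = "\t")
    emit(file.path(out, "network_restricted.tsv"))
  })

  stage("mediate", {
    cogs <- setdiff(config$targets, "age")
    if (length(cogs)) {
      tg <- cogs[1L]
      med <- mediate_topk(conn_maps[[tg]], X, coh$cohort$age, coh$cohort[[tg]],
                          covariates = cbind(gender = coh$cohort$gender,
                                             mean_fd = coh$cohort$mean_fd),
                          k = config$mediation_k, sign = "positive",
                          n_boot = config$mediation_boot, seed = config$seed)
      data.table::fwrite(med$records, file.path(out, "mediation.tsv"),
                         sep = "\t")
      emit(file.path(out, "mediation.tsv"))
      jsonlite::write_json(
        list(k = med$k, sign = med$sign, n_significant = med$n_significant,
             prop_min = med$prop_range[1L], prop_max = med$prop_range[2L]),
        file.path(out, "mediation.json"), auto_unbox = TRUE, digits = NA)
      emit(file.path(out, "mediation.json"))
    }
  })

  stage("transfer", {
    res <- list()
    for (tg in config$targets) {
      pred <- apply_model(models[[tg]], ext$connectomes, atlas = atlas)
      res[[tg]] <- validate_transfer(pred, ext$cohort$age, ext$cohort$mean_fd,
                                     n_models_tested = length(config$targets),
                                     target_name = tg)
    }
    jsonlite::write_json(res, file.path(out, "transfer.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(file.path(out, "transfer.json"))
  })

  invisible(finish_manifest())
}
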