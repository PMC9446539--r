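#' Configuration for an end-to-end case-study run
#'
#' All randomness in a run is funneled through named sub-seeds derived from
#' one master seed, so a configuration reproduces bit-identically.
#'
#' @param case `1` (CRGs 1000/5192/5424) or `2` (adds CRG-6144).
#' @param seed master integer seed; sub-seeds for generation, under-sampling,
#'   splitting, model training, clustering and embedding are derived from it.
#' @param vocab the [code_vocabulary()] to generate against.
#' @param dae a [dae_config()]; its seed is overridden by the derived model
#'   seed.
#' @param k_range candidate numbers of clusters.
#' @param embed logical; run the joint t-SNE embedding and trajectory stage
#'   (the most expensive stage; the clustering results do not depend on it).
#' @param tsne_perplexity,tsne_max_iter embedding parameters.
#' @param out_dir optional directory for CSV/JSON artifacts and the run
#'   manifest; `NULL` keeps everything in memory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(case = 1, seed = 1, vocab = default_vocabulary(),
                       dae = dae_config(), k_range = 2:10, embed = TRUE,
                       tsne_perplexity = 30, tsne_max_iter = 1000,
                       out_dir = NULL) {
  stopifnot(case %in% c(1, 2))
  seed <- as.integer(seed)
  seeds <- list(generator = seed * 1000L + 1L,
                undersample = seed * 1000L + 2L,
                split = seed * 1000L + 3L,
                model = seed * 1000L + 4L,
                clustering = seed * 1000L + 5L,
                embedding = seed * 1000L + 6L)
  dae$seed <- seeds$model
  structure(list(case = case, seed = seed, seeds = seeds, vocab = vocab,
                 dae = dae, k_range = as.integer(k_range), embed = embed,
                 tsne_perplexity = tsne_perplexity,
                 tsne_max_iter = tsne_max_iter, out_dir = out_dir),
            class = "run_config")
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run one case study end to end
#'
#' Generate (or accept) a cohort; under-sample to the minority CRG; split
#' 75/25; train the denoising autoencoder on the training subset; select the
#' number of clusters on the training latent representations by
#' cluster-validity majority; cluster the test latent representations with
#' Ward AHC at the selected k; characterize the test clusters (profiles,
#' top-5 codes per family, profile PCC against CRG profiles and against the
#' generating sub-groups, cluster-vs-CRG cross-tabulation, age summaries);
#' optionally build simple/complex synthetic patients from each cluster's top
#' codes and map their trajectories in a joint t-SNE embedding.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built `cohort` (e.g. from
#'   [load_user_cohort()]); by default the case's synthetic cohort is
#'   generated.
#' @return list with the balanced cohort, split, model, selection
#'   (`k_star`, `votes`, `cvi_table`), test clustering, characterization
#'   tables, recovery diagnostics (ARI against generating sub-groups, matched
#'   profile PCCs), optional embedding/trajectories, and a `manifest`.
#' @export
run_case_study <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))

  if (is.null(cohort)) {
    cohort <- with_stage("generate", {
      specs <- default_study_specs(config$case, config$vocab)
      generate_cohort(specs, config$vocab, seed = config$seeds$generator)
    })
  }
  balanced <- with_stage("undersample",
                         undersample(cohort, seed = config$seeds$undersample))
  split <- with_stage("split",
                      train_test_split(balanced, 0.75, seed = config$seeds$split))

  model <- with_stage("train_dae", train_dae(split$train$X, config$dae))
  H_train <- with_stage("represent_train", represent(split$train, model))
  selection <- with_stage("select_k",
                          select_n_clusters(H_train, config$k_range,
                                            seed = config$seeds$clustering))
  k_star <- selection$k_star

  H_test <- with_stage("represent_test", represent(split$test, model))
  clustering <- with_stage("cluster_test", ahc_ward(H_test, k_star))

  charac <- with_stage("characterize", {
    labels <- clustering$labels
    cluster_profiles <- lapply(sort(unique(labels)), function(cl) {
      compute_profile(split$test$X[labels == cl, , drop = FALSE],
                      config$vocab, subset_id = paste0("C", cl))
    })
    names(cluster_profiles) <- paste0("C", sort(unique(labels)))
    crg_profiles <- lapply(sort(unique(split$test$crg)), function(g) {
      compute_profile(split$test$X[split$test$crg == g, , drop = FALSE],
                      config$vocab, subset_id = g)
    })
    names(crg_profiles) <- sort(unique(split$test$crg))
    pcc <- do.call(rbind, lapply(names(cluster_profiles), function(cl) {
      do.call(rbind, lapply(names(crg_profiles), function(g) {
        r <- profile_pcc(cluster_profiles[[cl]], crg_profiles[[g]])
        data.frame(cluster = cl, crg = g, pcc_diagnosis = r[["diagnosis"]],
                   pcc_drug = r[["drug"]], pcc_all = r[["all"]])
      }))
    }))
    list(cluster_profiles = cluster_profiles, crg_profiles = crg_profiles,
         top_codes = lapply(cluster_profiles, top_codes),
         pcc = pcc,
         crosstab = cross_tabulate(labels, split$test$crg),
         ages = age_summary(split$test$age, labels))
  })

  recovery <- with_stage("recovery", {
    truth <- split$test$subgroup
    ari <- adjusted_rand_index(clustering$labels, truth)
    matched <- match_clusters(clustering$labels, truth)
    sub_profiles <- lapply(unique(truth), function(g) {
      compute_profile(split$test$X[truth == g, , drop = FALSE],
                      config$vocab, subset_id = g)
    })
    names(sub_profiles) <- unique(truth)
    cl_prof_by_label <- function(cl) {
      compute_profile(split$test$X[clustering$labels == as.integer(cl), ,
                                   drop = FALSE], config$vocab)
    }
    pcc <- do.call(rbind, lapply(seq_len(nrow(matched)), function(i) {
      r <- profile_pcc(cl_prof_by_label(matched$cluster[i]),
                       sub_profiles[[matched$group[i]]])
      data.frame(cluster = matched$cluster[i], subgroup = matched$group[i],
                 pcc_diagnosis = r[["diagnosis"]], pcc_drug = r[["drug"]])
    }))
    list(ari = ari, matched = matched, matched_pcc = pcc)
  })

  embedding <- NULL; trajectories <- NULL
  if (isTRUE(config$embed)) {
    embedding <- with_stage("embed", {
      synth <- list()
      for (cl in names(charac$top_codes)) {
        tc <- charac$top_codes[[cl]]
        for (fam in c("diagnosis", "drug")) {
          codes <- tc$code[tc$family == fam]
          for (cd in codes) {
            id <- paste0("simple_", cd)
            if (is.null(synth[[id]])) synth[[id]] <- make_simple_patient(cd, config$vocab)
          }
          cx <- make_complex_patients(codes, config$vocab)
          for (p in cx) {
            p$id <- paste0(cl, "_", fam, "_", p$id)
            synth[[p$id]] <- p
          }
        }
      }
      Xs <- synthetic_matrix(unname(synth))
      H_synth <- represent(Xs, model)
      emb <- embed_joint(H_test, H_synth,
                         perplexity = config$tsne_perplexity,
                         max_iter = config$tsne_max_iter,
                         seed = config$seeds$embedding)
      list(embedding = emb, synthetic = synth)
    })
    trajectories <- with_stage("trajectories", {
      out <- list()
      for (cl in names(charac$top_codes)) {
        tc <- charac$top_codes[[cl]]
        for (fam in c("diagnosis", "drug")) {
          ids <- grep(paste0("^", cl, "_", fam, "_complex"),
                      names(embedding$synthetic), value = TRUE)
          ids <- ids[order(vapply(embedding$synthetic[ids], `[[`, 1L, "N"))]
          out[[paste0(cl, "_", fam)]] <-
            extract_trajectory(embedding$embedding, ids)
        }
      }
      out
    })
  }

  result <- list(config = config, cohort = balanced, split = split,
                 model = model, selection = selection, k_star = k_star,
                 clustering = clustering, characterization = charac,
                 recovery = recovery, embedding = embedding,
                 trajectories = trajectories)
  result$manifest <- build_manifest(result)
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  result
}

# Compact, deterministic summary of a run (written alongside artifacts).
build_manifest <- function(result) {
  cfg <- result$config
  list(case = cfg$case,
       seeds = cfg$seeds,
       config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
       n_balanced = result$cohort$n,
       n_train = result$split$train$n,
       n_test = result$split$test$n,
       D = cfg$vocab$D,
       dae = list(d = cfg$dae$d, noise_type = cfg$dae$noise_type,
                  noise_level = cfg$dae$noise_level,
                  epochs_run = if (result$model$trained) nrow(result$model$history) else 0L,
                  best_val_loss = if (result$model$trained) min(result$model$history$val_loss) else NA_real_),
       k_star = result$k_star,
       votes = as.list(result$selection$votes),
       recovery_ari = result$recovery$ari,
       embedded = !is.null(result$embedding))
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(result$selection$cvi_table, p("cvi_table.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(patient_id = result$split$test$patient_id,
                              cluster = result$clustering$labels),
                   p("clusters_test.csv"), row.names = FALSE)
  utils::write.csv(result$characterization$pcc, p("profile_pcc.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$characterization$crosstab$counts),
                   p("crosstab_counts.csv"), row.names = FALSE)
  utils::write.csv(result$characterization$ages, p("age_summary.csv"),
                   row.names = FALSE)
  prof <- do.call(rbind, lapply(result$characterization$cluster_profiles,
                                function(pr) {
    data.frame(subset = pr$subset_id, code = names(pr$rates),
               family = pr$family, rate = unname(pr$rates))
  }))
  utils::write.csv(prof, p("cluster_profiles.csv"), row.names = FALSE)
  if (!is.null(result$trajectories)) {
    traj <- do.call(rbind, lapply(names(result$trajectories), function(nm) {
      cbind(trajectory = nm, result$trajectories[[nm]])
    }))
    utils::write.csv(traj, p("trajectories.csv"), row.names = FALSE)
    utils::write.csv(data.frame(id = result$embedding$embedding$ids,
                                role = result$embedding$embedding$role,
                                result$embedding$embedding$coordinates),
                     p("embedding.csv"), row.names = FALSE)
  }
  manifest <- result$manifest
  manifest$artifacts <- list.files(out_dir)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
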