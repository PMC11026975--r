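#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> train (one or both directions) -> reconstruct
#' -> ANS/RNS -> optional ComBat harmonization -> summaries and
#' fingerprinting on a held-out set, writing every product plus a manifest
#' (seeds, stage status, file hashes) into a run directory. Configuration
#' is a nested list (or YAML file) with elements `synth`, `ce`, `train`,
#' `n_holdout`, `directions`, `seed`.
#'
#' @param config list or path to a YAML file.
#' @param out_dir run directory (created).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  manifest <- list(seed = seed, stages = list(),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("hemispec")))
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- "ok"
    res
  }

  coh <- stage("simulate", function() {
    sa <- config$synth %||% list()
    sa$seed <- sa$seed %||% seed
    coh <- generate_cohort(do.call(synth_config, sa))
    write_cohort(coh, file.path(out_dir, "cohort"))
    coh
  })

  n <- length(coh$pairs)
  n_hold <- config$n_holdout %||% max(2L, round(n / 3))
  train_idx <- seq_len(n - n_hold)
  hold_idx <- setdiff(seq_len(n), train_idx)
  directions <- config$directions %||% "lh2rh"

  models <- list()
  for (dir_ in directions) {
    models[[dir_]] <- stage(paste0("train_", dir_), function() {
      ca <- config$ce %||% list()
      ca$in_shape <- dim(coh$mask)
      ta <- config$train %||% list()
      ta$direction <- dir_
      ta$seed <- ta$seed %||% seed
      model <- build_ce_model(do.call(ce_config, ca), seed = seed)
      fit <- train_ce(model, coh$pairs[train_idx], do.call(train_config, ta),
                      val_cohort = coh$pairs[hold_idx])
      write.csv(fit$log, file.path(out_dir, sprintf("loss_%s.csv", dir_)),
                row.names = FALSE)
      save_ce_model(fit$model, file.path(out_dir, sprintf("ce_%s.rds", dir_)))
      fit$model
    })
  }

  maps <- stage("specificity", function() {
    md <- file.path(out_dir, "maps")
    dir.create(md, showWarnings = FALSE)
    out <- list()
    for (dir_ in directions) {
      m <- models[[dir_]]
      src <- if (dir_ == "lh2rh") "lh" else "rh"
      tgt <- if (dir_ == "lh2rh") "rh" else "lh"
      ans <- lapply(hold_idx, function(i) {
        p <- coh$pairs[[i]]
        rec <- ce_generate(m, p[[src]])
        a <- ans_map(p[[tgt]], rec, subject_id = p$subject_id)
        write_volume(a, file.path(md, sprintf("%s_ans_%s.nii", p$subject_id, tgt)))
        a
      })
      rns <- lapply(hold_idx, function(i) {
        p <- coh$pairs[[i]]
        rec <- ce_generate(m, p[[src]])
        r <- rns_map(p[[tgt]], rec, subject_id = p$subject_id)
        write_volume(r, file.path(md, sprintf("%s_rns_%s.nii", p$subject_id, tgt)))
        r
      })
      out[[dir_]] <- list(ans = ans, rns = rns)
    }
    out
  })

  stage("harmonize", function() {
    cv <- coh$covariates[hold_idx, ]
    if (length(unique(cv$batch)) >= 2 && all(table(cv$batch) >= 2)) {
      for (dir_ in names(maps)) {
        maps[[dir_]]$ans <<- harmonize_combat(maps[[dir_]]$ans, cv$batch,
                                              cv[, c("age", "sex", "icv")])
      }
    }
    NULL
  })

  stage("summaries", function() {
    for (dir_ in names(maps)) {
      am <- maps[[dir_]]$ans
      mask <- am[[1]]$mask
      grp <- Reduce(`+`, lapply(am, function(m) m$values)) / length(am)
      grp_map <- new_specificity_map(grp, mask, "ANS", am[[1]]$hemisphere)
      dec <- decile_partition(grp_map)
      tabs <- lapply(seq_along(am), function(j) {
        t <- summarize_map(am[[j]], dec)
        t$subject_id <- am[[j]]$subject_id
        t
      })
      write.csv(do.call(rbind, tabs),
                file.path(out_dir, sprintf("ans_summaries_%s.csv", dir_)),
                row.names = FALSE)
      sim <- pairwise_similarity(am, am)
      write.csv(sim$values, file.path(out_dir, sprintf("ans_similarity_%s.csv", dir_)),
                row.names = FALSE)
    }
    NULL
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(files[!grepl("manifest", files)]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
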