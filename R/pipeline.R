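#' Validate a pipeline run configuration
#'
#' Checks every enabled stage's parameter block before any stage runs, so
#' a misconfigured late stage fails fast.
#'
#' @param config A list (or YAML path) with a global `seed`,
#'   `output_dir`, and optional stage blocks `simulate`, `inputs`,
#'   `preprocess`, `scan`, `trajectories`, `mediate`, `riskmodel`.
#' @return The normalised config list, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) stop("config needs output_dir",
                                       call. = FALSE)
  on_ <- function(block) isTRUE(config[[block]]$enabled)
  if (!on_("simulate") && is.null(config$inputs)) {
    stop("config needs either an enabled simulate block or inputs paths",
         call. = FALSE)
  }
  if (on_("simulate")) {
    sim_args <- config$simulate
    sim_args$enabled <- NULL
    do.call(sim_config, c(sim_args,
                          list(seed = derive_seed(config$seed, "simulate"))))
  }
  if (on_("preprocess")) {
    pp <- config$preprocess
    if (!is.null(pp$max_missing) &&
        (pp$max_missing < 0 || pp$max_missing > 1)) {
      stop("preprocess$max_missing must be in [0,1]", call. = FALSE)
    }
    if (!is.null(pp$split_frac) &&
        (pp$split_frac <= 0 || pp$split_frac >= 1)) {
      stop("preprocess$split_frac must be in (0,1)", call. = FALSE)
    }
  }
  if (on_("scan") && !is.null(config$scan$alpha) &&
      (config$scan$alpha <= 0 || config$scan$alpha >= 1)) {
    stop("scan$alpha must be in (0,1)", call. = FALSE)
  }
  if (on_("mediate") &&
      !is.null(config$mediate$exposure) &&
      !config$mediate$exposure %in% c("bmi", "smoking")) {
    stop("mediate$exposure must be 'bmi' or 'smoking'", call. = FALSE)
  }
  invisible(structure(config, class = "run_config"))
}

# Internal: run one stage with named-failure semantics.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the analysis pipeline end-to-end from a single configuration
#'
#' Executes the enabled stages in order — simulate, preprocess, scan,
#' trajectories, mediate, riskmodel — writing every intermediate as
#' delimited text or JSON under `output_dir`, and a manifest recording the
#' package version, per-stage derived seeds and output digests. A stage
#' failure halts the run with the failing stage named; outputs of earlier
#' stages are retained.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  seeds <- list()
  on_ <- function(block) isTRUE(config[[block]]$enabled)

  if (on_("simulate")) {
    seeds$simulate <- derive_seed(config$seed, "simulate")
    run_stage("simulate", {
      sim_args <- config$simulate
      sim_args$enabled <- NULL
      cfg <- do.call(sim_config, c(sim_args, list(seed = seeds$simulate)))
      write_simulated_data(simulate_cohort(cfg), config$output_dir)
    })
    cohort_path <- out("cohort.csv")
    protein_path <- out("proteins.csv")
  } else {
    cohort_path <- config$inputs$cohort
    protein_path <- config$inputs$proteins
  }

  if (on_("preprocess")) {
    seeds$preprocess <- derive_seed(config$seed, "preprocess")
    run_stage("preprocess", {
      pp <- config$preprocess
      cohort <- read_cohort(cohort_path)
      mat <- read_protein_matrix(protein_path)
      exc <- if ("prior_cancer" %in% names(cohort)) {
        apply_exclusions(cohort)
      } else {
        list(cohort = cohort, log = c(prior_cancer = 0L,
                                      missing_covariates = 0L))
      }
      cohort <- exc$cohort
      mat <- mat[match(cohort$participant_id, rownames(mat)), ,
                 drop = FALSE]
      mat <- filter_proteins(mat, pp$max_missing %||% 0.20)
      dropped <- attr(mat, "dropped")
      mat <- knn_impute(mat, k = pp$knn_k %||% 10)
      split <- split_cohort(cohort, frac = pp$split_frac %||% 0.80,
                            seed = seeds$preprocess)
      utils::write.csv(cohort, out("cohort_clean.csv"), row.names = FALSE,
                       na = "")
      utils::write.csv(data.frame(participant_id = rownames(mat), mat,
                                  check.names = FALSE),
                       out("proteins_imputed.csv"), row.names = FALSE)
      jsonlite::write_json(list(exclusions = as.list(exc$log),
                                dropped_proteins = dropped,
                                split = split),
                           out("preprocess_log.json"), auto_unbox = TRUE,
                           pretty = TRUE)
    })
    cohort_path <- out("cohort_clean.csv")
    protein_path <- out("proteins_imputed.csv")
  }

  scan_path <- NULL
  if (on_("scan")) {
    run_stage("scan", {
      sc <- config$scan
      cohort <- read_cohort(cohort_path)
      mat <- read_protein_matrix(protein_path)
      if (ncol(mat) == 0L) stop("no proteins to scan")
      if (file.exists(out("preprocess_log.json"))) {
        split <- jsonlite::read_json(out("preprocess_log.json"),
                                     simplifyVector = TRUE)$split
        keep <- cohort$participant_id %in% split$derivation
        cohort <- cohort[keep, , drop = FALSE]
        mat <- mat[match(cohort$participant_id, rownames(mat)), ,
                   drop = FALSE]
      }
      res <- pwas_scan(cohort, mat, alpha = sc$alpha %||% 0.05,
                       family_size = sc$family_size)
      utils::write.csv(res, out("scan.csv"), row.names = FALSE)
    })
    scan_path <- out("scan.csv")
  }

  if (on_("trajectories")) {
    seeds$trajectories <- derive_seed(config$seed, "trajectories")
    run_stage("trajectories", {
      tj <- config$trajectories
      if (is.null(scan_path)) stop("requires the scan stage")
      scan <- utils::read.csv(scan_path, stringsAsFactors = FALSE)
      hits <- scan$protein[which(scan$bonferroni_sig)]
      top_n <- tj$top_n %||% 8
      if (length(hits) < 2L) {
        hits <- scan$protein[order(scan$p)][seq_len(min(top_n, nrow(scan)))]
      }
      cohort <- read_cohort(cohort_path)
      mat <- read_protein_matrix(protein_path)
      matched <- match_controls(cohort, ratio = tj$ratio %||% 10,
                                seed = seeds$trajectories)
      adj <- residualize(mat, cohort)
      z <- zscore_cases(adj[, hits, drop = FALSE], matched)
      lead <- cohort$lead_time[match(rownames(z), cohort$participant_id)]
      traj <- fit_trajectories(z, lead, span = tj$span %||% 0.75,
                               threshold = tj$threshold %||% 0.45)
      k <- tj$k %||% 4
      labels <- rep(NA_integer_, length(hits))
      if (length(hits) >= k) {
        cl <- cluster_trajectories(traj, k = k,
                                   method = tj$method %||% "hierarchical",
                                   seed = seeds$trajectories)
        labels <- cl$labels[hits]
      }
      utils::write.csv(data.frame(lead_time = traj$grid, traj$curves,
                                  check.names = FALSE),
                       out("trajectory_curves.csv"), row.names = FALSE)
      utils::write.csv(data.frame(protein = hits,
                                  onset = traj$onset[hits],
                                  cluster = labels),
                       out("trajectory_clusters.csv"), row.names = FALSE)
    })
  }

  if (on_("mediate")) {
    seeds$mediate <- derive_seed(config$seed, "mediate")
    run_stage("mediate", {
      md <- config$mediate
      if (is.null(scan_path)) stop("requires the scan stage")
      scan <- utils::read.csv(scan_path, stringsAsFactors = FALSE)
      hits <- union(scan$protein[which(scan$bonferroni_sig)],
                    scan$protein[order(scan$p)][seq_len(min(md$top_n %||% 8,
                                                            nrow(scan)))])
      cohort <- read_cohort(cohort_path)
      mat <- read_protein_matrix(protein_path)
      exposure <- md$exposure %||% "bmi"
      ea <- exposure_associations(cohort, mat[, hits, drop = FALSE],
                                  exposure)
      cand <- screen_mediators(ea, scan[scan$protein %in% hits, ])
      if (!length(cand)) stop("no candidate mediators pass screening")
      n_boot <- md$n_boot %||% 200
      fw <- lapply(cand, function(pr) {
        models <- fit_mediation_models(cohort, exposure, pr, matrix = mat)
        fourway_decompose(models, n_boot = n_boot, seed = seeds$mediate)
      })
      names(fw) <- cand
      tab <- do.call(rbind, lapply(cand, function(pr) {
        f <- fw[[pr]]
        data.frame(protein = pr, exposure = exposure, te = f$te,
                   cde = f$cde, int_ref = f$int_ref, int_med = f$int_med,
                   pie = f$pie,
                   proportion_mediated = f$proportion_mediated,
                   p_te = f$p[["te"]], p_pie = f$p[["pie"]],
                   significant = f$significant)
      }))
      utils::write.csv(tab, out("mediation.csv"), row.names = FALSE)
      sig <- tab$protein[tab$significant]
      if (length(sig) >= 2L) {
        pca <- pca_aggregate(mat, fourway = fw[sig])
        pca_res <- mediate_via_pca(cohort, pca$scores, exposure,
                                   n_boot = n_boot, seed = seeds$mediate)
        jsonlite::write_json(
          list(retained_components = pca$retained,
               mediators = pca$mediators,
               combined_proportion = pca_res$combined_proportion,
               approximate = pca_res$approximate),
          out("mediation_pca.json"), auto_unbox = TRUE, pretty = TRUE)
      }
    })
  }

  if (on_("riskmodel")) {
    seeds$riskmodel <- derive_seed(config$seed, "riskmodel")
    run_stage("riskmodel", {
      rm_ <- config$riskmodel
      if (is.null(scan_path)) stop("requires the scan stage")
      scan <- utils::read.csv(scan_path, stringsAsFactors = FALSE)
      cohort <- read_cohort(cohort_path)
      mat <- read_protein_matrix(protein_path)
      deriv <- cohort; repl <- cohort
      if (file.exists(out("preprocess_log.json"))) {
        split <- jsonlite::read_json(out("preprocess_log.json"),
                                     simplifyVector = TRUE)$split
        deriv <- cohort[cohort$participant_id %in% split$derivation, ]
        repl <- cohort[cohort$participant_id %in% split$replication, ]
      }
      fdr_hits <- scan$protein[which(scan$fdr_q < 0.05)]
      if (!length(fdr_hits)) {
        fdr_hits <- scan$protein[order(scan$p)][seq_len(min(5, nrow(scan)))]
      }
      clinical <- fit_clinical(deriv)
      protein <- fit_protein(deriv, mat, fdr_hits,
                             cv_folds = rm_$cv_folds %||% 10,
                             seed = seeds$riskmodel)
      combined <- fit_combined(deriv, mat, clinical, protein)
      horizons <- rm_$horizons %||% 2:10
      evals <- lapply(list(clinical = clinical, protein = protein,
                           combined = combined), function(m) {
        ref <- if (!identical(m$kind, "clinical")) clinical
        evaluate_risk_model(m, repl, mat, horizons = horizons,
                            reference = ref,
                            n_boot = rm_$n_boot %||% 200,
                            seed = seeds$riskmodel)
      })
      tab <- do.call(rbind, lapply(evals, function(e) {
        data.frame(kind = e$kind, c_index = e$c_index,
                   c_low = e$c_index_ci[1], c_high = e$c_index_ci[2],
                   auc_min = suppressWarnings(min(e$td_auc, na.rm = TRUE)),
                   auc_max = suppressWarnings(max(e$td_auc, na.rm = TRUE)),
                   idi = e$idi, c_comparison_p = e$c_index_comparison_p,
                   logrank_p = e$logrank_p)
      }))
      utils::write.csv(tab, out("risk_eval.csv"), row.names = FALSE)
      coefs <- do.call(rbind, lapply(
        list(clinical, protein, combined), function(m) {
          cf <- stats::coef(m$fit)
          if (!length(cf)) return(NULL)
          data.frame(model = m$kind, term = names(cf), coef = unname(cf))
        }))
      utils::write.csv(coefs, out("risk_coefficients.csv"),
                       row.names = FALSE)
    })
  }

  files <- list.files(config$output_dir, full.names = TRUE)
  manifest <- list(
    package = "prediagprot",
    version = as.character(utils::packageVersion("prediagprot")),
    global_seed = config$seed,
    stage_seeds = seeds,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(files[!grepl("manifest", files)])),
      basename(files[!grepl("manifest", files)])))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a summary report from pipeline outputs
#'
#' Assembles a single markdown document from whatever stage outputs are
#' present in the directory: top association hits, trajectory clusters,
#' four-way mediation components, and model evaluation; stages that did
#' not run are noted. Regenerating from the same outputs yields an
#' identical document.
#'
#' @param dir Pipeline output directory.
#' @param file Output path; default `report.md` inside `dir`.
#' @return Invisibly, the report text (also written to `file`).
#' @export
render_report <- function(dir, file = file.path(dir, "report.md")) {
  if (!dir.exists(dir) || !length(list.files(dir))) {
    stop("no pipeline outputs found in ", dir, call. = FALSE)
  }
  fmt_table <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x)
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
    paste(c(header, sep, rows), collapse = "\n")
  }
  section <- function(title, path, prep = identity) {
    if (file.exists(file.path(dir, path))) {
      df <- utils::read.csv(file.path(dir, path), stringsAsFactors = FALSE)
      paste0("## ", title, "\n\n", fmt_table(prep(df)), "\n")
    } else {
      paste0("## ", title, "\n\nnot run\n")
    }
  }
  txt <- paste(
    "# Pipeline summary\n",
    section("Top association hits", "scan.csv", function(df) {
      utils::head(df[order(df$p),
                     c("protein", "hr", "ci_low", "ci_high", "p",
                       "fdr_q", "bonferroni_sig")], 10)
    }),
    section("Trajectory clusters", "trajectory_clusters.csv"),
    section("Four-way mediation components", "mediation.csv"),
    section("Risk model evaluation", "risk_eval.csv"),
    sep = "\n")
  writeLines(txt, file)
  invisible(txt)
}
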