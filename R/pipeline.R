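#' Pipeline configuration
#'
#' Collects input paths, the analysis thresholds (all defaulting to the
#' values the method prescribes: FC > 2 / FC < 0.5 DEG calling; |log2FC| > 1
#' and p < 0.01 for differential miRNAs; delta-beta > 0.15 at FDR < 0.05 for
#' DMPs; p < 0.05 univariate screen; consensus clustering up to k = 8),
#' clustering and split settings, and the seed.
#'
#' @param expression,roles,clinical,signatures Required input paths
#'   (expression TSV, sample-role TSV, clinical TSV, signatures GMT).
#' @param mirna,beta,mirna_targets,pathways Optional input paths; stages
#'   needing an absent input are skipped.
#' @param out_dir Output directory for artifacts.
#' @param pseudocount,fc_up,fc_down DEG-calling parameters.
#' @param transform Profile view used for clustering (`"neglog10"` or `"p"`).
#' @param k_min,k_max,n_resamples,item_fraction,select_threshold Consensus
#'   clustering settings.
#' @param de_min_log2fc,de_max_p Differential miRNA thresholds.
#' @param dmp_min_delta,dmp_max_q DMP thresholds.
#' @param screen_alpha Univariate Cox screen threshold.
#' @param panel_size miRNAs per subtype classifier panel.
#' @param train_fraction Training fraction for the risk model and the
#'   classifiers (test gets the remainder).
#' @param ntree Random-forest tree count.
#' @param seed Master seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, roles, clinical, signatures,
                            mirna = NULL, beta = NULL, mirna_targets = NULL,
                            pathways = NULL, out_dir = "tcd_run",
                            pseudocount = 0.01, fc_up = 2, fc_down = 0.5,
                            transform = c("neglog10", "p"),
                            k_min = 2, k_max = 8, n_resamples = 100,
                            item_fraction = 0.8, select_threshold = 0.1,
                            de_min_log2fc = 1, de_max_p = 0.01,
                            dmp_min_delta = 0.15, dmp_max_q = 0.05,
                            screen_alpha = 0.05, panel_size = 3,
                            train_fraction = 0.7, ntree = 500, seed = 1) {
  transform <- match.arg(transform)
  cfg <- as.list(environment())
  for (th in c("pseudocount", "fc_up", "fc_down", "de_min_log2fc", "de_max_p",
               "dmp_min_delta", "dmp_max_q", "screen_alpha"))
    if (!is.numeric(cfg[[th]]) || cfg[[th]] < 0)
      .stop_input("threshold '%s' must be a nonnegative number", th)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    .stop_input("train_fraction must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stop_input("file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown))
    .stop_input("unknown config key '%s'", unknown[1L])
  do.call(pipeline_config, raw)
}

.pipeline_stage <- function(report, name, fun) {
  out <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  report$stages <- c(report$stages, name)
  list(report = report, value = out)
}

#' Run the TCD analysis pipeline end to end
#'
#' Executes, in order: TCD profile construction, consensus subtyping with
#' delta-area k selection, severity ordering, signature scoring and group
#' summaries, differential miRNA selection (T-high and T-low one-vs-rest),
#' DMP detection per subtype (when beta values are supplied), anti-correlated
#' target selection (when a miRNA-target map is supplied), univariate Cox
#' screening of the selected miRNAs, multivariate Cox fitting on a training
#' split with held-out high/low risk stratification, subtype classifiers with
#' ROC/AUC evaluation, and survival comparisons. All artifacts are written as
#' TSV/JSON under `config$out_dir`; the run is a pure function of the config
#' (no timestamps), so reruns are byte-identical.
#'
#' @param config A [pipeline_config()] or a YAML/JSON config path.
#' @return The run report (invisibly also written as `run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) .stop_input("not a pipeline_config")
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("TCDtype")),
                 config = .config_echo(cfg), stages = character(0),
                 warnings = character(0), skipped = character(0))
  note_warn <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    # --- inputs ------------------------------------------------------------
    st <- .pipeline_stage(report, "read_inputs", function() {
      expr <- read_expression_table(cfg$expression)
      roles <- read_sample_roles(cfg$roles)
      clinical <- read_clinical(cfg$clinical)
      signatures <- read_gmt(cfg$signatures)
      mirna <- if (!is.null(cfg$mirna)) read_expression_table(cfg$mirna)
      beta <- if (!is.null(cfg$beta)) read_expression_table(cfg$beta)
      targets <- if (!is.null(cfg$mirna_targets))
        data.table::fread(cfg$mirna_targets, data.table = FALSE)
      pathways <- if (!is.null(cfg$pathways)) read_gmt(cfg$pathways)
      list(expr = expr, roles = roles, clinical = clinical,
           signatures = signatures, mirna = mirna, beta = beta,
           targets = targets, pathways = pathways)
    })
    report <- st$report; inp <- st$value
    normal_ids <- names(inp$roles)[inp$roles == "normal"]
    report$n_samples <- list(normal = length(normal_ids),
                             tumour = sum(inp$roles == "tumour"),
                             genes = nrow(inp$expr))

    # --- TCD profile -------------------------------------------------------
    st <- .pipeline_stage(report, "tcd_profile", function()
      build_tcd_profile(inp$expr, inp$signatures, normal_ids,
                        pseudocount = cfg$pseudocount,
                        up = cfg$fc_up, down = cfg$fc_down))
    report <- st$report; profile <- st$value
    write_expression_table(profile$p, file.path(cfg$out_dir, "tcd_profile_p.tsv"),
                           id_column = "state")
    report$universe_size <- profile$universe_size
    report$median_n_deg <- stats::median(profile$n_deg)

    # --- consensus subtypes ------------------------------------------------
    st <- .pipeline_stage(report, "consensus_subtypes", function()
      consensus_cluster(profile_matrix(profile, cfg$transform),
                        k_min = cfg$k_min, k_max = cfg$k_max,
                        n_resamples = cfg$n_resamples,
                        item_fraction = cfg$item_fraction,
                        seed = cfg$seed,
                        select_threshold = cfg$select_threshold))
    report <- st$report; cc <- st$value
    report$areas <- as.list(round(cc$areas, 6))
    report$delta_areas <- as.list(round(cc$delta_areas, 6))
    report$chosen_k <- cc$chosen_k

    st <- .pipeline_stage(report, "severity_ordering", function()
      order_subtypes(profile, cc$labels[[paste0("k", cc$chosen_k)]]))
    report <- st$report; assignment <- st$value
    subtype <- assignment$subtype
    report$subtype_sizes <- as.list(table(subtype))
    utils::write.table(
      data.frame(sample_id = names(subtype),
                 cluster = unname(assignment$cluster),
                 subtype = as.character(subtype)),
      file.path(cfg$out_dir, "subtypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    # --- survival across subtypes ------------------------------------------
    clin <- inp$clinical[match(names(subtype), inp$clinical$sample_id), ]
    st <- .pipeline_stage(report, "subtype_survival", function()
      logrank_test(clin$os_time, clin$os_event, subtype))
    report <- st$report
    report$subtype_logrank <- st$value

    # --- signature scores and summaries ------------------------------------
    st <- .pipeline_stage(report, "signature_scores", function() {
      tum <- names(subtype)
      sc <- signature_score(log2(inp$expr[, tum, drop = FALSE] + 1),
                            inp$signatures)
      gs <- group_summary(sc, subtype, stat = "mean", reference = "T-high")
      write_expression_table(sc, file.path(cfg$out_dir, "signature_scores.tsv"),
                             id_column = "signature")
      gs
    })
    report <- st$report
    report$score_group_means <- as.list(as.data.frame(t(st$value$summary)))

    # --- differential miRNAs ------------------------------------------------
    de_panels <- NULL
    if (!is.null(inp$mirna)) {
      st <- .pipeline_stage(report, "de_mirna", function() {
        tum <- names(subtype)
        panels <- list()
        for (target_subtype in c("T-high", "T-low")) {
          A <- tum[subtype == target_subtype]
          B <- setdiff(tum, A)
          de <- two_group_de(inp$mirna[, tum, drop = FALSE], A, B,
                             log_transform = TRUE)
          sel <- select_de_features(de, cfg$de_min_log2fc, cfg$de_max_p)
          sel <- sel[order(-abs(sel$log2FC)), ]
          panels[[target_subtype]] <- list(
            de = de, selected = sel$feature,
            panel = utils::head(sel$feature[sel$log2FC > 0], cfg$panel_size))
          utils::write.table(de, file.path(cfg$out_dir,
                                           sprintf("de_mirna_%s.tsv", gsub("-", "", target_subtype))),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        panels
      })
      report <- st$report; de_panels <- st$value
      report$de_mirnas <- list(
        `T-high` = de_panels$`T-high`$selected,
        `T-low` = de_panels$`T-low`$selected)
      report$mirna_panels <- list(`T-high` = de_panels$`T-high`$panel,
                                  `T-low` = de_panels$`T-low`$panel)
    } else report$skipped <- c(report$skipped, "de_mirna")

    # --- DMPs ---------------------------------------------------------------
    if (!is.null(inp$beta)) {
      st <- .pipeline_stage(report, "dmp", function() {
        tum <- names(subtype)
        all_dmps <- character(0)
        per <- list()
        for (s in levels(subtype)) {
          A <- tum[subtype == s]; B <- setdiff(tum, A)
          rec <- find_dmps(inp$beta[, tum, drop = FALSE], A, B,
                           cfg$dmp_min_delta, cfg$dmp_max_q)
          per[[s]] <- sum(rec$selected)
          all_dmps <- union(all_dmps, rec$feature[rec$selected])
          utils::write.table(rec, file.path(cfg$out_dir,
                                            sprintf("dmps_%s.tsv", gsub("-", "", s))),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
        list(per = per, union = all_dmps)
      })
      report <- st$report
      report$n_dmps <- list(per_subtype = st$value$per,
                            union = length(st$value$union))
    } else report$skipped <- c(report$skipped, "dmp")

    # --- anti-correlated targets -------------------------------------------
    if (!is.null(inp$targets) && !is.null(inp$mirna)) {
      st <- .pipeline_stage(report, "anticorrelated_targets", function() {
        tum <- names(subtype)
        out <- list()
        for (m in unique(inp$targets$mirna)) {
          cand <- intersect(inp$targets$gene[inp$targets$mirna == m],
                            rownames(inp$expr))
          if (!length(cand) || !m %in% rownames(inp$mirna)) next
          out[[m]] <- anticorrelated_targets(
            inp$mirna[m, tum], inp$expr[cand, tum, drop = FALSE], subtype)
        }
        out
      })
      report <- st$report
      report$anticorrelated_targets <- st$value
      if (!is.null(inp$pathways) && length(st$value)) {
        st <- .pipeline_stage(report, "target_overrepresentation", function() {
          hits <- unique(unlist(report$anticorrelated_targets))
          orr <- overrepresentation(hits, rownames(inp$expr), inp$pathways)
          utils::write.table(orr, file.path(cfg$out_dir, "target_pathways.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          orr
        })
        report <- st$report
      }
    } else report$skipped <- c(report$skipped, "anticorrelated_targets")

    # --- prognostic miRNA model --------------------------------------------
    if (!is.null(de_panels)) {
      st <- .pipeline_stage(report, "mirna_prognosis", function() {
        sel <- union(de_panels$`T-high`$selected, de_panels$`T-low`$selected)
        if (length(sel) < 1) return(NULL)
        tum <- names(subtype)
        feats <- log2(inp$mirna[sel, tum, drop = FALSE] + 1)
        surv <- clin[match(tum, clin$sample_id), ]
        screened <- univariate_screen(feats, surv, alpha = cfg$screen_alpha)
        if (length(screened) < 1) return(NULL)
        sp <- split_samples(tum,
                            c(train = cfg$train_fraction,
                              test = 1 - cfg$train_fraction),
                            labels = subtype, stratify = TRUE, seed = cfg$seed)
        Xall <- t(feats[screened, , drop = FALSE])
        train_rec <- cbind(surv[match(sp$train, surv$sample_id), ],
                           Xall[sp$train, , drop = FALSE])
        model <- cox_fit(train_rec, screened)
        test_rec <- surv[match(sp$test, surv$sample_id), ]
        val <- validate_model(model, test_rec, Xall[sp$test, , drop = FALSE])
        jsonlite::write_json(
          list(covariates = model$covariates, coef = model$coef,
               se = model$se, hr = model$hr, p = model$p,
               loglik = model$loglik, n = model$n, n_events = model$n_events),
          file.path(cfg$out_dir, "cox_model.json"),
          auto_unbox = TRUE, digits = NA)
        utils::write.table(val$stratification,
                           file.path(cfg$out_dir, "risk_groups_test.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        list(screened = screened, model = model, validation = val)
      })
      report <- st$report
      if (!is.null(st$value)) {
        report$screened_mirnas <- st$value$screened
        report$cox_coef <- as.list(st$value$model$coef)
        report$cox_hr <- as.list(st$value$model$hr)
        report$risk_logrank <- st$value$validation$logrank
      } else report$skipped <- c(report$skipped, "mirna_prognosis")
    } else report$skipped <- c(report$skipped, "mirna_prognosis")

    # --- subtype classifiers ------------------------------------------------
    if (!is.null(de_panels)) {
      st <- .pipeline_stage(report, "subtype_classifiers", function() {
        tum <- names(subtype)
        out <- list()
        for (target_subtype in c("T-high", "T-low")) {
          panel <- de_panels[[target_subtype]]$panel
          if (length(panel) < 1) next
          y <- stats::setNames(subtype == target_subtype, names(subtype))[tum]
          sp <- split_samples(tum,
                              c(train = cfg$train_fraction,
                                test = 1 - cfg$train_fraction),
                              labels = y, stratify = TRUE, seed = cfg$seed)
          feats <- t(log2(inp$mirna[panel, tum, drop = FALSE] + 1))
          clf <- train_subtype_classifier(feats[sp$train, , drop = FALSE],
                                          y[sp$train], positive = "TRUE",
                                          ntree = cfg$ntree, seed = cfg$seed)
          pr <- predict(clf, feats[sp$test, , drop = FALSE])
          ev <- roc_auc(pr, y[sp$test])
          utils::write.table(ev$roc,
                             file.path(cfg$out_dir,
                                       sprintf("roc_%s.tsv", gsub("-", "", target_subtype))),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          km_groups <- ifelse(pr >= 0.5, "predicted_positive", "predicted_negative")
          lr <- if (length(unique(km_groups)) == 2) {
            test_clin <- clin[match(sp$test, clin$sample_id), ]
            logrank_test(test_clin$os_time, test_clin$os_event, km_groups)
          }
          out[[target_subtype]] <- list(panel = panel, auc = ev$auc,
                                        logrank = lr)
        }
        out
      })
      report <- st$report
      report$classifier_auc <- lapply(st$value, function(z) z$auc)
    } else report$skipped <- c(report$skipped, "subtype_classifiers")
  }, warning = note_warn)

  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(structure(report, class = "tcd_run_report"))
}

.config_echo <- function(cfg) {
  out <- unclass(cfg)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.tcd_run_report <- function(x, ...) {
  cat("TCD pipeline run\n")
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = ", ")))
  if (length(x$skipped)) cat(sprintf("  skipped: %s\n", paste(x$skipped, collapse = ", ")))
  cat(sprintf("  chosen k: %s; subtype sizes: %s\n", x$chosen_k,
              paste(sprintf("%s=%s", names(x$subtype_sizes), unlist(x$subtype_sizes)),
                    collapse = ", ")))
  invisible(x)
}
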