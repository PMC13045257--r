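#' Configuration for the synthetic TCD cohort generator
#'
#' Defines the statistical structure of a generated cohort: log-normal
#' FPKM-like expression with subtype-dependent shifts planted on the four TCD
#' signature gene sets, monotone miRNA effects across severity, logit-normal
#' methylation beta values decreasing with severity, and exponential survival
#' with a severity-dependent hazard under independent uniform censoring.
#'
#' Severity is indexed 0..(n_subtypes-1); subtype s shifts the log2 mean of
#' every signature gene by `severity_effects[s]`, which must be strictly
#' increasing. `mirna_effects` is an `n_mirnas x n_subtypes` matrix of log2
#' shifts; the default plants six informative miRNAs among nulls: three
#' rising with severity (the "T-high panel") and three falling (the "T-low
#' panel"), in steps of 0.75 log2 per severity grade. A block of
#' `n_dmp_probes` methylation probes loses `beta_trend` logit units of mean
#' per severity grade; `n_target_genes` non-signature genes fall by
#' `target_trend` log2 per grade, providing planted anti-correlated miRNA
#' targets.
#'
#' @param n_subtypes Number of tumour subtypes (severity grades).
#' @param samples_per_subtype Integer vector of tumour sample counts, recycled
#'   to `n_subtypes`.
#' @param n_normal Number of normal reference samples.
#' @param n_genes Total genes in the expression matrix.
#' @param signature_sizes Sizes of the four TCD signatures
#'   (exhaustion, senescence, exclusion, dysfunction).
#' @param severity_effects Per-subtype log2 shift of signature genes, strictly
#'   increasing with severity.
#' @param n_mirnas Number of miRNAs.
#' @param mirna_effects `n_mirnas x n_subtypes` log2 shift matrix, or `NULL`
#'   for the default 6-informative-miRNA layout.
#' @param n_probes Number of methylation probes.
#' @param n_dmp_probes Number of probes carrying the methylation trend.
#' @param beta_trend Logit-scale mean decrement per severity grade for the
#'   trending probes.
#' @param n_target_genes Number of planted anti-regulated miRNA target genes.
#' @param target_trend Log2 decrement per severity grade for target genes.
#' @param surv_base_hazard Baseline exponential event rate (1/time unit).
#' @param surv_log_hr_per_severity Log hazard ratio per severity grade.
#' @param censor_fraction Expected censored fraction, in `[0, 1)`.
#' @param noise_sd Log2-scale (and logit-scale) standard deviation of the
#'   per-cell noise.
#' @param base_log2_mean Log2 mean of the normal expression distribution.
#' @param base_logit_beta Logit-scale mean of the non-trending beta probes.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subtypes = 4,
                          samples_per_subtype = 50,
                          n_normal = 50,
                          n_genes = 2000,
                          signature_sizes = c(26, 25, 292, 90),
                          severity_effects = c(0, 0.5, 1, 2),
                          n_mirnas = 50,
                          mirna_effects = NULL,
                          n_probes = 200,
                          n_dmp_probes = 40,
                          beta_trend = 0.5,
                          n_target_genes = 10,
                          target_trend = 0.75,
                          surv_base_hazard = 0.1,
                          surv_log_hr_per_severity = 1.0,
                          censor_fraction = 0.3,
                          noise_sd = 0.5,
                          base_log2_mean = 5,
                          base_logit_beta = 1,
                          seed = 1) {
  cfg <- list(
    n_subtypes = n_subtypes,
    samples_per_subtype = rep_len(samples_per_subtype, n_subtypes),
    n_normal = n_normal, n_genes = n_genes,
    signature_sizes = signature_sizes,
    severity_effects = severity_effects,
    n_mirnas = n_mirnas, mirna_effects = mirna_effects,
    n_probes = n_probes, n_dmp_probes = n_dmp_probes,
    beta_trend = beta_trend,
    n_target_genes = n_target_genes, target_trend = target_trend,
    surv_base_hazard = surv_base_hazard,
    surv_log_hr_per_severity = surv_log_hr_per_severity,
    censor_fraction = censor_fraction,
    noise_sd = noise_sd,
    base_log2_mean = base_log2_mean,
    base_logit_beta = base_logit_beta,
    seed = seed
  )
  .validate_cohort_config(cfg)
  if (is.null(cfg$mirna_effects))
    cfg$mirna_effects <- .default_mirna_effects(cfg$n_mirnas, cfg$n_subtypes)
  if (!is.matrix(cfg$mirna_effects) ||
      nrow(cfg$mirna_effects) != cfg$n_mirnas ||
      ncol(cfg$mirna_effects) != cfg$n_subtypes)
    .stop_input("configuration error in 'mirna_effects': must be an %d x %d matrix",
                cfg$n_mirnas, cfg$n_subtypes)
  structure(cfg, class = "cohort_config")
}

.validate_cohort_config <- function(cfg) {
  chk <- function(ok, field) if (!ok)
    .stop_input("configuration error in '%s'", field)
  chk(.is_count(cfg$n_subtypes) && cfg$n_subtypes >= 1, "n_subtypes")
  chk(.is_count(cfg$samples_per_subtype), "samples_per_subtype")
  chk(.is_count(cfg$n_normal), "n_normal")
  chk(.is_count(cfg$n_genes), "n_genes")
  chk(.is_count(cfg$signature_sizes) && length(cfg$signature_sizes) == 4,
      "signature_sizes")
  chk(cfg$n_genes >= sum(cfg$signature_sizes) + cfg$n_target_genes, "n_genes")
  chk(is.numeric(cfg$severity_effects) &&
        length(cfg$severity_effects) == cfg$n_subtypes &&
        (cfg$n_subtypes == 1 || all(diff(cfg$severity_effects) > 0) ||
           all(cfg$severity_effects == 0)),
      "severity_effects")
  chk(.is_count(cfg$n_mirnas), "n_mirnas")
  chk(.is_count(cfg$n_probes), "n_probes")
  chk(is.numeric(cfg$n_dmp_probes) && cfg$n_dmp_probes >= 0 &&
        cfg$n_dmp_probes <= cfg$n_probes, "n_dmp_probes")
  chk(is.numeric(cfg$beta_trend) && is.finite(cfg$beta_trend), "beta_trend")
  chk(is.numeric(cfg$n_target_genes) && cfg$n_target_genes >= 0, "n_target_genes")
  chk(is.numeric(cfg$surv_base_hazard) && cfg$surv_base_hazard > 0,
      "surv_base_hazard")
  chk(is.numeric(cfg$surv_log_hr_per_severity) &&
        is.finite(cfg$surv_log_hr_per_severity), "surv_log_hr_per_severity")
  chk(is.numeric(cfg$censor_fraction) && cfg$censor_fraction >= 0 &&
        cfg$censor_fraction < 1, "censor_fraction")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd > 0, "noise_sd")
  chk(.is_count(abs(cfg$seed) + 1), "seed")
  invisible(cfg)
}

.default_mirna_effects <- function(n_mirnas, n_subtypes) {
  eff <- matrix(0, n_mirnas, n_subtypes)
  grades <- seq_len(n_subtypes) - 1
  up <- seq_len(min(3, n_mirnas))
  dn <- setdiff(seq_len(min(6, n_mirnas)), up)
  eff[up, ] <- matrix(0.75 * grades, length(up), n_subtypes, byrow = TRUE)
  eff[dn, ] <- matrix(0.75 * rev(grades), length(dn), n_subtypes, byrow = TRUE)
  eff
}

#' Generate a synthetic TCD cohort with known ground truth
#'
#' Draws all pipeline inputs (expression, miRNA, beta values, clinical table,
#' signature collection) from the model described in [cohort_config()], and
#' records the planted truth (per-sample subtype, effect sizes, informative
#' feature ids). One random stream is seeded once from `config$seed`;
#' sub-generators use child seeds drawn deterministically from it.
#'
#' @param config A [cohort_config()].
#' @return An object of class `tcd_cohort`: list with `expression`, `mirna`,
#'   `beta` (matrices), `sample_role` (named "normal"/"tumour"), `clinical`
#'   (data.frame: sample_id, os_time, os_event, age, group), `signatures`
#'   (named list), `mirna_targets` (data.frame mirna/gene candidate map) and
#'   `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  cfg <- config
  set.seed(cfg$seed)
  child <- sample.int(.Machine$integer.max - 1L, 4L)

  n_tum <- sum(cfg$samples_per_subtype)
  subtype <- rep(seq_len(cfg$n_subtypes), times = cfg$samples_per_subtype)
  tum_ids <- sprintf("T%04d", seq_len(n_tum))
  nor_ids <- sprintf("N%04d", seq_len(cfg$n_normal))
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))

  sizes <- cfg$signature_sizes
  sig_names <- c("exhaustion", "senescence", "exclusion", "dysfunction")
  sig_idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), times = sizes))
  signatures <- lapply(sig_idx, function(i) gene_ids[i])
  names(signatures) <- sig_names
  tgt_idx <- if (cfg$n_target_genes > 0)
    sum(sizes) + seq_len(cfg$n_target_genes) else integer(0)
  target_genes <- gene_ids[tgt_idx]

  # expression: log-normal on log2 scale, planted subtype shifts
  set.seed(child[1L])
  mu <- cfg$base_log2_mean
  normal <- matrix(stats::rnorm(cfg$n_genes * cfg$n_normal, mu, cfg$noise_sd),
                   cfg$n_genes, dimnames = list(gene_ids, nor_ids))
  tum_l2 <- matrix(stats::rnorm(cfg$n_genes * n_tum, mu, cfg$noise_sd),
                   cfg$n_genes, dimnames = list(gene_ids, tum_ids))
  all_sig <- unlist(sig_idx, use.names = FALSE)
  shift <- cfg$severity_effects[subtype]
  tum_l2[all_sig, ] <- tum_l2[all_sig, ] +
    matrix(shift, length(all_sig), n_tum, byrow = TRUE)
  if (length(tgt_idx)) {
    tshift <- -cfg$target_trend * (subtype - 1)
    tum_l2[tgt_idx, ] <- tum_l2[tgt_idx, ] +
      matrix(tshift, length(tgt_idx), n_tum, byrow = TRUE)
  }
  expression <- cbind(2^tum_l2, 2^normal)

  # miRNA: same log-normal model with the planted effect matrix
  set.seed(child[2L])
  mir_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  mir_l2 <- matrix(stats::rnorm(cfg$n_mirnas * n_tum, mu, cfg$noise_sd),
                   cfg$n_mirnas, dimnames = list(mir_ids, tum_ids))
  mir_l2 <- mir_l2 + cfg$mirna_effects[, subtype, drop = FALSE]
  mirna <- 2^mir_l2

  # methylation: logit-normal, trending block decreasing with severity
  set.seed(child[3L])
  probe_ids <- sprintf("cg%05d", seq_len(cfg$n_probes))
  logit <- matrix(stats::rnorm(cfg$n_probes * n_tum, cfg$base_logit_beta,
                               cfg$noise_sd),
                  cfg$n_probes, dimnames = list(probe_ids, tum_ids))
  dmp_idx <- seq_len(cfg$n_dmp_probes)
  if (length(dmp_idx))
    logit[dmp_idx, ] <- logit[dmp_idx, ] -
      matrix(cfg$beta_trend * (subtype - 1), length(dmp_idx), n_tum, byrow = TRUE)
  beta <- stats::plogis(logit)

  # survival + clinical covariates
  set.seed(child[4L])
  clinical <- generate_survival(subtype, cfg, sample_ids = tum_ids)
  clinical$age <- round(stats::rnorm(n_tum, 60, 10), 1)

  sample_role <- c(stats::setNames(rep("tumour", n_tum), tum_ids),
                   stats::setNames(rep("normal", cfg$n_normal), nor_ids))

  up_panel <- mir_ids[which(cfg$mirna_effects[, cfg$n_subtypes] -
                              rowMeans(cfg$mirna_effects) > 0)]
  dn_panel <- mir_ids[which(cfg$mirna_effects[, 1L] -
                              rowMeans(cfg$mirna_effects) > 0)]
  mirna_targets <- if (length(target_genes) && length(up_panel))
    data.frame(mirna = up_panel[1L],
               gene = c(target_genes,
                        signatures$exclusion[seq_len(min(20, sizes[3L]))]),
               stringsAsFactors = FALSE)
  else data.frame(mirna = character(0), gene = character(0))

  structure(list(
    expression = expression,
    mirna = mirna,
    beta = beta,
    sample_role = sample_role,
    clinical = clinical,
    signatures = signatures,
    mirna_targets = mirna_targets,
    truth = list(
      subtype = stats::setNames(subtype, tum_ids),
      severity_effects = cfg$severity_effects,
      mirna_effects = cfg$mirna_effects,
      informative_mirnas = mir_ids[rowSums(abs(cfg$mirna_effects)) > 0],
      up_panel = up_panel, down_panel = dn_panel,
      dmp_probes = probe_ids[dmp_idx],
      target_genes = target_genes,
      config = cfg
    )
  ), class = "tcd_cohort")
}

#' Generate exponential survival with a severity-dependent hazard
#'
#' Event times are exponential with rate
#' `surv_base_hazard * exp((severity - 1) * surv_log_hr_per_severity)`.
#' Censoring is by an independent uniform time whose upper bound is calibrated
#' per subject so that the expected censored fraction equals
#' `censor_fraction` exactly.
#'
#' @param severity_labels Integer vector of severity grades (1-based).
#' @param config A [cohort_config()] (only the survival fields are used).
#' @param sample_ids Optional sample ids for the output table.
#' @return A data.frame: `sample_id`, `os_time`, `os_event`, `group`.
#' @export
generate_survival <- function(severity_labels, config, sample_ids = NULL) {
  if (!length(severity_labels)) .stop_input("severity labels must be nonempty")
  cfg <- config
  if (!is.numeric(cfg$surv_base_hazard) || cfg$surv_base_hazard <= 0)
    .stop_input("configuration error in 'surv_base_hazard': must be positive")
  n <- length(severity_labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  lambda <- cfg$surv_base_hazard *
    exp((severity_labels - 1) * cfg$surv_log_hr_per_severity)
  t_event <- stats::rexp(n, rate = lambda)
  f <- cfg$censor_fraction
  if (f > 0) {
    # solve (1 - exp(-a))/a = f for the dimensionless bound a = lambda * u
    a <- stats::uniroot(function(a) (1 - exp(-a)) / a - f,
                        lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    t_cens <- stats::runif(n, 0, a / lambda)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  data.frame(sample_id = sample_ids, os_time = time, os_event = event,
             group = severity_labels, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to the standard pipeline input files
#'
#' Emits `expression.tsv`, `mirna.tsv`, `beta.tsv` (features x samples TSV),
#' `clinical.tsv`, `sample_roles.tsv`, `signatures.gmt`, `mirna_targets.tsv`
#' and `truth.json` under `dir`.
#'
#' @param cohort A `tcd_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named list of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "tcd_cohort")) .stop_input("not a tcd_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    mirna = file.path(dir, "mirna.tsv"),
    beta = file.path(dir, "beta.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    roles = file.path(dir, "sample_roles.tsv"),
    signatures = file.path(dir, "signatures.gmt"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_table(cohort$expression, paths$expression)
  write_expression_table(cohort$mirna, paths$mirna)
  write_expression_table(cohort$beta, paths$beta)
  utils::write.table(cohort$clinical, paths$clinical, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$sample_role),
               role = unname(cohort$sample_role)),
    paths$roles, sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(cohort$signatures, paths$signatures)
  utils::write.table(cohort$mirna_targets, paths$mirna_targets, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @export
print.tcd_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic TCD cohort: %d tumour + %d normal samples, %d genes\n",
              sum(cfg$samples_per_subtype), cfg$n_normal, cfg$n_genes))
  cat(sprintf("  %d miRNAs, %d beta probes; severity effects: %s (log2)\n",
              cfg$n_mirnas, cfg$n_probes,
              paste(cfg$severity_effects, collapse = "/")))
  invisible(x)
}
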