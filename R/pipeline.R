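# Bidirectional pipeline: run configuration, the instrument-selection policy
# (with the relaxed-threshold fallback), and the two-direction orchestrator.

#' Build a run configuration
#'
#' All thresholds default to the values used for the bidirectional brain-IDP
#' / neurodegenerative-disease analysis: instrument p < 5e-8 (relaxed to
#' 5e-6 with per-SNP F > 10 when fewer than 4 instruments survive), clumping
#' at r^2 < 0.001 within 10,000 kb, confounder/outcome association removal
#' at p < 5e-8, palindrome MAF window 0.08, weak-instrument bound F >= 10,
#' study-wide Bonferroni level 0.05 / (M_eff * n_diseases * 2 directions)
#' and nominal level 1e-4.
#'
#' @param exposure_files,outcome_files named character vectors of
#'   summary-statistic file paths (names are trait labels). `outcome_files`
#'   lists the disease traits; `n_diseases` defaults to its length.
#' @param outcome_binary named logical vector (or single value) saying which
#'   outcome traits are binary.
#' @param outcome_cases,outcome_totals named numeric vectors of case counts
#'   and GWAS sizes for binary outcome traits (used for power).
#' @param ld_file LD matrix path (square or long dialect).
#' @param confounder_file confounder catalog path (optional).
#' @param corr_file phenotype correlation matrix path, or `m_eff` to supply
#'   the effective test count directly.
#' @param m_eff effective number of tests (overrides `corr_file`).
#' @param iv_p,relaxed_p,strict_p instrument significance thresholds.
#' @param clump_r2,clump_kb clumping parameters.
#' @param catalog_p confounder/outcome association removal threshold.
#' @param f_min weak-instrument bound.
#' @param min_k instrument count below which the relaxed threshold applies.
#' @param palindrome_window palindromic-SNP MAF window.
#' @param mhc_exclude,mhc_chrom,mhc_start,mhc_end MHC-region exclusion.
#' @param n_diseases,n_directions,base_alpha,nominal_alpha correction inputs.
#' @param standardize standardize effect sizes before selection.
#' @param wm_boot,presso_nsim,seed randomized-procedure controls.
#' @param out_dir output directory for [run_bidirectional()].
#' @return object of class `mr_config` (list).
#' @export
mr_config <- function(exposure_files = character(0),
                      outcome_files = character(0),
                      outcome_binary = TRUE,
                      outcome_cases = numeric(0), outcome_totals = numeric(0),
                      ld_file = NULL, confounder_file = NULL,
                      corr_file = NULL, m_eff = NULL,
                      iv_p = 5e-8, relaxed_p = 5e-6, strict_p = 5e-9,
                      clump_r2 = 0.001, clump_kb = 10000,
                      catalog_p = 5e-8, f_min = 10, min_k = 4,
                      palindrome_window = 0.08,
                      mhc_exclude = FALSE, mhc_chrom = "6",
                      mhc_start = 28477797, mhc_end = 33448354,
                      n_diseases = max(length(outcome_files), 1L),
                      n_directions = 2, base_alpha = 0.05,
                      nominal_alpha = 1e-4, standardize = TRUE,
                      wm_boot = 1000, presso_nsim = 1000, seed = 1,
                      out_dir = "results/mr_run") {
  cfg <- as.list(environment())
  validate_config(cfg)
  class(cfg) <- "mr_config"
  cfg
}

validate_config <- function(cfg) {
  in_unit <- function(x) is.numeric(x) && x > 0 && x <= 1
  for (p in c("iv_p", "relaxed_p", "strict_p", "catalog_p", "base_alpha",
              "nominal_alpha")) {
    if (!in_unit(cfg[[p]])) bimr_stop("config_error", "%s must be in (0, 1]", p)
  }
  if (cfg$clump_r2 < 0 || cfg$clump_r2 > 1) bimr_stop("config_error", "clump_r2 must be in [0, 1]")
  if (cfg$clump_kb <= 0) bimr_stop("config_error", "clump_kb must be positive")
  if (cfg$palindrome_window < 0 || cfg$palindrome_window >= 0.5) {
    bimr_stop("config_error", "palindrome_window must be in [0, 0.5)")
  }
  if (cfg$f_min < 0 || cfg$min_k < 1) bimr_stop("config_error", "f_min/min_k out of range")
  if (cfg$n_directions < 1 || cfg$n_diseases < 1) {
    bimr_stop("config_error", "n_diseases and n_directions must be >= 1")
  }
  invisible(TRUE)
}

#' Write / read a run configuration (YAML)
#'
#' Configurations round-trip through serialization unchanged.
#'
#' @param config an [mr_config()].
#' @param path file path.
#' @return `write_config`: `path` invisibly; `read_config`: an `mr_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mr_config"))
  lst <- unclass(config)
  # yaml drops names of atomic vectors; store the named fields as maps
  for (f in c("exposure_files", "outcome_files", "outcome_cases",
              "outcome_totals")) {
    lst[[f]] <- as.list(lst[[f]])
  }
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  # yaml deserializes named vectors as lists; restore the vector types
  for (f in c("exposure_files", "outcome_files")) {
    if (!is.null(lst[[f]])) lst[[f]] <- unlist(lst[[f]])
    else lst[[f]] <- character(0)
  }
  for (f in c("outcome_cases", "outcome_totals")) {
    if (!is.null(lst[[f]])) lst[[f]] <- unlist(lst[[f]]) else lst[[f]] <- numeric(0)
  }
  if (!is.null(lst$outcome_binary)) lst$outcome_binary <- unlist(lst$outcome_binary)
  cfg <- do.call(mr_config, lst[setdiff(names(lst), "n_diseases")])
  cfg$n_diseases <- lst$n_diseases
  validate_config(cfg)
  cfg
}

#' Select instrumental variables for one exposure/outcome pair
#'
#' Applies the full selection policy: significance filter at `iv_p`, greedy
#' LD clumping, confounder-catalog exclusion, outcome-associated SNP
#' exclusion (outcome p < `catalog_p`), optional MHC exclusion, and the
#' per-SNP weak-instrument filter (F >= `f_min`). If fewer than `min_k`
#' instruments survive, selection reruns once from the significance filter
#' at `relaxed_p`, still keeping only per-SNP F >= `f_min`.
#'
#' @param exposure,outcome [gwas_table()]s (exposure supplies instruments;
#'   outcome supplies the outcome-association exclusion p-values).
#' @param ld an [ld_matrix()].
#' @param catalog a [confounder_catalog()] or `NULL`.
#' @param config an [mr_config()].
#' @param p_threshold override for the primary significance threshold
#'   (e.g. the strict 5e-9 sensitivity setting).
#' @return list with `instruments` (a `gwas_table`), `stats`
#'   ([instrument_strength()] or `NULL` if empty), `relaxed` (logical),
#'   `drops` (combined drop log).
#' @export
select_instruments <- function(exposure, outcome, ld, catalog, config,
                               p_threshold = config$iv_p) {
  run_once <- function(p_thr) {
    tab <- filter_significant(exposure, p_thr)
    tab <- clump(tab, ld, config$clump_r2, config$clump_kb)
    if (!is.null(catalog)) tab <- exclude_by_catalog(tab, catalog, config$catalog_p)
    # outcome-associated SNP removal via the same catalog mechanism
    out_hits <- outcome[outcome$pval < config$catalog_p &
                          outcome$snp_id %in% tab$snp_id, , drop = FALSE]
    if (nrow(out_hits)) {
      out_cat <- confounder_catalog(data.frame(
        snp_id = out_hits$snp_id,
        trait = attr(outcome, "trait_name"),
        pval = out_hits$pval, stringsAsFactors = FALSE))
      tab <- exclude_by_catalog(tab, out_cat, config$catalog_p)
    }
    if (isTRUE(config$mhc_exclude)) {
      tab <- exclude_region(tab, config$mhc_chrom, config$mhc_start, config$mhc_end)
    }
    if (nrow(tab) > 0) {
      st <- instrument_strength(tab)
      weak <- st$per_snp_f < config$f_min
      if (any(weak)) {
        keep <- !weak
        tab2 <- tab[keep, , drop = FALSE]
        rownames(tab2) <- NULL
        tab2 <- keep_gwas_attrs(tab2, tab)
        attr(tab2, "drops") <- attr(tab, "drops")
        tab <- add_drops(tab2, tab$snp_id[weak], "weak_instrument",
                         sprintf("F=%.2f", st$per_snp_f[weak]))
      }
    }
    tab
  }
  instruments <- run_once(p_threshold)
  relaxed <- FALSE
  if (nrow(instruments) < config$min_k && config$relaxed_p > p_threshold) {
    instruments <- run_once(config$relaxed_p)
    relaxed <- TRUE
  }
  stats <- if (nrow(instruments) >= 1) instrument_strength(instruments) else NULL
  list(instruments = instruments, stats = stats, relaxed = relaxed,
       drops = drop_log(instruments))
}

classify_hit <- function(pval, thresholds) {
  if (!is.finite(pval)) return("none")
  if (pval < thresholds$bonferroni_p) return("significant")
  if (pval < thresholds$nominal_p) return("nominal")
  "none"
}

run_pair <- function(exposure, outcome, ld, catalog, config, thresholds,
                     direction, pair_seed) {
  if (isTRUE(config$standardize)) {
    exposure <- standardize_effects(exposure)
    outcome <- standardize_effects(outcome)
  }
  sel <- select_instruments(exposure, outcome, ld, catalog, config)
  if (nrow(sel$instruments) == 0) {
    bimr_stop("input_error", "no instruments for %s -> %s",
              attr(exposure, "trait_name"), attr(outcome, "trait_name"))
  }
  exp_sel <- exposure[exposure$snp_id %in% sel$instruments$snp_id, , drop = FALSE]
  exp_sel <- keep_gwas_attrs(exp_sel, exposure)
  hs <- harmonize(exp_sel, outcome, config$palindrome_window)

  all_res <- mr_run_all(hs, n_boot = config$wm_boot, seed = pair_seed)
  primary <- if (!is.null(all_res$results$ivw)) all_res$results$ivw
             else all_res$results$wald_ratio
  class_label <- classify_hit(primary$pval, thresholds)

  res_rows <- do.call(rbind, lapply(all_res$results, as.data.frame))
  res_rows <- data.frame(direction = direction,
                         exposure = attr(hs, "exposure"),
                         outcome = attr(hs, "outcome"),
                         res_rows,
                         relaxed_selection = sel$relaxed,
                         r2_total = sel$stats$r2_total,
                         f_stat = sel$stats$f_stat,
                         classification = class_label,
                         stringsAsFactors = FALSE)

  sens_rows <- NULL
  power <- NA_real_
  if (class_label != "none") {
    srep <- run_sensitivity(hs, n_sim = config$presso_nsim,
                            seed = child_seed(pair_seed, 1L),
                            sig_level = thresholds$nominal_p)
    sens_rows <- sensitivity_long(srep, attr(hs, "exposure"), attr(hs, "outcome"))
    sens_rows <- data.frame(direction = direction, sens_rows,
                            stringsAsFactors = FALSE)
    binary <- isTRUE(attr(hs, "outcome_binary"))
    cr <- if (binary && !is.null(attr(hs, "n_cases_out"))) {
      attr(hs, "n_cases_out") / attr(hs, "n_out")
    } else NULL
    power <- mr_power(attr(hs, "n_out"), sel$stats$r2_total,
                      primary$estimate, case_ratio = cr,
                      alpha = thresholds$bonferroni_p)
  }
  res_rows$power <- ifelse(res_rows$method %in% c("ivw", "wald_ratio"),
                           power, NA_real_)

  drops <- rbind(
    data.frame(stage = "selection", drop_log(sel$instruments),
               stringsAsFactors = FALSE),
    data.frame(stage = "harmonization", drop_log(hs), stringsAsFactors = FALSE))
  # bulk reasons (every sub-threshold or non-overlapping SNP) are aggregated
  # to counts; per-SNP rows are kept for the decisions that need auditing
  bulk <- drops$reason %in% c("above_p_threshold", "absent_in_exposure",
                              "absent_in_outcome")
  if (any(bulk)) {
    agg <- stats::aggregate(list(n = drops$snp_id[bulk]),
                            by = list(stage = drops$stage[bulk],
                                      reason = drops$reason[bulk]),
                            FUN = length)
    drops <- rbind(drops[!bulk, ],
                   data.frame(stage = agg$stage, snp_id = "(aggregated)",
                              reason = agg$reason,
                              detail = sprintf("n=%d", agg$n),
                              stringsAsFactors = FALSE))
  }
  drops <- data.frame(direction = direction,
                      exposure = attr(hs, "exposure"),
                      outcome = attr(hs, "outcome"),
                      drops, stringsAsFactors = FALSE)
  list(results = res_rows, sensitivity = sens_rows, drops = drops,
       failures = all_res$failures)
}

#' Run the bidirectional two-sample MR analysis
#'
#' For every (exposure, outcome) pair in both directions — forward with the
#' exposure set as exposures, reverse with the outcome set as exposures —
#' selects instruments (with the relaxed-threshold fallback), harmonizes,
#' runs the estimator battery, classifies the primary (IVW, or Wald ratio
#' when k = 1) p-value against the corrected and nominal thresholds, runs
#' the sensitivity battery and computes power for every hit. A failing pair
#' is recorded and skipped; the run continues. Writes `results.tsv`,
#' `sensitivity.tsv`, `drops.tsv`, `failures.tsv` and `config_echo.yaml`
#' under `config$out_dir`. Reruns with an identical configuration produce
#' byte-identical outputs.
#'
#' @param config an [mr_config()]; file fields must point to readable files.
#' @param exposures,outcomes optional named lists of in-memory
#'   [gwas_table()]s overriding the file lists.
#' @param ld,catalog optional in-memory [ld_matrix()] /
#'   [confounder_catalog()] overrides.
#' @return list with `results`, `sensitivity`, `drops`, `failures`
#'   data.frames and `thresholds`; written to disk as a side effect.
#' @export
run_bidirectional <- function(config, exposures = NULL, outcomes = NULL,
                              ld = NULL, catalog = NULL) {
  stopifnot(inherits(config, "mr_config"))
  if (is.null(exposures)) {
    exposures <- lapply(seq_along(config$exposure_files), function(i) {
      read_sumstats(config$exposure_files[[i]],
                    trait_name = names(config$exposure_files)[i])
    })
    names(exposures) <- names(config$exposure_files)
  }
  if (is.null(outcomes)) {
    binary <- rep_len(config$outcome_binary, length(config$outcome_files))
    outcomes <- lapply(seq_along(config$outcome_files), function(i) {
      nm <- names(config$outcome_files)[i]
      ncase <- if (nm %in% names(config$outcome_cases)) config$outcome_cases[[nm]] else NULL
      ntot <- if (nm %in% names(config$outcome_totals)) config$outcome_totals[[nm]] else NULL
      read_sumstats(config$outcome_files[[i]], trait_name = nm,
                    is_binary = binary[i], n_cases = ncase,
                    n_controls = if (!is.null(ncase) && !is.null(ntot)) ntot - ncase else NULL)
    })
    names(outcomes) <- names(config$outcome_files)
  }
  if (is.null(ld) && !is.null(config$ld_file)) ld <- read_ld_matrix(config$ld_file)
  if (is.null(catalog) && !is.null(config$confounder_file)) {
    catalog <- read_catalog(config$confounder_file)
  }
  m_eff <- config$m_eff
  if (is.null(m_eff)) {
    if (is.null(config$corr_file)) {
      bimr_stop("config_error", "either m_eff or corr_file must be supplied")
    }
    corr <- as.matrix(utils::read.table(config$corr_file, header = TRUE,
                                        row.names = 1, sep = "\t",
                                        check.names = FALSE))
    m_eff <- matspd_meff(corr)$m_eff
  }
  thresholds <- corrected_thresholds(m_eff, config$n_diseases,
                                     config$n_directions, config$base_alpha,
                                     config$nominal_alpha)

  # deterministic pair ordering and seeds, invariant to input list order
  pairs <- rbind(
    expand.grid(exp = sort(names(exposures)), out = sort(names(outcomes)),
                direction = "forward", stringsAsFactors = FALSE),
    expand.grid(exp = sort(names(outcomes)), out = sort(names(exposures)),
                direction = "reverse", stringsAsFactors = FALSE))

  results <- list(); sens <- list(); drops <- list(); fails <- list()
  for (i in seq_len(nrow(pairs))) {
    direction <- pairs$direction[i]
    exp_tbl <- if (direction == "forward") exposures[[pairs$exp[i]]] else outcomes[[pairs$exp[i]]]
    out_tbl <- if (direction == "forward") outcomes[[pairs$out[i]]] else exposures[[pairs$out[i]]]
    pair_seed <- child_seed(config$seed, i)
    r <- tryCatch(
      run_pair(exp_tbl, out_tbl, ld, catalog, config, thresholds,
               direction, pair_seed),
      error = function(e) e)
    if (inherits(r, "error")) {
      fails[[i]] <- data.frame(direction = direction,
                               exposure = attr(exp_tbl, "trait_name"),
                               outcome = attr(out_tbl, "trait_name"),
                               error = conditionMessage(r),
                               stringsAsFactors = FALSE)
    } else {
      results[[i]] <- r$results
      sens[[i]] <- r$sensitivity
      drops[[i]] <- r$drops
      if (length(r$failures)) {
        fails[[i]] <- data.frame(direction = direction,
                                 exposure = attr(exp_tbl, "trait_name"),
                                 outcome = attr(out_tbl, "trait_name"),
                                 error = sprintf("%s: %s", names(r$failures),
                                                 r$failures),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  bundle <- list(
    results = do.call(rbind, results[!vapply(results, is.null, TRUE)]),
    sensitivity = do.call(rbind, sens[!vapply(sens, is.null, TRUE)]),
    drops = do.call(rbind, drops[!vapply(drops, is.null, TRUE)]),
    failures = do.call(rbind, fails[!vapply(fails, is.null, TRUE)]),
    thresholds = thresholds)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name) {
    if (is.null(df)) df <- data.frame()
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                       file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv(bundle$results, "results.tsv")
  write_tsv(bundle$sensitivity, "sensitivity.tsv")
  write_tsv(bundle$drops, "drops.tsv")
  write_tsv(bundle$failures, "failures.tsv")
  write_config(config, file.path(config$out_dir, "config_echo.yaml"))
  bundle
}
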