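#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. `cohort` is either a
#' [cohort_config()] (the cohort is simulated) or a directory written by
#' [write_cohort()] (recordings are read).
#'
#' @param cohort A `cohort_config` or an input directory path.
#' @param band Spectral analysis band (Hz) inside (0, 500].
#' @param n_keep Movement cycles retained per recording.
#' @param psd_mode `"welch"` or `"single512"`.
#' @param mdf_mode `"interp"` or `"bin"`.
#' @param pca_normalize Unit-area normalize profiles before PCA.
#' @param pca_k_max,pca_min_prop Component retention rule.
#' @param t_variant `"student"` (pooled) or `"welch"`.
#' @param holm Apply Holm correction to the per-muscle group t-tests.
#' @param out_dir Output directory (default: a fresh temp dir).
#' @param seed Master seed (overrides `cohort$seed` when simulating).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            band = c(20, 500),
                            n_keep = 9,
                            psd_mode = c("welch", "single512"),
                            mdf_mode = c("interp", "bin"),
                            pca_normalize = TRUE,
                            pca_k_max = 4,
                            pca_min_prop = 0.10,
                            t_variant = c("student", "welch"),
                            holm = FALSE,
                            out_dir = NULL,
                            seed = NULL) {
  psd_mode <- match.arg(psd_mode)
  mdf_mode <- match.arg(mdf_mode)
  t_variant <- match.arg(t_variant)
  if (is.character(cohort) && !dir.exists(cohort))
    stop("input directory does not exist: ", cohort)
  if (band[1] <= 0 || band[2] > 500 || band[1] >= band[2])
    stop("band must lie within (0, 500] Hz")
  if (inherits(cohort, "cohort_config") && !is.null(seed)) {
    cohort <- do.call(cohort_config, utils::modifyList(
      cohort[setdiff(names(cohort), "copd_params")],
      list(seed = as.integer(seed))))
  }
  structure(list(cohort = cohort, band = band, n_keep = n_keep,
                 psd_mode = psd_mode, mdf_mode = mdf_mode,
                 pca_normalize = pca_normalize, pca_k_max = pca_k_max,
                 pca_min_prop = pca_min_prop, t_variant = t_variant,
                 holm = holm, out_dir = out_dir,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate/read -> kinematic segmentation -> EMG preprocessing -> spectral
#' features -> varimax PCA of spectral profiles -> group statistics, with
#' all tables written to `out_dir` and a machine-readable `summary.json`
#' echoing the configuration flags in effect. Deterministic under identical
#' config + seed.
#'
#' @param config A [pipeline_config()].
#' @param clinical Optional clinical records for the severity regressions;
#'   defaults to the shipped patient fixture when patient ids match.
#' @return Invisible list with `features`, `participant_means`,
#'   `group_comparison`, `anova2` (mixed-ANOVA table), `cycle_stability`,
#'   `pca` (per muscle x direction summaries), `regression`, `gates`,
#'   `out_dir`, `summary` (the JSON payload).
#' @export
run_pipeline <- function(config = pipeline_config(), clinical = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("spectromyo-",
                                           as.integer(stats::runif(1, 1, 1e8))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate/read"
  res <- tryCatch({
    recordings <- if (inherits(config$cohort, "cohort_config")) {
      generate_cohort(config$cohort)
    } else read_recordings(config$cohort)

    stage <- "preprocess+spectral"
    ana <- analyze_cohort(recordings,
                          n_keep = config$n_keep, band = config$band,
                          mdf_interpolate = config$mdf_mode == "interp",
                          psd_mode = config$psd_mode)
    feats <- ana$features
    pm <- participant_means(feats)
    data.table::fwrite(feats, file.path(out_dir, "features.csv"))
    data.table::fwrite(pm[, c("participant_id", "group", "muscle",
                              "direction", "area")],
                       file.path(out_dir, "areas.csv"))
    data.table::fwrite(ana$events, file.path(out_dir, "events.csv"))
    data.table::fwrite(ana$segments, file.path(out_dir, "segments.csv"))

    stage <- "group statistics"
    pooled <- config$t_variant == "student"
    gc_rows <- list()
    an_rows <- list()
    cyc_rows <- list()
    for (m in unique(pm$muscle)) for (d in unique(pm$direction)) {
      sub <- pm[pm$muscle == m & pm$direction == d, ]
      a <- sub[sub$group == "COPD", ]
      b <- sub[sub$group == "control", ]
      if (nrow(a) < 2L || nrow(b) < 2L) next
      row <- data.table::data.table(muscle = m, direction = d)
      for (v in c("mnf", "mdf", "area")) {
        tt <- two_sample_t(a[[v]], b[[v]], pooled = pooled)
        row[[paste0(v, "_copd")]] <- tt$mean_a
        row[[paste0(v, "_control")]] <- tt$mean_b
        row[[paste0(v, "_pct_diff")]] <- 100 * (tt$mean_a - tt$mean_b) /
          tt$mean_b
        row[[paste0(v, "_t")]] <- tt$statistic
        row[[paste0(v, "_p")]] <- tt$p
      }
      gc_rows[[paste(m, d)]] <- row
      mat <- as.matrix(sub[, c("mnf", "mdf")])
      an <- mixed_anova_2way(mat, sub$group)
      an_rows[[paste(m, d)]] <- data.table::data.table(
        muscle = m, direction = d, effect = an$effect, F = an$F,
        df1 = an$df1, df2 = an$df2, p = an$p, eta_p2 = an$eta_p2)
      # cycle stability: RM-ANOVA over cycles, per group, on MNF
      for (g in c("COPD", "control")) {
        fsub <- feats[feats$muscle == m & feats$direction == d &
                        feats$group == g, ]
        wide <- data.table::dcast(fsub, participant_id ~ cycle_index,
                                  value.var = "mnf")
        mat_c <- as.matrix(wide[, -1])
        if (anyNA(mat_c) || nrow(mat_c) < 2L) next
        rg <- rm_anova_1way_gg(mat_c)
        cyc_rows[[paste(m, d, g)]] <- data.table::data.table(
          muscle = m, direction = d, group = g, F = rg$F,
          df1_gg = rg$df1_gg, df2_gg = rg$df2_gg,
          epsilon_gg = rg$epsilon_gg, p = rg$p, eta_p2 = rg$eta_p2)
      }
    }
    group_comparison <- data.table::rbindlist(gc_rows)
    if (config$holm)
      for (v in c("mnf", "mdf", "area")) {
        pcol <- paste0(v, "_p")
        group_comparison[[pcol]] <- stats::p.adjust(group_comparison[[pcol]],
                                                    method = "holm")
      }
    anova2 <- data.table::rbindlist(an_rows)
    cycle_stability <- data.table::rbindlist(cyc_rows)
    data.table::fwrite(anova2, file.path(out_dir, "table3_like.csv"))

    gates <- lapply(c("mnf", "mdf", "area"), function(v) {
      lapply(split(pm, paste(pm$muscle, pm$direction)), function(sub)
        normality_variance_gates(split(sub[[v]], sub$group)))
    })
    names(gates) <- c("mnf", "mdf", "area")

    stage <- "pca"
    pca_out <- list()
    comp_rows <- list()
    for (key in names(ana$psds)) {
      bundle <- ana$psds[[key]]
      pmx <- build_profile_matrix(bundle$psds, bundle$groups,
                                  normalize = config$pca_normalize)
      model <- fit_pca_varimax(pmx, k_max = config$pca_k_max,
                               min_prop = config$pca_min_prop)
      cmp <- compare_group_weights(model$W, pmx$groups,
                                   proportions = model$proportions)
      md <- strsplit(key, ".", fixed = TRUE)[[1L]]
      cmp <- cbind(muscle = md[1L], direction = md[2L], cmp)
      pca_out[[key]] <- list(model = model, summary = cmp)
      comp_rows[[key]] <- data.table::data.table(
        muscle = md[1L], direction = md[2L],
        frequency = rep(model$col_freqs, model$k),
        component = rep(paste0("PC", seq_len(model$k)),
                        each = length(model$col_freqs)),
        loading = as.vector(model$components))
    }
    pca_summary <- data.table::rbindlist(lapply(pca_out, `[[`, "summary"))
    data.table::fwrite(pca_summary, file.path(out_dir, "pca_summary.csv"))
    data.table::fwrite(data.table::rbindlist(comp_rows),
                       file.path(out_dir, "components.csv"))

    stage <- "severity regression"
    if (is.null(clinical)) clinical <- copd_clinical()
    regression <- NULL
    if (any(pm$participant_id %in% clinical$patient_id)) {
      regression <- severity_regression(pm[pm$group == "COPD", ], clinical)
      data.table::fwrite(regression, file.path(out_dir, "table5_like.csv"))
    }

    stage <- "summary"
    summary <- list(
      package_version = as.character(packageVersion("spectromyo")),
      config = list(
        simulated = inherits(config$cohort, "cohort_config"),
        seed = if (inherits(config$cohort, "cohort_config"))
          config$cohort$seed else config$seed,
        band = config$band, n_keep = config$n_keep,
        psd_mode = config$psd_mode, mdf_mode = config$mdf_mode,
        pca_normalize = config$pca_normalize,
        pca_k_max = config$pca_k_max, pca_min_prop = config$pca_min_prop,
        t_variant = config$t_variant, holm = config$holm),
      group_comparison = group_comparison,
      anova_group_by_parameter = anova2,
      cycle_stability = cycle_stability,
      pca_summary = pca_summary,
      regression = regression
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         pretty = TRUE)
    list(features = feats, participant_means = pm,
         group_comparison = group_comparison, anova2 = anova2,
         cycle_stability = cycle_stability, pca = pca_out,
         pca_summary = pca_summary, regression = regression,
         gates = gates, out_dir = out_dir, summary = summary)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Command-line entry point
#'
#' Implements `spectromyo simulate|run|report`. `simulate` writes a
#' synthetic cohort to `--out`; `run` executes the full pipeline on a
#' simulated (default) or on-disk (`--in DIR`) cohort; `report` prints the
#' group-comparison block of an existing `summary.json`.
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Exit status, invisibly.
#' @export
spectromyo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: spectromyo <simulate|run|report> [--out DIR] [--in DIR]",
    "[--seed N] [--n-per-group N] [--band LO,HI] [--psd-mode welch|single512]",
    "[--mdf-mode interp|bin] [--t-variant student|welch] [--holm]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- list(out = "spectromyo-out", input = NULL, seed = 1L,
              n_per_group = 10L, band = c(20, 500), psd_mode = "welch",
              mdf_mode = "interp", t_variant = "student", holm = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    val <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--out" = opt$out <- val(),
      "--in" = opt$input <- val(),
      "--seed" = opt$seed <- as.integer(val()),
      "--n-per-group" = opt$n_per_group <- as.integer(val()),
      "--band" = opt$band <- as.numeric(strsplit(val(), ",")[[1L]]),
      "--psd-mode" = opt$psd_mode <- val(),
      "--mdf-mode" = opt$mdf_mode <- val(),
      "--t-variant" = opt$t_variant <- val(),
      "--holm" = opt$holm <- TRUE,
      stop("unknown option: ", a)
    )
    i <- i + 1L
  }
  cc <- cohort_config(n_per_group = opt$n_per_group, band = opt$band,
                      seed = opt$seed)
  if (cmd == "simulate") {
    write_cohort(generate_cohort(cc), opt$out, config = cc)
    message("cohort written to ", opt$out)
  } else if (cmd == "run") {
    cfg <- pipeline_config(
      cohort = if (is.null(opt$input)) cc else opt$input,
      band = opt$band, psd_mode = opt$psd_mode, mdf_mode = opt$mdf_mode,
      t_variant = opt$t_variant, holm = opt$holm, out_dir = opt$out,
      seed = opt$seed)
    res <- run_pipeline(cfg)
    message("pipeline outputs in ", res$out_dir)
  } else if (cmd == "report") {
    f <- file.path(opt$out, "summary.json")
    if (!file.exists(f)) stop("no summary.json under ", opt$out)
    s <- jsonlite::read_json(f, simplifyVector = TRUE)
    print(s$group_comparison)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
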