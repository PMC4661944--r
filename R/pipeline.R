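# End-to-end pipeline: heritability -> adjusted means -> scan ->
# permutation thresholds -> QTL calls -> regional heritability -> merge
# analysis -> confidence intervals, with all artifacts written as TSV and
# a machine-readable run log.

#' Default pipeline configuration
#'
#' @param seed integer seed used (with fixed offsets) by every stochastic
#'   stage.
#' @return Nested configuration list; fields mirror the pipeline stages.
#' @export
default_config <- function(seed = 20151126L) {
  list(
    seed = seed,
    paths = list(phenotypes = NULL, tensor_prefix = NULL, catalogue = NULL,
                 output = "ccqtl_out"),
    simulate = list(n_lines = 31L, n_per_line = 5L, n_chrom = 10L,
                    length_mb = 100, marker_spacing_bp = 1e6,
                    n_variants = 200L, breakpoint_rate_per_mb = 0.05,
                    soft_halfwidth_bp = 2e5),
    scan = list(weights = TRUE, n_perm = 200L, percentiles = c(95, 99),
                call_level = 99, split_level = 95),
    ci = list(n_sim = 1000L, neighborhood_mb = 5, levels = c(50, 90, 95),
              mode = "additive"),
    merge = list(region_pad_mb = 5, min_minor_mass = 0.5)
  )
}

# merge user config over defaults, recursively
merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else user[[nm]]
  }
  base
}

#' Run the full QTL-mapping pipeline
#'
#' Stages run in order: load or simulate the cohort; heritability per
#' trait; covariate-adjusted line means; haplotype scan; permutation
#' thresholds; QTL calls; regional heritability; merge analysis around
#' each call; simulation and quick confidence intervals.  All artifacts
#' are written under the output directory together with `run_log.json`
#' (seed, config echo, per-stage timings, decision flags).  Given the same
#' seed the run is deterministic.
#'
#' @param config configuration list (see [default_config()]) or the path
#'   of a YAML file holding one; partial configs are merged over defaults.
#' @param traits trait columns to analyse; defaults to every numeric
#'   column after the covariates.
#' @return Invisibly, a results bundle: cohort objects plus per-trait
#'   heritability, scan, thresholds, calls, merge and CI results.
#' @export
run_pipeline <- function(config = default_config(), traits = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_config(), config)
  out_dir <- config$paths$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed,
              versions = list(
                ccqtl = as.character(utils::packageVersion("ccqtl")),
                R = paste(R.version$major, R.version$minor, sep = ".")),
              config = config, stages = list())
  t_stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log$stages[[nm]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  cohort <- t_stage("load", {
    if (!is.null(config$paths$phenotypes)) {
      list(phenotypes = read_phenotypes(config$paths$phenotypes),
           tensor = read_tensor(config$paths$tensor_prefix),
           catalogue = if (!is.null(config$paths$catalogue)) {
             read_catalogue(config$paths$catalogue)
           })
    } else {
      sim <- config$simulate
      sim_cohort(n_lines = sim$n_lines, n_per_line = sim$n_per_line,
                 chrom_lengths = cc_genome(sim$n_chrom, sim$length_mb),
                 marker_spacing_bp = sim$marker_spacing_bp,
                 n_variants = sim$n_variants,
                 breakpoint_rate_per_mb = sim$breakpoint_rate_per_mb,
                 soft_halfwidth_bp = sim$soft_halfwidth_bp,
                 seed = config$seed)
    }
  })
  phen <- cohort$phenotypes
  if (is.null(traits)) {
    covs <- c("animal_id", "line", "sex", "age_weeks")
    traits <- names(phen)[!names(phen) %in% covs &
                            vapply(phen, is.numeric, logical(1))]
  }

  results <- list(cohort = cohort, traits = list())
  herits <- list()
  for (tr in traits) {
    res <- list()
    res$herit <- t_stage(paste0("h2_", tr), {
      heritability(fit_nested_models(phen, tr))
    })
    herits[[tr]] <- res$herit
    means <- t_stage(paste0("means_", tr), adjusted_line_means(phen, tr))
    res$line_means <- means
    res$scan <- t_stage(paste0("scan_", tr), {
      scan_haplotypes(means, cohort$tensor, trait = tr)
    })
    res$thresholds <- t_stage(paste0("perm_", tr), {
      perm_thresholds(means, cohort$tensor, n_perm = config$scan$n_perm,
                      percentiles = config$scan$percentiles,
                      seed = config$seed + 101L)
    })
    res$calls <- t_stage(paste0("call_", tr), {
      call_qtls(res$scan, res$thresholds, level = config$scan$call_level,
                split_level = config$scan$split_level)
    })
    if (nrow(res$calls)) {
      res$calls$h2_r <- NA_real_
      res$calls$h2_r_logp <- NA_real_
      res$merge <- list()
      res$ci <- list()
      for (qi in seq_len(nrow(res$calls))) {
        q <- res$calls[qi, ]
        rh <- t_stage(paste0("h2r_", tr, "_", qi), {
          regional_h2(phen, tr, cohort$tensor, q$peak_marker)
        })
        res$calls$h2_r[qi] <- rh$h2_r
        res$calls$h2_r_logp[qi] <- rh$logp
        if (!is.null(cohort$catalogue)) {
          res$merge[[qi]] <- t_stage(paste0("merge_", tr, "_", qi), {
            pad <- config$merge$region_pad_mb * 1e6
            dos <- impute_dosages(cohort$tensor, cohort$catalogue,
                                  region = list(chrom = q$chrom,
                                                start_bp = q$peak_bp - pad,
                                                end_bp = q$peak_bp + pad))
            ms <- merge_scan(means, dos, scan = res$scan,
                             min_minor_mass = config$merge$min_minor_mass)
            ms$candidate <- ms$variant_id %in%
              candidate_filter(ms, q$peak_logp)$variant_id
            ms
          })
        }
        res$ci[[qi]] <- t_stage(paste0("ci_", tr, "_", qi), {
          rbind(qtl_ci_sim(means, cohort$tensor, q,
                           n_sim = config$ci$n_sim,
                           neighborhood_mb = config$ci$neighborhood_mb,
                           levels = config$ci$levels, mode = config$ci$mode,
                           seed = config$seed + 202L + qi),
                qtl_ci_li(q, res$scan, levels = config$ci$levels))
        })
      }
    }
    # artifacts
    write_scan_tsv(res$scan, file.path(out_dir, paste0("scan_", tr, ".tsv")))
    jsonlite::write_json(as.list(res$thresholds$thresholds),
                         file.path(out_dir, paste0("thresholds_", tr, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write_calls_tsv(res$calls, file.path(out_dir, paste0("qtl_", tr, ".tsv")))
    if (length(res$ci %||% list())) {
      write_ci_tsv(do.call(rbind, res$ci),
                   file.path(out_dir, paste0("ci_", tr, ".tsv")))
    }
    if (length(res$merge %||% list())) {
      write_merge_tsv(do.call(rbind, res$merge),
                      file.path(out_dir, paste0("merge_", tr, ".tsv")))
    }
    results$traits[[tr]] <- res
  }
  write_herit_tsv(herits, file.path(out_dir, "heritability.tsv"))
  write_phenotypes(phen, file.path(out_dir, "phenotypes.csv"))

  log$decisions <- list(ci_mode = config$ci$mode,
                        neighborhood_mb = config$ci$neighborhood_mb,
                        covariate_effect_mode = "single",
                        permutation_unit = "line")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(results)
}
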