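# Configuration, orchestration and report generation.

# tiny deterministic string hash (djb2) for run manifests
.config_hash <- function(x) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 5381
  for (ch in s) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Builds (or reads from a YAML file) the configuration driving
#' [run_pipeline()]: dataset location or synthetic-generation settings,
#' estimation initials and SAEM controls, diagnostic settings (bootstrap
#' resamples, NPDE replicates, VPC simulations), the PTA scenario and an
#' explicit seed per stochastic stage. Shipped defaults are 1,000
#' bootstrap resamples, 500 VPC simulations, 1,000 NPDE replicates and
#' 1,000 PTA profiles.
#'
#' @param path optional YAML file; entries override the defaults.
#' @param ... named overrides applied after the file.
#' @return A list of class `pipeline_config` that round-trips through
#'   [yaml::as.yaml()].
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    dataset = NULL,                  # CSV path; NULL -> synthetic cohort
    n_subjects = 18L,
    stages = c("fit", "diagnose", "covariates", "pta"),
    saem = list(n_explore = 500L, n_smooth = 200L, rse_method = "louis"),
    bootstrap = list(n_resamples = 1000L, enabled = FALSE),
    npde = list(K = 1000L),
    vpc = list(n_sim = 500L),
    pta = list(n_profiles = 1000L, target = 50, stasis = TRUE),
    popmodel = NULL,                 # named list(fixed, omega, b) for pta-only
    seeds = list(simulate = 101L, fit = 1L, bootstrap = 11L, npde = 21L,
                 vpc = 31L, covariates = 41L, pta = 51L))
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, over)
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_tsv <- function(tab, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s  config: %s", seed, hash), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: data acquisition (read a
#' long-format CSV or generate the synthetic cohort), SAEM estimation,
#' diagnostics (goodness-of-fit table, NPDE, pc-VPC, optional bootstrap),
#' the stepwise covariate search, and the Monte Carlo PTA tables (kill and
#' stasis targets). Writes an estimates table, diagnostic tables, the
#' covariate decision log, PTA tables (TSV and markdown), and a JSON run
#' manifest carrying all seeds, the configuration hash and package
#' version. Each TSV carries its generating seed and the configuration
#' hash in a header comment. A stage failure halts the run with a
#' stage-named error; outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "pk-run") {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(unclass(config))
  res <- list(config = config, hash = hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data <- stage("data", {
    if (!is.null(config$dataset)) {
      read_pk_dataset(config$dataset)
    } else {
      dat <- generate_pk_dataset(study_design(n_subjects = config$n_subjects),
                                 dalbavancin_model(),
                                 seed = config$seeds$simulate)
      write_pk_dataset(dat, file.path(outdir, "dataset.csv"))
      dat
    }
  })
  res$data <- data

  fit <- NULL
  if ("fit" %in% config$stages) {
    fit <- stage("fit", {
      ctl <- do.call(saem_control, config$saem)
      saem(data, control = ctl, seed = config$seeds$fit)
    })
    res$fit <- fit
    stab <- summary(fit)$table
    .write_tsv(stab, file.path(outdir, "estimates.tsv"), config$seeds$fit,
               hash)
  }

  pop <- if (!is.null(fit)) {
    fit$estimates
  } else if (!is.null(config$popmodel)) {
    popmodel(config$popmodel$fixed, config$popmodel$omega,
             config$popmodel$b)
  } else {
    dalbavancin_model()
  }

  if ("diagnose" %in% config$stages && !is.null(fit)) {
    diag <- stage("diagnose", {
      gof <- gof_table(fit, K = config$npde$K, seed = config$seeds$npde)
      .write_tsv(gof, file.path(outdir, "gof.tsv"), config$seeds$npde, hash)
      np <- npde(fit, K = config$npde$K, seed = config$seeds$npde)
      .write_tsv(np$global, file.path(outdir, "npde_tests.tsv"),
                 config$seeds$npde, hash)
      vp <- pc_vpc(fit, n_sim = config$vpc$n_sim, seed = config$seeds$vpc)
      .write_tsv(vp$bands, file.path(outdir, "pcvpc.tsv"),
                 config$seeds$vpc, hash)
      list(npde = np, vpc = vp)
    })
    res$npde <- diag$npde
    res$vpc <- diag$vpc
    if (isTRUE(config$bootstrap$enabled)) {
      res$bootstrap <- stage("bootstrap", {
        bs <- pk_bootstrap(fit, n_resamples = config$bootstrap$n_resamples,
                           seed = config$seeds$bootstrap)
        .write_tsv(bs$table, file.path(outdir, "bootstrap.tsv"),
                   config$seeds$bootstrap, hash)
        bs
      })
    }
  }

  if ("covariates" %in% config$stages && !is.null(fit) &&
      !is.null(data$covariates)) {
    res$covariates <- stage("covariates", {
      cs <- stepwise_covariates(data, fit, seed = config$seeds$covariates)
      write_decision_log(cs, file.path(outdir, "covariate_log.tsv"))
      cs
    })
  }

  if ("pta" %in% config$stages) {
    pta_res <- stage("pta", {
      sc <- pta_scenario(n_profiles = config$pta$n_profiles,
                         target = config$pta$target,
                         seed = config$seeds$pta)
      pt <- pta_table(pop, sc)
      write_pta_table(pt, file.path(outdir, "pta.tsv"))
      write_pta_table(pt, file.path(outdir, "pta.md"), format = "markdown")
      st <- NULL
      if (isTRUE(config$pta$stasis)) {
        st <- stasis_table(pop, sc)
        write_pta_table(st, file.path(outdir, "pta_stasis.tsv"))
      }
      list(pta = pt, stasis = st)
    })
    res$pta <- pta_res$pta
    res$pta_stasis <- pta_res$stasis
  }

  manifest <- list(package = "dalbapk",
                   version = as.character(utils::packageVersion("dalbapk")),
                   config_hash = hash, seeds = config$seeds,
                   stages = config$stages)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$outdir <- outdir
  invisible(res)
}
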