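#' Assemble a reproducible end-to-end run configuration
#'
#' Bundles the parameter blocks of every stage (generator, condition
#' presets, burst detection thresholds, conductance model, lever model)
#' plus a master seed. The configuration round-trips through a YAML file
#' via [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed; each stage derives its own sub-stream.
#' @param generator A [generator_params()].
#' @param presets List of [condition_preset()] objects to simulate.
#' @param law A [hill_law()] for the generator's open level.
#' @param detection List with `open_threshold`, `min_burst_gap`,
#'   `min_dwell` (ms/pS; see [detect_bursts()]).
#' @param conduct A [conductance_model()].
#' @param lever A [lever_params()], or `NULL` to skip the model stage.
#' @param n_patches Patches per condition.
#' @param bin_width_G,bin_width_r Histogram bin widths (pS, nm).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_params(patch_duration = 1),
                       presets = list(
                         condition_preset("no_syt", calcium = 0),
                         condition_preset("c2ab_wt", calcium = 0),
                         condition_preset("c2ab_wt", calcium = 100)),
                       law = hill_law(),
                       detection = list(open_threshold = 25,
                                        min_burst_gap = 500, min_dwell = 1),
                       conduct = conductance_model(),
                       lever = NULL,
                       n_patches = 20,
                       bin_width_G = 20, bin_width_r = 0.05) {
  structure(list(seed = as.integer(seed), generator = generator,
                 presets = presets, law = law, detection = detection,
                 conduct = conduct, lever = lever, n_patches = n_patches,
                 bin_width_G = bin_width_G, bin_width_r = bin_width_r),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks every block of a [run_config()] against its own invariants and
#' returns a character vector of violations (empty when valid), each
#' naming the offending field and rule. Constructor-enforced invariants
#' are re-checked here so that configurations read from files or edited
#' by hand are also covered.
#'
#' @param config A `run_config` (or a plain list with the same fields).
#' @return Character vector of violation messages; `character(0)` if the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  g <- config$generator
  if (!is.null(g)) {
    p <- g$flicker_success_prob
    if (!is.numeric(p) || p <= 0 || p > 1) {
      add("generator.flicker_success_prob: must be in (0, 1]")
    }
    for (f in c("burst_mean_duration", "flicker_mean_closed",
                "open_mean_dwell", "sample_interval", "patch_duration")) {
      if (!is.numeric(g[[f]]) || g[[f]] <= 0) {
        add(sprintf("generator.%s: must be > 0", f))
      }
    }
    if (is.numeric(g$nucleation_rate) && g$nucleation_rate < 0) {
      add("generator.nucleation_rate: must be >= 0")
    }
    if (is.numeric(g$sample_interval) && is.numeric(g$flicker_mean_closed) &&
        is.numeric(g$open_mean_dwell) &&
        g$sample_interval >= min(g$flicker_mean_closed, g$open_mean_dwell) / 5) {
      add("generator.sample_interval: must be < mean dwells / 5")
    }
  }
  for (i in seq_along(config$presets)) {
    pr <- config$presets[[i]]
    if (pr$calcium < 0) add(sprintf("presets[%d].calcium: must be >= 0", i))
    if (pr$conductance_scale <= 0 || pr$nucleation_scale <= 0) {
      add(sprintf("presets[%d]: scales must be > 0", i))
    }
  }
  law <- config$law
  if (!is.null(law)) {
    if (law$a < 0 || law$c < 0) add("law: a and c must be >= 0")
    if (law$n <= 0) add("law.n: must be > 0")
    if (law$K <= 0) add("law.K: must be > 0")
  }
  d <- config$detection
  if (!is.null(d)) {
    for (f in c("open_threshold", "min_burst_gap", "min_dwell")) {
      if (!is.numeric(d[[f]]) || d[[f]] <= 0) {
        add(sprintf("detection.%s: must be > 0", f))
      }
    }
  }
  cm <- config$conduct
  if (!is.null(cm)) {
    if (cm$L <= 0) add("conduct.L: must be > 0")
    if (cm$sigma <= 0) add("conduct.sigma: must be > 0")
  }
  lv <- config$lever
  if (!is.null(lv)) {
    if (lv$mem$kappa <= 0) add("lever.mem.kappa: must be > 0")
    if (lv$mem$gamma < 0) add("lever.mem.gamma: must be >= 0")
    if (lv$scaf$disc_radius <= 0) add("lever.scaf.disc_radius: must be > 0")
    if (lv$snares$N < 0) add("lever.snares.N: must be >= 0")
    if (lv$snares$rod_footprint <= 0) {
      add("lever.snares.rod_footprint: must be > 0")
    }
    ta <- lv$c2b$tilt_angle
    if (ta <= 0 || ta >= 90) add("lever.c2b.tilt_angle: must be in (0, 90)")
  }
  v
}

#' Write and read run configurations as YAML
#'
#' @param config A [run_config()].
#' @param path File path of the YAML configuration.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: cannot read ", path)
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    seed = raw$seed %||% 1L,
    generator = do.call(generator_params, raw$generator),
    presets = lapply(raw$presets, function(p) {
      do.call(condition_preset,
              p[intersect(names(p),
                          c("label", "calcium", "pip2_present",
                            "conductance_scale", "nucleation_scale"))])
    }),
    law = do.call(hill_law, raw$law),
    detection = raw$detection,
    conduct = do.call(conductance_model, raw$conduct),
    n_patches = raw$n_patches %||% 20,
    bin_width_G = raw$bin_width_G %||% 20,
    bin_width_r = raw$bin_width_r %||% 0.05)
  cfg
}

#' Reproducible end-to-end run
#'
#' Executes simulate -> idealize -> pore statistics (-> lever model) for
#' every condition preset in the configuration and returns a
#' machine-readable results table of the headline quantities: per-
#' condition nucleation rates and burst-metric means, pooled conductance
#' and radius distributions with their apparent free-energy profiles,
#' the fixed conductance-to-radius correspondences of the cylinder
#' model, and (when a lever block is present) the model's calcium
#' fold-change predictions. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for delimited-text outputs.
#' @param verbose Print stage progress.
#' @return A list with `results` (data.frame `quantity`, `condition`,
#'   `value`), `conditions` (per-condition detail), and `model`
#'   (titration data.frame or `NULL`).
#' @export
run_reproduction <- function(config = run_config(), out_dir = NULL,
                             verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("run_reproduction: invalid config:\n  ",
         paste(viol, collapse = "\n  "))
  }
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(config$presets) + 1L)

  results <- list()
  addr <- function(quantity, condition, value) {
    results[[length(results) + 1]] <<- data.frame(
      quantity = quantity, condition = condition, value = value)
  }

  conditions <- list()
  for (i in seq_along(config$presets)) {
    pr <- config$presets[[i]]
    tag <- sprintf("%s_ca%g", pr$label, pr$calcium)
    say("simulate + analyze: %s", tag)
    g <- config$generator
    g$seed <- stage_seeds[i]
    recs <- simulate_patches(config$n_patches, g, pr, config$law)
    bursts <- list()
    for (rec in recs) {
      det <- detect_bursts(rec$trace,
                           open_threshold = config$detection$open_threshold,
                           min_burst_gap = config$detection$min_burst_gap,
                           min_dwell = config$detection$min_dwell)
      bursts <- c(bursts, det)
    }
    rate <- nucleation_rate(recs)
    addr("pores_per_min_naive", tag, rate$naive)
    addr("pores_per_min_censoring_aware", tag, rate$censoring_aware)
    cond <- list(preset = pr, n_bursts = length(bursts), rate = rate)
    if (length(bursts)) {
      met <- bursts_metrics(bursts)
      for (m in c("G_po_pS", "T_o_ms", "n_flickers", "P_o",
                  "fluctuation_pS")) {
        addr(paste0("mean_", m), tag, mean(met[[m]]))
      }
      pooled <- pool_point_conductances(bursts)
      pdf_G <- estimate_pdf(pooled, config$bin_width_G)
      radii <- conductance_to_radius(pmax(pooled, 0), config$conduct)
      pdf_r <- estimate_pdf(radii, config$bin_width_r)
      cond$metrics <- met
      cond$pdf_G <- pdf_G
      cond$pdf_r <- pdf_r
      cond$profile <- tryCatch(boltzmann_invert(pdf_r),
                               error = function(e) NULL)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_metrics(met, file.path(out_dir,
                                     sprintf("metrics_%s.tsv", tag)))
        if (!is.null(cond$profile)) {
          utils::write.table(cond$profile,
                             file.path(out_dir,
                                       sprintf("profile_%s.tsv", tag)),
                             sep = "\t", row.names = FALSE, quote = FALSE)
        }
      }
    }
    conditions[[tag]] <- cond
  }

  # fixed conductance <-> radius correspondences of the cylinder model
  addr("radius_at_200pS_nm", "conversion",
       conductance_to_radius(200, config$conduct))
  addr("radius_at_1nS_nm", "conversion",
       conductance_to_radius(1000, config$conduct))
  addr("conductance_at_5nm_nS", "conversion",
       radius_to_conductance(5, config$conduct) / 1000)

  model <- NULL
  if (!is.null(config$lever)) {
    say("lever model titration")
    model <- lever_titration(config$lever, calcium = c(0, 1000))
    addr("model_mean_r_noCa_nm", "model", model$mean_r[1])
    addr("model_mean_h_noCa_nm", "model", model$mean_h[1])
    addr("model_mean_r_satCa_nm", "model",
         model$mean_r[nrow(model)])
    addr("model_fold_r", "model", model$fold_r[nrow(model)])
    addr("model_fold_G", "model", model$fold_G[nrow(model)])
  }

  results <- do.call(rbind, results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(results = results, conditions = conditions, model = model)
}
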