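# Default demo configuration; every value a consumed parameter that the
# manifest echoes back.
#' @noRd
default_config <- function() {
  list(
    seed = 1L,
    library = list(length = 30L, n = 10000L, bias_base = "none",
                   bias_p = 0.76),
    recruitment = list(intercept = -1, coef_terminal_g = 0.6,
                       coef_longest_a = 0.25, coef_structure = 0),
    fastq = list(adapter5 = "ACACGACGCTCTTCCGATCT",
                 adapter3 = "AGATCGGAAGAGCACACGTC",
                 polyg_tail_prob = 0.1, polyg_len = 12L),
    readproc = list(max_mismatch = 1L, min_tail = 5L),
    turbidity = list(A = 0.5, tau_r = 0.8, t_d = 12, w = 0.4,
                     noise_sd = 0.005, replicates = 3L),
    titration = list(salt_od0 = 0.5, salt_slope = 0.005,
                     salt_conc_step = 10, salt_conc_max = 150,
                     fuel_onset = 9, fuel_conc_step = 2.5,
                     fuel_conc_max = 30, noise_sd = 0),
    frap = list(a = 0.8, b = 0.7, c = 0.1, radius = 1,
                noise_sd = 0.02, replicates = 3L),
    partition = list(c_total = 50, v_total = 20,
                     c_supernatant = c(45.2, 44.8, 45.5),
                     v_droplet = c(0.095, 0.105, 0.1))
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list), applies documented
#' defaults for missing keys, rejects unknown keys, and range-checks every
#' parameter. The validated configuration is what [run_all()] echoes into
#' its run manifest.
#'
#' @param config path to a YAML file, or a (possibly partial) configuration
#'   list; `NULL` gives the full default demo configuration.
#' @return the validated configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("no such config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stopf("unknown config section: %s", unknown[1])
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad)) stopf("unknown key `%s` in section `%s`", bad[1], sec)
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  cfg <- def
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  check_count(cfg$library$n, "library$n")
  check_count(cfg$library$length, "library$length")
  if (!cfg$library$bias_base %in% c("none", DNA_BASES)) {
    stopf("library$bias_base must be 'none' or one of A, C, G, T")
  }
  if (cfg$fastq$polyg_tail_prob < 0 || cfg$fastq$polyg_tail_prob > 1) {
    stopf("fastq$polyg_tail_prob must be a probability")
  }
  if (cfg$turbidity$A <= 0 || cfg$turbidity$tau_r <= 0 || cfg$turbidity$w <= 0) {
    stopf("turbidity A, tau_r, w must be positive")
  }
  if (any(cfg$partition$c_supernatant < 0)) {
    stopf("partition$c_supernatant must be non-negative")
  }
  if (any(cfg$partition$v_droplet <= 0)) {
    stopf("partition$v_droplet must be positive")
  }
  if (cfg$frap$a <= 0 || cfg$frap$b <= 0 || cfg$frap$c < 0) {
    stopf("frap a, b must be positive and c non-negative")
  }
  cfg
}

# One global seed expanded into per-stage child seeds (documented scheme:
# seed + 104729 * stage index, reduced mod 2^31 - 1).
#' @noRd
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

#' Run the end-to-end synthetic study
#'
#' Generates the library, recruits droplet and supernatant pools, writes and
#' re-reads FASTQ through the cleaning pipeline, computes composition /
#' positional-difference / run-enrichment tables, the exact run
#' probabilities for the headline conditions, the turbidity, titration,
#' FRAP and partition summaries, and a manifest echoing every parameter
#' with an md5 checksum per output file. Deterministic given the config
#' seed.
#'
#' @param config see [validate_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config = NULL, outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(outdir, name)
    written <<- c(written, p)
    p
  }
  lib <- pools <- drop_clean <- sup_clean <- NULL
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stopf("pipeline stage `%s` failed: %s", stage, conditionMessage(e))
    })
  }

  profile <- if (cfg$library$bias_base == "none") {
    uniform_profile(cfg$library$length)
  } else {
    biased_profile(cfg$library$length, cfg$library$bias_base, cfg$library$bias_p)
  }

  run_stage("generate", {
    lib <- generate_library(profile, cfg$library$n, stage_seed(cfg$seed, 1))
  })
  run_stage("recruit", {
    model <- recruitment_model(cfg$recruitment$intercept,
                               cfg$recruitment$coef_terminal_g,
                               cfg$recruitment$coef_longest_a,
                               cfg$recruitment$coef_structure)
    pools <- recruit(lib, model, stage_seed(cfg$seed, 2))
  })
  run_stage("fastq", {
    emit_fastq(pools$droplet, cfg$fastq$adapter5, cfg$fastq$adapter3,
               cfg$fastq$polyg_tail_prob, stage_seed(cfg$seed, 3),
               out("droplet.fastq"), cfg$fastq$polyg_len)
    emit_fastq(pools$supernatant, cfg$fastq$adapter5, cfg$fastq$adapter3,
               cfg$fastq$polyg_tail_prob, stage_seed(cfg$seed, 4),
               out("supernatant.fastq"), cfg$fastq$polyg_len)
  })
  run_stage("readproc", {
    clean <- function(path, label) {
      raw <- read_fastq(path, mate = 1L, label = label)
      process_reads(raw, cfg$fastq$adapter3,
                    max_mismatch = cfg$readproc$max_mismatch,
                    adapter5 = cfg$fastq$adapter5,
                    min_tail = cfg$readproc$min_tail,
                    length = cfg$library$length)
    }
    drop_clean <- clean(file.path(outdir, "droplet.fastq"), "droplet")
    sup_clean <- clean(file.path(outdir, "supernatant.fastq"), "supernatant")
  })
  run_stage("enrich", {
    comp_d <- composition(drop_clean$reads)
    comp_s <- composition(sup_clean$reads)
    write_enrichment_tsv(comp_d, out("composition_droplet.tsv"))
    write_enrichment_tsv(comp_s, out("composition_supernatant.tsv"))
    write_enrichment_tsv(positional_difference(comp_d, comp_s),
                         out("difference.tsv"))
    write_enrichment_tsv(run_enrichment(drop_clean$reads, sup_clean$reads),
                         out("enrichment.tsv"))
  })
  run_stage("runprob", {
    conds <- list(
      biased_A20 = list(profile = biased_profile(cfg$library$length, "A"),
                        cset = condition_set(run_condition("A", 20))),
      biased_A7_end = list(profile = biased_profile(cfg$library$length, "A"),
                           cset = condition_set(run_condition("A", 7, anchor_d = 1))),
      uniform_either = list(profile = uniform_profile(cfg$library$length),
                            cset = condition_set(
                              run_condition("A", 7, anchor_d = 1),
                              run_condition("A", 20)))
    )
    df <- data.frame(
      condition = names(conds),
      exact_percent = vapply(conds, function(x) {
        100 * exact_probability(x$profile, x$cset)
      }, numeric(1))
    )
    write_tsv(df, out("runprob.tsv"))
  })
  run_stage("assays", {
    tb <- cfg$turbidity
    traces <- lapply(seq_len(tb$replicates), function(i) {
      simulate_turbidity(tb$A, tb$tau_r, tb$t_d, tb$w, noise_sd = tb$noise_sd,
                         seed = stage_seed(cfg$seed, 10 + i), replicate = i)
    })
    life <- vapply(traces, lifetime, numeric(1))
    lon <- vapply(traces, longevity, numeric(1))
    ti <- cfg$titration
    salt <- lapply(1:3, function(i) {
      simulate_titration("salt", seq(0, ti$salt_conc_max, by = ti$salt_conc_step),
                         od0 = ti$salt_od0, slope = ti$salt_slope,
                         noise_sd = ti$noise_sd,
                         seed = stage_seed(cfg$seed, 20 + i))
    })
    cs <- critical_salt(salt)
    fuel <- simulate_titration("fuel",
                               seq(ti$fuel_conc_step, ti$fuel_conc_max,
                                   by = ti$fuel_conc_step),
                               onset = ti$fuel_onset, noise_sd = ti$noise_sd,
                               seed = stage_seed(cfg$seed, 24))
    cf <- critical_fuel(fuel)
    write_tsv(data.frame(replicate = seq_along(life), lifetime_min = life,
                         longevity_min = lon),
              out("turbidity_summary.tsv"))
    write_tsv(data.frame(quantity = c("critical_salt_mM", "critical_salt_sd_mM",
                                      "critical_fuel_mM"),
                         value = c(cs$critical_mM, cs$sd_mM, cf)),
              out("titration_summary.tsv"))
  })
  run_stage("frap", {
    fp <- cfg$frap
    fits <- lapply(seq_len(fp$replicates), function(i) {
      tr <- simulate_frap(fp$a, fp$b, fp$c, fp$radius, noise_sd = fp$noise_sd,
                          seed = stage_seed(cfg$seed, 30 + i))
      fit_recovery(tr)
    })
    agg <- frap_aggregate(fits)
    write_tsv(data.frame(
      replicate = seq_along(fits),
      a = vapply(fits, `[[`, numeric(1), "a"),
      b = vapply(fits, `[[`, numeric(1), "b"),
      c = vapply(fits, `[[`, numeric(1), "c"),
      t_half_s = vapply(fits, `[[`, numeric(1), "t_half"),
      D_um2_s = vapply(fits, `[[`, numeric(1), "D")),
      out("frap_fits.tsv"))
    write_tsv(data.frame(quantity = c("mean_D_um2_s", "sd_D_um2_s",
                                      "mean_mobile_fraction"),
                         value = c(agg$mean_D, agg$sd_D,
                                   agg$mean_mobile_fraction)),
              out("frap_summary.tsv"))
  })
  run_stage("partition", {
    pp <- cfg$partition
    res <- k_p(pp$c_total, pp$v_total, pp$c_supernatant, pp$v_droplet)
    write_tsv(data.frame(quantity = c("k_p", "k_p_sd", "fraction_in_droplets"),
                         value = c(res$k_p, res$k_p_sd,
                                   res$fraction_in_droplets)),
              out("partition_summary.tsv"))
  })

  checksums <- tools::md5sum(written)
  manifest <- list(
    package = "coacervgeno",
    version = as.character(utils::packageVersion("coacervgeno")),
    config = cfg,
    outputs = as.list(checksums)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
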