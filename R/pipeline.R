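# Study orchestration: from a YAML/list config pointing at trial files and a
# genotype table, through per-trial outcomes and per-participant aggregates,
# to the association statistics, written as CSV plus a plain-text run log.

#' Study configuration
#'
#' @param trial_manifest path to a CSV with columns `participant_id`,
#'   `trial_type`, `trial_number`, `marker_file`, `force_file` (empty for
#'   sprints). Relative paths resolve against the manifest's directory.
#' @param genotype_csv path to the cohort genotype/covariate CSV.
#' @param output_dir directory for the report bundle.
#' @param cutoff_hz marker smoothing cutoff (Hz).
#' @param threshold_n flight-detection force threshold (N).
#' @param aggregation "mean" or "best" across a participant's trials.
#' @param outcomes outcome columns entered into association (default: the
#'   eccentric-phase torque peaks plus jump heights and reactive indices).
#' @param loci loci tested ("ace", "actn3").
#' @param models genetic models evaluated.
#' @param sex_groups sexes analysed (each separately); participants with
#'   other values are skipped.
#' @param seed seed recorded with the run (analysis itself is deterministic).
#' @return a `study_config` list.
#' @export
study_config <- function(trial_manifest, genotype_csv, output_dir,
                         cutoff_hz = 10, threshold_n = 10,
                         aggregation = c("mean", "best"),
                         outcomes = c("hip_rt_peak", "knee_rt_peak",
                                      "hip_power_peak", "knee_power_peak",
                                      "jump_height_ft_m", "rsi", "ireaf"),
                         loci = c("actn3", "ace"),
                         models = c("additive", "I_dominant", "D_dominant"),
                         sex_groups = "F",
                         seed = 1L) {
  aggregation <- match.arg(aggregation)
  structure(list(trial_manifest = trial_manifest, genotype_csv = genotype_csv,
                 output_dir = output_dir, cutoff_hz = cutoff_hz,
                 threshold_n = threshold_n, aggregation = aggregation,
                 outcomes = outcomes, loci = loci, models = models,
                 sex_groups = sex_groups, seed = seed),
            class = "study_config")
}

#' Load a study configuration from YAML
#' @param path YAML file with the [study_config()] fields.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y)
}

#' Run the full study analysis
#'
#' Stages: (1) read and filter the cohort (exclusion flags `parq_positive`,
#' `power_sport`, sex filter); (2) process every manifest trial into
#' outcomes, logging and skipping failures; (3) aggregate trials per
#' participant and derive the reactive indices (RSI, IReaF) from the
#' aggregated SJ/DJ heights and DJ contact time; (4) report Hardy-Weinberg
#' equilibrium per locus; (5) per outcome x locus: genotype ANOVA with Tukey
#' HSD and eta-squared, genetic-model variance shares, the dominant-grouping
#' t-test (RR+RX vs XX; DD+ID vs II) with KS normality checks, and a
#' likelihood-ratio test of the additive genotype code against a covariate
#' model (body mass, age). Everything is written under `output_dir`.
#'
#' @param config a [study_config()] or path to its YAML file.
#' @return invisibly, a list with `per_trial`, `per_participant`, `hwe`,
#'   `association`, `log` and the output file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("run_pipeline seed=%s aggregation=%s", config$seed, config$aggregation)

  geno <- read_genotype_table(config$genotype_csv)
  n0 <- nrow(geno)
  for (flag in c("parq_positive", "power_sport"))
    if (flag %in% names(geno)) geno <- geno[!isTRUE_vec(geno[[flag]]), , drop = FALSE]
  if ("sex" %in% names(geno))
    geno <- geno[geno$sex %in% config$sex_groups, , drop = FALSE]
  note("cohort: %d read, %d retained after exclusions", n0, nrow(geno))
  if (nrow(geno) == 0L) stop("run error: empty cohort after exclusions", call. = FALSE)

  manifest <- utils::read.csv(config$trial_manifest, stringsAsFactors = FALSE)
  root <- dirname(config$trial_manifest)
  resolve <- function(p) ifelse(nzchar(p) & !grepl("^/", p), file.path(root, p), p)

  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rows[[i]] <- tryCatch({
      mk <- read_marker_tsv(resolve(m$marker_file))
      fp <- if (!is.na(m$force_file) && nzchar(m$force_file))
        read_forceplate_tsv(resolve(m$force_file)) else NULL
      mass <- geno$body_mass_kg[match(m$participant_id, geno$id)]
      if (is.na(mass)) stop("participant not in retained cohort")
      out <- trial_outcomes(mk, fp, trial_type = m$trial_type,
                            total_mass_kg = mass,
                            cutoff_hz = config$cutoff_hz,
                            threshold_n = config$threshold_n)
      note("trial %s/%s #%s: ok (phases computed)", m$participant_id,
           m$trial_type, m$trial_number)
      cbind(data.frame(participant_id = m$participant_id,
                       trial_number = m$trial_number,
                       stringsAsFactors = FALSE), out)
    }, error = function(e) {
      warning(sprintf("trial %s/%s #%s failed: %s", m$participant_id,
                      m$trial_type, m$trial_number, conditionMessage(e)),
              call. = FALSE)
      note("trial %s/%s #%s: FAILED (%s)", m$participant_id, m$trial_type,
           m$trial_number, conditionMessage(e))
      NULL
    })
  }
  per_trial <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_trial) || nrow(per_trial) == 0L)
    stop("run error: no trial produced outcomes", call. = FALSE)

  per_part <- aggregate_trials(per_trial, config$aggregation,
                               by = c("participant_id", "trial_type"))
  # reshape to one row per participant with per-type columns, then indices
  per_participant <- participant_outcomes(per_part)
  note("participants with outcomes: %d", nrow(per_participant))

  dat <- merge(per_participant, geno, by.x = "participant_id", by.y = "id")

  hwe <- do.call(rbind, lapply(config$loci, function(locus) {
    genos <- if (locus == "ace") ACE_GENOTYPES else ACTN3_GENOTYPES
    counts <- as.integer(table(factor(dat[[locus]], levels = genos)))
    h <- hwe_chi_square(counts)
    data.frame(locus = locus, n_hom1 = counts[1], n_het = counts[2],
               n_hom2 = counts[3], chi_square = h$chi_square, df = h$df,
               p_value = h$p_value, allele_freq = h$allele_freq,
               stringsAsFactors = FALSE)
  }))
  note("HWE tested for %d locus/loci", nrow(hwe))

  assoc <- list()
  for (oc in intersect(config$outcomes, names(dat))) {
    for (locus in config$loci) {
      res <- tryCatch(
        associate_outcome(dat, oc, locus, config$models),
        error = function(e) {
          note("association %s x %s skipped: %s", oc, locus, conditionMessage(e))
          NULL
        })
      if (!is.null(res)) assoc[[length(assoc) + 1L]] <- res
    }
  }
  association <- if (length(assoc)) rbind_fill(assoc) else
    data.frame(outcome = character(0), locus = character(0))

  paths <- list(
    per_trial = file.path(config$output_dir, "per_trial_outcomes.csv"),
    per_participant = file.path(config$output_dir, "per_participant_outcomes.csv"),
    hwe = file.path(config$output_dir, "hwe.csv"),
    association = file.path(config$output_dir, "association_results.csv"),
    log = file.path(config$output_dir, "run_log.txt")
  )
  write_results_table(per_trial, paths$per_trial)
  write_results_table(per_participant, paths$per_participant)
  write_results_table(hwe, paths$hwe)
  write_results_table(association, paths$association)
  writeLines(log_lines, paths$log)
  invisible(list(per_trial = per_trial, per_participant = per_participant,
                 hwe = hwe, association = association, log = log_lines,
                 paths = paths))
}

# rbind data frames whose column sets differ (per-locus genotype columns),
# filling absent cells with NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[cols]
  }))
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) x & !is.na(x)
  else tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

# wide per-participant table: per-jump-type columns + reactive indices
participant_outcomes <- function(per_part) {
  ids <- unique(per_part$participant_id)
  rows <- lapply(ids, function(pid) {
    sub <- per_part[per_part$participant_id == pid, , drop = FALSE]
    row <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
    pick <- function(type, col) {
      v <- sub[[col]][sub$trial_type == type]
      if (length(v)) v[1] else NA_real_
    }
    for (type in c("SJ", "CMJ", "DJ")) {
      for (col in c("jump_height_ft_m", "jump_height_marker_m", "hip_rt_peak",
                    "knee_rt_peak", "hip_power_peak", "knee_power_peak",
                    "rfd_n_per_s"))
        row[[paste0(tolower(type), "_", col)]] <- pick(type, col)
    }
    row$contact_time_s <- pick("DJ", "contact_time_s")
    row$sprint_time_s <- pick("SPRINT", "sprint_time_s")
    # headline torque/power outcomes: eccentric-phase peaks of the CMJ
    # (matching the conventional group comparison), plus reactive indices
    row$hip_rt_peak <- pick("CMJ", "hip_rt_peak")
    row$knee_rt_peak <- pick("CMJ", "knee_rt_peak")
    row$hip_power_peak <- pick("CMJ", "hip_power_peak")
    row$knee_power_peak <- pick("CMJ", "knee_power_peak")
    row$jump_height_ft_m <- pick("CMJ", "jump_height_ft_m")
    sj <- pick("SJ", "jump_height_ft_m")
    dj <- pick("DJ", "jump_height_ft_m")
    if (!is.na(sj) && !is.na(dj) && sj > 0 && !is.na(row$contact_time_s) &&
        row$contact_time_s > 0) {
      ri <- reactive_indices(dj, sj, row$contact_time_s)
      row$rsi <- ri$rsi
      row$ireaf <- ri$ireaf
      row$ssc_speed <- classify_ssc_speed(row$contact_time_s)
    } else {
      row$rsi <- NA_real_
      row$ireaf <- NA_real_
      row$ssc_speed <- NA_character_
    }
    row
  })
  do.call(rbind, rows)
}

# one outcome x locus association block -> one result row
associate_outcome <- function(dat, outcome, locus, models) {
  y <- dat[[outcome]]
  g <- dat[[locus]]
  an <- genotype_anova(y, g)
  mv <- tryCatch(model_variance_percent(y, g, locus, models),
                 error = function(e) NULL)
  genos <- if (locus == "ace") ACE_GENOTYPES else ACTN3_GENOTYPES
  # dominant grouping: carriers of the first allele vs variant homozygotes
  # (RR+RX vs XX; DD+ID vs II reverses which allele is grouped)
  grouping <- if (locus == "ace")
    factor(ifelse(g == "II", "II", "DD+ID"), levels = c("DD+ID", "II"))
  else
    factor(ifelse(g == "XX", "XX", "RR+RX"), levels = c("RR+RX", "XX"))
  tt <- tryCatch(dominant_group_ttest(y, grouping), error = function(e) NULL)
  lrt_dat <- data.frame(y = y,
                        code = code_genetic_model(g, genetic_model_coding("additive", locus)),
                        body_mass = dat$body_mass_kg, age = dat$age)
  lr <- tryCatch(lrt_covariate(lrt_dat, "y", c("code", "body_mass", "age"), "code"),
                 error = function(e) NULL)
  row <- data.frame(outcome = outcome, locus = locus,
                    f_statistic = an$f_statistic, anova_p = an$p_value,
                    eta_squared = an$eta_squared,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(an$groups))) {
    gk <- an$groups[k, ]
    row[[paste0("n_", gk$genotype)]] <- gk$n
    row[[paste0("mean_", gk$genotype)]] <- gk$mean
    row[[paste0("sd_", gk$genotype)]] <- gk$sd
  }
  if (!is.null(mv)) {
    for (k in seq_len(nrow(mv$table))) {
      mk <- mv$table[k, ]
      row[[paste0("r2_", mk$model)]] <- mk$r_squared
      row[[paste0("pct_", mk$model)]] <- mk$percent_of_anova
    }
    row$best_model <- mv$best_model
  }
  if (!is.null(tt)) {
    row$t_statistic <- tt$t_statistic
    row$t_p <- tt$p_value
    row$t_grouping <- paste(tt$grouping_levels, collapse = " vs ")
    row$ks_p_group1 <- tt$ks_p[1]
    row$ks_p_group2 <- tt$ks_p[2]
  }
  if (!is.null(lr)) {
    row$lr_statistic <- lr$lr_statistic
    row$lr_df <- lr$df
    row$lr_p <- lr$p_value
  }
  row
}

#' Write a complete synthetic study to disk
#'
#' Generates a genotyped cohort ([simulate_cohort()]) and, for each retained
#' participant, one simulated trial per requested type, written through the
#' package's own TSV writers together with the trial manifest. The embedded
#' genetic effect acts multiplicatively on each participant's jump vigour
#' (flight height), so torque/power outcomes inherit it through the full
#' biomechanical chain.
#'
#' @param dir output directory (created).
#' @param n_participants cohort size.
#' @param trial_types trial types generated per participant.
#' @param effect_locus,model,effect_size passed to [cohort_sim_config()];
#'   `effect_size` here scales flight height (m) per unit model code.
#' @param noise_sd marker jitter sd (m).
#' @param frequency sampling rate (Hz).
#' @param seed master seed; per-trial seeds derive from it.
#' @return list `manifest` (path), `genotype_csv` (path), `truth`.
#' @export
simulate_study <- function(dir, n_participants = 20,
                           trial_types = c("SJ", "CMJ", "DJ"),
                           effect_locus = "ace", model = "additive",
                           effect_size = 0, noise_sd = 0.001,
                           frequency = 200, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(cohort_sim_config(
    n = n_participants, effect_locus = if (effect_size != 0) effect_locus else "none",
    model = model, effect_size = 1, seed = seed))
  geno <- coh$genotypes
  geno_path <- file.path(dir, "genotypes.csv")
  write_genotype_table(geno, geno_path)

  coding <- genetic_model_coding(model, locus = effect_locus)
  codes <- code_genetic_model(geno[[effect_locus]], coding)

  manifest <- list()
  base_height <- 0.22
  # individual variability in jump vigour on top of the genetic shift
  h_vec <- withr::with_seed(seed + 1L,
    pmax(0.10, base_height + effect_size * codes +
           stats::rnorm(n_participants, 0, 0.02)))
  for (i in seq_len(n_participants)) {
    h_i <- h_vec[i]
    for (type in trial_types) {
      trial_seed <- (seed * 1000L + i * 10L +
                       match(type, c("SJ", "CMJ", "DJ", "SPRINT"))) %% .Machine$integer.max
      cfg <- jump_sim_config(type, target_flight_height = h_i,
                             countermovement_depth = if (type == "SJ") NULL else 0.30,
                             body_mass = geno$body_mass_kg[i],
                             frequency = frequency, noise_sd = noise_sd,
                             seed = trial_seed)
      sim <- simulate_jump_trial(cfg)
      mfile <- sprintf("%s_%s_markers.tsv", geno$id[i], type)
      ffile <- sprintf("%s_%s_force.tsv", geno$id[i], type)
      write_marker_tsv(sim$markers, file.path(dir, mfile))
      write_forceplate_tsv(sim$force, file.path(dir, ffile))
      manifest[[length(manifest) + 1L]] <- data.frame(
        participant_id = geno$id[i], trial_type = type, trial_number = 1L,
        marker_file = mfile, force_file = ffile, stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, manifest)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  list(manifest = man_path, genotype_csv = geno_path,
       truth = list(cohort = coh$truth, effect_locus = effect_locus,
                    model = model, effect_size = effect_size,
                    base_height = base_height, codes = codes))
}
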