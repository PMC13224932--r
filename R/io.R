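# Readers/writers for the tabular interchange formats and the analysis
# configuration. Longitudinal PK data use NONMEM column conventions
# (ID, TIME, AMT, RATE, DV, EVID + covariate columns); CSV with header row,
# UTF-8, period decimal separator, missing values as empty cells.

cov_map <- c(age = "AGE", weight = "WT", bsa = "BSA", crcl = "CRCL",
             kidney_mass = "KIDNEY_MASS", sex = "SEX", study = "STUDY",
             population = "POPULATION")

#' Write a PK dataset to a NONMEM-convention CSV
#'
#' Dose events become `EVID = 1` rows (AMT in GBq, RATE = AMT/duration, empty
#' DV); observations become `EVID = 0` rows (empty AMT/RATE). Baseline
#' covariates are repeated on every row; the GBq-to-amount conversion is
#' carried in a constant `AMTSCALE` column so the file round-trips.
#'
#' @param data A [pk_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  rows <- lapply(data$subjects$id, function(sid) {
    dos <- data$doses[data$doses$id == sid, ]
    obs <- data$observations[data$observations$id == sid, ]
    d <- tibble::tibble(ID = sid, TIME = dos$start_time, AMT = dos$amount,
                        RATE = dos$amount / dos$duration, DV = NA_real_,
                        EVID = 1L)
    o <- tibble::tibble(ID = sid, TIME = obs$time, AMT = NA_real_,
                        RATE = NA_real_, DV = obs$conc, EVID = 0L)
    x <- dplyr::bind_rows(d, o)
    x[order(x$TIME, -x$EVID), ]
  })
  out <- dplyr::bind_rows(rows)
  out$AMTSCALE <- data$amount_scale
  for (cv in names(cov_map)) {
    if (cv %in% names(data$subjects)) {
      out[[cov_map[[cv]]]] <-
        data$subjects[[cv]][match(out$ID, data$subjects$id)]
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a PK dataset from a NONMEM-convention CSV
#'
#' Mandatory columns: `ID`, `TIME`, `AMT`, `RATE` (or `DUR`), `DV`, `EVID`.
#' Dose rows (`EVID = 1`) become dose events; observation rows (`EVID = 0`)
#' become observations. Violations raise distinct, named conditions:
#' `io_missing_column`, `io_dv_on_dose_row`, `io_nonmonotone_time`,
#' `io_covariate_varies`.
#'
#' @param path CSV file path.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path) {
  ld_assert(file.exists(path), paste("file not found:", path), "io_file_missing")
  df <- as.data.frame(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE))
  need <- c("ID", "TIME", "AMT", "DV", "EVID")
  missing_cols <- setdiff(need, names(df))
  if (!any(c("RATE", "DUR") %in% names(df))) {
    missing_cols <- c(missing_cols, "RATE (or DUR)")
  }
  ld_assert(length(missing_cols) == 0L,
            paste("missing mandatory column(s):", paste(missing_cols, collapse = ", ")),
            "io_missing_column")
  dose_rows <- df$EVID == 1
  ld_assert(all(is.na(df$DV[dose_rows])),
            "DV present on a dose (EVID=1) row", "io_dv_on_dose_row")

  ids <- unique(df$ID)
  for (sid in ids) {
    tt <- df$TIME[df$ID == sid & df$EVID == 0]
    ld_assert(!is.unsorted(tt),
              sprintf("non-monotone observation times for subject %s", sid),
              "io_nonmonotone_time")
  }

  dur <- if ("DUR" %in% names(df)) df$DUR[dose_rows] else {
    df$AMT[dose_rows] / df$RATE[dose_rows]
  }
  doses <- tibble::tibble(id = df$ID[dose_rows], amount = df$AMT[dose_rows],
                          start_time = df$TIME[dose_rows], duration = dur)
  obs <- tibble::tibble(id = df$ID[!dose_rows], time = df$TIME[!dose_rows],
                        conc = df$DV[!dose_rows])

  subjects <- tibble::tibble(id = ids)
  present <- names(cov_map)[cov_map %in% names(df)]
  for (cv in present) {
    col <- df[[cov_map[[cv]]]]
    per <- tapply(col, df$ID, function(x) length(unique(x)))
    ld_assert(all(per == 1L),
              sprintf("covariate %s varies within subject", cov_map[[cv]]),
              "io_covariate_varies")
    subjects[[cv]] <- col[match(ids, df$ID)]
  }
  scale <- 1
  if ("AMTSCALE" %in% names(df)) {
    ld_assert(length(unique(df$AMTSCALE)) == 1L,
              "AMTSCALE varies within file", "io_covariate_varies")
    scale <- df$AMTSCALE[1]
  }
  pk_dataset(subjects, doses, obs, amount_scale = scale)
}

#' Write a dosimetry table
#'
#' Columns `ID`, `ORGAN`, `DOSE_GY`, `ACTIVITY_GBQ`, `CRCL`, `STUDY`,
#' `WEIGHT`: one row per subject per organ.
#'
#' @param records Dosimetry records tibble (see [fit_dosimetry()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosimetry_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  out <- tibble::tibble(ID = records$id, ORGAN = records$organ,
                        DOSE_GY = records$dose_gy,
                        ACTIVITY_GBQ = records$activity_gbq,
                        CRCL = records$crcl, STUDY = records$study,
                        WEIGHT = if ("weight" %in% names(records))
                          records$weight else NA_real_)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a dosimetry table
#'
#' Rejects duplicate subject-organ rows (`io_duplicate_record`): the design
#' carries exactly one dosimetry value per subject per organ.
#'
#' @param path CSV file path.
#' @return A tibble of dosimetry records.
#' @export
read_dosimetry_table <- function(path) {
  ld_assert(file.exists(path), paste("file not found:", path), "io_file_missing")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("ID", "ORGAN", "DOSE_GY", "ACTIVITY_GBQ", "CRCL", "STUDY")
  missing_cols <- setdiff(need, names(df))
  ld_assert(length(missing_cols) == 0L,
            paste("missing mandatory column(s):", paste(missing_cols, collapse = ", ")),
            "io_missing_column")
  ld_assert(!anyDuplicated(df[, c("ID", "ORGAN")]),
            "duplicate subject x organ rows", "io_duplicate_record")
  tibble::tibble(id = df$ID, organ = df$ORGAN, dose_gy = df$DOSE_GY,
                 activity_gbq = df$ACTIVITY_GBQ, crcl = df$CRCL,
                 study = df$STUDY,
                 weight = if ("WEIGHT" %in% names(df)) df$WEIGHT else NA_real_)
}

# ---------------------------------------------------------------------------
# Analysis configuration (YAML)
# ---------------------------------------------------------------------------

config_schema <- list(
  poppk = c("cl", "vc", "q", "vp", "omega_cl", "omega_vc", "rho", "sigma_add"),
  dosimetry = c("a_pop", "b_pop", "c_pop", "beta_study", "d_pop", "e_pop",
                "f_pop", "b1", "b2", "ref_activity", "ref_crcl"),
  grid = c("activities", "crcl_values", "n_subjects_per_cell", "n_cycles"),
  trial_design = c("n_per_trial", "n_trials", "activity_per_cycle", "n_cycles"),
  crcl_distribution = c("center", "spread", "lower", "upper"),
  thresholds = c("kidney", "bone_marrow"),
  cohorts = c("n_adult", "n_adolescent"),
  seed = NULL, output_dir = NULL, amount_scale = NULL,
  sampling_schedule = NULL)

expand_range <- function(x) {
  if (is.list(x) && all(c("from", "to", "by") %in% names(x))) {
    seq(x$from, x$to, by = x$by)
  } else {
    unlist(x)
  }
}

#' Read and validate an analysis configuration
#'
#' YAML configuration with blocks `poppk`, `dosimetry`, `grid`,
#' `trial_design`, `crcl_distribution`, `thresholds`, `cohorts` and scalars
#' `seed`, `output_dir`, `amount_scale`, `sampling_schedule`. Unknown keys —
#' at the top level or inside a block — are rejected with a named error
#' (`io_unknown_config_key`) before any stage runs; each block present is
#' converted to its typed object so invariants are checked up front. A fully
#' populated default reproducing the published settings ships with the
#' package: `system.file("extdata", "default_config.yaml", package =
#' "lutadosim")`.
#'
#' @param path YAML file path.
#' @return A named list of class `analysis_config` with typed components
#'   (`poppk` as [poppk_model()], `dosimetry` as [dosimetry_params()], ...).
#' @export
read_config <- function(path) {
  ld_assert(file.exists(path), paste("file not found:", path),
            "io_config_error")
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown) > 0L) {
    ld_abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
             c("io_unknown_config_key", "io_config_error"))
  }
  for (blk in names(raw)) {
    allowed <- config_schema[[blk]]
    if (!is.null(allowed)) {
      bad <- setdiff(names(raw[[blk]]), allowed)
      if (length(bad) > 0L) {
        ld_abort(sprintf("unknown key(s) in config block '%s': %s", blk,
                         paste(bad, collapse = ", ")),
                 c("io_unknown_config_key", "io_config_error"))
      }
    }
  }
  cfg <- list()
  if (!is.null(raw$poppk)) {
    p <- raw$poppk
    cfg$poppk <- poppk_model(pk_params(p$cl, p$vc, p$q, p$vp),
                             omega_cl = p$omega_cl %||% 0,
                             omega_vc = p$omega_vc %||% 0,
                             rho = p$rho %||% 0, sigma_add = p$sigma_add)
  }
  if (!is.null(raw$dosimetry)) {
    d <- raw$dosimetry
    cfg$dosimetry <- dosimetry_params(
      a_pop = d$a_pop, b_pop = d$b_pop, c_pop = d$c_pop,
      beta_study = d$beta_study %||% 0, d_pop = d$d_pop, e_pop = d$e_pop,
      f_pop = d$f_pop, b1 = d$b1, b2 = d$b2,
      ref_activity = d$ref_activity %||% 7.4, ref_crcl = d$ref_crcl %||% 99)
  }
  if (!is.null(raw$grid)) {
    g <- raw$grid
    cfg$grid <- scenario_grid(
      activities = expand_range(g$activities),
      crcl_values = expand_range(g$crcl_values),
      n_subjects_per_cell = g$n_subjects_per_cell %||% 500,
      n_cycles = g$n_cycles %||% 4)
  }
  if (!is.null(raw$trial_design)) {
    t <- raw$trial_design
    designs <- lapply(expand_range(t$n_per_trial), function(n) {
      trial_design(n, n_trials = t$n_trials %||% 500,
                   activity_per_cycle = t$activity_per_cycle %||% 7.4,
                   n_cycles = t$n_cycles %||% 4)
    })
    cfg$trial_design <- designs
  }
  if (!is.null(raw$crcl_distribution)) {
    d <- raw$crcl_distribution
    cfg$crcl_distribution <- crcl_distribution(
      center = d$center, spread = d$spread, lower = d$lower, upper = d$upper)
  }
  if (!is.null(raw$thresholds)) {
    cfg$thresholds <- lapply(raw$thresholds, unlist)
  }
  if (!is.null(raw$cohorts)) cfg$cohorts <- raw$cohorts
  cfg$seed <- raw$seed %||% 1L
  cfg$output_dir <- raw$output_dir %||% "."
  cfg$amount_scale <- raw$amount_scale %||% 27
  cfg$sampling_schedule <- unlist(raw$sampling_schedule) %||%
    default_sampling_schedule()
  structure(cfg, class = "analysis_config")
}
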