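# Longitudinal population PK dataset container.

#' Construct a population PK dataset
#'
#' Container tying together per-subject dose events, observation records and
#' baseline covariates, mirroring the longitudinal (NONMEM-convention) CSV
#' layout used by [read_pk_dataset()] / [write_pk_dataset()].
#'
#' @param subjects Tibble with one row per subject: `id` plus baseline
#'   covariates (any of `age`, `weight`, `bsa`, `crcl`, `kidney_mass`, `sex`,
#'   `study`, `population`).
#' @param doses Tibble with columns `id`, `amount`, `start_time`, `duration`.
#' @param observations Tibble with columns `id`, `time` and (optionally,
#'   `NA` for a simulation skeleton) `conc`.
#' @param amount_scale Scalar conversion from administered activity (GBq) to
#'   the mass-equivalent amount unit of the concentrations (see
#'   [predict_concentrations()]).
#'
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects, doses, observations, amount_scale = 1) {
  subjects <- tibble::as_tibble(subjects)
  doses <- tibble::as_tibble(doses)
  observations <- tibble::as_tibble(observations)
  ld_assert(all(c("id") %in% names(subjects)) &&
              all(c("id", "amount", "start_time", "duration") %in% names(doses)) &&
              all(c("id", "time") %in% names(observations)),
            "pk_dataset components are missing required columns",
            "pk_invalid_dataset")
  ld_assert(!anyDuplicated(subjects$id), "duplicate subject ids", "pk_invalid_dataset")
  ld_assert(all(doses$id %in% subjects$id) && all(observations$id %in% subjects$id),
            "dose/observation ids not present in subjects table", "pk_invalid_dataset")
  if (!"conc" %in% names(observations)) observations$conc <- NA_real_
  # every observation at or after the subject's first dose
  first_dose <- tapply(doses$start_time, doses$id, min)
  fd <- first_dose[as.character(observations$id)]
  ld_assert(all(is.na(fd) | observations$time >= fd),
            "observation before first dose", "pk_invalid_dataset")
  ok_sorted <- vapply(split(observations$time, observations$id),
                      function(t) !is.unsorted(t), logical(1))
  ld_assert(all(ok_sorted), "observation times not sorted within subject",
            "pk_invalid_dataset")
  structure(list(subjects = subjects, doses = doses,
                 observations = observations, amount_scale = amount_scale),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset> %d subjects, %d dose events, %d observations (amount_scale=%g)\n",
              nrow(x$subjects), nrow(x$doses), nrow(x$observations),
              x$amount_scale))
  invisible(x)
}

#' Number of subjects in a PK dataset
#' @param data A `pk_dataset`.
#' @export
n_subjects <- function(data) nrow(data$subjects)

# Flatten a pk_dataset into the per-subject list structure the compiled
# likelihood consumes (dose amounts pre-multiplied by amount_scale).
subject_list <- function(data, require_conc = TRUE) {
  lapply(data$subjects$id, function(sid) {
    obs <- data$observations[data$observations$id == sid, ]
    dos <- data$doses[data$doses$id == sid, ]
    if (require_conc && anyNA(obs$conc)) {
      ld_abort("dataset has missing concentrations", "pk_invalid_dataset")
    }
    list(times = as.numeric(obs$time), y = as.numeric(obs$conc),
         amt = as.numeric(dos$amount) * data$amount_scale,
         start = as.numeric(dos$start_time), dur = as.numeric(dos$duration))
  })
}
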