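#' Write a cohort as a long-format TAC table
#'
#' One row per subject, region and frame with columns `subject_id`, `group`,
#' `region`, `frame_start_s`, `frame_duration_s`, `activity_bq_ml`,
#' `injected_dose_mbq`, `mmse`, `cdr_sob`. Row order (subject, region,
#' frame) and float formatting (`%.17g`, round-trip safe) are deterministic,
#' so the same cohort always produces a byte-identical file.
#'
#' @param cohort a `"pet_cohort"` (an empty subject list writes the header
#'   only).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "pet_cohort"))
  cols <- c("subject_id", "group", "region", "frame_start_s",
            "frame_duration_s", "activity_bq_ml", "injected_dose_mbq",
            "mmse", "cdr_sob")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  for (s in cohort$subjects) {
    sch <- s$schedule
    for (rg in rownames(s$activity)) {
      lines <- paste(s$subject_id, s$group, rg,
                     num(sch$start), num(sch$duration),
                     num(s$activity[rg, ]), num(s$injected_dose),
                     num(rep(if (is.null(s$mmse)) NA_real_ else s$mmse,
                             length(sch$start))),
                     num(rep(if (is.null(s$cdr_sob)) NA_real_ else s$cdr_sob,
                             length(sch$start))),
                     sep = ",")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read a long-format TAC table into a cohort
#'
#' Accepts CSV or TSV (dialect sniffed from the header line). Schedules are
#' reconstructed per subject and validated: frames must start at 0 and be
#' contiguous with no gaps or overlaps, all regions of a subject must share
#' the schedule, and the injected dose must be consistent within a subject;
#' violations are rejected with the subject named, never repaired. Dose is
#' taken in MBq; a column named `injected_dose_mci` is converted (1 mCi =
#' 37 MBq).
#'
#' @param path CSV/TSV file with the columns written by [write_tac_table()].
#' @return A `"pet_cohort"` (without simulator ground truth).
#' @export
read_tac_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, fill = FALSE)
  dose_col <- intersect(c("injected_dose_mbq", "injected_dose_mci",
                          "injected_dose"), names(d))
  need <- c("subject_id", "group", "region", "frame_start_s",
            "frame_duration_s", "activity_bq_ml")
  miss <- setdiff(need, names(d))
  if (length(miss) || length(dose_col) == 0)
    stop("TAC table is missing column(s): ",
         paste(c(miss, if (length(dose_col) == 0) "injected_dose_mbq"),
               collapse = ", "))
  dose_col <- dose_col[1L]
  dose_factor <- if (dose_col == "injected_dose_mci") 37 else 1
  if (nrow(d) == 0)
    return(structure(list(subjects = list(), schedule = NULL, config = NULL,
                          ground_truth = NULL,
                          reference_region = "cerebellar_cortex"),
                     class = "pet_cohort"))
  ids <- unique(d$subject_id)
  subjects <- vector("list", length(ids))
  ref_schedule <- NULL
  for (i in seq_along(ids)) {
    ds <- d[d$subject_id == ids[i], , drop = FALSE]
    regions <- unique(ds$region)
    dose <- unique(ds[[dose_col]]) * dose_factor
    if (length(dose) != 1)
      stop(sprintf("subject '%s': inconsistent injected dose across rows", ids[i]))
    grp <- unique(ds$group)
    if (length(grp) != 1 || !grp %in% c("AD", "HC", "unknown"))
      stop(sprintf("subject '%s': group must be one consistent value of AD/HC/unknown",
                   ids[i]))
    sch <- NULL
    act <- NULL
    for (rg in regions) {
      dr <- ds[ds$region == rg, , drop = FALSE]
      dr <- dr[order(dr$frame_start_s), , drop = FALSE]
      sch_r <- tryCatch(frame_schedule(dr$frame_start_s, dr$frame_duration_s),
                        error = function(e)
                          stop(sprintf("subject '%s', region '%s': %s",
                                       ids[i], rg, conditionMessage(e)),
                               call. = FALSE))
      if (is.null(sch)) {
        sch <- sch_r
        act <- matrix(NA_real_, length(regions), length(sch$start),
                      dimnames = list(regions, NULL))
      } else if (!same_schedule(sch, sch_r)) {
        stop(sprintf("subject '%s': region '%s' has a different frame schedule",
                     ids[i], rg))
      }
      act[rg, ] <- dr$activity_bq_ml
    }
    if (anyNA(act))
      stop(sprintf("subject '%s': incomplete region x frame grid", ids[i]))
    if (is.null(ref_schedule)) ref_schedule <- sch
    mm <- if ("mmse" %in% names(ds)) ds$mmse[1L] else NA_real_
    cs <- if ("cdr_sob" %in% names(ds)) ds$cdr_sob[1L] else NA_real_
    subjects[[i]] <- structure(list(subject_id = ids[i], group = grp,
                                    schedule = sch, injected_dose = dose,
                                    activity = act, mmse = mm, cdr_sob = cs),
                               class = "pet_subject")
  }
  structure(list(subjects = subjects, schedule = ref_schedule, config = NULL,
                 ground_truth = NULL,
                 reference_region = "cerebellar_cortex"),
            class = "pet_cohort")
}

#' Write the simulator ground-truth table
#'
#' One row per subject and region with the true kinetic parameters
#' (`R1`, `k2`, `bpnd`) and `dvr_true = 1 + bpnd`.
#'
#' @param cohort a simulated `"pet_cohort"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "pet_cohort"))
  if (is.null(cohort$ground_truth))
    stop("cohort has no ground truth (not simulated)")
  gt <- cohort$ground_truth
  num <- function(v) if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(gt), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(gt, num), list(sep = ","))), con)
  invisible(path)
}

#' Read a run configuration file
#'
#' Reads a JSON or YAML configuration for the pipeline and validates it
#' strictly: unknown keys are rejected. Recognized keys are the arguments of
#' [cohort_config()] (scalar ones), plus `folds`, `n_test_ad`, `n_test_hc`
#' and `tune`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A named list of validated settings.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("n_ad", "n_hc", "r1_mean_ad", "r1_mean_hc", "r1_sd",
               "k1_ref", "k2_ref", "ref_scale_sd", "noise_level",
               "dose_range_mci", "mmse_intercept", "mmse_slope", "mmse_sd",
               "cdr_slope", "cdr_sd", "fine_step", "seed",
               "folds", "n_test_ad", "n_test_hc", "tune")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  bad <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) || is.logical(v), TRUE)]
  if (length(bad))
    stop("configuration key(s) must be numeric or logical: ",
         paste(bad, collapse = ", "))
  cfg
}
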