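# Cohort manifests and subject-level train/validation/test splitting.

#' Build and validate a cohort manifest
#'
#' A manifest has one row per scan session: subject id, session id, PMA at
#' scan in weeks, optional gestational age at birth, sex, and the path of the
#' label volume (may be `NA` in tabular-only mode).
#'
#' @param subject_id,session_id character vectors; the pair must be unique.
#' @param pma_weeks numeric PMA at scan, weeks.
#' @param birth_ga_weeks optional numeric gestational age at birth, weeks.
#' @param sex factor-like in `c("female", "male", "unknown")`.
#' @param volume_path character paths or `NA`.
#' @param pma_window plausibility window for `pma_weeks` (default 20-60).
#' @return data.frame of class `cohort_manifest`.
#' @export
cohort_manifest <- function(subject_id, session_id, pma_weeks,
                            birth_ga_weeks = NA_real_, sex = "unknown",
                            volume_path = NA_character_,
                            pma_window = c(20, 60)) {
  n <- length(subject_id)
  m <- data.frame(
    subject_id = as.character(subject_id),
    session_id = as.character(session_id),
    pma_weeks = as.numeric(pma_weeks),
    birth_ga_weeks = rep_len(as.numeric(birth_ga_weeks), n),
    sex = rep_len(as.character(sex), n),
    volume_path = rep_len(as.character(volume_path), n),
    stringsAsFactors = FALSE)
  key <- paste(m$subject_id, m$session_id, sep = "\r")
  if (anyDuplicated(key)) stopf("duplicate subject_id + session_id pairs")
  if (!all(m$sex %in% c("female", "male", "unknown"))) {
    stopf("sex must be one of female/male/unknown")
  }
  bad <- !is.na(m$pma_weeks) &
    (m$pma_weeks < pma_window[1] | m$pma_weeks > pma_window[2])
  if (any(bad) || anyNA(m$pma_weeks)) {
    stopf("pma_weeks outside plausible window [%g, %g] or missing",
          pma_window[1], pma_window[2])
  }
  class(m) <- c("cohort_manifest", "data.frame")
  m
}

#' Read / write a cohort manifest (TSV)
#'
#' @param path TSV file with the manifest columns.
#' @param pma_window passed to [cohort_manifest()].
#' @return a `cohort_manifest`.
#' @export
read_manifest <- function(path, pma_window = c(20, 60)) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character",
                                        session_id = "character"))
  need <- c("subject_id", "session_id", "pma_weeks")
  if (!all(need %in% names(d))) {
    stopf("manifest must contain columns: %s", paste(need, collapse = ", "))
  }
  cohort_manifest(d$subject_id, d$session_id, d$pma_weeks,
                  birth_ga_weeks = d$birth_ga_weeks %||% NA_real_,
                  sex = d$sex %||% "unknown",
                  volume_path = d$volume_path %||% NA_character_,
                  pma_window = pma_window)
}

#' @rdname read_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Split a cohort into train / validation / test at subject level
#'
#' Subjects (not sessions) are shuffled with the seeded generator, then
#' assigned subject-by-subject to the first partition (train, validation,
#' test in that order) whose session count is still below its target. With
#' single-session subjects the targets are met exactly; multi-session
#' subjects keep all their sessions in one partition, so counts can deviate
#' by at most the largest session count per subject.
#'
#' Targets for N total sessions and fractions (f_train, f_val, f_test):
#' n_train = floor(f_train N), n_val = round(f_val N),
#' n_test = N - n_train - n_val. For N = 558 at (0.60, 0.15, 0.25) this
#' gives the canonical 334 / 84 / 140.
#'
#' @param manifest a `cohort_manifest`.
#' @param fractions numeric length-3 (train, validation, test), summing to 1.
#' @param seed integer seed for the shuffle.
#' @return data.frame of class `split_assignment`: manifest keys plus a
#'   `partition` factor, with attributes `seed` and `fractions`.
#' @export
split_cohort <- function(manifest, fractions = c(0.60, 0.15, 0.25), seed = 0L) {
  if (nrow(manifest) == 0L) stopf("manifest is empty")
  if (length(fractions) != 3L || any(fractions < 0)) {
    stopf("fractions must be 3 non-negative numbers")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stopf("fractions must sum to 1")

  n_sessions <- nrow(manifest)
  n_train <- floor(fractions[1] * n_sessions)
  n_val <- round(fractions[2] * n_sessions)
  n_test <- n_sessions - n_train - n_val
  target <- c(train = n_train, validation = n_val, test = n_test)

  subjects <- unique(manifest$subject_id)
  order_idx <- with_seed(seed, sample.int(length(subjects)))
  shuffled <- subjects[order_idx]
  sess_per_subject <- table(manifest$subject_id)

  filled <- c(train = 0L, validation = 0L, test = 0L)
  assign_subject <- setNames(character(length(shuffled)), shuffled)
  for (s in shuffled) {
    k <- sess_per_subject[[s]]
    part <- names(target)[which(filled < target)[1]]
    if (is.na(part)) part <- "test"
    assign_subject[[s]] <- part
    filled[[part]] <- filled[[part]] + k
  }

  out <- data.frame(
    subject_id = manifest$subject_id,
    session_id = manifest$session_id,
    partition = factor(assign_subject[manifest$subject_id],
                       levels = c("train", "validation", "test")),
    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "fractions") <- fractions
  class(out) <- c("split_assignment", "data.frame")
  out
}
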