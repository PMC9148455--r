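#' Balanced two-group repeated-measures study design
#'
#' Builds the sample layout and fixed-effect design matrix for a two-group
#' longitudinal study with a fixed number of timepoints per subject. The model
#' is parameterised with reference coding: an intercept, a treatment-group
#' indicator, indicator columns for timepoints 2..T, and group-by-timepoint
#' interaction columns, so with four timepoints the coefficient vector is
#' (beta0, ..., beta7) on the natural-log scale.
#'
#' @param n_per_group Number of subjects in each of the two groups.
#' @param n_timepoints Observations per subject (default 4).
#' @param group_labels Character vector of length 2; the first label is the
#'   reference (control) group.
#'
#' @return An object of class `study_design`: a list with the per-sample
#'   metadata (`samples`), the design matrix (`X`), the subject factor
#'   (`subject`) and bookkeeping fields.
#' @export
#' @examples
#' des <- study_design(n_per_group = 3)
#' dim(des$X)  # 24 samples x 8 coefficients
study_design <- function(n_per_group, n_timepoints = 4,
                         group_labels = c("control", "treatment")) {
  stopifnot(n_per_group >= 1, n_timepoints >= 2, length(group_labels) == 2,
            !anyDuplicated(group_labels))
  n_subj <- 2L * n_per_group
  subject <- sprintf("S%03d", seq_len(n_subj))
  samples <- data.frame(
    sample  = paste0(rep(subject, each = n_timepoints), "_T",
                     rep(seq_len(n_timepoints), times = n_subj)),
    subject = rep(subject, each = n_timepoints),
    group   = rep(group_labels, each = n_per_group * n_timepoints),
    time    = rep(seq_len(n_timepoints), times = n_subj),
    stringsAsFactors = FALSE
  )
  new_study_design(samples, group_ref = group_labels[1])
}

#' Construct a study design from per-sample metadata
#'
#' Validates sample metadata (columns `sample`, `subject`, `group`, `time`)
#' and builds the reference-coded design matrix. The first group level
#' (alphabetically, unless `group_ref` is given) is the reference group and
#' the first timepoint is the reference timepoint.
#'
#' @param samples Data frame with columns `sample`, `subject`, `group`, `time`.
#' @param group_ref Optional reference group label.
#' @return A `study_design` object.
#' @export
new_study_design <- function(samples, group_ref = NULL) {
  required <- c("sample", "subject", "group", "time")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  samples <- as.data.frame(samples)[, required]
  samples$sample <- as.character(samples$sample)
  samples$subject <- as.character(samples$subject)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in metadata")
  ngrp <- tapply(samples$group, samples$subject, function(g) length(unique(g)))
  if (any(ngrp > 1))
    stop("subject(s) assigned to more than one group: ",
         paste(names(ngrp)[ngrp > 1], collapse = ", "))
  nt <- table(samples$subject)
  if (length(unique(nt)) != 1)
    stop("every subject must have the same number of samples; found counts ",
         paste(sort(unique(nt)), collapse = ", "))
  grp_levels <- sort(unique(samples$group))
  if (!is.null(group_ref)) {
    if (!group_ref %in% grp_levels) stop("unknown reference group: ", group_ref)
    grp_levels <- c(group_ref, setdiff(grp_levels, group_ref))
  }
  if (length(grp_levels) != 2)
    stop("the design requires exactly 2 groups; found ", length(grp_levels))
  group <- factor(samples$group, levels = grp_levels)
  time_levels <- sort(unique(samples$time))
  time <- factor(samples$time, levels = time_levels)
  subject <- factor(samples$subject, levels = unique(samples$subject))

  X <- stats::model.matrix(~ group * time)
  nT <- length(time_levels)
  colnames(X) <- c("(Intercept)", "group",
                   paste0("time", time_levels[-1]),
                   paste0("group:time", time_levels[-1]))
  rownames(X) <- samples$sample

  structure(list(
    samples = samples,
    X = X,
    subject = subject,
    n_timepoints = nT,
    n_subjects = nlevels(subject),
    group_levels = grp_levels,
    time_levels = time_levels,
    p = ncol(X)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", x$n_subjects, "subjects x", x$n_timepoints,
      "timepoints (", nrow(x$X), "samples ),", x$p, "coefficients\n")
  cat("  groups:", paste(x$group_levels, collapse = " / "),
      "(reference =", x$group_levels[1], ")\n")
  invisible(x)
}

## Normalise the `design` argument of the per-gene fitters: either a full
## study_design or a bare list(X=, subject=) for toy problems.
fit_inputs <- function(design) {
  if (inherits(design, "study_design")) {
    list(X = design$X, subject = design$subject)
  } else if (is.list(design) && !is.null(design$X) && !is.null(design$subject)) {
    X <- as.matrix(design$X)
    if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)) - 1L)
    list(X = X, subject = droplevels(as.factor(design$subject)))
  } else {
    stop("`design` must be a study_design or a list with elements X and subject")
  }
}
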