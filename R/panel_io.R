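#' IgE component panels
#'
#' A panel is a tibble holding one follow-up's component-resolved IgE
#' measurements: one row per subject, a `subject_id` column first, and one
#' numeric column per allergen component, in ISAC standardized units (ISU).
#' A subject absent at a follow-up is simply absent from the panel (never
#' imputed as zero); a subject present in the table but unmeasured must have
#' a fully missing row.
#'
#' @param data a data frame whose first column is the subject identifier and
#'   whose remaining columns are non-negative numeric ISU values.
#' @param age_label time point label (years), stored as an attribute.
#' @return a `quant_panel` tibble.
#' @export
quant_panel <- function(data, age_label = NULL) {
  data <- tibble::as_tibble(data)
  if (ncol(data) < 2) {
    stop("a panel needs a subject-ID column plus at least one component column")
  }
  names(data)[1] <- "subject_id"
  data$subject_id <- as.character(data$subject_id)
  dup_s <- unique(data$subject_id[duplicated(data$subject_id)])
  if (length(dup_s) > 0) {
    stop("duplicated subject IDs: ", paste(dup_s, collapse = ", "))
  }
  comp <- names(data)[-1]
  dup_c <- unique(comp[duplicated(comp)])
  if (length(dup_c) > 0) {
    stop("duplicated component names: ", paste(dup_c, collapse = ", "))
  }
  vals <- as.matrix(data[-1])
  if (!is.numeric(vals)) stop("component columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative ISU values are not allowed")
  }
  n_na <- rowSums(is.na(vals))
  partial <- n_na > 0 & n_na < ncol(vals)
  if (any(partial)) {
    stop(
      "missing values must cover whole subject rows; partial rows for: ",
      paste(head(data$subject_id[partial], 5), collapse = ", ")
    )
  }
  structure(data,
    class = c("quant_panel", class(tibble::tibble())),
    age_label = age_label
  )
}

#' Read a delimited IgE panel
#'
#' Reads a comma- or tab-delimited text file (auto-detected from the header
#' line) with a header of component names and the subject identifier in the
#' first column.
#'
#' @param path file path.
#' @param age_label optional time point label (years).
#' @return a [quant_panel()] tibble with axes in file order.
#' @export
read_panel <- function(path, age_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  fields <- strsplit(header, delim, fixed = TRUE)[[1]]
  dup_h <- unique(fields[duplicated(fields)])
  if (length(dup_h) > 0) {
    stop("duplicated component names in header: ", paste(dup_h, collapse = ", "))
  }
  df <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, col_types = readr::cols()
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(
      "malformed rows at line(s) ",
      paste(unique(probs$row), collapse = ", "), " of ", path
    )
  }
  quant_panel(df, age_label = age_label)
}

#' Write a panel to delimited text
#'
#' Comma-delimited unless the path ends in `.tsv`/`.tab`. Reading the file
#' back with [read_panel()] reproduces the panel cell for cell.
#'
#' @param panel a quant or binary panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- tibble::as_tibble(unclass_panel(panel))
  if (grepl("\\.(tsv|tab)$", path)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

unclass_panel <- function(panel) {
  class(panel) <- setdiff(class(panel), c("quant_panel", "binary_panel"))
  panel
}

#' Panel value matrix
#'
#' @param panel a panel tibble.
#' @return numeric matrix, subjects as rownames, components as colnames.
#' @export
panel_matrix <- function(panel) {
  m <- as.matrix(panel[-1])
  rownames(m) <- panel$subject_id
  m
}

#' Age label of a panel
#' @param panel a panel tibble.
#' @return the stored age label (or `NULL`).
#' @export
age_label <- function(panel) attr(panel, "age_label")

#' Binarize an ISU panel at a positivity threshold
#'
#' A measurement is called positive when it reaches the threshold
#' (inclusive); the conventional ISAC cutoff of 0.30 ISU is the default.
#' Missing subject rows stay missing.
#'
#' @param panel a [quant_panel()].
#' @param threshold positivity cutoff in ISU, `> 0`.
#' @return a `binary_panel` tibble of 0/1 values with the threshold recorded
#'   in the `threshold_used` attribute.
#' @export
binarize_panel <- function(panel, threshold = 0.30) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  vals <- panel_matrix(panel)
  bin <- matrix(as.integer(vals >= threshold), nrow(vals), ncol(vals),
    dimnames = dimnames(vals)
  )
  out <- tibble::as_tibble(bin)
  out <- tibble::add_column(out, subject_id = panel$subject_id, .before = 1)
  structure(out,
    class = c("binary_panel", class(tibble::tibble())),
    age_label = attr(panel, "age_label"),
    threshold_used = threshold
  )
}

#' Active components of a binary panel
#'
#' A component is active at a time point when at least `min_positive`
#' subjects respond to it there; counting uses present subjects only.
#'
#' @param panel a binary panel.
#' @param min_positive minimum number of positive responders (default 3).
#' @return character vector of active component names, in panel order.
#' @export
active_components <- function(panel, min_positive = 3) {
  vals <- panel_matrix(panel)
  colnames(vals)[colSums(vals, na.rm = TRUE) >= min_positive]
}

#' Responder subjects of a binary panel
#'
#' Subjects positive to at least one active component; the complement among
#' present subjects is the candidate nonsensitized group at that age.
#'
#' @param panel a binary panel.
#' @param active character vector of active components (subset of the
#'   panel's components); typically [active_components()].
#' @return character vector of subject IDs.
#' @export
responder_subjects <- function(panel, active) {
  comp <- names(panel)[-1]
  if (!all(active %in% comp)) {
    stop("active set contains components absent from the panel")
  }
  if (length(active) == 0) {
    warning("empty active set: no responders")
    return(character(0))
  }
  vals <- panel_matrix(panel)[, active, drop = FALSE]
  panel$subject_id[rowSums(vals, na.rm = TRUE) >= 1]
}

panel_ages <- function(panels) {
  ages <- names(panels)
  if (is.null(ages) || any(!nzchar(ages))) {
    ages <- vapply(panels, function(p) {
      al <- attr(p, "age_label")
      if (is.null(al)) NA_character_ else as.character(al)
    }, character(1))
  }
  num <- suppressWarnings(as.numeric(ages))
  if (any(is.na(num))) stop("panels must carry numeric age labels (list names or age_label)")
  if (any(diff(num) <= 0)) stop("ages must be strictly increasing")
  num
}

#' Component activity timeline across ages
#'
#' Tracks, for every component ever seen, whether it is active at each age,
#' when it first became active, and where it dropped out (became inactive
#' after having been active earlier — not necessarily permanently; a
#' component may re-activate later).
#'
#' @param panels list of binary panels in age order; names (or `age_label`
#'   attributes) give the ages in years.
#' @param min_positive activity rule (default 3 positive responders).
#' @return an `activity_timeline` tibble with one row per component per age:
#'   `component_id`, `age`, `status` (`active`, `inactive` or
#'   `never-active`), `first_active_age`, `dropout` and `dropout_cause`
#'   (`NA` until [classify_dropout_cause()] fills it).
#' @export
build_activity_timeline <- function(panels, min_positive = 3) {
  ages <- panel_ages(panels)
  universe <- unique(unlist(lapply(panels, function(p) names(p)[-1])))
  act <- vapply(panels, function(p) {
    a <- active_components(p, min_positive)
    universe %in% a
  }, logical(length(universe)))
  act <- matrix(act, nrow = length(universe), dimnames = list(universe, ages))

  ever <- rowSums(act) > 0
  first_age <- unname(apply(
    act, 1, function(r) if (any(r)) ages[which(r)[1]] else NA_real_
  ))

  tl <- tidyr::expand_grid(component_id = universe, age = ages)
  tl$active <- as.vector(t(act))
  tl$first_active_age <- rep(first_age, each = length(ages))
  tl$status <- dplyr::case_when(
    tl$active ~ "active",
    rep(!ever, each = length(ages)) ~ "never-active",
    TRUE ~ "inactive"
  )
  # dropout: active at the previous measured age, inactive now
  prev_active <- as.vector(t(cbind(FALSE, act[, -ncol(act), drop = FALSE])))
  tl$dropout <- !tl$active & prev_active
  if (length(panels) < 2) tl$dropout <- FALSE
  tl$dropout_cause <- ifelse(tl$dropout, "undetermined", NA_character_)
  structure(tl,
    class = c("activity_timeline", class(tibble::tibble())),
    ages = ages, min_positive = min_positive
  )
}

#' Classify each component drop-out as resolution or attrition
#'
#' A drop-out is traced back to the subjects who were positive at the
#' previous (active) age: if all of them are still present and now negative,
#' sensitization resolved; if all of them are absent from the follow-up, the
#' drop-out reflects attrition; any mixture (or subjects present but
#' unmeasured) is left undetermined.
#'
#' @param timeline an [build_activity_timeline()] result.
#' @param panels the same list of binary panels the timeline was built from.
#' @return the timeline with `dropout_cause` filled in
#'   (`resolution`, `attrition` or `undetermined`).
#' @export
classify_dropout_cause <- function(timeline, panels) {
  ages <- attr(timeline, "ages")
  if (!identical(ages, panel_ages(panels))) {
    stop("timeline and panels cover different ages")
  }
  mats <- lapply(panels, panel_matrix)
  idx <- which(timeline$dropout)
  for (r in idx) {
    comp <- timeline$component_id[r]
    t_at <- match(timeline$age[r], ages)
    t_prev <- t_at - 1L
    prev <- mats[[t_prev]]
    if (!comp %in% colnames(prev)) next
    pos_subj <- rownames(prev)[!is.na(prev[, comp]) & prev[, comp] == 1]
    if (length(pos_subj) == 0) next
    now <- mats[[t_at]]
    present <- pos_subj[pos_subj %in% rownames(now)]
    if (length(present) == 0) {
      timeline$dropout_cause[r] <- "attrition"
    } else if (length(present) == length(pos_subj) && comp %in% colnames(now)) {
      vals <- now[present, comp]
      if (all(!is.na(vals)) && all(vals == 0)) {
        timeline$dropout_cause[r] <- "resolution"
      } else {
        timeline$dropout_cause[r] <- "undetermined"
      }
    } else {
      timeline$dropout_cause[r] <- "undetermined"
    }
  }
  timeline
}

#' Per-component activity summary
#'
#' @param timeline an [build_activity_timeline()] result.
#' @return one row per component: first active age, number of active ages,
#'   drop-out ages (list column) and whether the component stayed active
#'   once it first became so.
#' @export
activity_summary <- function(timeline) {
  timeline |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$component_id) |>
    dplyr::summarise(
      first_active_age = .data$first_active_age[1],
      n_active_ages = sum(.data$active),
      dropout_ages = list(.data$age[.data$dropout]),
      persistent = {
        f <- .data$first_active_age[1]
        if (is.na(f)) NA else all(.data$active[.data$age >= f])
      },
      .groups = "drop"
    )
}

#' Percentage, rounded half-up to two decimals
#'
#' The printing convention of cohort demographic tables: `100 * n / d`,
#' round half away from zero, two decimal places.
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`. Vectorized.
#' @return numeric percentage(s).
#' @export
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  z <- 100 * numerator / denominator
  floor(z * 100 + 0.5 + 1e-9) / 100
}

#' Compare two groups on a 2 x 2 contingency table
#'
#' Chi-square test with continuity correction by default, switching to
#' Fisher's exact test when any expected cell count is below 5 (the common
#' small-sample rule). A degenerate table (a zero row or column margin)
#' carries no evidence of association and returns p = 1 with a warning.
#'
#' @param table 2 x 2 matrix of non-negative integer counts
#'   (groups x outcome).
#' @return one-row tibble: `method`, `statistic` (chi-square statistic, or
#'   the sample odds ratio for the exact test), `p_value`.
#' @export
compare_groups <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: no association testable")
    return(tibble::tibble(
      method = "degenerate", statistic = NA_real_, p_value = 1
    ))
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    ft <- fisher.test(table)
    tibble::tibble(
      method = "fisher", statistic = unname(ft$estimate), p_value = ft$p.value
    )
  } else {
    ct <- suppressWarnings(chisq.test(table, correct = TRUE))
    tibble::tibble(
      method = "chisq", statistic = unname(ct$statistic), p_value = ct$p.value
    )
  }
}
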