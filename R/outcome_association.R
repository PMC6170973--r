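#' Derive current asthma from its three defining features
#'
#' Current asthma holds when any 2 of the 3 features hold: current wheeze,
#' current use of asthma medication, physician-diagnosed asthma ever. Any
#' missing feature makes the outcome missing.
#'
#' @param wheeze,medication,diagnosis logical vectors.
#' @return logical vector.
#' @export
derive_asthma <- function(wheeze, medication, diagnosis) {
  s <- as.integer(wheeze) + as.integer(medication) + as.integer(diagnosis)
  out <- s >= 2L
  out[is.na(wheeze) | is.na(medication) | is.na(diagnosis)] <- NA
  out
}

#' Subject-level cluster sensitization profiles
#'
#' A subject is sensitized to a cluster when positive to at least one of its
#' member components; subjects positive to no active component form the
#' nonsensitized group.
#'
#' @param panel a binary panel.
#' @param clustering tibble with `component_id`, `cluster` covering the
#'   active set.
#' @param active character vector of active components (defaults to the
#'   clustered components).
#' @return tibble: `subject_id`, one logical `cluster_k` column per
#'   cluster, `nonsensitized`.
#' @export
build_profiles <- function(panel, clustering, active = clustering$component_id) {
  if (!all(active %in% clustering$component_id)) {
    stop("clustering must cover the active set")
  }
  vals <- panel_matrix(panel)
  missing_comp <- setdiff(active, colnames(vals))
  if (length(missing_comp) > 0) {
    stop("panel lacks active components: ", paste(missing_comp, collapse = ", "))
  }
  vals <- vals[, active, drop = FALSE]
  complete <- rowSums(is.na(vals)) == 0
  if (any(!complete)) {
    message("dropping ", sum(!complete), " unmeasured subject(s) from profiles")
    vals <- vals[complete, , drop = FALSE]
  }
  clusters <- sort(unique(clustering$cluster))
  out <- tibble::tibble(subject_id = rownames(vals))
  for (k in clusters) {
    members <- intersect(
      clustering$component_id[clustering$cluster == k], active
    )
    out[[paste0("cluster_", k)]] <-
      rowSums(vals[, members, drop = FALSE]) >= 1
  }
  out$nonsensitized <- rowSums(vals) == 0
  out
}

clean_or_result <- function(outcome_name, exposure_name, model,
                            or, lo, hi, p, n, flag) {
  tibble::tibble(
    outcome = outcome_name, exposure = exposure_name, model = model,
    or = or, ci_low = lo, ci_high = hi, p_value = p, n = n, flag = flag
  )
}

#' Univariable odds ratio for a binary exposure
#'
#' Logistic regression of the outcome on a single indicator; the odds ratio
#' is the exponentiated coefficient with a Wald 95% CI. For a binary
#' exposure this equals the 2 x 2 cross-product ratio. Complete separation
#' (an empty cell) is flagged and the unbounded estimate reported without
#' crashing.
#'
#' @param outcome,exposure logical (or 0/1) vectors; missing pairs are
#'   dropped (complete-case).
#' @param outcome_name,exposure_name labels carried into the result.
#' @return one-row tibble: `outcome`, `exposure`, `model`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `n`, `flag`.
#' @export
univariable_or <- function(outcome, exposure,
                           outcome_name = "outcome",
                           exposure_name = "exposure") {
  keep <- !is.na(outcome) & !is.na(exposure)
  y <- as.integer(outcome[keep])
  x <- as.integer(exposure[keep])
  n <- length(y)
  if (length(unique(x)) < 2) {
    return(clean_or_result(
      outcome_name, exposure_name, "univariable",
      NA_real_, NA_real_, NA_real_, NA_real_, n, "degenerate_exposure"
    ))
  }
  cells <- c(
    sum(y == 1 & x == 1), sum(y == 0 & x == 1),
    sum(y == 1 & x == 0), sum(y == 0 & x == 0)
  )
  if (any(cells == 0)) {
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    return(clean_or_result(
      outcome_name, exposure_name, "univariable",
      or, NA_real_, NA_real_, NA_real_, n, "separation"
    ))
  }
  fit <- glm(y ~ x, family = binomial())
  est <- coef(fit)[["x"]]
  se <- sqrt(vcov(fit)["x", "x"])
  clean_or_result(
    outcome_name, exposure_name, "univariable",
    exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
    2 * stats::pnorm(-abs(est / se)), n, ""
  )
}

#' Adjusted odds ratios from one joint logistic model
#'
#' All cluster indicators enter a single multiple logistic regression; one
#' adjusted OR per indicator with Wald 95% CIs. Degenerate (constant)
#' columns and aliased (collinear) terms are flagged; non-convergence and
#' separation are flagged on every term they affect.
#'
#' @param outcome logical (or 0/1) vector.
#' @param profile data frame of logical/0-1 exposure indicators (e.g. the
#'   `cluster_*` columns of [build_profiles()]).
#' @param outcome_name label carried into the results.
#' @return tibble, one row per indicator, same columns as
#'   [univariable_or()] with `model = "multiple"`.
#' @export
multiple_or <- function(outcome, profile, outcome_name = "outcome") {
  profile <- as.data.frame(lapply(profile, as.integer))
  keep <- !is.na(outcome) & complete.cases(profile)
  y <- as.integer(outcome[keep])
  X <- profile[keep, , drop = FALSE]
  n <- length(y)
  degenerate <- vapply(X, function(col) length(unique(col)) < 2, logical(1))
  out_deg <- purrr::map(names(X)[degenerate], function(nm) {
    clean_or_result(
      outcome_name, nm, "multiple",
      NA_real_, NA_real_, NA_real_, NA_real_, n, "degenerate_exposure"
    )
  })
  Xf <- X[!degenerate]
  if (ncol(Xf) == 0) {
    return(purrr::list_rbind(out_deg))
  }
  dat <- cbind(y = y, Xf)
  fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = dat))
  converged <- fit$converged
  separated <- any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8)
  aliased <- is.na(coef(fit))
  V <- vcov(fit)
  out_fit <- purrr::map(names(Xf), function(nm) {
    if (isTRUE(aliased[[nm]])) {
      return(clean_or_result(
        outcome_name, nm, "multiple",
        NA_real_, NA_real_, NA_real_, NA_real_, n, "aliased"
      ))
    }
    est <- coef(fit)[[nm]]
    se <- sqrt(V[nm, nm])
    flag <- paste(c(
      if (!converged) "nonconvergence",
      if (separated || se > 1e2) "separation"
    ), collapse = ";")
    clean_or_result(
      outcome_name, nm, "multiple",
      exp(est), exp(est - 1.96 * se), exp(est + 1.96 * se),
      2 * stats::pnorm(-abs(est / se)), n, flag
    )
  })
  purrr::list_rbind(c(out_fit, out_deg))
}

#' Associate cluster sensitization with outcomes
#'
#' Convenience wrapper joining profiles and outcomes by `subject_id` and
#' fitting the univariable model per cluster and/or the joint multiple
#' model.
#'
#' @param profiles a [build_profiles()] result.
#' @param outcomes tibble with `subject_id` and logical outcome columns.
#' @param outcome_cols outcome column names to model.
#' @param models any of `"univariable"`, `"multiple"`.
#' @return an `association_result` tibble (rows from [univariable_or()] /
#'   [multiple_or()]).
#' @export
associate_clusters <- function(profiles, outcomes, outcome_cols,
                               models = c("univariable", "multiple")) {
  models <- match.arg(models, several.ok = TRUE)
  dat <- dplyr::inner_join(profiles, outcomes, by = "subject_id")
  cluster_cols <- grep("^cluster_", names(profiles), value = TRUE)
  res <- purrr::map(outcome_cols, function(oc) {
    y <- dat[[oc]]
    parts <- list()
    if ("univariable" %in% models) {
      parts$uni <- purrr::list_rbind(purrr::map(cluster_cols, function(cc) {
        univariable_or(y, dat[[cc]], outcome_name = oc, exposure_name = cc)
      }))
    }
    if ("multiple" %in% models) {
      parts$multi <- multiple_or(y, dat[cluster_cols], outcome_name = oc)
    }
    purrr::list_rbind(parts)
  })
  out <- purrr::list_rbind(res)
  structure(out, class = c("association_result", class(tibble::tibble())))
}

#' Cross-age sensitization confusion matrix
#'
#' Counts, over the subjects measured at both ages, how many were sensitized
#' to cluster A at the first age and to cluster B at the second (subjects
#' may contribute to several cells).
#'
#' @param profiles_t1,profiles_t2 [build_profiles()] results at two ages.
#' @return integer matrix, clusters at t1 x clusters at t2.
#' @export
cross_age_confusion <- function(profiles_t1, profiles_t2) {
  shared <- intersect(profiles_t1$subject_id, profiles_t2$subject_id)
  c1 <- grep("^cluster_", names(profiles_t1), value = TRUE)
  c2 <- grep("^cluster_", names(profiles_t2), value = TRUE)
  if (length(shared) == 0) {
    warning("no subjects measured at both ages")
    return(matrix(0L, length(c1), length(c2), dimnames = list(c1, c2)))
  }
  a <- as.matrix(profiles_t1[match(shared, profiles_t1$subject_id), c1])
  b <- as.matrix(profiles_t2[match(shared, profiles_t2$subject_id), c2])
  m <- t(a) %*% b
  storage.mode(m) <- "integer"
  dimnames(m) <- list(c1, c2)
  m
}
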