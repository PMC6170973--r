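#' Simulate one binary sensitization panel with planted cluster structure
#'
#' Plants exactly the generative model the clustering assumes: components
#' are partitioned into clusters, subjects into matching blocks, and cell
#' (i, j) is Bernoulli with probability `theta_in` when component i's
#' cluster matches subject j's block and `theta_out` otherwise. ISU values
#' are drawn so that thresholding at 0.30 inverts the generation exactly
#' (positives uniform on \[0.30, 15\], negatives uniform on \[0, 0.30)).
#'
#' @param n_components,n_subjects panel dimensions.
#' @param partition integer vector (length `n_components`) giving each
#'   component's planted cluster in `1..G`.
#' @param theta_in,theta_out within-block and out-of-block positivity
#'   probabilities, `0 <= theta_out < theta_in <= 1`.
#' @param seed RNG seed (`NULL` = current state).
#' @return list: `quant` ([quant_panel()]), `binary` (binary panel), and
#'   `truth` (`partition` tibble, `subject_block`, thetas).
#' @export
simulate_panel <- function(n_components, n_subjects, partition,
                           theta_in = 0.7, theta_out = 0.05, seed = NULL) {
  stopifnot(
    length(partition) == n_components,
    theta_out >= 0, theta_out < theta_in, theta_in <= 1
  )
  if (!is.null(seed)) set.seed(seed)
  G <- max(partition)
  comp_ids <- sprintf("C%03d", seq_len(n_components))
  subj_ids <- sprintf("S%04d", seq_len(n_subjects))
  block <- sort(rep_len(seq_len(G), n_subjects))
  p <- matrix(theta_out, n_components, n_subjects)
  for (g in seq_len(G)) {
    p[partition == g, block == g] <- theta_in
  }
  x <- matrix(
    rbinom(n_components * n_subjects, 1, p),
    n_components, n_subjects, dimnames = list(comp_ids, subj_ids)
  )
  isu <- matrix(
    ifelse(x == 1, runif(length(x), 0.30, 15), runif(length(x), 0, 0.30)),
    n_components, n_subjects, dimnames = dimnames(x)
  )
  quant <- quant_panel(
    tibble::as_tibble(t(isu), rownames = "subject_id")
  )
  list(
    quant = quant,
    binary = binarize_panel(quant, 0.30),
    truth = list(
      partition = tibble::tibble(component_id = comp_ids, cluster = partition),
      subject_block = setNames(block, subj_ids),
      theta_in = theta_in, theta_out = theta_out
    )
  )
}

#' Scenario specification for a longitudinal synthetic cohort
#'
#' Encodes the study conditions a longitudinal run emulates: ages and
#' per-age subject counts, a fixed component universe where each component
#' belongs to one protein family, a per-age activity schedule, per-age
#' clusters expressed as sets of families, response probabilities, and the
#' outcome model for the final age.
#'
#' @param name scenario name.
#' @param ages character vector of age labels (years), strictly increasing.
#' @param n_subjects per-age number of children seen.
#' @param roster_size total cohort size subjects are drawn from.
#' @param components tibble with `component_id` and `family`.
#' @param schedule logical matrix (component x age): scheduled activity.
#' @param clusters per-age list; each element is a list of family vectors,
#'   one per cluster, in cluster-index order.
#' @param theta_in positivity probability of a subject for components of
#'   the cluster containing the subject's own family.
#' @param theta_out positivity probability for other active components.
#' @param theta_none positivity probability of nonsensitized-type subjects.
#' @param theta_inactive positivity probability of scheduled-inactive
#'   components (default 0: the schedule realizes exactly).
#' @param type_probs named probabilities over subject types (families plus
#'   `"none"`).
#' @param outcome list: `asthma_baseline`, `asthma_logors`,
#'   `rhinitis_baseline`, `rhinitis_logors` (log odds ratios per final-age
#'   cluster index).
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name, ages, n_subjects, roster_size, components,
                          schedule, clusters,
                          theta_in = 0.7, theta_out = 0.05,
                          theta_none = theta_out, theta_inactive = 0,
                          type_probs, outcome) {
  stopifnot(
    length(ages) == length(n_subjects),
    nrow(components) == nrow(schedule),
    ncol(schedule) == length(ages),
    abs(sum(type_probs) - 1) < 1e-8
  )
  # every active component's family must sit in at most one cluster per age
  for (a in seq_along(ages)) {
    cl <- clusters[[a]]
    fams <- unlist(cl)
    dup <- unique(fams[duplicated(fams)])
    if (length(dup) > 0) {
      stop(
        "flow script inconsistent at age ", ages[a],
        ": family in several clusters: ", paste(dup, collapse = ", ")
      )
    }
    active_fam <- unique(components$family[schedule[, a]])
    orphan <- setdiff(active_fam, fams)
    if (length(orphan) > 0) {
      bad <- components$component_id[schedule[, a] &
        components$family %in% orphan]
      stop(
        "flow script inconsistent at age ", ages[a],
        ": active component(s) with no cluster: ",
        paste(head(bad, 5), collapse = ", ")
      )
    }
  }
  structure(
    list(
      name = name, ages = as.character(ages), n_subjects = n_subjects,
      roster_size = roster_size, components = components,
      schedule = schedule, clusters = clusters,
      theta_in = theta_in, theta_out = theta_out,
      theta_none = theta_none, theta_inactive = theta_inactive,
      type_probs = type_probs, outcome = outcome
    ),
    class = "scenario_spec"
  )
}

#' Well-separated single-age recovery scenario (S1)
#'
#' Four planted clusters over 70 components and 400 subjects at one time
#' point, `theta_in = 0.7`, `theta_out = 0.05`: the parameter-recovery
#' benchmark of the pipeline.
#'
#' @param theta_in override of the within-block probability (the hard-mode
#'   variant of this scenario uses 0.4).
#' @return a `scenario_spec`.
#' @export
scenario_s1 <- function(theta_in = 0.7) {
  sizes <- c(18, 18, 17, 17)
  fams <- rep(paste0("f", 1:4), sizes)
  comps <- tibble::tibble(
    component_id = sprintf("C%03d", seq_along(fams)),
    family = fams
  )
  scenario_spec(
    name = "s1",
    ages = "5", n_subjects = 400, roster_size = 400,
    components = comps,
    schedule = matrix(TRUE, nrow(comps), 1),
    clusters = list(list("f1", "f2", "f3", "f4")),
    theta_in = theta_in, theta_out = 0.05, theta_none = 0.05,
    type_probs = c(f1 = 0.25, f2 = 0.25, f3 = 0.25, f4 = 0.25),
    outcome = list(
      asthma_baseline = stats::qlogis(0.10),
      asthma_logors = c(log(3.5), 0, 0, 0),
      rhinitis_baseline = stats::qlogis(0.25),
      rhinitis_logors = c(0, log(2.0), 0, 0)
    )
  )
}

#' Hard-mode variant of the recovery scenario
#'
#' Same structure as [scenario_s1()] with weak separation
#' (`theta_in = 0.4`), for stress tests.
#' @return a `scenario_spec`.
#' @export
scenario_hard <- function() {
  sc <- scenario_s1(theta_in = 0.4)
  sc$name <- "hard"
  sc
}

#' Six-age scenario emulating the childhood sensitization architecture
#'
#' A 112-component universe followed at ages 1, 3, 5, 8, 11 and 16 years
#' whose activity schedule ramps through 10, 26, 63, 68, 71 and 72 active
#' components by construction, with the qualitative flow events of the
#' childhood IgE architecture planted: a broad cluster present throughout
#' (with drop-outs and re-activations), a four-component dust-mite cluster
#' persisting from age 3, a grass singleton absorbing further grass
#' components plus the cat component at age 5, a single-component
#' *Alternaria* cluster reabsorbed by the broad cluster at age 11, a cat
#' cluster splitting off at age 11, and a PR-10/profilin cluster forming at
#' age 11 and dividing at age 16.
#'
#' @return a `scenario_spec`.
#' @export
scenario_paperlike <- function() {
  ages <- c("1", "3", "5", "8", "11", "16")
  # broad-family groups with distinct activity schedules
  grp <- function(n, fam, act) {
    list(n = n, family = fam, active = act)
  }
  A <- function(...) as.logical(c(...))
  groups <- list(
    grp(10, "broad", A(1, 1, 1, 1, 1, 1)), # active from age 1
    grp(11, "broad", A(0, 1, 1, 1, 1, 1)), # from age 3
    grp(21, "broad", A(0, 0, 1, 1, 1, 1)), # from age 5, persistent
    grp(7, "broad", A(0, 0, 1, 0, 0, 0)), # drop out at 8, permanently
    grp(4, "broad", A(0, 0, 1, 0, 1, 1)), # drop out at 8, re-activate at 11
    grp(1, "broad", A(0, 0, 0, 1, 0, 0)), # drops out at 11
    grp(3, "broad", A(0, 0, 0, 1, 1, 1)), # from age 8
    grp(1, "broad", A(0, 0, 0, 0, 0, 1)), # newly active at 16
    grp(4, "hdm", A(0, 1, 1, 1, 1, 1)),
    grp(1, "grass", A(0, 1, 1, 1, 1, 1)), # Phl p 1-like
    grp(3, "grass", A(0, 0, 1, 1, 1, 1)),
    grp(1, "cat", A(0, 0, 1, 1, 1, 1)), # Fel d 1-like
    grp(1, "alt", A(0, 0, 1, 1, 1, 1)), # Alt a 1-like
    grp(2, "grass_late", A(0, 0, 0, 1, 1, 1)), # Phl p 2/6-like
    grp(6, "pr10", A(0, 0, 0, 1, 1, 1)),
    grp(4, "profilin", A(0, 0, 0, 1, 1, 1)),
    grp(32, "never", A(0, 0, 0, 0, 0, 0))
  )
  fams <- unlist(lapply(groups, function(g) rep(g$family, g$n)))
  sched <- do.call(rbind, lapply(groups, function(g) {
    matrix(g$active, g$n, length(ages), byrow = TRUE)
  }))
  comps <- tibble::tibble(
    component_id = sprintf("C%03d", seq_along(fams)),
    family = fams
  )
  clusters <- list(
    list("broad"),
    list("broad", "hdm", "grass"),
    list("broad", "hdm", c("grass", "cat"), "alt"),
    list(
      c("broad", "pr10", "profilin", "grass_late"), "hdm",
      c("grass", "cat"), "alt"
    ),
    list(
      c("broad", "alt"), "hdm", c("grass", "grass_late"), "cat",
      c("pr10", "profilin")
    ),
    list(
      c("broad", "alt"), "hdm", c("grass", "grass_late"), "cat",
      "pr10", "profilin"
    )
  )
  scenario_spec(
    name = "paperlike",
    ages = ages,
    n_subjects = c(226, 248, 588, 543, 461, 361),
    roster_size = 922,
    components = comps,
    schedule = sched,
    clusters = clusters,
    theta_in = 0.7, theta_out = 0.01, theta_none = 0.001,
    type_probs = c(
      broad = 0.20, hdm = 0.08, grass = 0.06, cat = 0.05, alt = 0.04,
      grass_late = 0.02, pr10 = 0.06, profilin = 0.04, none = 0.45
    ),
    outcome = list(
      asthma_baseline = stats::qlogis(0.08),
      asthma_logors = c(0, log(2.6), log(1.5), 0, 0, 0),
      rhinitis_baseline = stats::qlogis(0.30),
      rhinitis_logors = c(log(1.5), 0, log(1.5), 0, 0, log(5.0))
    )
  )
}

preset_scenario <- function(name) {
  switch(name,
    s1 = scenario_s1(),
    paperlike = scenario_paperlike(),
    hard = scenario_hard(),
    stop("unknown scenario preset: ", name)
  )
}

# per-age cluster index of each component's family (NA when not clustered)
family_cluster <- function(families, clusters_age) {
  idx <- rep(NA_integer_, length(families))
  for (k in seq_along(clusters_age)) {
    idx[families %in% clusters_age[[k]]] <- k
  }
  idx
}

#' Simulate a longitudinal synthetic cohort
#'
#' Realizes a [scenario_spec()]: per-age quantitative and binary panels
#' (subjects sampled from the roster, so some subjects are absent at some
#' ages), the planted per-age cluster memberships, the planted activity
#' timeline, and final-age outcomes generated from a logistic model on the
#' realized cluster-sensitization indicators. Regeneration with the same
#' scenario and seed is bit-identical.
#'
#' @param scenario a `scenario_spec`, or a preset name
#'   (`"s1"`, `"paperlike"`, `"hard"`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a `synthetic_cohort` list: `ages`, `panels_quant`,
#'   `panels_binary` (named lists), `memberships` (planted per-age
#'   clusterings), `subject_types`, `outcomes`, `scenario`, `seed`.
#' @export
simulate_longitudinal <- function(scenario, seed = 1L) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  set.seed(seed)
  sc <- scenario
  roster <- sprintf("S%04d", seq_len(sc$roster_size))
  types <- sample(names(sc$type_probs), sc$roster_size,
    replace = TRUE, prob = sc$type_probs
  )
  names(types) <- roster

  panels_quant <- list()
  panels_binary <- list()
  memberships <- list()
  for (a in seq_along(sc$ages)) {
    present <- sort(sample(roster, sc$n_subjects[a]))
    fam_cl <- family_cluster(sc$components$family, sc$clusters[[a]])
    subj_cl <- family_cluster(types[present], sc$clusters[[a]])
    nc <- nrow(sc$components)
    ns <- length(present)
    p <- matrix(sc$theta_out, nc, ns)
    p[, types[present] == "none"] <- sc$theta_none
    same <- outer(fam_cl, subj_cl, function(a_, b_) {
      !is.na(a_) & !is.na(b_) & a_ == b_
    })
    p[same] <- sc$theta_in
    p[!sc$schedule[, a], ] <- sc$theta_inactive
    x <- matrix(rbinom(nc * ns, 1, p), nc, ns,
      dimnames = list(sc$components$component_id, present)
    )
    isu <- matrix(
      ifelse(x == 1, runif(length(x), 0.30, 15), runif(length(x), 0, 0.30)),
      nc, ns, dimnames = dimnames(x)
    )
    quant <- quant_panel(
      tibble::as_tibble(t(isu), rownames = "subject_id"),
      age_label = sc$ages[a]
    )
    panels_quant[[sc$ages[a]]] <- quant
    panels_binary[[sc$ages[a]]] <- binarize_panel(quant, 0.30)
    memberships[[sc$ages[a]]] <- tibble::tibble(
      component_id = sc$components$component_id[sc$schedule[, a]],
      cluster = fam_cl[sc$schedule[, a]]
    )
  }

  final <- sc$ages[length(sc$ages)]
  profiles <- build_profiles(
    panels_binary[[final]], memberships[[final]]
  )
  outcomes <- simulate_outcomes(
    profiles,
    baseline_logodds = sc$outcome$asthma_baseline,
    cluster_logors = sc$outcome$asthma_logors,
    rhinitis_baseline = sc$outcome$rhinitis_baseline,
    rhinitis_logors = sc$outcome$rhinitis_logors
  )

  structure(
    list(
      ages = sc$ages,
      panels_quant = panels_quant,
      panels_binary = panels_binary,
      memberships = memberships,
      subject_types = types,
      outcomes = outcomes,
      scenario = sc,
      seed = seed
    ),
    class = "synthetic_cohort"
  )
}

#' Simulate questionnaire outcomes from cluster-sensitization profiles
#'
#' Asthma status is drawn from `Bernoulli(logistic(baseline + sum of
#' cluster indicators x log-ORs))`; the wheeze / medication / diagnosis
#' triple is then generated consistently with the any-2-of-3 rule (2 or 3
#' features when asthmatic, 0 or 1 otherwise), so the derived outcome
#' reproduces the drawn status exactly and its prevalence is controlled by
#' the logistic model. Rhinitis is drawn from its own logistic model.
#'
#' @param profiles a [build_profiles()] result (the `cluster_*` columns are
#'   the exposures, in column order).
#' @param baseline_logodds asthma baseline log-odds.
#' @param cluster_logors log odds ratios, one per cluster column (recycled
#'   if scalar).
#' @param rhinitis_baseline,rhinitis_logors same for rhinitis.
#' @param seed RNG seed (`NULL` = current state).
#' @return tibble: `subject_id`, `current_wheeze`, `asthma_medication`,
#'   `physician_asthma_ever`, `current_asthma`, `current_rhinitis`.
#' @export
simulate_outcomes <- function(profiles, baseline_logodds,
                              cluster_logors,
                              rhinitis_baseline = stats::qlogis(0.25),
                              rhinitis_logors = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cols <- grep("^cluster_", names(profiles), value = TRUE)
  X <- as.matrix(as.data.frame(lapply(profiles[cols], as.numeric)))
  bA <- rep_len(cluster_logors, length(cols))
  bR <- rep_len(rhinitis_logors, length(cols))
  n <- nrow(X)
  asthma <- rbinom(n, 1, plogis(baseline_logodds + drop(X %*% bA))) == 1
  rhinitis <- rbinom(n, 1, plogis(rhinitis_baseline + drop(X %*% bR))) == 1

  # feature triple consistent with the 2-of-3 rule
  wheeze <- med <- dx <- logical(n)
  n_feat <- integer(n)
  n_feat[asthma] <- 2L + rbinom(sum(asthma), 1, 0.6)
  n_feat[!asthma] <- rbinom(sum(!asthma), 1, 0.3)
  which_feat <- matrix(FALSE, n, 3)
  for (i in seq_len(n)) {
    if (n_feat[i] > 0) {
      which_feat[i, sample.int(3, n_feat[i])] <- TRUE
    }
  }
  tibble::tibble(
    subject_id = profiles$subject_id,
    current_wheeze = which_feat[, 1],
    asthma_medication = which_feat[, 2],
    physician_asthma_ever = which_feat[, 3],
    current_asthma = derive_asthma(
      which_feat[, 1], which_feat[, 2], which_feat[, 3]
    ),
    current_rhinitis = rhinitis
  )
}
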