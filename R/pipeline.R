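#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the whole per-age analysis — binarize, activity/drop-out
#' annotation, restrict to active components and responders, fit the
#' Bernoulli mixture per age, select K*, relabel with ECR, build the flow
#' graph and membership timeline, and (when outcomes are supplied) the
#' association models — writing every table to `out_dir` together with a
#' manifest (config, seed, package version, input checksums). Stage outputs
#' are pure functions of (inputs, config, seed): re-running the same
#' configuration reproduces byte-identical tables.
#'
#' @param config a named list or the path of a YAML file. Fields:
#'   `panels` (named list age -> delimited-text path) or `cohort` (an
#'   in-memory [simulate_longitudinal()] result); `threshold` (default
#'   0.30); `min_positive` (default 3); `mixture` (arguments for
#'   [mixture_config()]); `mixture_per_age` (named list of per-age
#'   overrides, e.g. a different `Kmax`); `outcomes` (path or tibble with
#'   `subject_id` and outcome columns); `outcome_cols`; `profile_ages`
#'   (ages whose profiles enter the association models; default the last
#'   age); `models` (default univariable and multiple); `out_dir`; `seed`.
#' @return (invisibly) a `pipeline_run` list with every intermediate
#'   object and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(
    list(
      threshold = 0.30, min_positive = 3, mixture = list(),
      mixture_per_age = list(), outcomes = NULL, outcome_cols = NULL,
      profile_ages = NULL, models = c("univariable", "multiple"),
      out_dir = NULL, seed = 1L
    ),
    config
  )
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  checksums <- character(0)
  quant <- stage("read", {
    if (!is.null(cfg$cohort)) {
      cfg$cohort$panels_quant
    } else {
      paths <- unlist(cfg$panels)
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0) {
        stop("missing input file(s): ", paste(missing, collapse = ", "))
      }
      checksums <<- tools::md5sum(paths)
      out <- lapply(names(cfg$panels), function(a) {
        read_panel(cfg$panels[[a]], age_label = a)
      })
      names(out) <- names(cfg$panels)
      out
    }
  })
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  binary <- stage("binarize", {
    lapply(quant, binarize_panel, threshold = cfg$threshold)
  })
  ages <- names(binary)

  timeline <- stage("activity", {
    tl <- build_activity_timeline(binary, min_positive = cfg$min_positive)
    if (length(binary) > 1) tl <- classify_dropout_cause(tl, binary)
    tl
  })
  readr::write_csv(tibble::as_tibble(timeline), file.path(cfg$out_dir, "activity_timeline.csv"),
    progress = FALSE
  )

  fits <- list()
  memberships <- list()
  for (i in seq_along(ages)) {
    a <- ages[i]
    fits[[a]] <- stage(paste0("fit_age_", a), {
      args <- cfg$mixture
      over <- cfg$mixture_per_age[[a]]
      if (!is.null(over)) args <- modifyList(args, over)
      args$seed <- cfg$seed + i
      mcfg <- do.call(mixture_config, args)
      chain <- cluster_components(binary[[a]], mcfg,
        min_positive = cfg$min_positive
      )
      ks <- modal_K(chain)
      draws <- select_conditional_draws(chain, ks)
      rel <- relabel_chain(draws)
      asg <- assignment_matrix(rel)
      readr::write_csv(posterior_over_K(chain),
        file.path(cfg$out_dir, paste0("posterior_K_age_", a, ".csv")),
        progress = FALSE
      )
      readr::write_csv(tibble::as_tibble(asg),
        file.path(cfg$out_dir, paste0("assignment_age_", a, ".csv")),
        progress = FALSE
      )
      list(chain = chain, K_star = ks, assignment = asg)
    })
    memberships[[a]] <- modal_membership(fits[[a]]$assignment)
  }

  flow <- stage("flow", {
    universe <- unique(unlist(lapply(memberships, function(m) m$component_id)))
    graph <- build_flow_graph(memberships, universe)
    events <- summarize_flows(graph)
    flat <- tibble::as_tibble(graph)
    flat$components <- vapply(flat$components, paste, character(1),
      collapse = ";"
    )
    readr::write_csv(flat, file.path(cfg$out_dir, "flow_edges.csv"),
      progress = FALSE
    )
    readr::write_csv(events, file.path(cfg$out_dir, "flow_events.csv"),
      progress = FALSE
    )
    jsonlite::write_json(
      list(
        ages = ages,
        nodes = lapply(memberships, function(m) split(m$component_id, m$cluster)),
        edges = flat
      ),
      file.path(cfg$out_dir, "flow_graph.json"),
      auto_unbox = TRUE, digits = NA
    )
    mtl <- membership_timeline(memberships, timeline)
    mt <- tibble::as_tibble(mtl)
    mt$dropout_ages <- vapply(
      mt$dropout_ages, function(d) paste(d, collapse = ";"), character(1)
    )
    readr::write_csv(mt, file.path(cfg$out_dir, "membership_timeline.csv"),
      progress = FALSE
    )
    list(graph = graph, events = events, timeline = mtl)
  })

  associations <- NULL
  outcomes <- cfg$outcomes
  if (is.null(outcomes) && !is.null(cfg$cohort)) outcomes <- cfg$cohort$outcomes
  if (!is.null(outcomes)) {
    associations <- stage("associate", {
      if (is.character(outcomes)) {
        checksums <- c(checksums, tools::md5sum(outcomes))
        outcomes <- readr::read_csv(outcomes, show_col_types = FALSE, progress = FALSE)
      }
      oc <- cfg$outcome_cols
      if (is.null(oc)) {
        oc <- intersect(
          c("current_asthma", "current_rhinitis"), names(outcomes)
        )
      }
      pa <- cfg$profile_ages
      if (is.null(pa)) pa <- ages[length(ages)]
      res <- purrr::list_rbind(purrr::map(pa, function(a) {
        prof <- build_profiles(binary[[a]], memberships[[a]])
        out <- associate_clusters(prof, outcomes, oc, models = cfg$models)
        out$profile_age <- a
        out
      }))
      readr::write_csv(res, file.path(cfg$out_dir, "associations.csv"),
        progress = FALSE
      )
      res
    })
  }

  manifest <- list(
    package = "allergotype",
    version = as.character(utils::packageVersion("allergotype")),
    seed = cfg$seed,
    threshold = cfg$threshold,
    min_positive = cfg$min_positive,
    ages = ages,
    K_star = lapply(fits, function(f) f$K_star),
    input_md5 = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(structure(
    list(
      config = cfg, binary = binary, timeline = timeline, fits = fits,
      memberships = memberships, flow = flow, associations = associations,
      out_dir = cfg$out_dir
    ),
    class = "pipeline_run"
  ))
}
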