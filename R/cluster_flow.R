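#' Flow edges between two adjacent clusterings
#'
#' Builds one layer of the longitudinal flow architecture: a directed edge
#' from every cluster at age t (plus an `"inactive"` node) to every cluster
#' at age t+1 (plus `"inactive"`), weighted by the number of shared
#' components. Every component of the universe routes through exactly one
#' edge, so edge weights out of a node sum to that node's member count.
#'
#' @param members_t,members_t1 clusterings at the two ages: tibbles with
#'   `component_id` and `cluster` columns. Components of the universe not
#'   listed are inactive at that age.
#' @param universe character vector of all components to route.
#' @return tibble: `from`, `to` (cluster labels as character, or
#'   `"inactive"`), `weight`, `components` (list column).
#' @export
flow_edges <- function(members_t, members_t1, universe) {
  check_disjoint <- function(m, which) {
    dup <- unique(m$component_id[duplicated(m$component_id)])
    if (length(dup) > 0) {
      stop(
        "overlapping clusters at ", which, ": ",
        paste(dup, collapse = ", ")
      )
    }
  }
  check_disjoint(members_t, "age t")
  check_disjoint(members_t1, "age t+1")
  side <- function(m) {
    lab <- as.character(m$cluster[match(universe, m$component_id)])
    dplyr::coalesce(lab, "inactive")
  }
  tibble::tibble(
    component_id = universe,
    from = side(members_t),
    to = side(members_t1)
  ) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      weight = dplyr::n(),
      components = list(.data$component_id),
      .groups = "drop"
    )
}

#' Longitudinal flow graph across all ages
#'
#' @param memberships named list of clusterings (tibbles with
#'   `component_id`, `cluster`), names giving the ages in order.
#' @param universe components to route; defaults to every component ever
#'   assigned to a cluster.
#' @return a `flow_graph` tibble: `age_from`, `age_to`, `from`, `to`,
#'   `weight`, `components`.
#' @export
build_flow_graph <- function(memberships, universe = NULL) {
  ages <- names(memberships)
  if (is.null(ages)) stop("memberships must be a named list (names = ages)")
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(memberships, function(m) m$component_id)))
  }
  if (length(memberships) < 2) {
    empty <- tibble::tibble(
      age_from = character(0), age_to = character(0),
      from = character(0), to = character(0),
      weight = integer(0), components = list()
    )
    return(structure(empty,
      class = c("flow_graph", class(tibble::tibble())), ages = ages
    ))
  }
  layers <- purrr::map2(
    memberships[-length(memberships)], memberships[-1],
    function(a, b) flow_edges(a, b, universe)
  )
  out <- purrr::list_rbind(purrr::imap(layers, function(l, i) {
    idx <- match(i, ages[-length(ages)])
    l$age_from <- ages[idx]
    l$age_to <- ages[idx + 1]
    l
  }))
  out <- dplyr::relocate(out, "age_from", "age_to")
  structure(out,
    class = c("flow_graph", class(tibble::tibble())),
    ages = ages
  )
}

#' Label cluster-level flow events
#'
#' Deterministic event labels from the edge topology of each transition,
#' counting any shared component as a substantial link: `persist` (single
#' counterpart), `split` (several outgoing links), `absorb` (several
#' incoming links), `reabsorbed` (a singleton whose only member flows into
#' a larger cluster), `dropout` (all members went inactive) and
#' `newly-formed` (all members newly active). Invariant to cluster label
#' permutations within each age.
#'
#' @param graph a [build_flow_graph()] result (or one [flow_edges()] layer
#'   with `age_from`/`age_to` columns).
#' @return tibble: `age_from`, `age_to`, `node`, `side`
#'   (`source` = cluster at `age_from`, `target` = cluster at `age_to`),
#'   `event`.
#' @export
summarize_flows <- function(graph) {
  graph |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$age_from, .data$age_to) |>
    dplyr::group_modify(function(layer, key) {
      active <- function(x) x != "inactive"
      sizes_to <- layer |>
        dplyr::group_by(.data$to) |>
        dplyr::summarise(size = sum(.data$weight), .groups = "drop")
      src <- layer |>
        dplyr::filter(active(.data$from)) |>
        dplyr::group_by(node = .data$from) |>
        dplyr::group_modify(function(e, k) {
          outs <- e[active(e$to) & e$weight >= 1, ]
          size_a <- sum(e$weight)
          event <- if (nrow(outs) == 0) {
            "dropout"
          } else if (nrow(outs) > 1) {
            "split"
          } else {
            # a singleton is "reabsorbed" when its target is mainly the
            # continuation of some other cluster, not of itself
            other_in <- layer[
              active(layer$from) & layer$from != k$node &
                layer$to == outs$to[1] & layer$weight >= outs$weight[1],
            ]
            if (size_a == 1 && nrow(other_in) > 0) "reabsorbed" else "persist"
          }
          tibble::tibble(event = event)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(side = "source")
      tgt <- layer |>
        dplyr::filter(active(.data$to)) |>
        dplyr::group_by(node = .data$to) |>
        dplyr::group_modify(function(e, k) {
          ins <- e[active(e$from) & e$weight >= 1, ]
          event <- if (nrow(ins) == 0) {
            "newly-formed"
          } else if (nrow(ins) > 1) {
            "absorb"
          } else {
            "persist"
          }
          tibble::tibble(event = event)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(side = "target")
      dplyr::bind_rows(src, tgt)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("age_from", "age_to", "node", "side", "event")
}

#' Component-by-age membership timeline
#'
#' The activity/membership display: one row per ever-active component, one
#' column per age holding its cluster label (or `NA` when inactive). Rows
#' are sorted by first-activity age, then by total number of active ages
#' (descending), then by cluster membership at the first active age, then
#' by persistence; components active at exactly one time point go to the
#' bottom.
#'
#' @param memberships named list of clusterings per age (tibbles with
#'   `component_id`, `cluster`).
#' @param timeline an [build_activity_timeline()] result covering the same
#'   components.
#' @return a `membership_timeline` tibble.
#' @export
membership_timeline <- function(memberships, timeline) {
  ages <- names(memberships)
  smry <- activity_summary(timeline)
  ever <- smry[!is.na(smry$first_active_age), ]
  wide <- tibble::tibble(component_id = ever$component_id)
  for (a in ages) {
    m <- memberships[[a]]
    wide[[paste0("age_", a)]] <-
      m$cluster[match(wide$component_id, m$component_id)]
  }
  wide <- dplyr::left_join(wide, ever, by = "component_id")
  first_cluster <- vapply(seq_len(nrow(wide)), function(r) {
    a <- as.character(wide$first_active_age[r])
    v <- wide[[paste0("age_", a)]][r]
    if (is.null(v) || is.na(v)) Inf else as.numeric(v)
  }, numeric(1))
  ord <- order(
    wide$n_active_ages == 1, # single-age components last
    wide$first_active_age,
    -wide$n_active_ages,
    first_cluster,
    !wide$persistent
  )
  out <- wide[ord, ]
  structure(out,
    class = c("membership_timeline", class(tibble::tibble())),
    ages = ages
  )
}
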