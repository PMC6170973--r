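#' Tidy a fitted allocation chain
#'
#' @param x a `bmm_chain`.
#' @param ... unused.
#' @return the posterior over K as a tibble (`K`, `prob`).
#' @method tidy bmm_chain
#' @export
tidy.bmm_chain <- function(x, ...) {
  posterior_over_K(x)
}

#' One-row summary of a fitted allocation chain
#'
#' @param x a `bmm_chain`.
#' @param ... unused.
#' @return tibble: items, subjects, retained draws, modal K and its
#'   posterior probability, mean swap acceptance.
#' @method glance bmm_chain
#' @export
glance.bmm_chain <- function(x, ...) {
  pk <- posterior_over_K(x)
  ks <- modal_K(x)
  swaps <- x$diagnostics$swap_attempts
  tibble::tibble(
    n_items = length(x$item_ids),
    n_subjects = x$n_subjects,
    n_draws = nrow(x$draws),
    K_star = ks,
    prob_K_star = pk$prob[pk$K == ks],
    swap_rate = if (sum(swaps) > 0) {
      sum(x$diagnostics$swap_accepts) / sum(swaps)
    } else {
      NA_real_
    }
  )
}

#' Tidy an assignment-probability matrix
#'
#' @param x an `assignment_matrix`.
#' @param ... unused.
#' @return long tibble: `component_id`, `cluster`, `probability`, `modal`.
#' @method tidy assignment_matrix
#' @export
tidy.assignment_matrix <- function(x, ...) {
  P <- attr(x, "prob")
  out <- tibble::as_tibble(P)
  names(out) <- sub("^p_", "", names(out))
  out$component_id <- x$component_id
  out <- tidyr::pivot_longer(out, -"component_id",
    names_to = "cluster", values_to = "probability"
  )
  out$cluster <- as.integer(out$cluster)
  out$modal <- out$cluster == x$modal_cluster[
    match(out$component_id, x$component_id)
  ]
  out
}
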