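#' Draws conditional on the selected number of clusters
#'
#' Cluster membership is inferred conditional on the modal K*; this keeps
#' the retained draws whose K equals it, preserving order.
#'
#' @param chain a [mc3_run()] result.
#' @param K_star the selected number of clusters (typically [modal_K()]).
#' @return a `bmm_draws` object: `z` (allocations, draws x items),
#'   `log_post`, `sweep`, `K_star`, `item_ids`.
#' @export
select_conditional_draws <- function(chain, K_star) {
  keep <- which(chain$draws$K == K_star)
  if (length(keep) == 0) {
    stop(
      "no retained draws at K = ", K_star,
      "; run the sampler longer or check the posterior over K"
    )
  }
  if (length(keep) < 100) {
    warning("only ", length(keep), " draws at K = ", K_star)
  }
  structure(
    list(
      z = chain$z[keep, , drop = FALSE],
      log_post = chain$draws$log_post[keep],
      sweep = chain$draws$sweep[keep],
      K_star = as.integer(K_star),
      item_ids = chain$item_ids
    ),
    class = "bmm_draws"
  )
}

#' Pivot allocation for ECR relabeling
#'
#' The draw with maximal collapsed log posterior among the retained samples
#' (MAP); ties go to the earliest draw.
#'
#' @param draws a [select_conditional_draws()] result.
#' @return integer allocation vector.
#' @export
select_pivot <- function(draws) {
  i <- which.max(draws$log_post)
  draws$z[i, ]
}

# all permutations of 1..K in lexicographic order, one per row
perms_lex <- function(K) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]), deparse.level = 0)
    }))
  }
  rec(seq_len(K))
}

#' ECR label permutation for one draw
#'
#' Finds the permutation of `1..K_star` that, applied to the draw's labels,
#' minimizes the number of items disagreeing with the pivot — the
#' Equivalence Classes Representatives step, solved as an assignment
#' problem on the K* x K* agreement matrix. Exhaustive search (with
#' lexicographically-smallest tie-breaking) up to K* = 7; weighted bipartite
#' matching above.
#'
#' @param draw,pivot allocation vectors of equal length, labels in
#'   `1..K_star`. Empty labels are allowed and carry zero agreement.
#' @param K_star number of cluster labels.
#' @return integer permutation `perm`; label `k` in `draw` is renamed
#'   `perm[k]`.
#' @export
ecr_permute <- function(draw, pivot, K_star) {
  stopifnot(length(draw) == length(pivot))
  stopifnot(all(draw >= 1), all(draw <= K_star), all(pivot >= 1), all(pivot <= K_star))
  A <- matrix(0, K_star, K_star)
  for (i in seq_along(draw)) A[draw[i], pivot[i]] <- A[draw[i], pivot[i]] + 1
  if (K_star <= 7) {
    pm <- perms_lex(K_star)
    score <- vapply(seq_len(nrow(pm)), function(r) {
      sum(A[cbind(seq_len(K_star), pm[r, ])])
    }, numeric(1))
    pm[which.max(score), ]
  } else {
    g <- igraph::make_bipartite_graph(
      types = rep(c(FALSE, TRUE), each = K_star),
      edges = as.vector(rbind(
        rep(seq_len(K_star), each = K_star),
        rep(K_star + seq_len(K_star), times = K_star)
      ))
    )
    w <- as.vector(t(A)) + 1 # strictly positive: forces a perfect matching
    m <- igraph::max_bipartite_match(g, weights = w)
    as.integer(m$matching[seq_len(K_star)]) - K_star
  }
}

#' Relabel a conditional chain against its pivot
#'
#' Applies [ecr_permute()] draw by draw. Relabeling permutes cluster labels
#' only, so every draw's collapsed log posterior is unchanged.
#'
#' @param draws a [select_conditional_draws()] result.
#' @param pivot pivot allocation; defaults to [select_pivot()].
#' @return a `relabeled_chain`: `z` (relabeled draws), `perms` (one row per
#'   draw), `pivot`, `log_post`, `K_star`, `item_ids`.
#' @export
relabel_chain <- function(draws, pivot = select_pivot(draws)) {
  K <- draws$K_star
  nd <- nrow(draws$z)
  perms <- matrix(0L, nd, K)
  z <- draws$z
  for (d in seq_len(nd)) {
    p <- ecr_permute(z[d, ], pivot, K)
    perms[d, ] <- p
    z[d, ] <- p[z[d, ]]
  }
  structure(
    list(
      z = z, perms = perms, pivot = pivot,
      log_post = draws$log_post, K_star = K, item_ids = draws$item_ids
    ),
    class = "relabeled_chain"
  )
}

#' Posterior assignment probabilities per component
#'
#' Entry (i, k) is the fraction of relabeled draws allocating component i to
#' cluster k; the modal cluster takes ties to the lower cluster index.
#'
#' @param relabeled a [relabel_chain()] result.
#' @return an `assignment_matrix` tibble: `component_id`, one `p_k` column
#'   per cluster, `modal_cluster`, `modal_prob`. The bare probability
#'   matrix is available via [as.matrix()].
#' @export
assignment_matrix <- function(relabeled) {
  K <- relabeled$K_star
  z <- relabeled$z
  P <- vapply(seq_len(K), function(k) colMeans(z == k), numeric(ncol(z)))
  P <- matrix(P, ncol = K, dimnames = list(relabeled$item_ids, paste0("p_", seq_len(K))))
  modal <- apply(P, 1, which.max)
  out <- tibble::as_tibble(P)
  out <- tibble::add_column(out,
    component_id = relabeled$item_ids, .before = 1
  )
  out$modal_cluster <- as.integer(modal)
  out$modal_prob <- P[cbind(seq_len(nrow(P)), modal)]
  structure(out,
    class = c("assignment_matrix", class(tibble::tibble())),
    prob = P, K_star = K
  )
}

#' @export
as.matrix.assignment_matrix <- function(x, ...) attr(x, "prob")

#' Modal cluster membership as a clustering table
#'
#' @param assignment an [assignment_matrix()] result.
#' @return tibble `component_id`, `cluster` — the shape the flow stage
#'   consumes.
#' @export
modal_membership <- function(assignment) {
  tibble::tibble(
    component_id = assignment$component_id,
    cluster = assignment$modal_cluster
  )
}
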