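# fixtures are built in code; no data files

# binary panel from a subjects x components 0/1 matrix with dimnames
bin_panel <- function(m, age = NULL) {
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, subject_id = rownames(m), .before = 1)
  binarize_panel(quant_panel(df, age_label = age), threshold = 0.5)
}

rand_quant_panel <- function(n_subj, n_comp, age = NULL) {
  m <- matrix(round(runif(n_subj * n_comp, 0, 12), 3), n_subj, n_comp,
    dimnames = list(sprintf("S%02d", 1:n_subj), sprintf("C%02d", 1:n_comp))
  )
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, subject_id = rownames(m), .before = 1)
  quant_panel(df, age_label = age)
}

# the fixed small clustering toy used against the enumeration oracle
toy_6x4 <- function() {
  matrix(
    c(
      1, 1, 0, 0, 1, 0,
      1, 1, 0, 1, 0, 0,
      0, 0, 1, 1, 0, 1,
      0, 1, 1, 1, 0, 1
    ),
    nrow = 6, ncol = 4,
    dimnames = list(sprintf("C%d", 1:6), sprintf("S%d", 1:4))
  )
}

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# brute-force ECR oracle: best permutation by exhaustive search
ecr_brute <- function(draw, pivot, K) {
  A <- matrix(0, K, K)
  for (i in seq_along(draw)) A[draw[i], pivot[i]] <- A[draw[i], pivot[i]] + 1
  pm <- allergotype:::perms_lex(K)
  sc <- apply(pm, 1, function(p) sum(A[cbind(seq_len(K), p)]))
  pm[which.max(sc), ]
}

ecr_disagreement <- function(draw, pivot, perm) sum(perm[draw] != pivot)
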