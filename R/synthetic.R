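#' Synthetic dataset configuration
#'
#' Defaults are desk-scale but shaped like a curated circRNA-disease
#' resource: 200 circRNAs, 60 diseases, 49 expression samples, five circRNA
#' groups matched round-robin to five disease groups, association
#' probability 0.3 inside matched group blocks and 0.01 outside, target
#' within-group expression correlation 0.8, disease similarity 0.7 within
#' group and 0.1 between.
#'
#' @param n_circ,n_dis,n_samples dimensions.
#' @param n_circ_groups,n_dis_groups planted group counts.
#' @param p_in,p_out association probability inside / outside matched
#'   blocks; requires `0 <= p_out < p_in <= 1`.
#' @param rho_in target within-group expression Pearson correlation in
#'   \[0, 1).
#' @param sim_in,sim_out disease similarity inside / outside groups;
#'   requires `0 <= sim_out < sim_in <= 1`.
#' @param seed integer seed; generation is deterministic given it.
#' @return named list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_circ = 200L, n_dis = 60L, n_samples = 49L,
                             n_circ_groups = 5L, n_dis_groups = 5L,
                             p_in = 0.3, p_out = 0.01, rho_in = 0.8,
                             sim_in = 0.7, sim_out = 0.1, seed = 42L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("association probabilities must satisfy 0 <= p_out < p_in <= 1")
  }
  if (!(rho_in >= 0 && rho_in < 1)) stop("rho_in must lie in [0, 1)")
  if (!(sim_out >= 0 && sim_out < sim_in && sim_in <= 1)) {
    stop("disease similarities must satisfy 0 <= sim_out < sim_in <= 1")
  }
  structure(list(n_circ = as.integer(n_circ), n_dis = as.integer(n_dis),
                 n_samples = as.integer(n_samples),
                 n_circ_groups = as.integer(n_circ_groups),
                 n_dis_groups = as.integer(n_dis_groups),
                 p_in = p_in, p_out = p_out, rho_in = rho_in,
                 sim_in = sim_in, sim_out = sim_out, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic dataset with planted block structure
#'
#' circRNAs and diseases are assigned to groups round-robin; circRNA group
#' g is matched to disease group `(g - 1) %% n_dis_groups + 1`. Association
#' cells are Bernoulli(`p_in`) inside matched group blocks and
#' Bernoulli(`p_out`) outside. Expression profiles are a shared group
#' template plus Gaussian noise with the variance ratio chosen so the
#' expected within-group Pearson correlation is `rho_in`. Disease
#' similarity is `sim_in` within a group, `sim_out` between groups,
#' diagonal 1.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `assoc`, `expr`, `dsim`, and `groups` (the planted
#'   circRNA and disease group labels).
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  circ_ids <- sprintf("circ_%03d", seq_len(cfg$n_circ))
  dis_ids <- sprintf("disease_%02d", seq_len(cfg$n_dis))
  circ_grp <- rep_len(seq_len(cfg$n_circ_groups), cfg$n_circ)
  dis_grp <- rep_len(seq_len(cfg$n_dis_groups), cfg$n_dis)
  matched_dis <- (circ_grp - 1L) %% cfg$n_dis_groups + 1L

  p <- matrix(cfg$p_out, cfg$n_circ, cfg$n_dis)
  p[outer(matched_dis, dis_grp, `==`)] <- cfg$p_in
  A <- matrix(stats::rbinom(length(p), 1L, p), cfg$n_circ, cfg$n_dis,
              dimnames = list(circ_ids, dis_ids))

  # shared template per group; Var(template)/Var(total) = rho_in gives the
  # stated expected within-group Pearson correlation
  templates <- matrix(stats::rnorm(cfg$n_circ_groups * cfg$n_samples),
                      cfg$n_circ_groups, cfg$n_samples)
  sd_noise <- sqrt((1 - cfg$rho_in) / max(cfg$rho_in, .Machine$double.eps))
  if (cfg$rho_in == 0) sd_noise <- 1
  signal <- if (cfg$rho_in == 0) 0 else 1
  expr <- signal * templates[circ_grp, , drop = FALSE] +
    matrix(stats::rnorm(cfg$n_circ * cfg$n_samples, sd = sd_noise),
           cfg$n_circ, cfg$n_samples)
  dimnames(expr) <- list(circ_ids, sprintf("sample_%02d", seq_len(cfg$n_samples)))

  D <- matrix(cfg$sim_out, cfg$n_dis, cfg$n_dis)
  D[outer(dis_grp, dis_grp, `==`)] <- cfg$sim_in
  diag(D) <- 1
  dimnames(D) <- list(dis_ids, dis_ids)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  list(assoc = association_matrix(A),
       expr = expression_profiles(expr),
       dsim = similarity_matrix(D),
       groups = list(circ = stats::setNames(circ_grp, circ_ids),
                     disease = stats::setNames(dis_grp, dis_ids)))
}

#' Hold out a fraction of the known associations
#'
#' Removes `round(fraction * n_positives)` randomly chosen positives from
#' the association matrix and returns them separately, supporting
#' leakage-safe evaluation on planted data.
#'
#' @param dataset list with an `assoc` element (e.g. [generate_dataset()]
#'   output).
#' @param fraction fraction of positives to hold out, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` (the dataset with held-out positives zeroed)
#'   and `heldout` (data.frame of the removed `circRNA`/`disease` pairs).
#' @export
heldout_split <- function(dataset, fraction, seed = 42L) {
  stopifnot(fraction > 0, fraction < 1)
  A <- unclass_matrix(dataset$assoc)
  pos <- which(A == 1)
  n_hold <- round(fraction * length(pos))
  if (n_hold < 1L) stop("too few positives to hold out at this fraction")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  hold <- pos[sample.int(length(pos), n_hold)]
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  A[hold] <- 0
  train <- dataset
  train$assoc <- association_matrix(A)
  list(train = train,
       heldout = data.frame(circRNA = rownames(A)[(hold - 1L) %% nrow(A) + 1L],
                            disease = colnames(A)[(hold - 1L) %/% nrow(A) + 1L],
                            stringsAsFactors = FALSE))
}
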