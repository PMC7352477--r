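#' Initialize a particle swarm over the panel-selection hyperparameters
#'
#' Positions are drawn uniformly within the four published search bounds
#' (library-size correlation floor, FDR threshold, label-correlation
#' threshold, ranked-transcript count); velocities start at zero. Particle 1
#' is pinned to the documented default setting (fdr = 0.05, floor = -0.1,
#' cor = 0.5, n_ranked = min(1000, upper bound)) so the swarm can never do
#' worse than the default pipeline. The n_ranked dimension flies as a
#' continuous value and is rounded at evaluation time.
#'
#' @param bounds Named list of length-2 ranges as in [run_config()]:
#'   \code{libsize_cor}, \code{fdr}, \code{cor}, \code{n_ranked}.
#' @param n_particles Number of particles (>= 2).
#' @param seed Integer seed.
#' @return An object of class \code{"swarm_state"}.
#' @export
init_swarm <- function(bounds, n_particles, seed) {
  stopifnot(n_particles >= 2)
  lo <- c(bounds$libsize_cor[1], bounds$fdr[1], bounds$cor[1], bounds$n_ranked[1])
  hi <- c(bounds$libsize_cor[2], bounds$fdr[2], bounds$cor[2], bounds$n_ranked[2])
  if (all(lo == hi)) warning("degenerate bounds: all particles identical")
  pos <- with_seed(seed, {
    matrix(stats::runif(n_particles * 4, rep(lo, each = n_particles),
                        rep(hi, each = n_particles)),
           n_particles, 4)
  })
  default <- c(max(lo[1], min(hi[1], -0.1)),
               max(lo[2], min(hi[2], 0.05)),
               max(lo[3], min(hi[3], 0.5)),
               max(lo[4], min(hi[4], 1000)))
  pos[1, ] <- default
  colnames(pos) <- c("libsize_cor_lo", "fdr_threshold", "cor_threshold", "n_ranked")
  structure(list(position = pos,
                 velocity = matrix(0, n_particles, 4),
                 pbest = pos, pbest_fitness = rep(-Inf, n_particles),
                 gbest = default, gbest_fitness = -Inf,
                 lo = lo, hi = hi, iteration = 0L, seed = as.integer(seed)),
            class = "swarm_state")
}

position_to_params <- function(x) {
  particle_params(libsize_cor_lo = x[1], fdr_threshold = x[2],
                  cor_threshold = x[3], n_ranked = max(1L, as.integer(round(x[4]))))
}

# evaluate all particles and refresh personal/global bests; ties keep the
# earlier incumbent (strict improvement only) in (iteration, index) order
evaluate_swarm <- function(state, fitness_fn) {
  n <- nrow(state$position)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fit[i] <- fitness_fn(position_to_params(state$position[i, ]))
    if (is.na(fit[i]) || fit[i] < 0 || fit[i] > 1) {
      stop("fitness must lie in [0, 1], got ", fit[i])
    }
  }
  improved <- fit > state$pbest_fitness
  state$pbest[improved, ] <- state$position[improved, , drop = FALSE]
  state$pbest_fitness[improved] <- fit[improved]
  best_i <- which.max(state$pbest_fitness)
  if (state$pbest_fitness[best_i] > state$gbest_fitness) {
    state$gbest <- state$pbest[best_i, ]
    state$gbest_fitness <- state$pbest_fitness[best_i]
  }
  state$last_fitness <- fit
  state
}

#' Advance the swarm one iteration
#'
#' Evaluates every particle with \code{fitness_fn} (an AUC in \code{[0, 1]}),
#' updates personal and global bests, then applies the standard
#' inertia-weight update
#' \deqn{v \leftarrow \omega v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x),
#'       \quad x \leftarrow \mathrm{clamp}(x + v)}
#' with \eqn{\omega = 0.72}, \eqn{c_1 = c_2 = 1.49} and per-dimension uniform
#' \eqn{r_1, r_2}. Positions are clamped to the bounds; the global-best
#' fitness is non-decreasing by construction.
#'
#' @param state A [init_swarm()] state.
#' @param fitness_fn Function mapping a [particle_params()] to a fitness in
#'   \code{[0, 1]}.
#' @param inertia,cognitive,social PSO constants.
#' @return The updated \code{swarm_state} (fields \code{gbest},
#'   \code{gbest_fitness}, \code{last_fitness} refreshed).
#' @export
swarm_step <- function(state, fitness_fn, inertia = 0.72,
                       cognitive = 1.49, social = 1.49) {
  state <- evaluate_swarm(state, fitness_fn)
  n <- nrow(state$position)
  upd <- with_seed(derive_seed(state$seed, paste0("step", state$iteration)), {
    r1 <- matrix(stats::runif(n * 4), n, 4)
    r2 <- matrix(stats::runif(n * 4), n, 4)
    v <- inertia * state$velocity +
      cognitive * r1 * (state$pbest - state$position) +
      social * r2 * sweep(-state$position, 2, state$gbest, "+")
    x <- state$position + v
    x <- pmax(pmin(x, rep(state$hi, each = n)), rep(state$lo, each = n))
    list(v = v, x = x)
  })
  state$velocity <- upd$v
  state$position <- upd$x
  state$iteration <- state$iteration + 1L
  state
}

#' Swarm-optimize the biomarker panel and lock the winner
#'
#' The fitness of a particle is the ROC-AUC, on the evaluation series, of
#' the panel built from the training series with that particle's parameters
#' (degenerate panels score chance, 0.5). After \code{n_iterations} of
#' \code{n_particles} each, the best particle ever seen (ties: earliest
#' found) is re-built on the training series and LOCKED. Evaluation samples
#' never enter panel selection or SVM fitting; validation samples never
#' enter this function at all.
#'
#' @param norm_train,labels_train Training series data.
#' @param norm_eval,labels_eval Evaluation series data (must be disjoint
#'   from training).
#' @param config A [run_config()]; supplies bounds, particle/iteration
#'   counts, PSO constants and the seed.
#' @return List of class \code{"pso_result"}: \code{params} (best particle),
#'   \code{panel} (locked [build_panel()] artifact), \code{fitness} (its
#'   evaluation AUC), \code{trace} (data.frame: iteration, particle, the four
#'   parameters, eval AUC).
#' @export
pso_optimize <- function(norm_train, labels_train, norm_eval, labels_eval,
                         config) {
  stopifnot(inherits(config, "run_config"))
  overlap <- intersect(colnames(norm_train$values), colnames(norm_eval$values))
  if (length(overlap)) {
    stop("training and evaluation series overlap: ", paste(overlap, collapse = ", "))
  }
  if (length(unique(labels_train)) < 2 || length(unique(labels_eval)) < 2) {
    stop("training and evaluation series must both contain both classes")
  }
  bounds <- config$bounds
  bounds$n_ranked[2] <- min(bounds$n_ranked[2], nrow(norm_train$values))
  bounds$n_ranked[1] <- min(bounds$n_ranked[1], bounds$n_ranked[2])

  fitness_fn <- function(params) {
    panel <- build_panel(norm_train, labels_train, params)
    if (panel$degenerate) return(0.5)
    s <- tep_score(panel, norm_eval, series = "evaluation")
    unname(roc_auc(s, labels_eval, ci = FALSE)$auc)
  }

  state <- init_swarm(bounds, config$n_particles, derive_seed(config$seed, "swarm"))
  trace <- vector("list", config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    evaluated <- state$position  # positions at evaluation time (pre-move)
    state <- swarm_step(state, fitness_fn, inertia = config$inertia,
                        cognitive = config$cognitive, social = config$social)
    trace[[it]] <- data.frame(iteration = it,
                              particle = seq_len(config$n_particles),
                              evaluated,
                              eval_auc = state$last_fitness,
                              gbest_auc = state$gbest_fitness)
  }
  best_params <- position_to_params(state$gbest)
  panel <- lock_panel(build_panel(norm_train, labels_train, best_params))
  structure(list(params = best_params, panel = panel,
                 fitness = state$gbest_fitness,
                 trace = do.call(rbind, trace), state = state),
            class = "pso_result")
}
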