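#' Search spaces for parameter optimization
#'
#' Two fitting scenarios are supported. Scenario 1 fits the three global
#' parameters (`G`, one shared local coupling `L`, velocity `v`) with every
#' ensemble identical. Scenario 2 fixes `G` and `v` (taken from scenario 1)
#' and fits one local coupling per homotopic pair (`E/2` parameters), tying
#' mirror regions together via the connectome's homotopic pairing.
#'
#' @param names parameter names.
#' @param lower,upper numeric bounds per parameter, `lower < upper`.
#' @param scenario optional tag (`"scenario1"` / `"scenario2"`).
#' @return a list of class `search_space`.
#' @export
search_space <- function(names, lower, upper, scenario = NULL) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper))
  if (any(lower >= upper)) stop("each lower bound must be below its upper bound")
  structure(list(names = names, lower = as.numeric(lower),
                 upper = as.numeric(upper), scenario = scenario),
            class = "search_space")
}

#' @rdname search_space
#' @param G_range,L_range,v_range scenario-1 box bounds (defaults cover the
#'   plausible coupling and conduction-velocity ranges).
#' @export
scenario1_space <- function(G_range = c(0, 10), L_range = c(-5, 6),
                            v_range = c(1, 40)) {
  search_space(c("G", "L", "v"),
               c(G_range[1], L_range[1], v_range[1]),
               c(G_range[2], L_range[2], v_range[2]),
               scenario = "scenario1")
}

#' @rdname search_space
#' @param connectome a [connectome()] with `homotopic_pairs`.
#' @param L_half_range bounds applied to each per-pair local coupling.
#' @export
scenario2_space <- function(connectome, L_half_range = c(-5, 8)) {
  if (is.null(connectome$homotopic_pairs))
    stop("scenario 2 requires a connectome with homotopic pairing")
  n <- nrow(connectome$homotopic_pairs)
  search_space(paste0("L", seq_len(n)),
               rep(L_half_range[1], n), rep(L_half_range[2], n),
               scenario = "scenario2")
}

#' Expand / collapse homotopically tied local couplings
#'
#' `expand_homotopic` assigns `L_half[k]` to both members of homotopic pair
#' `k`; `collapse_homotopic` inverts this, recovering one value per pair
#' (and checks the tie holds).
#'
#' @param L_half numeric vector, one coupling per pair.
#' @param pairing 2-column integer matrix of (left, right) indices forming a
#'   perfect matching.
#' @return `expand_homotopic`: length-E vector; `collapse_homotopic`:
#'   length-`E/2` vector.
#' @export
expand_homotopic <- function(L_half, pairing) {
  pairing <- as.matrix(pairing)
  if (length(L_half) != nrow(pairing))
    stop("length(L_half) = ", length(L_half), " but pairing has ",
         nrow(pairing), " pairs")
  E <- 2L * nrow(pairing)
  if (!setequal(as.vector(pairing), seq_len(E)))
    stop("pairing must be a perfect matching over ", E, " indices")
  L_full <- numeric(E)
  L_full[pairing[, 1]] <- L_half
  L_full[pairing[, 2]] <- L_half
  L_full
}

#' @rdname expand_homotopic
#' @param L_full length-E vector with equal values within each pair.
#' @export
collapse_homotopic <- function(L_full, pairing) {
  pairing <- as.matrix(pairing)
  if (any(L_full[pairing[, 1]] != L_full[pairing[, 2]]))
    stop("homotopic tie violated: pair members differ")
  L_full[pairing[, 1]]
}

#' Uniform box sampling of a search space
#'
#' @param space a [search_space()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x d matrix of parameter vectors, one row per draw.
#' @export
sample_box <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "search_space"), n >= 1)
  d <- length(space$lower)
  with_seed(seed, {
    m <- matrix(runif(n * d), n, d)
    m <- sweep(m, 2L, space$upper - space$lower, `*`)
    m <- sweep(m, 2L, space$lower, `+`)
    colnames(m) <- space$names
    m
  })
}

new_optimizer_run <- function(algorithm, space, pop, gens, seed,
                              par_archive, val_archive, best_par, best_val) {
  colnames(par_archive) <- space$names
  structure(list(algorithm = algorithm, space = space, pop = pop,
                 gens = gens, seed = seed,
                 archive = list(parameters = par_archive,
                                values = val_archive),
                 best_parameters = stats::setNames(best_par, space$names),
                 best_value = best_val),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("<optimizer_run> %s, pop %d x %d generations, best value %.6g\n",
              x$algorithm, x$pop, x$gens, x$best_value))
  invisible(x)
}

#' Particle swarm optimization (canonical, bound-constrained)
#'
#' Minimizes `objective` over the box of `space` with the canonical
#' inertia-weight PSO: inertia 0.7298, cognitive = social = 1.49618
#' (constriction-equivalent coefficients), velocities clamped to half the
#' box range per dimension, positions clamped to the bounds. Every
#' evaluation is archived. Deterministic given `seed`.
#'
#' @param objective function taking a parameter vector, returning a scalar
#'   to minimize.
#' @param space a [search_space()].
#' @param pop swarm size (>= 2).
#' @param gens number of generations after the initial evaluation.
#' @param seed integer seed.
#' @param inertia,cognitive,social PSO coefficients.
#' @return an `optimizer_run` with the full evaluation archive (length
#'   `pop * (gens + 1)`), best parameters and best value.
#' @export
pso_minimize <- function(objective, space, pop = 20L, gens = 200L,
                         seed = 1L, inertia = 0.7298,
                         cognitive = 1.49618, social = 1.49618) {
  stopifnot(inherits(space, "search_space"), pop >= 2L)
  lower <- space$lower; upper <- space$upper
  d <- length(lower)
  range <- upper - lower
  vmax <- range / 2
  with_seed(seed, {
    X <- sample_box_local(pop, lower, upper)
    V <- matrix(runif(pop * d, -1, 1), pop, d) *
      matrix(vmax, pop, d, byrow = TRUE)
    f <- apply(X, 1L, objective)
    par_arc <- X; val_arc <- f
    Pbest <- X; fbest <- f
    g <- which.min(fbest)
    for (gen in seq_len(gens)) {
      r1 <- matrix(runif(pop * d), pop, d)
      r2 <- matrix(runif(pop * d), pop, d)
      V <- inertia * V + cognitive * r1 * (Pbest - X) +
        social * r2 * (matrix(Pbest[g, ], pop, d, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, pop, d, byrow = TRUE)),
                matrix(vmax, pop, d, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, pop, d, byrow = TRUE)),
                matrix(upper, pop, d, byrow = TRUE))
      f <- apply(X, 1L, objective)
      par_arc <- rbind(par_arc, X); val_arc <- c(val_arc, f)
      improved <- f < fbest
      Pbest[improved, ] <- X[improved, , drop = FALSE]
      fbest[improved] <- f[improved]
      g <- which.min(fbest)
    }
    new_optimizer_run("pso", space, pop, gens, seed, par_arc, val_arc,
                      Pbest[g, ], fbest[g])
  })
}

# uniform init inside the current RNG stream (unlike sample_box, which is
# independently seeded)
sample_box_local <- function(n, lower, upper) {
  d <- length(lower)
  m <- matrix(runif(n * d), n, d)
  sweep(sweep(m, 2L, upper - lower, `*`), 2L, lower, `+`)
}

#' Self-adaptive differential evolution (jDE-style)
#'
#' Minimizes `objective` with DE/rand/1/bin where each individual carries
#' its own mutation factor `F` in `[0.1, 1]` and crossover rate `CR` in
#' `[0, 1]`, each regenerated uniformly with probability 0.1 per generation
#' (the standard self-adaptation rule). Selection is greedy with ties kept
#' by the parent; trial vectors are clamped to the bounds. Every evaluation
#' is archived. Deterministic given `seed`.
#'
#' @inheritParams pso_minimize
#' @param pop population size (>= 5).
#' @return an `optimizer_run` (archive length `pop * (gens + 1)`).
#' @export
ade_minimize <- function(objective, space, pop = 20L, gens = 200L,
                         seed = 1L) {
  stopifnot(inherits(space, "search_space"), pop >= 5L)
  lower <- space$lower; upper <- space$upper
  d <- length(lower)
  with_seed(seed, {
    X <- sample_box_local(pop, lower, upper)
    f <- apply(X, 1L, objective)
    Fi <- rep(0.5, pop); CRi <- rep(0.9, pop)
    par_arc <- X; val_arc <- f
    for (gen in seq_len(gens)) {
      regenF <- runif(pop) < 0.1
      Fi[regenF] <- runif(sum(regenF), 0.1, 1)
      regenCR <- runif(pop) < 0.1
      CRi[regenCR] <- runif(sum(regenCR))
      for (i in seq_len(pop)) {
        idx <- sample(setdiff(seq_len(pop), i), 3L)
        mutant <- X[idx[1], ] + Fi[i] * (X[idx[2], ] - X[idx[3], ])
        cross <- runif(d) < CRi[i]
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, X[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        ft <- objective(trial)
        par_arc <- rbind(par_arc, matrix(trial, 1L))
        val_arc <- c(val_arc, ft)
        if (ft < f[i]) {   # strict: ties keep the parent
          X[i, ] <- trial
          f[i] <- ft
        }
      }
    }
    g <- which.min(f)
    new_optimizer_run("ade", space, pop, gens, seed, par_arc, val_arc,
                      X[g, ], f[g])
  })
}
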