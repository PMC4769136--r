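# Real-coded genetic algorithm used for fusion-weight and threshold
# learning. Minimizes `fitness(chromosome)`; chromosomes are kept feasible
# by `project` after every variation. Stops once `patience` consecutive
# generations fail to improve the incumbent, or at the generation cap.

ga_minimize <- function(fitness, n_dim, project, cfg, init = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  restore <- restore_rng()
  on.exit(restore())
  set.seed(cfg$rng_seed)
  np <- cfg$population_size
  pop <- matrix(runif(np * n_dim), np, n_dim)
  if (!is.null(init)) pop[1, ] <- init
  pop <- t(apply(pop, 1, project))
  if (n_dim == 1) pop <- matrix(pop, ncol = 1)
  fit <- apply(pop, 1, fitness)
  best_i <- which.min(fit)
  best <- pop[best_i, ]
  best_fit <- fit[best_i]
  stall <- 0L
  gen <- 0L
  while (gen < cfg$max_generations && stall < cfg$patience) {
    gen <- gen + 1L
    tournament <- function() {
      cand <- sample.int(np, 3)
      cand[which.min(fit[cand])]
    }
    children <- matrix(NA_real_, np, n_dim)
    children[1, ] <- best  # elitism
    for (i in 2:np) {
      p1 <- pop[tournament(), ]
      p2 <- pop[tournament(), ]
      child <- if (runif(1) < cfg$crossover_rate) {
        # blend crossover (BLX-0.5)
        lo <- pmin(p1, p2); hi <- pmax(p1, p2)
        span <- hi - lo
        lo - 0.5 * span + runif(n_dim) * (2 * span)
      } else p1
      mut <- runif(n_dim) < cfg$mutation_rate
      child[mut] <- child[mut] + rnorm(sum(mut), sd = cfg$mutation_sd)
      children[i, ] <- project(child)
    }
    pop <- children
    fit <- apply(pop, 1, fitness)
    i <- which.min(fit)
    if (fit[i] < best_fit - 1e-12) {
      best_fit <- fit[i]
      best <- pop[i, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  list(par = best, value = best_fit, generations = gen)
}

project_simplex <- function(w) {
  w <- pmax(w, 0)
  s <- sum(w)
  if (s <= 0) rep(1 / length(w), length(w)) else w / s
}
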