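#' Cartesian distance between two fireflies
#' @param a,b positions of equal length.
#' @return Euclidean norm of a - b.
#' @export
firefly_distance <- function(a, b) {
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Firefly attractiveness beta0 * exp(-gamma * r^2)
#' @param r distance (>= 0).
#' @param beta0 attractiveness at zero distance.
#' @param gamma light absorption coefficient.
#' @return attractiveness, monotone decreasing in r.
#' @export
firefly_attractiveness <- function(r, beta0, gamma) beta0 * exp(-gamma * r^2)

#' Move one firefly toward a brighter one
#'
#' pos_a + beta0 exp(-gamma r^2) (pos_b - pos_a) + alpha (rand - 0.5)
#' per coordinate. The brightest firefly of a generation takes only the
#' random term.
#'
#' @param pos_a,pos_b positions (b the brighter one).
#' @param beta0,gamma attraction parameters.
#' @param alpha random step scale.
#' @return updated position for a.
#' @export
firefly_move <- function(pos_a, pos_b, beta0, gamma, alpha) {
  r <- firefly_distance(pos_a, pos_b)
  pos_a + firefly_attractiveness(r, beta0, gamma) * (pos_b - pos_a) +
    alpha * (stats::runif(length(pos_a)) - 0.5)
}

#' Firefly-algorithm continuous minimizer
#'
#' Each firefly moves toward every brighter one with
#' distance-attenuated attraction plus a decaying random step; the
#' brightest performs only the random walk. Positions are clamped to
#' the bounds.
#'
#' @param objective function mapping a numeric vector to a scalar
#'   fitness (minimized).
#' @param dim problem dimension.
#' @param lower,upper scalar or per-dimension bounds.
#' @param pop population size (default 20).
#' @param iters iterations (default 100).
#' @param beta0 base attractiveness (default 1).
#' @param gamma light absorption; NULL sets 1 / (mean pairwise initial
#'   distance)^2.
#' @param alpha random step scale (default 0.2), multiplied by
#'   `alpha_decay` each iteration.
#' @param alpha_decay per-iteration decay (default 0.97).
#' @param seed RNG seed.
#' @return list with `best` (position), `fitness`, `trace`
#'   (best-so-far per iteration, non-increasing).
#' @export
fa_optimize <- function(objective, dim, lower = -1, upper = 1, pop = 20L,
                        iters = 100L, beta0 = 1, gamma = NULL, alpha = 0.2,
                        alpha_decay = 0.97, seed = 1L) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  with_seed(seed, {
    P <- matrix(stats::runif(pop * dim, lower, upper), pop, dim, byrow = TRUE)
    fit <- apply(P, 1, objective)
    if (is.null(gamma)) {
      dmat <- as.matrix(stats::dist(P))
      md <- mean(dmat[upper.tri(dmat)])
      gamma <- if (md > EPS) 1 / md^2 else 1
    }
    best_i <- which.min(fit)
    best <- P[best_i, ]; best_fit <- fit[best_i]
    trace <- numeric(iters)
    for (it in seq_len(iters)) {
      ord <- order(fit)
      for (a in seq_len(pop)) {
        brighter <- which(fit < fit[a])
        if (length(brighter) == 0L) {
          # brightest: random walk only
          P[a, ] <- P[a, ] + alpha * (stats::runif(dim) - 0.5)
        } else {
          for (b in brighter) {
            P[a, ] <- firefly_move(P[a, ], P[b, ], beta0, gamma, alpha)
          }
        }
        P[a, ] <- pmin(pmax(P[a, ], lower), upper)
        fit[a] <- objective(P[a, ])
      }
      i <- which.min(fit)
      if (fit[i] < best_fit) { best_fit <- fit[i]; best <- P[i, ] }
      trace[it] <- best_fit
      alpha <- alpha * alpha_decay
    }
    list(best = best, fitness = best_fit,
         trace = if (iters > 0) trace else best_fit)
  })
}

#' Capuchin iteration-decay factor tau = 2 exp(-21 (t / T)^2)
#' @param t,T current and maximum iteration.
#' @return scalar factor (2 at t = 0).
#' @export
csa_tau <- function(t, T) 2 * exp(-21 * (t / T)^2)

#' Capuchin jump angle theta = (3/2) r with r uniform in \[0, 1\]
#' @return scalar angle in \[0, 1.5\].
#' @export
csa_theta <- function() 1.5 * stats::runif(1)

#' Capuchin velocity update
#'
#' v <- rho v + tau z1 r1 (cbest - c) + tau z2 r2 (F - c) with r1, r2
#' uniform per coordinate.
#'
#' @param v current velocity.
#' @param pos current position c.
#' @param best personal best position cbest.
#' @param food global best (food) position F.
#' @param rho inertia, z1,z2 control constants, tau decay factor.
#' @return new velocity.
#' @export
csa_velocity <- function(v, pos, best, food, rho, z1, z2, tau) {
  d <- length(v)
  rho * v + tau * z1 * stats::runif(d) * (best - pos) +
    tau * z2 * stats::runif(d) * (food - pos)
}

#' Capuchin-search continuous minimizer
#'
#' Half the population are leaders moving by projectile-style jumps,
#' leaps, walks, swings and climbs around the food source (with a
#' random-relocation branch of probability Pr); the other half are
#' followers taking the midpoint of their own and the matching leader's
#' position. All moves are clamped to the bounds.
#'
#' @inheritParams fa_optimize
#' @param pop population size (default 45).
#' @param Pbf balance probability (default 0.8).
#' @param Pe elasticity probability (default 0.8).
#' @param Pr random-relocation probability (default 0.4).
#' @param rho velocity inertia (default 0.7).
#' @param z1,z2 velocity control constants (default 2).
#' @param g gravitational constant (9.81).
#' @return list with `best`, `fitness`, `trace`.
#' @export
csa_optimize <- function(objective, dim, lower = -1, upper = 1, pop = 45L,
                         iters = 100L, Pbf = 0.8, Pe = 0.8, Pr = 0.4,
                         rho = 0.7, z1 = 2, z2 = 2, g = 9.81, seed = 1L) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  n_lead <- max(1L, pop %/% 2L)
  with_seed(seed, {
    P <- matrix(stats::runif(pop * dim, lower, upper), pop, dim, byrow = TRUE)
    V <- matrix(0, pop, dim)
    fit <- apply(P, 1, objective)
    pbest <- P; pbest_fit <- fit
    i <- which.min(fit)
    food <- P[i, ]; food_fit <- fit[i]
    trace <- numeric(iters)
    for (t in seq_len(iters)) {
      tau <- csa_tau(t, iters)
      for (k in seq_len(n_lead)) {
        V[k, ] <- csa_velocity(V[k, ], P[k, ], pbest[k, ], food,
                               rho, z1, z2, tau)
        if (stats::runif(1) <= Pr) {
          # random relocation within the bounds
          P[k, ] <- tau * lower + stats::runif(dim) * (upper - lower)
        } else {
          eps_move <- stats::runif(1)
          theta <- csa_theta()
          proj <- V[k, ]^2 * sin(2 * theta) / g
          if (eps_move <= 0.2) {                       # jump on trees
            P[k, ] <- food + Pbf * proj
          } else if (eps_move <= 0.3) {                # leap on riverbanks
            P[k, ] <- food + Pe * Pbf * proj
          } else if (eps_move <= 0.5) {                # normal walking
            P[k, ] <- P[k, ] + V[k, ]
          } else if (eps_move <= 0.75) {               # swinging
            P[k, ] <- food + tau * Pbf * sin(2 * theta)
          } else {                                      # climbing
            P[k, ] <- food + tau * Pbf * V[k, ]
          }
        }
        P[k, ] <- pmin(pmax(P[k, ], lower), upper)
      }
      if (pop > n_lead) for (k in (n_lead + 1L):pop) {
        leader <- P[k - n_lead, ]
        P[k, ] <- pmin(pmax(0.5 * (leader + P[k, ]), lower), upper)
      }
      fit <- apply(P, 1, objective)
      imp <- fit < pbest_fit
      pbest[imp, ] <- P[imp, , drop = FALSE]; pbest_fit[imp] <- fit[imp]
      i <- which.min(fit)
      if (fit[i] < food_fit) { food_fit <- fit[i]; food <- P[i, ] }
      trace[t] <- food_fit
    }
    list(best = food, fitness = food_fit,
         trace = if (iters > 0) trace else food_fit)
  })
}

#' Tune the hidden layer of a weighted ELM with a swarm optimizer
#'
#' The decision vector is the flattened D x d input-weight matrix plus
#' the D biases, bounded in \[-1, 1\]; the fitness of a vector is
#' 1 - UAR on the validation split of the weighted ELM trained (with
#' its closed-form output weights) from those hidden parameters. The
#' returned model is refit with the best vector found.
#'
#' @param X_train,y_train training split.
#' @param X_val,y_val validation split (must contain every class).
#' @param optimizer "fa" or "csa".
#' @param D hidden-layer size.
#' @param lambda ridge coefficient.
#' @param pop,iters optimizer budget.
#' @param seed RNG seed.
#' @return an `elm_model` with optimized hidden parameters.
#' @export
optimize_welm <- function(X_train, y_train, X_val, y_val,
                          optimizer = c("fa", "csa"), D = 100L, lambda = 0.1,
                          pop = 20L, iters = 30L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  y_train <- as.character(y_train); y_val <- as.character(y_val)
  if (!all(unique(y_train) %in% unique(y_val)) ||
      !all(unique(y_val) %in% unique(y_train)))
    stop("validation split must contain every training class", call. = FALSE)
  d <- ncol(X_train)
  dim_total <- D * d + D
  w <- class_weights(y_train)
  fit_from_vec <- function(vec) {
    m <- welm_from_hidden(vec, d, D, X_train, y_train, lambda, w)
    1 - uar(y_val, elm_predict(m, X_val)$labels)
  }
  res <- if (optimizer == "fa") {
    fa_optimize(fit_from_vec, dim_total, -1, 1, pop = pop, iters = iters,
                seed = seed)
  } else {
    csa_optimize(fit_from_vec, dim_total, -1, 1, pop = max(pop, 4L),
                 iters = iters, seed = seed)
  }
  welm_from_hidden(res$best, d, D, X_train, y_train, lambda, w)
}

# rebuild a weighted ELM from a flat hidden-parameter vector
welm_from_hidden <- function(vec, d, D, X, y, lambda, weights) {
  W <- matrix(vec[seq_len(D * d)], D, d)
  b <- vec[D * d + seq_len(D)]
  classes <- sort(unique(as.character(y)))
  model <- structure(list(input_weights = W, biases = b,
                          activation = "sigmoid", lambda = lambda,
                          classes = classes, kernel = NULL),
                     class = "elm_model")
  H <- hidden_activations(as.matrix(X), model)
  Tm <- one_hot_pm(as.character(y), classes)
  model$beta <- solve_beta(H, Tm, lambda, weights)
  model
}
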