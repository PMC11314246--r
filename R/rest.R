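#' Geometric REST replica ladder
#'
#' Builds a replica-exchange-with-solute-tempering temperature ladder with
#' geometric spacing `T_i = T0 * (Tmax/T0)^(i/(n-1))` and scaling factors
#' `beta_i = T0 / T_i`.  The first replica has `beta = 1` (the physically
#' relevant replica); betas decrease strictly to `T0/Tmax`.
#'
#' @param T0 Base temperature, K.
#' @param Tmax Top effective temperature, K.
#' @param n_replicas Number of replicas (>= 2).
#'
#' @return An object of class `ps_ladder`: a tibble with columns `replica`,
#'   `temperature` (K) and `beta`.
#'
#' @examples
#' build_ladder(300, 440, 12)
#' @export
build_ladder <- function(T0 = 300, Tmax = 440, n_replicas = 12) {
  if (!(Tmax > T0 && T0 > 0)) abort("Require Tmax > T0 > 0.")
  if (n_replicas < 2) abort("At least 2 replicas are required.")
  i <- seq_len(n_replicas) - 1L
  temps <- T0 * (Tmax / T0)^(i / (n_replicas - 1L))
  temps[1] <- T0; temps[n_replicas] <- Tmax  # endpoints exact
  out <- tibble(replica = i + 1L, temperature = temps, beta = T0 / temps)
  class(out) <- c("ps_ladder", class(out))
  attr(out, "T0") <- T0
  out
}

#' @export
print.ps_ladder <- function(x, ...) {
  cat("<ps_ladder> ", nrow(x), " replicas, ",
      format(x$temperature[1]), "-", format(x$temperature[nrow(x)]),
      " K\n  scaling factors: ",
      paste0(format(round(x$beta, 3)), " (", round(x$temperature), " K)",
             collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Energy decomposition into solute/solvent terms
#'
#' @param epp,eps,ess Protein-protein, protein-solvent and solvent-solvent
#'   interaction energies, kcal/mol.
#' @return An object of class `ps_decomp` (named list).
#' @export
energy_decomposition <- function(epp, eps, ess) {
  vals <- c(epp = epp, eps = eps, ess = ess)
  if (any(!is.finite(vals))) abort("Energy components must be finite.")
  structure(as.list(vals), class = "ps_decomp")
}

#' REST-scaled potential energy
#'
#' Applies solute tempering to an energy decomposition:
#' `E_i = beta * Epp + sqrt(beta) * Eps + Ess`.  At `beta = 1` this is the
#' unscaled potential.
#'
#' @param decomp A `ps_decomp` from [energy_decomposition()].
#' @param beta Scaling factor in (0, 1].
#' @return Scaled energy, kcal/mol.
#'
#' @examples
#' scale_energy(energy_decomposition(10, 20, 5), 0.64)  # 27.4
#' @export
scale_energy <- function(decomp, beta) {
  stopifnot(inherits(decomp, "ps_decomp"))
  if (beta <= 0 || beta > 1) abort("beta must lie in (0, 1].")
  beta * decomp$epp + sqrt(beta) * decomp$eps + decomp$ess
}

#' Metropolis exchange probability between two REST replicas
#'
#' Probability of swapping the configurations held by replicas i and j under
#' the scaled-Hamiltonian Metropolis rule at the common bath temperature:
#' `min(1, exp(-Delta / kB T0))` with
#' `Delta = [E_i(x_j) + E_j(x_i)] - [E_i(x_i) + E_j(x_j)]`,
#' where `E_k(x)` scales configuration x's decomposition with replica k's
#' beta.
#'
#' @param decomp_i,decomp_j Energy decompositions of the configurations
#'   currently in replicas i and j.
#' @param beta_i,beta_j Replica scaling factors.
#' @param T0 Bath temperature, K.
#' @return Exchange probability in \[0, 1\].
#' @export
exchange_probability <- function(decomp_i, decomp_j, beta_i, beta_j,
                                 T0 = 300) {
  delta <- (scale_energy(decomp_j, beta_i) + scale_energy(decomp_i, beta_j)) -
    (scale_energy(decomp_i, beta_i) + scale_energy(decomp_j, beta_j))
  min(1, exp(-delta / (kB_KCAL * T0)))
}

# Toy landscape: double-well "protein" coordinate x with barrier height
# `barrier` kcal/mol and minima at +-1, harmonically coupled to a harmonic
# "solvent" coordinate y.
toy_energies <- function(x, y, barrier = 5, kc = 1, ks = 1) {
  list(
    epp = barrier * (x^2 - 1)^2,
    eps = 0.5 * kc * (x - y)^2,
    ess = 0.5 * ks * y^2
  )
}

#' Toy solute-tempering demonstration
#'
#' Runs Metropolis dynamics of a one-dimensional double-well "protein"
#' coordinate (barrier `barrier` kcal/mol between minima at x = -1 and
#' x = +1) coupled to a harmonic "solvent" coordinate, across a REST ladder
#' with configuration swaps attempted between a random neighbouring pair
#' every `exchange_every` steps.  The landscape is symmetric in
#' (x, y) -> (-x, -y), so the analytic occupancy of each well in the
#' beta = 1 replica is exactly 1/2.
#'
#' @param ladder A `ps_ladder` (use a single-row ladder via
#'   `build_ladder`'s first replica for a no-exchange reference, or set
#'   `exchange = FALSE`).
#' @param n_steps Metropolis steps per replica.
#' @param exchange_every Steps between exchange attempts.
#' @param exchange Attempt exchanges at all.
#' @param barrier Double-well barrier height, kcal/mol.
#' @param kc,ks Coupling and solvent force constants, kcal/mol.
#' @param step Proposal standard deviation for both coordinates.
#' @param burn_in Fraction of initial steps excluded from the reported
#'   occupancy and crossing statistics (all samples are still returned).
#' @param T0 Bath temperature, K.
#' @param seed Integer seed.
#'
#' @return An object of class `ps_rest`: list with `samples` (tibble:
#'   `step`, `replica`, `beta`, `x`, `y`), `exchange` (tibble per
#'   neighbouring pair: `pair`, `attempts`, `accepted`, `rate`),
#'   `crossings` (sign changes of x in the beta = 1 replica after burn-in)
#'   and `occupancy` (post-burn-in fraction of beta = 1 samples with
#'   x > 0).  `tidy()`
#'   returns the exchange table, `glance()` a one-row summary.
#' @export
toy_rest_run <- function(ladder, n_steps = 2000, exchange_every = 5,
                         exchange = TRUE, barrier = 5, kc = 1, ks = 1,
                         step = 0.35, burn_in = 0.25,
                         T0 = attr(ladder, "T0") %||% 300, seed = 1) {
  stopifnot(inherits(ladder, "ps_ladder"))
  set.seed(seed)
  nr <- nrow(ladder)
  betas <- ladder$beta
  kt <- kB_KCAL * T0
  # all replicas start in the x = -1 well
  x <- rep(-1, nr); y <- rep(-1, nr)
  e_of <- function(x, y, b) {
    t <- toy_energies(x, y, barrier, kc, ks)
    b * t$epp + sqrt(b) * t$eps + t$ess
  }
  e_now <- e_of(x, y, betas)

  xs <- matrix(NA_real_, n_steps, nr)
  ys <- matrix(NA_real_, n_steps, nr)
  ex_attempts <- integer(max(nr - 1L, 1L))
  ex_accepted <- integer(max(nr - 1L, 1L))

  for (s in seq_len(n_steps)) {
    # coordinate moves, all replicas at once
    for (coord in 1:2) {
      if (coord == 1) {
        prop_x <- x + rnorm(nr, sd = step); prop_y <- y
      } else {
        prop_x <- x; prop_y <- y + rnorm(nr, sd = step)
      }
      e_prop <- e_of(prop_x, prop_y, betas)
      acc <- runif(nr) < exp(-(e_prop - e_now) / kt)
      x[acc] <- prop_x[acc]; y[acc] <- prop_y[acc]
      e_now[acc] <- e_prop[acc]
    }
    # exchange attempt between a random neighbouring pair
    if (exchange && nr > 1L && s %% exchange_every == 0L) {
      i <- sample.int(nr - 1L, 1L)
      j <- i + 1L
      di <- do.call(energy_decomposition,
                    toy_energies(x[i], y[i], barrier, kc, ks))
      dj <- do.call(energy_decomposition,
                    toy_energies(x[j], y[j], barrier, kc, ks))
      p <- exchange_probability(di, dj, betas[i], betas[j], T0)
      ex_attempts[i] <- ex_attempts[i] + 1L
      if (runif(1) < p) {
        ex_accepted[i] <- ex_accepted[i] + 1L
        tmp <- c(x[i], y[i])
        x[i] <- x[j]; y[i] <- y[j]
        x[j] <- tmp[1]; y[j] <- tmp[2]
        e_now[c(i, j)] <- e_of(x[c(i, j)], y[c(i, j)], betas[c(i, j)])
      }
    }
    xs[s, ] <- x; ys[s, ] <- y
  }

  samples <- tibble(
    step = rep(seq_len(n_steps), nr),
    replica = rep(seq_len(nr), each = n_steps),
    beta = rep(betas, each = n_steps),
    x = as.vector(xs),
    y = as.vector(ys)
  )
  x1 <- xs[seq.int(floor(burn_in * n_steps) + 1L, n_steps), 1]
  exchange_tab <- if (nr > 1L) {
    tibble(
      pair = paste0(seq_len(nr - 1L), "-", seq.int(2L, nr)),
      attempts = ex_attempts,
      accepted = ex_accepted,
      rate = ifelse(ex_attempts > 0, ex_accepted / ex_attempts, NA_real_)
    )
  } else {
    tibble(pair = character(), attempts = integer(), accepted = integer(),
           rate = numeric())
  }
  structure(
    list(
      samples = samples,
      exchange = exchange_tab,
      crossings = sum(diff(sign(x1[x1 != 0])) != 0),
      occupancy = mean(x1 > 0),
      seed = seed, T0 = T0, barrier = barrier
    ),
    class = "ps_rest"
  )
}

#' @export
print.ps_rest <- function(x, ...) {
  cat("<ps_rest> ", length(unique(x$samples$replica)), " replicas x ",
      max(x$samples$step), " steps; ", x$crossings,
      " barrier crossings at beta = 1; right-well occupancy ",
      format(x$occupancy, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ps_rest <- function(x, ...) x$exchange

#' @export
glance.ps_rest <- function(x, ...) {
  tibble(
    n_steps = max(x$samples$step),
    n_replicas = length(unique(x$samples$replica)),
    crossings = x$crossings,
    occupancy_right = x$occupancy,
    exchange_rate = if (nrow(x$exchange)) {
      sum(x$exchange$accepted) / max(sum(x$exchange$attempts), 1L)
    } else {
      NA_real_
    },
    seed = x$seed
  )
}
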